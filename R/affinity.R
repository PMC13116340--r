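# Affinity-matrix data model: replicate-table I/O, aggregation with QC
# flags, outlier screening under an additive two-way model, heatmap score
# binning, and bootstrap-stability clustering.

#' Read a replicate docking-score table from CSV
#'
#' Expects columns `compound`, `target`, `replicate`, `score` (kcal/mol);
#' an optional `class` column carries the compound class label.
#'
#' @param path CSV file path.
#' @return A replicate-table `data.frame`.
#' @export
read_replicate_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound", "target", "replicate", "score")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("replicate table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(tab$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$score))))[1]
    stop(sprintf("non-numeric score at data line %d", bad), call. = FALSE)
  }
  if (any(!is.finite(tab$score))) {
    stop(sprintf("non-finite score at data line %d",
                 which(!is.finite(tab$score))[1]), call. = FALSE)
  }
  key <- paste(tab$compound, tab$target, tab$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (compound, target, replicate) at data line %d",
                 which(duplicated(key))[1]), call. = FALSE)
  }
  tab
}

#' Aggregate docking replicates into an affinity matrix
#'
#' Each (compound, target) pair is summarised by the arithmetic mean of its
#' replicate scores; the sample SD across replicates (0 for a single
#' replicate) is kept alongside, and a QC flag marks pairs whose SD reaches
#' `sd_threshold` (default 0.15 kcal/mol, the reproducibility bound used
#' for triplicate docking panels). The input must cover the complete
#' compound-by-target cross product; gaps are an error, not imputed.
#'
#' @param table replicate table (see [read_replicate_table()]).
#' @param sd_threshold QC flag threshold on the replicate SD (kcal/mol).
#' @return An object of class `affinity_matrix`: list with `scores`
#'   (compound x target mean matrix), `replicate_sd`, `qc_flag`, and an
#'   optional named `class_label` vector.
#' @export
aggregate_replicates <- function(table, sd_threshold = 0.15) {
  if (!nrow(table)) stop("replicate table is empty", call. = FALSE)
  compounds <- unique(table$compound)
  targets <- unique(table$target)
  full <- expand.grid(compound = compounds, target = targets,
                      stringsAsFactors = FALSE)
  have <- unique(paste(table$compound, table$target, sep = "\r"))
  want <- paste(full$compound, full$target, sep = "\r")
  gaps <- full[!(want %in% have), , drop = FALSE]
  if (nrow(gaps)) {
    stop(sprintf("incomplete matrix; missing pair(s): %s",
                 paste(paste(gaps$compound, gaps$target, sep = "/"),
                       collapse = ", ")), call. = FALSE)
  }
  scores <- matrix(NA_real_, length(compounds), length(targets),
                   dimnames = list(compounds, targets))
  sds <- scores
  agg_mean <- tapply(table$score, list(table$compound, table$target), mean)
  agg_sd <- tapply(table$score, list(table$compound, table$target),
                   function(x) if (length(x) > 1L) stats::sd(x) else 0)
  scores[] <- agg_mean[compounds, targets]
  sds[] <- agg_sd[compounds, targets]
  class_label <- NULL
  if ("class" %in% names(table)) {
    class_label <- vapply(compounds, function(cc) {
      unique(table$class[table$compound == cc])[1]
    }, character(1))
  }
  affinity_matrix(scores, replicate_sd = sds, qc_flag = sds >= sd_threshold,
                  class_label = class_label)
}

#' Construct an affinity matrix
#'
#' @param scores numeric compound x target matrix of mean docking scores
#'   (kcal/mol), with dimnames.
#' @param replicate_sd matrix of replicate SDs (defaults to zero).
#' @param qc_flag logical matrix of QC flags (defaults to all `FALSE`).
#' @param class_label optional named character vector, compound -> class.
#' @return An object of class `affinity_matrix`.
#' @export
affinity_matrix <- function(scores, replicate_sd = NULL, qc_flag = NULL,
                            class_label = NULL) {
  if (!is.matrix(scores) || is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("scores must be a matrix with compound rownames and target colnames",
         call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  replicate_sd <- replicate_sd %||% (scores * 0)
  qc_flag <- qc_flag %||% (scores * 0 > 0)
  if (any(replicate_sd < 0)) stop("replicate_sd must be >= 0", call. = FALSE)
  if (!is.null(class_label)) {
    class_label <- class_label[rownames(scores)]
  }
  structure(list(scores = scores, replicate_sd = replicate_sd,
                 qc_flag = qc_flag, class_label = class_label),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("Affinity matrix: %d compounds x %d targets (kcal/mol)\n",
              nrow(x$scores), ncol(x$scores)))
  cat(sprintf("QC-flagged pairs (replicate SD over threshold): %d\n",
              sum(x$qc_flag)))
  print(round(x$scores, 2), ...)
  invisible(x)
}

#' @export
summary.affinity_matrix <- function(object, ...) {
  means <- colMeans(object$scores)
  sds <- apply(object$scores, 2, stats::sd)
  out <- data.frame(target = colnames(object$scores),
                    mean = means, sd = sds, row.names = NULL)
  class(out) <- c("summary.affinity_matrix", class(out))
  out
}

#' @export
as.matrix.affinity_matrix <- function(x, ...) x$scores

#' Export an affinity matrix as wide CSV
#'
#' Compounds as rows, targets as columns, values rounded to 2 decimals.
#'
#' @param matrix an `affinity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_affinity_matrix <- function(matrix, path) {
  utils::write.csv(round(matrix$scores, 2), path, quote = FALSE)
  invisible(path)
}

#' Screen an affinity matrix for outlying and influential cells
#'
#' Fits the additive two-way model `score ~ compound + target` by least
#' squares and screens the residuals: cells with |z| above `z_threshold`
#' (z = residual / residual SD) are reported as outliers, and cells whose
#' Cook's distance exceeds `influence_threshold` (default 4 / number of
#' cells) as influential. Screening residuals rather than raw scores keeps
#' target-level mean shifts -- the panel's own main effect -- from masking
#' or mimicking outliers.
#'
#' @param matrix an `affinity_matrix` with >= 2 compounds and >= 2 targets.
#' @param z_threshold |z| cutoff (default 3).
#' @param influence_threshold Cook's distance cutoff (default `4/n_cells`).
#' @return An object of class `outlier_report`: list with data.frames
#'   `z_outliers` (compound, target, z_value) and `influential`
#'   (compound, target, cooks_distance), plus the thresholds used.
#' @export
detect_outliers <- function(matrix, z_threshold = 3,
                            influence_threshold = NULL) {
  sc <- matrix$scores
  if (nrow(sc) < 2L || ncol(sc) < 2L) {
    stop("need >= 2 compounds and >= 2 targets for the additive fit",
         call. = FALSE)
  }
  n_cells <- length(sc)
  influence_threshold <- influence_threshold %||% (4 / n_cells)
  long <- data.frame(
    compound = factor(rep(rownames(sc), ncol(sc))),
    target = factor(rep(colnames(sc), each = nrow(sc))),
    score = as.vector(sc)
  )
  fit <- stats::lm(score ~ compound + target, data = long)
  res <- stats::residuals(fit)
  s <- stats::sd(res)
  # an (almost) exactly additive matrix has no outliers; guard against
  # z-scores built from pure rounding noise
  degenerate <- s <= 1e-8 * max(1, stats::sd(long$score))
  z <- if (degenerate) res * 0 else res / s
  cd <- if (degenerate) res * 0 else stats::cooks.distance(fit)
  cd[!is.finite(cd)] <- 0
  zi <- which(abs(z) > z_threshold)
  ci <- which(cd > influence_threshold)
  structure(list(
    z_outliers = data.frame(compound = as.character(long$compound[zi]),
                            target = as.character(long$target[zi]),
                            z_value = unname(z[zi])),
    influential = data.frame(compound = as.character(long$compound[ci]),
                             target = as.character(long$target[ci]),
                             cooks_distance = unname(cd[ci])),
    z_threshold = z_threshold,
    influence_threshold = influence_threshold
  ), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier screen: %d cell(s) with |z| > %g; %d influential (Cook's d > %.4g)\n",
              nrow(x$z_outliers), x$z_threshold, nrow(x$influential),
              x$influence_threshold))
  if (nrow(x$z_outliers)) print(x$z_outliers)
  invisible(x)
}

#' Heatmap score bins
#'
#' Half-open intervals `(low, high]` over the given breaks; scores outside
#' the break range are clamped into the nearest terminal bin.
#'
#' @param breaks strictly increasing numeric breaks
#'   (default `c(-12, -10, -7, -4, -1)` kcal/mol).
#' @param labels per-interval labels (default `"(low, high]"`).
#' @return An object of class `heatmap_bins`.
#' @export
heatmap_bins <- function(breaks = c(-12, -10, -7, -4, -1), labels = NULL) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  n <- length(breaks) - 1L
  labels <- labels %||% sprintf("(%g, %g]", breaks[-length(breaks)], breaks[-1])
  if (length(labels) != n) stop("need one label per interval", call. = FALSE)
  structure(list(breaks = breaks, labels = labels), class = "heatmap_bins")
}

#' Bin a docking score into a heatmap interval
#'
#' @param score numeric vector of finite scores (kcal/mol).
#' @param bins a [heatmap_bins()].
#' @return Character vector of interval labels.
#' @export
bin_score <- function(score, bins = heatmap_bins()) {
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  idx <- findInterval(score, bins$breaks, left.open = TRUE,
                      rightmost.closed = FALSE)
  # findInterval with left.open: idx 0 below lowest break, n+1 above highest;
  # scores exactly at the lowest break get idx 0 too -> clamp both ends.
  idx <- pmin(pmax(idx, 1L), length(bins$labels))
  bins$labels[idx]
}

#' Hierarchical clustering with bootstrap co-clustering stability
#'
#' Complete-linkage agglomerative clustering on Euclidean distances over
#' rows (compounds) and columns (targets). Row co-clustering stability is
#' the fraction of `n_boot` bootstrap resamples of the columns (sampled
#' with replacement) in which each compound pair lands in the same cluster
#' when the row tree is cut at `k`.
#'
#' @param matrix an `affinity_matrix` with >= 3 compounds.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param k number of clusters at which trees are cut (default 2).
#' @return An object of class `cluster_result`: `row_tree`, `col_tree`
#'   (hclust objects), `row_order`, `col_order`, and `costability`
#'   (symmetric compound x compound matrix of co-clustering fractions).
#' @export
cluster_with_bootstrap <- function(matrix, n_boot = 1000L, seed = 1L, k = 2L) {
  sc <- matrix$scores
  if (nrow(sc) < 3L) stop("need >= 3 compounds to cluster", call. = FALSE)
  row_tree <- stats::hclust(stats::dist(sc), method = "complete")
  col_tree <- stats::hclust(stats::dist(t(sc)), method = "complete")
  n <- nrow(sc)
  co <- matrix(0, n, n, dimnames = list(rownames(sc), rownames(sc)))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(sc), replace = TRUE)
      bs <- sc[, cols, drop = FALSE]
      cl <- stats::cutree(stats::hclust(stats::dist(bs), method = "complete"), k = k)
      same <- outer(cl, cl, "==")
      co <- co + same
    }
  })
  co <- co / n_boot
  structure(list(row_tree = row_tree, col_tree = col_tree,
                 row_order = row_tree$order, col_order = col_tree$order,
                 costability = co, n_boot = n_boot, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Complete-linkage clustering (%d bootstrap resamples, cut at k = %d)\n",
              x$n_boot, x$k))
  cat("Row order:", paste(x$row_tree$labels[x$row_order], collapse = ", "), "\n")
  invisible(x)
}
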