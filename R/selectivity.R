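# Selectivity statistics: paired and class-stratified target comparisons
# with Bonferroni control and paired-design effect sizes, SI/SPI indices,
# the one-sample SI test, and the combined CK1d+PINK1 risk ranking.

#' Statistical configuration for panel comparisons
#'
#' @param alpha_family family-wise alpha (default 0.05).
#' @param m_target_comparisons Bonferroni divisor for pairwise target
#'   comparisons (default 6, i.e. C(4,2) for a four-target panel).
#' @param m_class_comparisons Bonferroni divisor for per-target class
#'   comparisons (default 8).
#' @param control_target control kinase id (default `"TIE2"`).
#' @return An object of class `stat_config`.
#' @export
stat_config <- function(alpha_family = 0.05, m_target_comparisons = 6L,
                        m_class_comparisons = 8L, control_target = "TIE2") {
  if (alpha_family <= 0 || alpha_family >= 1) {
    config_error("alpha_family must lie in (0, 1)")
  }
  if (m_target_comparisons < 1 || m_class_comparisons < 1) {
    config_error("comparison counts must be >= 1")
  }
  structure(list(alpha_family = alpha_family,
                 m_target_comparisons = as.integer(m_target_comparisons),
                 m_class_comparisons = as.integer(m_class_comparisons),
                 control_target = control_target),
            class = "stat_config")
}

#' Bonferroni-adjusted alpha
#'
#' @param alpha family-wise alpha.
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) config_error("m must be >= 1")
  alpha / m
}

bonferroni_p <- function(p, m) pmin(1, p * m)

effect_label <- function(d) {
  a <- abs(d)
  if (a >= 0.8) "large" else if (a >= 0.5) "medium" else if (a >= 0.2) "small"
  else "below-small"
}

#' Paired comparison of two targets across the compound panel
#'
#' Two-sided paired t-test on per-compound differences (target `a` minus
#' target `b`), with the Bonferroni-adjusted p-value and alpha, the paired
#' effect size `d_z = mean(diff) / sd(diff)`, and a Shapiro-Wilk normality
#' p-value on the differences. Zero-variance differences are an error:
#' fabricating a p-value for a degenerate contrast would silently corrupt
#' simulation suites.
#'
#' @param matrix an `affinity_matrix`.
#' @param target_a,target_b target column names.
#' @param config a [stat_config()].
#' @return An object of class `paired_test`, a one-row list with fields
#'   `target_pair`, `n`, `mean_diff`, `t_statistic`, `p_raw`, `p_adjusted`,
#'   `alpha_adjusted`, `cohens_d`, `effect_label`, `shapiro_p`,
#'   `significant`.
#' @export
paired_comparison <- function(matrix, target_a, target_b,
                              config = stat_config()) {
  sc <- matrix$scores
  for (tg in c(target_a, target_b)) {
    if (!tg %in% colnames(sc)) {
      stop(sprintf("target '%s' not in matrix", tg), call. = FALSE)
    }
  }
  d <- sc[, target_a] - sc[, target_b]
  n <- length(d)
  if (n < 3L) stop("need >= 3 compounds for a paired comparison", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop(sprintf("per-compound differences %s - %s have zero variance",
                 target_a, target_b), call. = FALSE)
  }
  tt <- stats::t.test(d, mu = 0)
  m <- config$m_target_comparisons
  dz <- mean(d) / stats::sd(d)
  p_adj <- bonferroni_p(tt$p.value, m)
  alpha_adj <- bonferroni_alpha(config$alpha_family, m)
  structure(list(
    target_pair = c(target_a, target_b), n = n,
    mean_diff = unname(mean(d)),
    t_statistic = unname(tt$statistic),
    p_raw = tt$p.value, p_adjusted = p_adj, alpha_adjusted = alpha_adj,
    cohens_d = dz, effect_label = effect_label(dz),
    shapiro_p = stats::shapiro.test(d)$p.value,
    significant = tt$p.value < alpha_adj
  ), class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t-test %s vs %s: mean diff %.2f kcal/mol, t = %.3f (n = %d)\n",
              x$target_pair[1], x$target_pair[2], x$mean_diff, x$t_statistic, x$n))
  cat(sprintf("  p = %.3g (Bonferroni-adjusted %.3g, alpha_adj = %.4g)%s\n",
              x$p_raw, x$p_adjusted, x$alpha_adjusted,
              if (x$significant) " *" else ""))
  cat(sprintf("  d_z = %.2f (%s), Shapiro-Wilk p = %.3g\n",
              x$cohens_d, x$effect_label, x$shapiro_p))
  invisible(x)
}

#' All pairwise target comparisons for a panel
#'
#' One [paired_comparison()] per unordered target pair; the Bonferroni
#' divisor is the number of pairs (6 for four targets).
#'
#' @param matrix an `affinity_matrix` with >= 2 targets.
#' @param config a [stat_config()]; its `m_target_comparisons` is replaced
#'   by the actual pair count.
#' @return List of `paired_test` objects, named `"a_vs_b"`.
#' @export
panel_comparisons <- function(matrix, config = stat_config()) {
  targets <- colnames(matrix$scores)
  if (length(targets) < 2L) stop("need >= 2 targets", call. = FALSE)
  pairs <- utils::combn(targets, 2, simplify = FALSE)
  config$m_target_comparisons <- length(pairs)
  out <- lapply(pairs, function(pr) {
    paired_comparison(matrix, pr[1], pr[2], config)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  out
}

#' Welch tests of compound class per target
#'
#' For each target, compares the two compound classes (e.g. upstream
#' SMO-directed agents vs downstream modulators) with Welch's unequal-
#' variance t-test, reports the Welch-Satterthwaite degrees of freedom, a
#' Brown-Forsythe (median-centred Levene) homoscedasticity p-value, and the
#' Bonferroni-adjusted p-value using `m_class_comparisons`.
#'
#' @param matrix an `affinity_matrix` whose `class_label` names exactly two
#'   classes, each with >= 2 compounds.
#' @param config a [stat_config()].
#' @return List of objects of class `welch_test`, one per target.
#' @export
class_stratified_comparisons <- function(matrix, config = stat_config()) {
  cls <- matrix$class_label
  if (is.null(cls) || any(is.na(cls))) {
    stop("class_label must be defined for every compound", call. = FALSE)
  }
  lv <- unique(cls)
  if (length(lv) != 2L) stop("exactly two compound classes required", call. = FALSE)
  if (any(table(cls) < 2L)) {
    stop("each class needs >= 2 compounds", call. = FALSE)
  }
  m <- config$m_class_comparisons
  alpha_adj <- bonferroni_alpha(config$alpha_family, m)
  out <- lapply(colnames(matrix$scores), function(tg) {
    a <- matrix$scores[cls == lv[1], tg]
    b <- matrix$scores[cls == lv[2], tg]
    tt <- stats::t.test(a, b, var.equal = FALSE)
    lev <- car::leveneTest(
      c(a, b) ~ factor(rep(lv, c(length(a), length(b)))), center = stats::median
    )
    structure(list(
      target = tg, class_a = lv[1], class_b = lv[2],
      class_a_mean = mean(a), class_b_mean = mean(b),
      mean_diff = mean(a) - mean(b),
      t_statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, p_adjusted = bonferroni_p(tt$p.value, m),
      alpha_adjusted = alpha_adj,
      levene_p = lev[["Pr(>F)"]][1]
    ), class = "welch_test")
  })
  names(out) <- colnames(matrix$scores)
  out
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test at %s (%s vs %s): diff %.2f kcal/mol, t = %.3f, df = %.1f, p = %.3g\n",
              x$target, x$class_a, x$class_b, x$mean_diff, x$t_statistic,
              x$df, x$p_raw))
  invisible(x)
}

#' Selectivity and specificity indices
#'
#' Per compound, the selectivity index
#' `SI = (Affinity_CK1d + Affinity_PINK1) / 2 - Affinity_TIE2` (more
#' negative = stronger preference for the developmental kinases over the
#' control) and the specificity index `SPI = |Affinity_CK1d -
#' Affinity_PINK1|` (low SPI = balanced dual engagement).
#'
#' @param matrix an `affinity_matrix`.
#' @param dev_targets the two developmental kinase columns
#'   (default `c("CK1d", "PINK1")`).
#' @param control the control kinase column (default `"TIE2"`).
#' @return A `data.frame` with columns `compound`, `si`, `spi`, in matrix
#'   compound order.
#' @export
compute_indices <- function(matrix, dev_targets = c("CK1d", "PINK1"),
                            control = "TIE2") {
  sc <- matrix$scores
  needed <- c(dev_targets, control)
  missing <- setdiff(needed, colnames(sc))
  if (length(missing)) {
    stop(sprintf("target(s) not in matrix: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  si <- (sc[, dev_targets[1]] + sc[, dev_targets[2]]) / 2 - sc[, control]
  spi <- abs(sc[, dev_targets[1]] - sc[, dev_targets[2]])
  data.frame(compound = rownames(sc), si = unname(si), spi = unname(spi),
             stringsAsFactors = FALSE)
}

#' One-sample t-test of the mean selectivity index against zero
#'
#' @param indices output of [compute_indices()] (or any data.frame with an
#'   `si` column).
#' @return List with `mean_si`, `sd_si`, `n`, `t_statistic`, `p_value`.
#' @export
si_panel_test <- function(indices) {
  si <- indices$si
  if (length(si) < 3L) stop("need >= 3 compounds", call. = FALSE)
  if (stats::sd(si) == 0) stop("SI values have zero variance", call. = FALSE)
  tt <- stats::t.test(si, mu = 0)
  list(mean_si = mean(si), sd_si = stats::sd(si), n = length(si),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Rank compounds by combined developmental-kinase affinity
#'
#' Orders compounds by the sum of their affinities at the named nodes
#' (default PINK1 + CK1d), most negative (highest predicted developmental
#' risk) first. Exact ties are broken lexicographically by compound id and
#' flagged. If `reference_order` is supplied and disagrees with the
#' computed order (on their common compounds), a warning documents the
#' discrepancy rather than silently adopting either ordering.
#'
#' @param matrix an `affinity_matrix`.
#' @param nodes target columns to sum (default `c("PINK1", "CK1d")`).
#' @param reference_order optional character vector: an externally reported
#'   ranking to compare against.
#' @return A `data.frame` with columns `compound`, `combined_score`,
#'   `rank`, `tied`, ordered by increasing `combined_score`.
#' @export
risk_rank <- function(matrix, nodes = c("PINK1", "CK1d"),
                      reference_order = NULL) {
  sc <- matrix$scores
  missing <- setdiff(nodes, colnames(sc))
  if (length(missing)) {
    stop(sprintf("target(s) not in matrix: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  combined <- rowSums(sc[, nodes, drop = FALSE])
  ord <- order(combined, rownames(sc))
  out <- data.frame(compound = rownames(sc)[ord],
                    combined_score = unname(combined[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$combined_score) |
    duplicated(out$combined_score, fromLast = TRUE)
  if (!is.null(reference_order)) {
    common <- intersect(reference_order, out$compound)
    if (length(common) >= 2L &&
        !identical(out$compound[out$compound %in% common], common)) {
      warning(sprintf(
        paste("computed risk ranking (%s) disagrees with the supplied",
              "reference order (%s) on the common compounds; the computed",
              "ranking follows the combined affinity sums"),
        paste(out$compound[out$compound %in% common], collapse = " > "),
        paste(common, collapse = " > ")), call. = FALSE)
    }
  }
  out
}

#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk on a single sample (e.g. paired differences) and, when two
#' groups are given, a Brown-Forsythe (median-centred Levene) test. These
#' are reported alongside the main tests and never gate them.
#'
#' @param x numeric vector (single sample), or the first group.
#' @param y optional second group.
#' @return List with `shapiro_p` and (when `y` is given) `levene_p`.
#' @export
assumption_checks <- function(x, y = NULL) {
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined",
                              call. = FALSE)
  out <- list(shapiro_p = stats::shapiro.test(x)$p.value)
  if (!is.null(y)) {
    g <- factor(rep(c("a", "b"), c(length(x), length(y))))
    lev <- car::leveneTest(c(x, y) ~ g, center = stats::median)
    out$levene_p <- lev[["Pr(>F)"]][1]
  }
  out
}
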