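# Gene-set integration: GMT / plain-list readers, exact Venn region
# decomposition, staged intersection/union/filter pipelines, and subset
# fractions. Symbols are compared case-insensitively after uppercasing; no
# alias or identifier mapping is attempted.

#' Read gene sets from GMT or plain-list files
#'
#' GMT: one set per line, `name<TAB>description<TAB>symbol...`. Plain list:
#' one symbol per line, the set named after the file. Symbols are
#' uppercased and deduplicated; duplicates are reported via a message.
#'
#' @param paths file paths.
#' @param format `"gmt"` or `"list"`.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(paths, format = c("gmt", "list")) {
  format <- match.arg(format)
  sets <- list()
  for (path in paths) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    lines <- readLines(path)
    if (format == "gmt") {
      lines <- lines[nzchar(lines)]
      if (!length(lines)) {
        warning(sprintf("empty gene-set file: %s", path), call. = FALSE)
        next
      }
      for (ln in lines) {
        fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(fields) < 2L) {
          stop(sprintf("malformed GMT line in %s: %s", path, ln), call. = FALSE)
        }
        sym <- toupper(fields[-(1:2)])
        sym <- sym[nzchar(sym)]
        if (anyDuplicated(sym)) {
          message(sprintf("duplicate symbol(s) in set '%s': %s", fields[1],
                          paste(unique(sym[duplicated(sym)]), collapse = ", ")))
        }
        sets[[fields[1]]] <- sort(unique(sym))
      }
    } else {
      nm <- tools::file_path_sans_ext(basename(path))
      sym <- toupper(trimws(lines))
      sym <- sym[nzchar(sym)]
      if (!length(sym)) warning(sprintf("empty gene-set file: %s", path),
                                call. = FALSE)
      if (anyDuplicated(sym)) {
        message(sprintf("duplicate symbol(s) in set '%s': %s", nm,
                        paste(unique(sym[duplicated(sym)]), collapse = ", ")))
      }
      sets[[nm]] <- sort(unique(sym))
    }
  }
  sets
}

#' Canonical Venn region label
#'
#' @param set_names character vector of set names forming the region.
#' @return Sorted names joined with `"&"`.
#' @export
venn_region_label <- function(set_names) {
  paste(sort(set_names), collapse = "&")
}

#' Exact Venn decomposition of a gene-set collection
#'
#' Assigns every member of the union to exactly one exclusive region (the
#' subset of sets that contain it), so that region counts sum to the union
#' size. Regions are labelled by their sorted set names joined with `"&"`;
#' all `2^k - 1` regions are reported, empty ones included.
#'
#' @param sets named list of character vectors (1--10 sets; more is refused
#'   as a combinatorial guard).
#' @return An object of class `venn_decomposition`: list with `counts`
#'   (named integer vector per region) and `members` (named list).
#' @export
venn_decompose <- function(sets) {
  k <- length(sets)
  if (k < 1L) stop("need at least one set", call. = FALSE)
  if (k > 10L) stop("refusing to decompose more than 10 sets", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names", call. = FALSE)
  }
  sets <- lapply(sets, function(x) unique(toupper(x)))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, names(sets)))
  # all non-empty subsets of set names
  nm <- names(sets)
  subsets <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(nm, m, simplify = FALSE)
  }), recursive = FALSE)
  labels <- vapply(subsets, venn_region_label, character(1))
  members <- stats::setNames(vector("list", length(subsets)), labels)
  if (length(universe)) {
    sig <- apply(membership, 1, function(row) venn_region_label(nm[row]))
    for (i in seq_along(labels)) {
      members[[i]] <- sort(universe[sig == labels[i]])
    }
  } else {
    members[] <- list(character(0))
  }
  counts <- vapply(members, length, integer(1))
  structure(list(counts = counts, members = members, set_names = nm),
            class = "venn_decomposition")
}

#' @export
print.venn_decomposition <- function(x, ...) {
  cat(sprintf("Venn decomposition over %d set(s); union size %d\n",
              length(x$set_names), sum(x$counts)))
  nz <- x$counts[x$counts > 0]
  if (length(nz)) print(nz)
  invisible(x)
}

#' Run a staged gene-set integration
#'
#' Applies the stages of `spec` in order. Each stage is a list with
#' `name`, `operation` (`"intersection"`, `"union"`, or `"filter-by-set"`)
#' and `operands` (set names resolvable in the collection or in earlier
#' stage results). `filter-by-set` keeps members of the first operand that
#' also occur in the union of the remaining operands.
#'
#' @param sets named list of character vectors.
#' @param spec list of stage lists.
#' @return List with `final` (character vector) and `trace` (data.frame of
#'   per-stage output sizes).
#' @export
run_integration <- function(sets, spec) {
  if (!length(spec)) stop("integration spec needs >= 1 stage", call. = FALSE)
  env <- lapply(sets, function(x) unique(toupper(x)))
  trace <- data.frame(stage = character(0), operation = character(0),
                      size = integer(0), stringsAsFactors = FALSE)
  result <- character(0)
  for (st in spec) {
    op <- st$operation
    if (!op %in% c("intersection", "union", "filter-by-set")) {
      stop(sprintf("unknown operation '%s' in stage '%s'", op, st$name),
           call. = FALSE)
    }
    missing <- setdiff(st$operands, names(env))
    if (length(missing)) {
      stop(sprintf("stage '%s': unknown set name(s): %s", st$name,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    ops <- env[st$operands]
    result <- switch(op,
      intersection = Reduce(intersect, ops),
      union = sort(unique(unlist(ops, use.names = FALSE))),
      `filter-by-set` = intersect(ops[[1]],
                                  unique(unlist(ops[-1], use.names = FALSE)))
    )
    result <- sort(unique(result))
    env[[st$name]] <- result
    trace <- rbind(trace, data.frame(stage = st$name, operation = op,
                                     size = length(result),
                                     stringsAsFactors = FALSE))
  }
  list(final = result, trace = trace)
}

#' Fraction of a denominator set covered, as a percentage
#'
#' `100 * |numerator intersect denominator| / |denominator|` when sets are
#' given, or `100 * n / d` for plain sizes, rounded half-away-from-zero to
#' `digits` decimals (default nearest integer, matching reporting such as
#' 255 of 474 kinome genes = 54\%).
#'
#' @param numerator character vector (a set) or a single count.
#' @param denominator character vector (a set) or a single count.
#' @param digits decimal places (default 0).
#' @return Numeric percentage in `[0, 100]`.
#' @export
subset_fraction <- function(numerator, denominator, digits = 0) {
  if (is.numeric(numerator) && is.numeric(denominator)) {
    n <- numerator
    d <- denominator
  } else {
    denominator <- unique(toupper(denominator))
    numerator <- unique(toupper(numerator))
    n <- length(intersect(numerator, denominator))
    d <- length(denominator)
  }
  if (d <= 0) stop("denominator must be non-empty", call. = FALSE)
  round_half_up(100 * n / d, digits)
}
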