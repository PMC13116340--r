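# Synthetic-data generators: replicate docking tables, tool-prediction
# tables, gene universes with exact Venn structure, and motif-bearing
# protein sequences. These emulate the statistical structure the analysis
# assumes so every downstream stage is testable without docking runs or
# web-tool queries.

#' Configuration for the replicate docking-score generator
#'
#' Defines the mean structure of a compound-by-target docking panel. Scores
#' for compound \eqn{i} (class \eqn{c}) at target \eqn{j} are generated as
#' \deqn{s_{ijr} = \mu_j + \delta_{cj} + u_i + w_{ij} + \epsilon_{ijr}}
#' with a compound random effect \eqn{u_i \sim N(0, \sigma_u^2)} shared
#' across targets (inducing the within-compound correlation that makes
#' paired target comparisons more powerful than unpaired ones), a
#' target-specific deviation \eqn{w_{ij}}, and replicate noise
#' \eqn{\epsilon_{ijr} \sim N(0, \sigma_{rep}^2)}. `target_sds` gives the
#' \emph{total} between-compound SD per target; the target-specific residual
#' SD is derived as \eqn{\sqrt{\mathrm{target\_sd}_j^2 - \sigma_u^2}}, so
#' `compound_sd` must not exceed the smallest `target_sds` entry.
#'
#' @param target_means named numeric, mean score per target (kcal/mol).
#' @param target_sds named numeric, total between-compound SD per target
#'   (kcal/mol); names must match `target_means`.
#' @param class_offsets named list: class -> named numeric per-target
#'   additive shift (kcal/mol). Classes default to zero shift.
#' @param n_compounds_per_class named integer, compounds per class.
#' @param n_replicates integer >= 1, docking replicates per pair.
#' @param replicate_sd within-pair replicate noise SD (kcal/mol).
#' @param compound_sd SD of the shared per-compound random effect.
#' @return An object of class `generator_config`.
#' @seealso [generate_replicate_table()], [panel_generator_config()]
#' @export
generator_config <- function(target_means,
                             target_sds,
                             class_offsets = list(),
                             n_compounds_per_class = c(panel = 17L),
                             n_replicates = 3L,
                             replicate_sd = 0.05,
                             compound_sd = 0) {
  if (is.null(names(target_means)) || is.null(names(target_sds))) {
    config_error("target_means and target_sds must be named numeric vectors")
  }
  if (!setequal(names(target_means), names(target_sds))) {
    config_error("target_means and target_sds must have identical names")
  }
  target_sds <- target_sds[names(target_means)]
  if (any(target_sds < 0) || replicate_sd < 0 || compound_sd < 0) {
    config_error("all SDs must be >= 0")
  }
  if (compound_sd > min(target_sds) + 1e-12) {
    config_error("compound_sd (%.3g) exceeds the smallest target SD (%.3g)",
                 compound_sd, min(target_sds))
  }
  if (length(n_replicates) != 1L || n_replicates < 1) {
    config_error("n_replicates must be a single integer >= 1")
  }
  if (is.null(names(n_compounds_per_class)) || any(n_compounds_per_class < 1)) {
    config_error("n_compounds_per_class must be a named vector of counts >= 1")
  }
  for (cls in names(class_offsets)) {
    off <- class_offsets[[cls]]
    if (!all(names(off) %in% names(target_means))) {
      config_error("class_offsets for '%s' name unknown target(s): %s", cls,
                   paste(setdiff(names(off), names(target_means)), collapse = ", "))
    }
  }
  if (!all(names(class_offsets) %in% names(n_compounds_per_class))) {
    config_error("class_offsets refer to classes absent from n_compounds_per_class")
  }
  structure(
    list(
      target_means = target_means,
      target_sds = target_sds,
      class_offsets = class_offsets,
      n_compounds_per_class = n_compounds_per_class,
      n_replicates = as.integer(n_replicates),
      replicate_sd = replicate_sd,
      compound_sd = compound_sd
    ),
    class = "generator_config"
  )
}

#' Default panel-calibrated generator configuration
#'
#' Reproduces the study conditions of the 17-compound x 4-target
#' cross-docking panel: per-target means CK1d -8.34, PINK1 -8.80,
#' SMO -7.56, TIE2 -6.76 kcal/mol with between-compound SDs
#' 1.06/1.19/0.81/0.76, two compound classes (9 upstream SMO-directed
#' agents, 8 downstream modulators), triplicate replicates with 0.05
#' kcal/mol replicate noise, and a 1.11 kcal/mol upstream-vs-downstream
#' offset at PINK1 (the only between-class difference reported), weighted
#' so the overall PINK1 panel mean is unchanged.
#'
#' @return A `generator_config`.
#' @export
panel_generator_config <- function() {
  n_up <- 9L
  n_dn <- 8L
  pink1_gap <- 1.11 # upstream binds PINK1 more strongly (more negative)
  generator_config(
    target_means = c(CK1d = -8.34, PINK1 = -8.80, SMO = -7.56, TIE2 = -6.76),
    target_sds = c(CK1d = 1.06, PINK1 = 1.19, SMO = 0.81, TIE2 = 0.76),
    class_offsets = list(
      upstream = c(PINK1 = -pink1_gap * n_dn / (n_up + n_dn)),
      downstream = c(PINK1 = pink1_gap * n_up / (n_up + n_dn))
    ),
    n_compounds_per_class = c(upstream = n_up, downstream = n_dn),
    n_replicates = 3L,
    replicate_sd = 0.05,
    compound_sd = 0.60
  )
}

#' Generate a replicate docking-score table
#'
#' Simulates per-replicate docking scores under the mean structure of a
#' [generator_config()]. Deterministic given `seed`.
#'
#' @param config a `generator_config`.
#' @param seed integer seed.
#' @return A `data.frame` with columns `compound`, `target`, `replicate`,
#'   `score` (kcal/mol) and a `class` column with the compound class label.
#' @export
generate_replicate_table <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  targets <- names(config$target_means)
  classes <- names(config$n_compounds_per_class)
  compounds <- character(0)
  compound_class <- character(0)
  for (cls in classes) {
    n <- config$n_compounds_per_class[[cls]]
    ids <- sprintf("%s_%02d", cls, seq_len(n))
    compounds <- c(compounds, ids)
    compound_class <- c(compound_class, rep(cls, n))
  }
  names(compound_class) <- compounds

  resid_sd <- sqrt(pmax(config$target_sds^2 - config$compound_sd^2, 0))

  with_seed(seed, {
    u <- stats::rnorm(length(compounds), 0, config$compound_sd)
    names(u) <- compounds
    rows <- vector("list", length(compounds) * length(targets))
    k <- 0L
    for (ci in seq_along(compounds)) {
      cmp <- compounds[ci]
      cls <- compound_class[[cmp]]
      off <- config$class_offsets[[cls]]
      for (tj in seq_along(targets)) {
        tg <- targets[tj]
        shift <- if (!is.null(off) && tg %in% names(off)) off[[tg]] else 0
        pair_mean <- config$target_means[[tg]] + shift + u[[cmp]] +
          stats::rnorm(1, 0, resid_sd[[tg]])
        scores <- pair_mean + stats::rnorm(config$n_replicates, 0, config$replicate_sd)
        k <- k + 1L
        rows[[k]] <- data.frame(
          compound = cmp, target = tg,
          replicate = seq_len(config$n_replicates),
          score = scores, class = cls,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Tool performance profile for the prediction-table generator
#'
#' @param tool_code one of the seven tool codes `KP, NP, PP, GP, PN, PS, UP`.
#' @param sensitivity probability that a planted true site is reported.
#' @param false_positive_rate per-candidate probability that a non-site
#'   S/T residue is reported.
#' @param isoform_aware whether the tool resolves CK1 isoforms (`PP`, `PS`
#'   and `UP` do not in the default seven-tool panel).
#' @return An object of class `tool_profile`.
#' @export
tool_profile <- function(tool_code, sensitivity = 1, false_positive_rate = 0,
                         isoform_aware = !(tool_code %in% ISOFORM_AGNOSTIC_TOOLS)) {
  if (!is_string(tool_code) || !(tool_code %in% TOOL_CODES)) {
    config_error("tool_code must be one of: %s", paste(TOOL_CODES, collapse = ", "))
  }
  if (sensitivity < 0 || sensitivity > 1 || false_positive_rate < 0 ||
      false_positive_rate > 1) {
    config_error("sensitivity and false_positive_rate must lie in [0, 1]")
  }
  structure(
    list(tool_code = tool_code, sensitivity = sensitivity,
         false_positive_rate = false_positive_rate,
         isoform_aware = isTRUE(isoform_aware)),
    class = "tool_profile"
  )
}

#' Default seven-tool profile set
#'
#' One [tool_profile()] per tool code, all with the given sensitivity and
#' false-positive rate.
#'
#' @param sensitivity,false_positive_rate shared performance parameters.
#' @return A list of seven `tool_profile` objects.
#' @export
default_tool_profiles <- function(sensitivity = 1, false_positive_rate = 0) {
  lapply(TOOL_CODES, tool_profile, sensitivity = sensitivity,
         false_positive_rate = false_positive_rate)
}

#' Generate synthetic per-tool phosphosite prediction tables
#'
#' Stands in for the outputs of independent web prediction tools. Each tool
#' reports every planted true site with probability `sensitivity`, and every
#' other S/T residue with probability `false_positive_rate`. Tyrosines are
#' never reported. Deterministic given `seed`.
#'
#' @param sequence a [protein_sequence()] (or plain residue string, in which
#'   case the protein id defaults to `"QUERY"`).
#' @param true_sites integer positions of planted sites; must be S or T.
#' @param profiles list of [tool_profile()] objects with unique tool codes.
#' @param seed integer seed.
#' @return A `data.frame` with columns `tool`, `protein`, `position`,
#'   `residue`, `kinase_label`.
#' @export
generate_tool_predictions <- function(sequence, true_sites, profiles, seed) {
  sequence <- as_protein_sequence(sequence)
  res <- strsplit(sequence$residues, "")[[1]]
  true_sites <- as.integer(true_sites)
  if (any(true_sites < 1 | true_sites > length(res))) {
    stop("true site position out of sequence range", call. = FALSE)
  }
  bad <- true_sites[!res[true_sites] %in% c("S", "T")]
  if (length(bad)) {
    stop(sprintf("true site(s) at non-S/T residue: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  codes <- vapply(profiles, function(p) p$tool_code, character(1))
  if (anyDuplicated(codes)) {
    config_error("duplicate tool codes in profiles")
  }
  st_positions <- which(res %in% c("S", "T"))
  non_sites <- setdiff(st_positions, true_sites)

  with_seed(seed, {
    rows <- list()
    for (p in profiles) {
      hit_true <- true_sites[stats::runif(length(true_sites)) < p$sensitivity]
      hit_fp <- non_sites[stats::runif(length(non_sites)) < p$false_positive_rate]
      pos <- sort(c(hit_true, hit_fp))
      if (length(pos)) {
        rows[[length(rows) + 1L]] <- data.frame(
          tool = p$tool_code, protein = sequence$protein_id,
          position = pos, residue = res[pos],
          kinase_label = "CK1d", stringsAsFactors = FALSE
        )
      }
    }
    if (!length(rows)) {
      return(data.frame(tool = character(0), protein = character(0),
                        position = integer(0), residue = character(0),
                        kinase_label = character(0), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate named gene sets with exact Venn region cardinalities
#'
#' Builds a collection of gene-symbol sets whose exclusive Venn region
#' counts equal the requested specification, for round-trip testing of
#' [venn_decompose()].
#'
#' @param region_cardinalities named integer vector; each name is a region
#'   label written as set names joined by `"&"` (e.g. `"A&B"`), each value
#'   the number of symbols exclusive to that region.
#' @param set_names character vector of all set names (defaults to the
#'   names appearing in the region labels).
#' @param seed integer seed (controls symbol shuffling only).
#' @return A named list of character vectors (a gene-set collection).
#' @export
generate_gene_universe <- function(region_cardinalities, set_names = NULL,
                                   seed = 1L) {
  if (length(region_cardinalities) &&
      is.null(names(region_cardinalities))) {
    config_error("region_cardinalities must be named by region label")
  }
  labels <- names(region_cardinalities)
  if (anyDuplicated(labels)) config_error("duplicate region labels")
  members <- strsplit(labels, "&", fixed = TRUE)
  set_names <- set_names %||% sort(unique(unlist(members)))
  for (m in members) {
    if (!length(m) || !all(m %in% set_names)) {
      config_error("region label must be a non-empty subset of set names")
    }
  }
  if (any(region_cardinalities < 0)) config_error("cardinalities must be >= 0")

  total <- sum(region_cardinalities)
  with_seed(seed, {
    symbols <- sprintf("GENE%05d", sample.int(max(total, 1L) * 3L, total))
    sets <- stats::setNames(rep(list(character(0)), length(set_names)), set_names)
    at <- 0L
    for (i in seq_along(labels)) {
      k <- region_cardinalities[[i]]
      if (k == 0L) next
      sym <- symbols[(at + 1L):(at + k)]
      at <- at + k
      for (s in members[[i]]) sets[[s]] <- c(sets[[s]], sym)
    }
    lapply(sets, function(x) sort(unique(x)))
  })
}

#' Generate a protein sequence with planted CK1 substrate motifs
#'
#' Plants primed (`S/T` with an `S/T` three residues upstream) and
#' acidic-cluster (`S/T` preceded by >= 3 Asp/Glu within the five upstream
#' residues) motif positions into a background that excludes S, T, D and E,
#' so that [scan_ck1_motifs()] finds exactly the planted positions.
#'
#' @param length sequence length.
#' @param primed_positions positions to carry a primed motif (>= 4).
#' @param acidic_positions positions to carry an acidic-cluster motif (>= 4).
#' @param seed integer seed.
#' @param protein_id sequence identifier.
#' @return A [protein_sequence()].
#' @export
generate_motif_sequence <- function(length, primed_positions = integer(0),
                                    acidic_positions = integer(0), seed = 1L,
                                    protein_id = "SYNTH") {
  primed_positions <- as.integer(primed_positions)
  acidic_positions <- as.integer(acidic_positions)
  all_pos <- c(primed_positions, acidic_positions)
  if (any(all_pos < 4L) || any(all_pos > length)) {
    stop("planted positions must lie in [4, length]", call. = FALSE)
  }
  if (anyDuplicated(all_pos)) {
    stop("primed and acidic position sets must be disjoint", call. = FALSE)
  }
  background <- setdiff(AMINO_ACIDS, c("S", "T", "D", "E"))
  with_seed(seed, {
    res <- sample(background, length, replace = TRUE)
    for (p in primed_positions) {
      res[p] <- sample(c("S", "T"), 1)
      res[p - 3L] <- sample(c("S", "T"), 1)
    }
    for (p in acidic_positions) {
      res[p] <- sample(c("S", "T"), 1)
      res[(p - 3L):(p - 1L)] <- sample(c("D", "E"), 3, replace = TRUE)
    }
    protein_sequence(protein_id, paste(res, collapse = ""))
  })
}

#' Write a replicate table to CSV
#'
#' @param table a replicate table data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_replicate_table <- function(table, path) {
  utils::write.csv(table[, c("compound", "target", "replicate", "score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a gene-set collection as GMT
#'
#' One line per set: name, description tab field, then member symbols.
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a protein sequence as FASTA
#'
#' @param sequence a [protein_sequence()].
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequence, path, width = 60L) {
  sequence <- as_protein_sequence(sequence)
  n <- nchar(sequence$residues)
  starts <- seq(1L, n, by = width)
  chunks <- substring(sequence$residues, starts, pmin(starts + width - 1L, n))
  writeLines(c(paste0(">", sequence$protein_id), chunks), path)
  invisible(path)
}
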