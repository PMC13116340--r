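# End-to-end orchestration: a single config drives data generation or
# loading, QC, selectivity statistics, indices, node assignment, phenotype
# prediction, consensus calling and gene-set integration, producing a
# report bundle with a complete provenance block.

#' Run the analysis pipeline from a configuration
#'
#' Stages run in dependency order: data (generated or read) -> QC
#' (aggregation + outlier screen) -> statistics and indices -> node
#' assignment, phenotype prediction and decision tree. The consensus and
#' gene-set stages are independent and run when configured. A partial
#' configuration runs only the stages it requests. Identical config and
#' seed give identical bundles.
#'
#' @param config a named list (or path to a YAML file) with any of:
#'   \describe{
#'     \item{replicate_csv / generator}{path to a replicate CSV, or
#'       `"panel"` / a [generator_config()] for synthetic data.}
#'     \item{sd_threshold}{QC threshold (default 0.15).}
#'     \item{stat}{list of [stat_config()] arguments.}
#'     \item{thresholds}{list of [rule_thresholds()] arguments.}
#'     \item{dev_targets, control_target}{index/test target names.}
#'     \item{consensus}{list with `sequence` (FASTA path or `"synthetic_smo"`),
#'       `predictions` (TSV path or `"published_smo"`), `threshold`,
#'       `isoform_filter`.}
#'     \item{genesets}{list with `gmt` (path) and optional `integration`
#'       stages and `fraction` (numerator/denominator set names).}
#'   }
#' @param seed integer seed for any generated data.
#' @return An object of class `report_bundle`.
#' @export
run_pipeline <- function(config, seed = 1L) {
  if (is_string(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)

  bundle <- list()
  stat_cfg <- do.call(stat_config, config$stat %||% list())
  thr <- do.call(rule_thresholds, config$thresholds %||% list())
  dev_targets <- config$dev_targets %||% c("CK1d", "PINK1")
  control <- config$control_target %||% stat_cfg$control_target

  wants_affinity <- !is.null(config$replicate_csv) || !is.null(config$generator)
  if (!is.null(config$phenotype_stage) && isTRUE(config$phenotype_stage) &&
      !wants_affinity) {
    config_error("phenotype stage requested without an affinity data source")
  }

  if (wants_affinity) {
    table <- if (!is.null(config$replicate_csv)) {
      read_replicate_table(config$replicate_csv)
    } else {
      gen <- config$generator
      if (is_string(gen) && gen == "panel") gen <- panel_generator_config()
      if (is.list(gen) && !inherits(gen, "generator_config")) {
        gen$target_means <- unlist(gen$target_means)
        gen$target_sds <- unlist(gen$target_sds)
        gen$n_compounds_per_class <- unlist(gen$n_compounds_per_class)
        if (!is.null(gen$class_offsets)) {
          gen$class_offsets <- lapply(gen$class_offsets, unlist)
        }
        gen <- do.call(generator_config, gen)
      }
      generate_replicate_table(gen, seed = seed)
    }
    matrix <- aggregate_replicates(table, config$sd_threshold %||% 0.15)
    bundle$affinity_summary <- summary(matrix)
    bundle$matrix <- matrix
    bundle$outliers <- detect_outliers(matrix)
    bundle$paired_tests <- panel_comparisons(matrix, stat_cfg)
    if (!is.null(matrix$class_label) &&
        length(unique(matrix$class_label)) == 2L) {
      bundle$class_tests <- class_stratified_comparisons(matrix, stat_cfg)
    }
    have <- all(c(dev_targets, control) %in% colnames(matrix$scores))
    if (have) {
      bundle$indices <- compute_indices(matrix, dev_targets, control)
      bundle$si_test <- si_panel_test(bundle$indices)
      bundle$risk_ranking <- risk_rank(matrix, nodes = rev(dev_targets))
    }
    node_targets <- config$node_targets %||%
      stats::setNames(c("SMO", dev_targets), c("SMO", dev_targets))
    if (all(node_targets %in% colnames(matrix$scores))) {
      assignments <- assign_panel(matrix, node_targets, thr)
      bundle$assignments <- assignments
      catalog <- config$catalog %||% default_phenotype_catalog()
      bundle$phenotypes <- lapply(assignments, predict_phenotypes,
                                  catalog = catalog)
      bundle$tree <- build_decision_tree(assignments, catalog, matrix)
    }
  }

  if (!is.null(config$consensus)) {
    cc <- config$consensus
    seq <- if (identical(cc$sequence, "synthetic_smo")) synthetic_smo_sequence()
      else read_fasta(cc$sequence)
    preds <- if (identical(cc$predictions, "published_smo")) {
      published_smo_predictions()
    } else {
      utils::read.delim(cc$predictions, stringsAsFactors = FALSE)
    }
    cm <- build_consensus_matrix(preds, seq,
                                 isoform_filter = cc$isoform_filter %||% TRUE)
    calls <- call_consensus_sites(cm, threshold = cc$threshold %||% 3L)
    bundle$consensus <- classify_sites(calls, seq)
  }

  if (!is.null(config$genesets)) {
    gs <- config$genesets
    sets <- read_gene_sets(gs$gmt, format = "gmt")
    bundle$venn <- venn_decompose(sets)
    if (!is.null(gs$integration)) {
      bundle$integration <- run_integration(sets, gs$integration)
    }
    if (!is.null(gs$fraction)) {
      bundle$kinome_fraction <- subset_fraction(sets[[gs$fraction$numerator]],
                                                sets[[gs$fraction$denominator]])
    }
  }

  cfgfile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(rapply(config, unclass, how = "replace"), cfgfile)
  bundle$provenance <- list(
    seed = seed,
    config_hash = unname(tools::md5sum(cfgfile)),
    thresholds = unclass(thr),
    stat = unclass(stat_cfg),
    package_version = as.character(utils::packageVersion("dockpanel")),
    r_version = R.version.string
  )
  unlink(cfgfile)
  structure(bundle, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Report bundle with sections:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  cat(sprintf("Provenance: seed %s, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}

fmt_kcal <- function(x) sprintf("%.2f", x)
fmt_p <- function(x) sprintf("%.3g", x)

bundle_tables <- function(bundle) {
  tabs <- list()
  if (!is.null(bundle$affinity_summary)) {
    s <- as.data.frame(bundle$affinity_summary)
    s$mean <- fmt_kcal(s$mean); s$sd <- fmt_kcal(s$sd)
    tabs$affinity_summary <- s
  }
  if (!is.null(bundle$paired_tests)) {
    tabs$paired_tests <- do.call(rbind, lapply(bundle$paired_tests, function(x) {
      data.frame(target_a = x$target_pair[1], target_b = x$target_pair[2],
                 n = x$n, mean_diff = fmt_kcal(x$mean_diff),
                 t = sprintf("%.3f", x$t_statistic), p_raw = fmt_p(x$p_raw),
                 p_adjusted = fmt_p(x$p_adjusted),
                 cohens_d = sprintf("%.2f", x$cohens_d),
                 effect = x$effect_label, shapiro_p = fmt_p(x$shapiro_p),
                 significant = x$significant, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(bundle$class_tests)) {
    tabs$class_tests <- do.call(rbind, lapply(bundle$class_tests, function(x) {
      data.frame(target = x$target, mean_diff = fmt_kcal(x$mean_diff),
                 t = sprintf("%.3f", x$t_statistic),
                 df = sprintf("%.1f", x$df), p_raw = fmt_p(x$p_raw),
                 p_adjusted = fmt_p(x$p_adjusted), levene_p = fmt_p(x$levene_p),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(bundle$indices)) {
    ix <- bundle$indices
    ix$si <- fmt_kcal(ix$si); ix$spi <- fmt_kcal(ix$spi)
    tabs$indices <- ix
  }
  if (!is.null(bundle$risk_ranking)) {
    rr <- bundle$risk_ranking
    rr$combined_score <- fmt_kcal(rr$combined_score)
    tabs$risk_ranking <- rr
  }
  if (!is.null(bundle$assignments)) {
    tabs$assignments <- do.call(rbind, lapply(bundle$assignments, function(a) {
      data.frame(compound = a$compound_id,
                 assigned_nodes = paste(a$assigned_nodes, collapse = "+"),
                 dominant = paste(a$dominant_nodes, collapse = "+"),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(bundle$consensus)) tabs$consensus <- bundle$consensus
  if (!is.null(bundle$integration)) tabs$integration_trace <- bundle$integration$trace
  tabs
}

#' Write a report bundle to files
#'
#' One file per table per requested format under `dir`: TSV
#' (`<table>.tsv`), JSON (`report.json`, re-readable), and markdown
#' (`report.md`). kcal/mol values are written to 2 decimals and p-values
#' with 3 significant digits; the provenance block (seed, config hash,
#' thresholds, versions) is always included.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("tsv", "json", "markdown")`.
#' @return Character vector of files written, invisibly.
#' @export
emit_report <- function(bundle, dir, formats = c("tsv", "json", "markdown")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- bundle_tables(bundle)
  written <- character(0)
  if ("tsv" %in% formats) {
    for (nm in names(tabs)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(tabs[[nm]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(c(tabs, list(provenance = bundle$provenance)), f,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  if ("markdown" %in% formats) {
    f <- file.path(dir, "report.md")
    md <- c("# Cross-docking panel report", "")
    for (nm in names(tabs)) {
      tab <- tabs[[nm]]
      md <- c(md, paste("##", nm), "",
              paste("|", paste(names(tab), collapse = " | "), "|"),
              paste("|", paste(rep("---", ncol(tab)), collapse = " | "), "|"),
              vapply(seq_len(nrow(tab)), function(i) {
                paste("|", paste(unlist(tab[i, ]), collapse = " | "), "|")
              }, character(1)), "")
    }
    md <- c(md, "## provenance", "",
            sprintf("- seed: %s", bundle$provenance$seed),
            sprintf("- config hash: %s", bundle$provenance$config_hash),
            sprintf("- strong/moderate cutoffs: %s / %s kcal/mol",
                    bundle$provenance$thresholds$strong_cutoff,
                    bundle$provenance$thresholds$moderate_cutoff),
            sprintf("- alpha: %s (m = %s target / %s class comparisons)",
                    bundle$provenance$stat$alpha_family,
                    bundle$provenance$stat$m_target_comparisons,
                    bundle$provenance$stat$m_class_comparisons),
            sprintf("- dockpanel %s, %s", bundle$provenance$package_version,
                    bundle$provenance$r_version))
    writeLines(md, f)
    written <- c(written, f)
  }
  invisible(written)
}
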