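# Reported reference values transcribed from the source study's printed
# tables and text: the per-compound docking affinities that are stated
# explicitly, the per-target panel summary statistics, the seven-tool
# consensus matrix for human SMO, and the proposed developmental-risk
# ordering. These are inputs for reanalysis, not outputs of this package.

#' Reported per-compound docking affinities
#'
#' The subset of the 17-compound x 4-target cross-docking matrix whose
#' values are printed explicitly in the source report (the full 68-cell
#' matrix is not deposited). `NA` marks unprinted cells. Purmorphamine's
#' TIE2 value (-7.5) is taken from the figure-level reporting rather than
#' the body text.
#'
#' @return A `data.frame` with columns `compound`, `class`, `SMO`, `CK1d`,
#'   `PINK1`, `TIE2` (kcal/mol).
#' @export
published_affinities <- function() {
  data.frame(
    compound = c("purmorphamine", "taladegib", "cyclopamine", "vismodegib",
                 "Thz1", "physalinB", "umbralisib", "imiquimod", "GANT61"),
    class = c("upstream", "upstream", "upstream", "upstream",
              "downstream", "downstream", "downstream", "downstream",
              "downstream"),
    SMO   = c(-9.1, -8.3, -7.6,   NA,   NA, -9.0, -8.7,   NA,   NA),
    CK1d  = c(-10.4, -9.2, -8.2,  NA, -8.7,   NA, -8.6,   NA, -8.3),
    PINK1 = c(-10.4, -10.5,  NA, -9.6, -10.3,  NA, -9.6,   NA,   NA),
    TIE2  = c(-7.5,   NA,   NA,   NA,   NA,   NA,   NA, -4.9,   NA),
    stringsAsFactors = FALSE
  )
}

#' Reported per-target panel summary statistics
#'
#' Mean +/- SD docking score per target over the 17-compound panel, as
#' printed in the body text. (The figure-level reporting gives a slightly
#' different SMO mean, -7.50 +/- 0.97, and CK1d SD, 0.86; the body-text
#' values are used here.)
#'
#' @return A `data.frame` with columns `target`, `mean`, `sd` (kcal/mol).
#' @export
published_panel_means <- function() {
  data.frame(
    target = c("CK1d", "PINK1", "SMO", "TIE2"),
    mean = c(-8.34, -8.80, -7.56, -6.76),
    sd = c(1.06, 1.19, 0.81, 0.76),
    stringsAsFactors = FALSE
  )
}

#' Reported cross-tool predictions for CK1d sites in human SMO
#'
#' The tick/dash consensus matrix for the three residues of human SMO
#' reported by at least one of the seven prediction tools, as a long
#' prediction table suitable for [build_consensus_matrix()].
#'
#' @return A `data.frame` with columns `tool`, `protein`, `position`,
#'   `residue`, `kinase_label`.
#' @export
published_smo_predictions <- function() {
  entries <- list(
    list(pos = 593L, res = "T", tools = c("KP", "NP", "PP", "GP", "PN", "PS", "UP")),
    list(pos = 615L, res = "S", tools = c("KP", "NP", "GP", "PN", "PS")),
    list(pos = 751L, res = "S", tools = c("KP", "NP", "PP"))
  )
  rows <- do.call(rbind, lapply(entries, function(e) {
    data.frame(tool = e$tools, protein = "SMO_HUMAN", position = e$pos,
               residue = e$res, kinase_label = "CK1d", stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Reported developmental-risk ordering
#'
#' The proposed rank order of predicted developmental risk by combined
#' PINK1 + CK1d affinity, as stated in the source report. Note that this
#' stated order conflicts with the printed per-compound affinity sums
#' (taladegib -19.7 vs purmorphamine -20.8 kcal/mol); [risk_rank()]
#' surfaces the conflict with a warning when given this vector as
#' `reference_order`.
#'
#' @return Character vector of compound ids, highest predicted risk first.
#' @export
published_risk_order <- function() {
  c("taladegib", "purmorphamine", "vismodegib", "Thz1", "sonidegib",
    "SAGHCl", "cyclopamine", "Cur61414", "SANT1")
}

#' Synthetic stand-in for the human SMO sequence
#'
#' A 787-residue synthetic sequence (the canonical human SMO length) with
#' primed CK1 motifs planted at the three reported consensus positions --
#' T593, S615, S751 -- so that the reported cross-tool prediction table can
#' be rebuilt and re-voted without the undeposited real sequence. This is
#' \emph{not} the human SMO sequence; it reproduces only the features the
#' consensus analysis depends on (length, residue identity and canonical
#' motif context at the three sites).
#'
#' @return A [protein_sequence()] with id `"SMO_HUMAN"`.
#' @export
synthetic_smo_sequence <- function() {
  seq <- generate_motif_sequence(787L, primed_positions = c(593L, 615L, 751L),
                                 seed = 20260405L, protein_id = "SMO_HUMAN")
  res <- strsplit(seq$residues, "")[[1]]
  res[593L] <- "T"
  res[c(615L, 751L)] <- "S"
  protein_sequence("SMO_HUMAN", paste(res, collapse = ""))
}
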