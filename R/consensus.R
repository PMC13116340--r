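# Cross-tool phosphosite consensus calling: protein sequences, CK1
# substrate-motif scanning, residue x tool consensus matrices, >=3-of-7
# voting, and primary/secondary site classification.

#' Construct a protein sequence
#'
#' @param protein_id sequence identifier.
#' @param residues residue string over the 20 standard amino-acid letters,
#'   1-based numbering.
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(protein_id, residues) {
  if (!is_string(protein_id) || !is_string(residues) || !nchar(residues)) {
    stop("protein_id and a non-empty residue string are required", call. = FALSE)
  }
  residues <- toupper(residues)
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters), AMINO_ACIDS)
  if (length(bad)) {
    stop(sprintf("non-standard residue letter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(protein_id = protein_id, residues = residues),
            class = "protein_sequence")
}

as_protein_sequence <- function(x) {
  if (inherits(x, "protein_sequence")) return(x)
  if (is_string(x)) return(protein_sequence("QUERY", x))
  stop("expected a protein_sequence or residue string", call. = FALSE)
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf(">%s (%d aa)\n", x$protein_id, nchar(x$residues)))
  invisible(x)
}

#' Read a single-record FASTA file
#'
#' @param path FASTA file path (first record is used).
#' @return A [protein_sequence()].
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    stop("not a FASTA file (missing '>' header)", call. = FALSE)
  }
  headers <- which(startsWith(lines, ">"))
  end <- if (length(headers) > 1L) headers[2] - 1L else length(lines)
  id <- sub("^>\\s*", "", lines[1])
  id <- strsplit(id, "\\s+")[[1]][1]
  protein_sequence(id, paste(lines[2:end], collapse = ""))
}

#' Scan a sequence for CK1 substrate consensus motifs
#'
#' Flags every serine/threonine position `p` that matches either canonical
#' CK1 substrate class: \emph{primed} -- an S or T at `p - 3` (priming
#' phosphorylation status is not knowable from sequence alone, so any S/T
#' counts as a potential primer); or \emph{acidic} -- at least
#' `acidic_min` Asp/Glu among the `acidic_window` residues immediately
#' upstream (window clipped at the N-terminus). Positions matching both
#' classes are reported as primed.
#'
#' @param sequence a [protein_sequence()] or residue string.
#' @param acidic_window upstream window width (default 5).
#' @param acidic_min minimum D/E count in the window (default 3).
#' @return A `data.frame` with columns `position`, `residue`,
#'   `motif_class` (`"primed"` or `"acidic"`).
#' @export
scan_ck1_motifs <- function(sequence, acidic_window = 5L, acidic_min = 3L) {
  sequence <- as_protein_sequence(sequence)
  res <- strsplit(sequence$residues, "")[[1]]
  st <- which(res %in% c("S", "T"))
  hits <- lapply(st, function(p) {
    primed <- p > 3L && res[p - 3L] %in% c("S", "T")
    lo <- max(1L, p - acidic_window)
    acidic <- p > 1L && sum(res[lo:(p - 1L)] %in% c("D", "E")) >= acidic_min
    if (primed) {
      data.frame(position = p, residue = res[p], motif_class = "primed",
                 stringsAsFactors = FALSE)
    } else if (acidic) {
      data.frame(position = p, residue = res[p], motif_class = "acidic",
                 stringsAsFactors = FALSE)
    } else {
      NULL
    }
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(position = integer(0), residue = character(0),
                      motif_class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Build a residue x tool consensus matrix from prediction tables
#'
#' Compiles per-tool phosphosite predictions into a boolean matrix with one
#' row per residue reported by at least one tool and one column per tool
#' code (tools absent from the input contribute all-FALSE columns,
#' mirroring dash entries). With `isoform_filter = TRUE`, rows coming only
#' from isoform-agnostic tools (`PP`, `PS`, `UP`) are kept only where the
#' position matches a canonical CK1 motif per [scan_ck1_motifs()] --
#' the manual motif-consistency filter applied to generic CK1-family
#' predictions. Tyrosine predictions are rejected.
#'
#' @param predictions prediction table with columns `tool`, `position`,
#'   `residue` (see [generate_tool_predictions()]).
#' @param sequence the query [protein_sequence()].
#' @param isoform_filter apply the motif filter to isoform-agnostic tools.
#' @return An object of class `consensus_matrix`: list with `residues`
#'   (data.frame `position`, `residue`) and `predicted` (logical matrix,
#'   rows = residues, columns = the seven tool codes).
#' @export
build_consensus_matrix <- function(predictions, sequence,
                                   isoform_filter = TRUE) {
  sequence <- as_protein_sequence(sequence)
  res <- strsplit(sequence$residues, "")[[1]]
  if (nrow(predictions)) {
    if (any(predictions$position < 1L | predictions$position > length(res))) {
      stop("prediction position out of sequence range", call. = FALSE)
    }
    actual <- res[predictions$position]
    if (any(!actual %in% c("S", "T"))) {
      bad <- predictions$position[!actual %in% c("S", "T")][1]
      stop(sprintf("prediction at non-S/T residue (position %d is %s)",
                   bad, res[bad]), call. = FALSE)
    }
    mism <- actual != predictions$residue
    if (any(mism)) {
      stop(sprintf("prediction residue letter disagrees with sequence at position %d",
                   predictions$position[mism][1]), call. = FALSE)
    }
    unknown <- setdiff(unique(predictions$tool), TOOL_CODES)
    if (length(unknown)) {
      stop(sprintf("unknown tool code(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
  }
  positions <- sort(unique(predictions$position))
  pred <- matrix(FALSE, length(positions), length(TOOL_CODES),
                 dimnames = list(NULL, TOOL_CODES))
  for (i in seq_len(nrow(predictions))) {
    r <- match(predictions$position[i], positions)
    pred[r, predictions$tool[i]] <- TRUE
  }
  if (isoform_filter && length(positions)) {
    motif_pos <- scan_ck1_motifs(sequence)$position
    keep_tool <- setdiff(TOOL_CODES, ISOFORM_AGNOSTIC_TOOLS)
    # a row survives if an isoform-aware tool predicts it, or the position
    # carries a canonical CK1 motif
    keep <- rowSums(pred[, keep_tool, drop = FALSE]) > 0 |
      positions %in% motif_pos
    # and isoform-agnostic ticks at motif-free positions are dropped
    drop_tick <- !(positions %in% motif_pos)
    pred[drop_tick, ISOFORM_AGNOSTIC_TOOLS] <- FALSE
    pred <- pred[keep, , drop = FALSE]
    positions <- positions[keep]
  }
  structure(list(
    residues = data.frame(position = positions,
                          residue = res[positions],
                          stringsAsFactors = FALSE),
    predicted = pred,
    protein_id = sequence$protein_id
  ), class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("Consensus matrix for %s: %d residue(s) x %d tools\n",
              x$protein_id, nrow(x$residues), ncol(x$predicted)))
  if (nrow(x$residues)) {
    disp <- ifelse(x$predicted, "✓", "—")
    rownames(disp) <- paste0(x$residues$residue, x$residues$position)
    print(as.data.frame(disp))
  }
  invisible(x)
}

#' Vote consensus phosphosites from a cross-tool matrix
#'
#' A residue is a high-confidence consensus site when it is independently
#' predicted by at least `threshold` of the seven tools (default 3).
#' Sub-threshold residues are retained with `consensus = FALSE` (recorded
#' but not considered further).
#'
#' @param matrix a [build_consensus_matrix()] result.
#' @param threshold minimum supporting tool count (default 3).
#' @return A `data.frame` of site calls: `position`, `residue`,
#'   `support_count`, `consensus`.
#' @export
call_consensus_sites <- function(matrix, threshold = 3L) {
  if (threshold < 1L) stop("threshold must be >= 1", call. = FALSE)
  support <- as.integer(rowSums(matrix$predicted))
  data.frame(position = matrix$residues$position,
             residue = matrix$residues$residue,
             support_count = support,
             consensus = support >= threshold,
             stringsAsFactors = FALSE)
}

#' Classify consensus sites into primary and secondary tiers
#'
#' A site is \emph{primary} when it is a consensus call and lies on a
#' canonical CK1 motif (primed or acidic); all other calls are
#' \emph{secondary} (sub-threshold support or non-canonical context). The
#' +/-7-residue sequence window is attached, truncated at the termini.
#'
#' @param calls output of [call_consensus_sites()].
#' @param sequence the query [protein_sequence()].
#' @param motif_hits optional precomputed [scan_ck1_motifs()] table.
#' @return `calls` with added columns `motif_class` (`"primed"`,
#'   `"acidic"`, `"none"`), `tier` (`"primary"`/`"secondary"`), `context`.
#' @export
classify_sites <- function(calls, sequence, motif_hits = NULL) {
  sequence <- as_protein_sequence(sequence)
  motif_hits <- motif_hits %||% scan_ck1_motifs(sequence)
  n <- nchar(sequence$residues)
  idx <- match(calls$position, motif_hits$position)
  calls$motif_class <- ifelse(is.na(idx), "none", motif_hits$motif_class[idx])
  calls$tier <- ifelse(calls$consensus & calls$motif_class != "none",
                       "primary", "secondary")
  calls$context <- vapply(calls$position, function(p) {
    substr(sequence$residues, max(1L, p - 7L), min(n, p + 7L))
  }, character(1))
  calls
}

#' Export a consensus matrix as a tick/dash table
#'
#' Writes a TSV mirroring the published layout: one row per residue, one
#' column per tool, ticks for predicted and em-dashes for not predicted.
#'
#' @param matrix a `consensus_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_matrix <- function(matrix, path) {
  disp <- ifelse(matrix$predicted, "✓", "—")
  out <- cbind(
    Residue = paste0(matrix$residues$residue, matrix$residues$position),
    as.data.frame(disp, stringsAsFactors = FALSE)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
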