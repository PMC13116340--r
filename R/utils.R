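# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generators take explicit seeds
#' without disturbing the caller's random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a consistent message prefix for configuration problems.
config_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Tool codes in canonical column order (seven prediction tools).
TOOL_CODES <- c("KP", "NP", "PP", "GP", "PN", "PS", "UP")

# Tools that report generic CK1-family predictions without isoform
# resolution; their rows are subject to the motif-consistency filter.
ISOFORM_AGNOSTIC_TOOLS <- c("PP", "PS", "UP")
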