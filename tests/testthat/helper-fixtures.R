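# Shared fixtures built in code.

# Small fixed affinity matrix with known structure (scores in kcal/mol).
toy_matrix <- function() {
  sc <- rbind(
    cpdA = c(SMO = -9.1, CK1d = -10.4, PINK1 = -10.4, TIE2 = -7.5),
    cpdB = c(SMO = -8.3, CK1d = -9.2, PINK1 = -10.5, TIE2 = -6.9),
    cpdC = c(SMO = -7.6, CK1d = -8.2, PINK1 = -8.0, TIE2 = -6.5),
    cpdD = c(SMO = -7.0, CK1d = -6.9, PINK1 = -7.4, TIE2 = -6.0),
    cpdE = c(SMO = -8.7, CK1d = -8.6, PINK1 = -9.6, TIE2 = -7.1)
  )
  affinity_matrix(sc, class_label = c(cpdA = "up", cpdB = "up", cpdC = "up",
                                      cpdD = "down", cpdE = "down"))
}

# Replicate table where every pair has exactly-known mean and SD.
toy_replicates <- function() {
  data.frame(
    compound = rep(c("a", "b"), each = 6),
    target = rep(rep(c("t1", "t2"), each = 3), 2),
    replicate = rep(1:3, 4),
    score = c(-10.4, -10.4, -10.4, # a/t1: mean -10.4, sd 0
              -8.0, -8.2, -8.4,    # a/t2: mean -8.2, sd 0.2
              -7.5, -7.6, -7.7,    # b/t1: mean -7.6, sd 0.1
              -6.0, -6.0, -6.0),   # b/t2
    stringsAsFactors = FALSE
  )
}

# Additive (zero-residual) matrix: mu + row effect + column effect.
additive_matrix <- function(n_row = 4, n_col = 4) {
  row_eff <- seq(-1, 1, length.out = n_row)
  col_eff <- seq(-2, 2, length.out = n_col)
  sc <- outer(row_eff, col_eff, `+`) - 8
  dimnames(sc) <- list(paste0("c", seq_len(n_row)), paste0("t", seq_len(n_col)))
  affinity_matrix(sc)
}

# Brute-force transcription of the branch-assignment rule text, written
# independently of assign_nodes(): strong (<= -8.0) always included;
# moderate (-8.0, -7.0] included iff dominant (strongest = most negative,
# within tolerance); weak (> -7.0) excluded unless no stronger affinity
# exists anywhere, in which case the dominant weak node(s) are kept.
oracle_assign <- function(scores, strong = -8, moderate = -7, tol = 0.05) {
  tier <- function(s) if (s <= strong) "strong" else if (s <= moderate) "moderate" else "weak"
  tiers <- vapply(scores, tier, character(1))
  dominant <- names(scores)[scores <= min(scores) + tol]
  keep <- character(0)
  for (nd in names(scores)) {
    if (tiers[[nd]] == "strong") keep <- c(keep, nd)
    else if (tiers[[nd]] == "moderate" && nd %in% dominant) keep <- c(keep, nd)
    else if (tiers[[nd]] == "weak" && all(tiers == "weak") && nd %in% dominant)
      keep <- c(keep, nd)
  }
  keep
}
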