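test_that("motif scanner applies the primed and acidic rules by hand-checkable cases", {
  # S at 5 with S at position 2 (p - 3): primed
  hits <- scan_ck1_motifs("ASAAS")
  expect_equal(hits[hits$position == 5, "motif_class"], "primed")
  # S at 5 with 4 acidic residues in the upstream window: acidic
  hits2 <- scan_ck1_motifs("DDEES")
  expect_equal(hits2, data.frame(position = 5L, residue = "S",
                                 motif_class = "acidic"))
  # no S/T at all
  expect_equal(nrow(scan_ck1_motifs("AAAAA")), 0)
  # both rules match: primed wins
  hits3 <- scan_ck1_motifs("DDSEES") # S at 6: S at 3 primes it; 4 D/E upstream
  expect_equal(hits3[hits3$position == 6, "motif_class"], "primed")
  # exactly 2 acidic upstream: below the >= 3 default
  expect_false(5 %in% scan_ck1_motifs("DAAES")$position)
})

test_that("consensus matrix construction validates input and applies the isoform filter", {
  seq <- generate_motif_sequence(30, primed_positions = 10, seed = 2)
  # a PP-only (isoform-agnostic) tick at a motif-free S: dropped with the
  # filter on, kept with it off
  res <- strsplit(seq$residues, "")[[1]]
  free_pos <- 20L
  res[free_pos] <- "S" # S in a motif-free background
  seq2 <- protein_sequence("X", paste(res, collapse = ""))
  preds <- data.frame(tool = c("PP", "KP"), protein = "X",
                      position = c(free_pos, 10L),
                      residue = c("S", res[10]), stringsAsFactors = FALSE)
  cm_on <- build_consensus_matrix(preds, seq2, isoform_filter = TRUE)
  expect_false(free_pos %in% cm_on$residues$position)
  cm_off <- build_consensus_matrix(preds, seq2, isoform_filter = FALSE)
  expect_true(free_pos %in% cm_off$residues$position)
  # filter soundness: every retained isoform-agnostic tick is a motif hit
  motif_pos <- scan_ck1_motifs(seq2)$position
  agn <- cm_on$predicted[, c("PP", "PS", "UP"), drop = FALSE]
  expect_true(all(cm_on$residues$position[rowSums(agn) > 0] %in% motif_pos))
  # validation errors
  badpos <- data.frame(tool = "KP", protein = "X", position = 999L,
                       residue = "S", stringsAsFactors = FALSE)
  expect_error(build_consensus_matrix(badpos, seq2), "out of sequence range")
  nonst <- data.frame(tool = "KP", protein = "X", position = 1L,
                      residue = res[1], stringsAsFactors = FALSE)
  expect_error(build_consensus_matrix(nonst, seq2), "non-S/T")
  # empty table -> empty matrix
  empty <- build_consensus_matrix(preds[0, ], seq2)
  expect_equal(nrow(empty$residues), 0)
})

test_that("consensus voting matches the reported SMO cross-tool matrix", {
  seq <- synthetic_smo_sequence()
  cm <- build_consensus_matrix(published_smo_predictions(), seq,
                               isoform_filter = TRUE)
  calls <- call_consensus_sites(cm, threshold = 3)
  expect_equal(calls$position, c(593L, 615L, 751L))
  expect_equal(calls$residue, c("T", "S", "S"))
  expect_equal(calls$support_count, c(7L, 5L, 3L))
  expect_true(all(calls$consensus))
  # per-tool ticks match the published rows
  expect_true(all(cm$predicted[cm$residues$position == 593, ]))
  expect_equal(unname(cm$predicted[cm$residues$position == 615, ]),
               c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)) # KP NP PP GP PN PS UP
  expect_equal(unname(cm$predicted[cm$residues$position == 751, ]),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("support counts equal a column-sum oracle and voting is threshold-monotone", {
  seq <- generate_motif_sequence(5000, primed_positions = seq(10, 4990, by = 10),
                                 seed = 6)
  true_sites <- seq(10, 4990, by = 10)
  profiles <- default_tool_profiles(sensitivity = 0.6, false_positive_rate = 0)
  preds <- generate_tool_predictions(seq, true_sites, profiles, seed = 31)
  cm <- build_consensus_matrix(preds, seq, isoform_filter = FALSE)
  calls <- call_consensus_sites(cm, threshold = 3)
  # oracle: brute-force tally of the prediction table itself
  tally <- table(preds$position)
  expect_equal(calls$support_count,
               as.integer(tally[as.character(calls$position)]))
  expect_equal(calls$support_count, unname(as.integer(rowSums(cm$predicted))))
  # raising the threshold never adds consensus sites
  sets <- lapply(1:7, function(k) {
    c <- call_consensus_sites(cm, threshold = k)
    c$position[c$consensus]
  })
  for (k in 2:7) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  expect_true(all(call_consensus_sites(cm, threshold = 1)$consensus))
  expect_error(call_consensus_sites(cm, threshold = 0), ">= 1")
})

test_that("perfect tool profiles recover exactly the planted sites at threshold 7", {
  seq <- generate_motif_sequence(400, primed_positions = c(50, 120, 300), seed = 12)
  preds <- generate_tool_predictions(seq, c(50, 120, 300),
                                     default_tool_profiles(1, 0), seed = 13)
  cm <- build_consensus_matrix(preds, seq, isoform_filter = TRUE)
  calls <- call_consensus_sites(cm, threshold = 7)
  expect_setequal(calls$position[calls$consensus], c(50, 120, 300))
  expect_equal(nrow(calls), 3) # no false rows at FPR 0
})

test_that("site classification assigns tiers and sequence context windows", {
  seq <- generate_motif_sequence(100, primed_positions = 40, seed = 9)
  # consensus site on the primed motif plus a consensus site off-motif
  res <- strsplit(seq$residues, "")[[1]]
  res[70] <- "S"
  seq2 <- protein_sequence("Y", paste(res, collapse = ""))
  preds <- do.call(rbind, lapply(c("KP", "NP", "GP"), function(tc) {
    data.frame(tool = tc, protein = "Y", position = c(40L, 70L),
               residue = res[c(40, 70)], stringsAsFactors = FALSE)
  }))
  cm <- build_consensus_matrix(preds, seq2, isoform_filter = FALSE)
  calls <- classify_sites(call_consensus_sites(cm, 3), seq2)
  expect_equal(calls$tier[calls$position == 40], "primary")
  expect_equal(calls$motif_class[calls$position == 70], "none")
  expect_equal(calls$tier[calls$position == 70], "secondary")
  expect_equal(nchar(calls$context[calls$position == 40]), 15)
  # window truncation at the N-terminus
  short <- protein_sequence("Z", "STAAAAAAAA")
  p2 <- data.frame(tool = "KP", protein = "Z", position = 2L, residue = "T",
                   stringsAsFactors = FALSE)
  cm2 <- build_consensus_matrix(p2, short, isoform_filter = FALSE)
  calls2 <- classify_sites(call_consensus_sites(cm2, 1), short)
  expect_equal(calls2$context, substr(short$residues, 1, 9))
  # duplicate-context convention: two positions with identical +/-7 windows
  # receive identical motif classes
  dup <- protein_sequence("D", paste0(strrep("A", 7), "SAAS", strrep("A", 7),
                                      strrep("G", 10),
                                      strrep("A", 7), "SAAS", strrep("A", 7)))
  hits <- scan_ck1_motifs(dup)
  ctx <- classify_sites(
    data.frame(position = c(11L, 39L), residue = c("S", "S"),
               support_count = c(3L, 3L), consensus = TRUE), dup)
  expect_equal(ctx$context[1], ctx$context[2])
  expect_equal(ctx$motif_class[1], ctx$motif_class[2])
})
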