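test_that("paired comparison matches the closed-form t and d_z", {
  # differences (-1, -2, -3): mean -2, SD 1, t = -2 * sqrt(3), d_z = -2
  sc <- cbind(a = c(-9, -10, -11), b = c(-8, -8, -8))
  rownames(sc) <- paste0("c", 1:3)
  m <- affinity_matrix(sc)
  res <- paired_comparison(m, "a", "b", stat_config(m_target_comparisons = 1))
  expect_equal(res$mean_diff, -2)
  expect_equal(res$t_statistic, -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$cohens_d, -2)
  expect_equal(res$effect_label, "large")
  # antisymmetry
  rev <- paired_comparison(m, "b", "a", stat_config(m_target_comparisons = 1))
  expect_equal(rev$mean_diff, -res$mean_diff)
  expect_equal(rev$t_statistic, -res$t_statistic)
  expect_equal(rev$p_raw, res$p_raw)
  # mean_diff equals the difference of column means
  expect_equal(res$mean_diff, mean(sc[, "a"]) - mean(sc[, "b"]))
  # degenerate zero-variance differences are an error, not a p-value
  expect_error(paired_comparison(m, "a", "a"), "zero variance")
  expect_error(paired_comparison(m, "a", "zz"), "not in matrix")
})

test_that("panel comparisons enumerate target pairs with Bonferroni control", {
  m <- toy_matrix()
  res <- panel_comparisons(m)
  expect_length(res, choose(4, 2))
  expect_equal(res[[1]]$alpha_adjusted, 0.05 / 6)
  expect_equal(round(res[[1]]$alpha_adjusted, 4), 0.0083)
  for (r in res) {
    expect_equal(r$p_adjusted, min(1, r$p_raw * 6))
    expect_true(r$p_adjusted >= r$p_raw)
  }
  # two targets: single comparison at the family alpha
  m2 <- affinity_matrix(m$scores[, 1:2])
  res2 <- panel_comparisons(m2)
  expect_length(res2, 1)
  expect_equal(res2[[1]]$alpha_adjusted, 0.05)
})

test_that("paired t-test holds its type-I error under the null", {
  n_sim <- 10000
  n <- 17
  cfg <- stat_config(m_target_comparisons = 1)
  set.seed(2601)
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    sc <- cbind(a = rnorm(n, -8, 1), b = rnorm(n, -8, 1))
    rownames(sc) <- paste0("c", 1:n)
    rej[i] <- paired_comparison(affinity_matrix(sc), "a", "b", cfg)$p_raw < 0.05
  }
  expect_true(abs(mean(rej) - 0.05) < 0.006)
})

test_that("class-stratified Welch tests report df, Levene p and detect no sham effects", {
  m <- toy_matrix()
  res <- class_stratified_comparisons(m, stat_config())
  expect_length(res, 4)
  expect_true(all(vapply(res, function(x) x$df > 0, logical(1))))
  expect_true(all(vapply(res, function(x) x$p_raw >= 0 && x$p_raw <= 1, logical(1))))
  expect_equal(res$SMO$p_adjusted, min(1, res$SMO$p_raw * 8))
  # identical class columns: zero difference, t = 0
  sc <- rbind(u1 = c(t1 = -8, t2 = -7), u2 = c(-9, -6),
              d1 = c(-8, -7), d2 = c(-9, -6))
  meq <- affinity_matrix(sc, class_label = c(u1 = "up", u2 = "up",
                                             d1 = "down", d2 = "down"))
  # (identical class columns make the Levene fit exact; the warning from
  # that degenerate anova is expected)
  req <- suppressWarnings(class_stratified_comparisons(meq, stat_config()))
  expect_equal(req$t1$mean_diff, 0)
  expect_equal(req$t1$t_statistic, 0)
  # a class with one member is refused
  bad <- affinity_matrix(sc, class_label = c(u1 = "up", u2 = "down",
                                             d1 = "down", d2 = "down"))
  expect_error(class_stratified_comparisons(bad, stat_config()), ">= 2")
})

test_that("between-class power at the reported PINK1 gap is in a plausible band", {
  # true offset 1.11 kcal/mol, n = 9 vs 8, SD 1.0: the median Welch p across
  # seeds should fall in a band containing marginal outcomes (p around 0.05).
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    a <- rnorm(9, -9.3, 1)
    b <- rnorm(8, -8.2, 1)
    t.test(a, b)$p.value
  }, numeric(1))
  expect_gt(median(ps), 0.001)
  expect_lt(median(ps), 0.3)
})

test_that("SI and SPI follow the printed formulas", {
  m <- toy_matrix()
  ix <- compute_indices(m)
  expect_equal(ix$compound, rownames(m$scores))
  # purmorphamine-like profile: CK1d -10.4, PINK1 -10.4, TIE2 -7.5
  expect_equal(ix$si[ix$compound == "cpdA"], (-10.4 + -10.4) / 2 - (-7.5))
  expect_equal(ix$si[ix$compound == "cpdA"], -2.9)
  expect_equal(ix$spi[ix$compound == "cpdA"], 0)
  # umbralisib-like profile: CK1d -8.6, PINK1 -9.6, TIE2 -7.0 (synthetic TIE2)
  sc <- rbind(u = c(CK1d = -8.6, PINK1 = -9.6, TIE2 = -7.0))
  ix2 <- compute_indices(affinity_matrix(sc))
  expect_equal(ix2$si, -2.1)
  expect_equal(ix2$spi, 1.0)
  # all equal -> SI = 0, SPI = 0
  ix3 <- compute_indices(affinity_matrix(rbind(z = c(CK1d = -8, PINK1 = -8, TIE2 = -8))))
  expect_equal(ix3$si, 0)
  expect_equal(ix3$spi, 0)
  expect_error(compute_indices(affinity_matrix(sc[, 1:2, drop = FALSE])),
               "not in matrix")
})

test_that("SI/SPI are invariant under a common shift of all three targets", {
  m <- toy_matrix()
  ix <- compute_indices(m)
  shifted <- m
  shifted$scores[, c("CK1d", "PINK1", "TIE2")] <-
    shifted$scores[, c("CK1d", "PINK1", "TIE2")] + 1.7
  ix2 <- compute_indices(shifted)
  expect_equal(ix2$si, ix$si)
  expect_equal(ix2$spi, ix$spi)
})

test_that("one-sample SI test matches closed form and has power at the panel effect", {
  expect_equal(si_panel_test(data.frame(si = c(-1, -2, -3)))$t_statistic,
               -2 * sqrt(3), tolerance = 1e-12)
  sym <- si_panel_test(data.frame(si = c(-1, 0, 1)))
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_error(si_panel_test(data.frame(si = rep(-2, 5))), "zero variance")
  # true mean SI -1.8, SD 0.5, n 17: essentially always rejected
  rej <- vapply(1:1000, function(s) {
    set.seed(s)
    si_panel_test(data.frame(si = rnorm(17, -1.8, 0.5)))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.99)
})

test_that("risk ranking orders by combined affinity and surfaces reference conflicts", {
  sc <- rbind(A = c(PINK1 = -10, CK1d = -10), B = c(-8, -8))
  rr <- risk_rank(affinity_matrix(sc))
  expect_equal(rr$compound, c("A", "B"))
  # exact tie: lexicographic order, both flagged
  sct <- rbind(b = c(PINK1 = -9, CK1d = -9), a = c(-9, -9))
  rrt <- risk_rank(affinity_matrix(sct))
  expect_equal(rrt$compound, c("a", "b"))
  expect_true(all(rrt$tied))
  # printed per-compound values rank purmorphamine (-20.8) above
  # taladegib (-19.7), conflicting with the reported order -> warning
  pub <- published_affinities()
  both <- pub[!is.na(pub$PINK1) & !is.na(pub$CK1d), ]
  sc2 <- as.matrix(both[, c("PINK1", "CK1d")])
  rownames(sc2) <- both$compound
  expect_warning(
    rr2 <- risk_rank(affinity_matrix(sc2), reference_order = published_risk_order()),
    "disagrees with the supplied reference order"
  )
  expect_equal(rr2$compound[1], "purmorphamine")
  expect_equal(rr2$combined_score[1], -20.8)
  expect_equal(rr2$combined_score[rr2$compound == "taladegib"], -19.7)
  # an agreeing reference emits no warning
  expect_silent(risk_rank(affinity_matrix(sc), reference_order = c("A", "B")))
})

test_that("assumption checks are calibrated near their nominal level", {
  shap <- vapply(1:1000, function(s) {
    set.seed(s); assumption_checks(rnorm(17))$shapiro_p < 0.05
  }, logical(1))
  expect_true(abs(mean(shap) - 0.05) < 0.02)
  lev <- vapply(1:1000, function(s) {
    set.seed(s + 5000)
    assumption_checks(rnorm(9), rnorm(8))$levene_p < 0.05
  }, logical(1))
  expect_true(abs(mean(lev) - 0.05) < 0.02)
  expect_error(assumption_checks(rep(1, 10)), "constant")
  expect_error(assumption_checks(c(1, 2)), "3 <= n")
})
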