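# cohort_stats: descriptives, Friedman/Wilcoxon, paired t, Spearman, ICC

test_that("describe computes type-7 quartiles and honors the normality gate", {
  d <- describe(c(1, 2, 3, 4, 5))
  expect_equal(c(d$q1, d$median, d$q3), c(2, 3, 4))
  expect_error(describe(c(1, 2)), class = "sta_validation_error")
  expect_warning(dc <- describe(rep(3, 10)), "non-normal")
  expect_equal(dc$sd, 0)
  expect_false(dc$normal)
  set.seed(31)
  dn <- describe(stats::rnorm(1000))
  expect_true(dn$normal)
  expect_lt(abs(dn$mean), 0.1)
  # strongly skewed sample triggers the median/IQR gate
  set.seed(32)
  ds <- describe(stats::rexp(100)^2)
  expect_false(ds$normal)
})

test_that("Friedman statistic matches the hand-computed fixture and the all-tied convention", {
  fr <- friedman_rank_test(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(fr$statistic, 6)
  expect_equal(fr$df, 2L)
  tied <- friedman_rank_test(matrix(5, 6L, 3L))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p, 1)
})

test_that("Wilcoxon signed-rank matches brute-force sign-flip enumeration", {
  set.seed(44)
  fixtures <- list(
    c(1.2, -0.4, 2.5, 3.1, -0.2, 0.8),              # n = 6, no ties
    c(1, 1, -1, 2, 3, -2, 4, 5),                    # n = 8, ties
    c(0, 1.5, -0.7, 2.2, 0, 3.0, -1.1),             # zeros (Pratt)
    round(stats::rnorm(8), 1))
  for (d in fixtures) {
    got <- wilcoxon_signed_rank(d)
    oracle <- wilcoxon_perm_oracle(d)
    expect_equal(got$statistic, oracle$statistic)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
  }
  # agrees with stats::wilcox.test in the clean exact case (no ties/zeros)
  d <- c(1.2, -0.4, 2.5, 3.1, -0.2, 0.8, -2.2, 0.9)
  expect_equal(wilcoxon_signed_rank(d)$p,
               stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("Friedman agrees with the within-block permutation oracle", {
  set.seed(45)
  # clear separation: all three pairwise shifts >> jitter
  strong <- cbind(AA = stats::rnorm(5, 0, 0.3), TS = stats::rnorm(5, 10, 0.3),
                  AI = stats::rnorm(5, 20, 0.3))
  got <- friedman_rank_test(strong)
  oracle <- friedman_perm_oracle(strong)
  expect_equal(got$statistic, oracle$statistic, tolerance = 1e-12)
  expect_lt(got$p, 0.05); expect_lt(oracle$p_perm, 0.05)
  # null-ish data: both clearly non-significant
  null_d <- cbind(stats::rnorm(5), stats::rnorm(5), stats::rnorm(5))
  got0 <- friedman_rank_test(null_d)
  oracle0 <- friedman_perm_oracle(null_d)
  expect_equal(got0$statistic, oracle0$statistic, tolerance = 1e-12)
  expect_gt(got0$p, 0.2); expect_gt(oracle0$p_perm, 0.2)
})

test_that("compare_three_landmarks runs the omnibus + Bonferroni battery", {
  set.seed(46)
  AA <- stats::rnorm(20, 30, 1)
  TS <- AA + 10 + stats::rnorm(20, 0, 0.5)
  AI <- AA + 20 + stats::rnorm(20, 0, 0.5)
  res <- compare_three_landmarks(AA, TS, AI)
  expect_lt(res$friedman$p, 0.05)
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adjusted < 0.05))
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, 3 * res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
  # identical samples: statistic 0, p 1, no post-hoc tests
  tied <- compare_three_landmarks(AA, AA, AA)
  expect_equal(tied$friedman$statistic, 0)
  expect_equal(tied$friedman$p, 1)
  expect_equal(nrow(tied$pairwise), 0L)
  expect_error(compare_three_landmarks(AA[1:4], TS[1:4], AI[1:4]),
               class = "sta_validation_error")
})

test_that("paired t matches the hand-computed fixture and recovers a planted offset", {
  b <- c(2, 4, 6, 8, 10); m <- c(1, 2, 3, 4, 5)   # differences 1..5
  res <- paired_t(b, m)
  expect_equal(res$mean_diff, 3)
  expect_equal(res$statistic, 3 / (stats::sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$statistic, 4.242640687, tolerance = 1e-9)
  expect_equal(res$p, stats::t.test(b, m, paired = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(paired_t(m, m + 0:4 - 2)$mean_diff, 0)
  expect_error(paired_t(b, b), class = "sta_validation_error")
  # planted bone - marker offset 13.5 deg, sd 5.9, n = 20
  set.seed(47)
  marker <- stats::rnorm(20, 27, 5)
  bone <- marker + stats::rnorm(20, 13.5, 5.9)
  rec <- paired_t(bone, marker)
  expect_lt(abs(rec$mean_diff - 13.5), 2 * 5.9 / sqrt(20))
  expect_lt(rec$p, 0.05)
})

test_that("Spearman handles monotone, reversed and hand-ranked fixtures", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rank(x, x^3)$rho, 1)
  expect_equal(spearman_rank(x, -x)$rho, -1)
  got <- spearman_rank(x, c(3, 1, 2, 5, 4))
  expect_equal(got$rho, 0.6)     # 1 - 6*8/(5*24)
  expect_equal(got$rho,
               unname(stats::cor(x, c(3, 1, 2, 5, 4), method = "spearman")))
  expect_error(spearman_rank(x, rep(1, 5)), class = "sta_validation_error")
  expect_error(spearman_rank(x[1:4], x[1:4]), class = "sta_validation_error")
})

test_that("ICC matches the aov variance-component oracle and known edge cases", {
  # identical raters, varying subjects: perfect agreement
  subj <- c(10, 12, 15, 20, 25, 31)
  perfect <- cbind(subj, subj)
  expect_equal(icc(perfect, "2,1")$icc, 1, tolerance = 1e-12)
  expect_equal(icc(perfect, "1,1")$icc, 1, tolerance = 1e-12)
  # no subject variance, raters pure disagreement: BMS = 0, icc at its -1 bound
  flip <- rbind(c(0, 1), c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 0))
  expect_equal(icc(flip, "1,1")$icc, -1)
  expect_lte(icc(flip, "2,1")$icc, 0)
  # seeded simulation: subject sd 10, rater error sd 1 -> high reliability
  set.seed(49)
  truth <- stats::rnorm(10, 50, 10)
  mat <- cbind(truth + stats::rnorm(10), truth + stats::rnorm(10))
  r21 <- icc(mat, "2,1")
  expect_gt(r21$icc, 0.9)
  expect_true(r21$ci[1] <= r21$icc && r21$icc <= r21$ci[2])
  expect_lte(r21$ci[2], 1)
  # both models agree with the aov-based variance-component oracle
  for (model in c("1,1", "2,1")) {
    for (s in 1:3) {
      set.seed(400 + s)
      truth <- stats::rnorm(8, 0, 3)
      m <- cbind(truth + stats::rnorm(8, 0.5, 1.5), truth + stats::rnorm(8, -0.5, 1.5),
                 truth + stats::rnorm(8, 0, 1.5))
      expect_equal(icc(m, model)$icc, icc_aov_oracle(m, model), tolerance = 1e-9)
    }
  }
  expect_error(icc(cbind(c(1, 2, NA, 4, 5), 1:5), "2,1"),
               class = "sta_validation_error")
})
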