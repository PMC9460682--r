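# Cohort statistics: normality-gated descriptives, Friedman + Wilcoxon
# signed-rank with Bonferroni adjustment, paired t-tests, Spearman rank
# correlation and Shrout-Fleiss intraclass correlation coefficients.
#
# Standard distribution functions (t, chi-square, F, Shapiro-Wilk
# internals) are delegated to stats; rank orchestration, the exact Wilcoxon
# null, the Friedman statistic and the ICC ANOVA algebra are implemented
# here so they can be checked against brute-force permutation oracles.

#' Descriptive summary with a normality gate
#'
#' Median and interquartile range plus mean and standard deviation, with a
#' Shapiro-Wilk normality flag (`normal` is `TRUE` when p >= alpha).
#' Reporting convention: when `normal` is `FALSE` the median/IQR is the
#' primary descriptive, otherwise the mean/SD. Quartiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param values numeric vector, n >= 3.
#' @param alpha normality-test significance level (default 0.05).
#' @return list: `n`, `median`, `q1`, `q3`, `mean`, `sd`, `shapiro_p`,
#'   `normal`.
#' @export
describe <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) sta_error("sta_validation_error", "describe() needs n >= 3, got %d", n)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  sw <- tryCatch(stats::shapiro.test(values)$p.value, error = function(e) {
    warning("Shapiro-Wilk test degenerate (", conditionMessage(e),
            "); treating sample as non-normal")
    0
  })
  list(n = n, median = q[2L], q1 = q[1L], q3 = q[3L],
       mean = mean(values), sd = stats::sd(values),
       shapiro_p = sw, normal = sw >= alpha)
}

# ---- Wilcoxon signed rank -------------------------------------------------

# Signed-rank statistic with Pratt zero handling: zeros are ranked together
# with the non-zero |differences| but their ranks are dropped from V.
signed_rank_statistic <- function(d) {
  r <- rank(abs(d))            # average ranks for ties, zeros included
  keep <- d != 0
  list(V = sum(r[keep][d[keep] > 0]), ranks = r, keep = keep)
}

# Exact null distribution of 2*V by sign-flip enumeration, as a generating
# function convolution over the (doubled, hence integer) ranks of the
# non-zero differences. Returns P(V_null >= v_lo) style tail probabilities.
exact_signed_rank_p <- function(ranks2, V2) {
  total <- sum(ranks2)
  probs <- numeric(total + 1L)   # index s+1 = probability weight of sum s
  probs[1L] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs[seq_len(total + 1L - r)])
    probs <- probs + shifted
  }
  probs <- probs / sum(probs)
  mu <- total / 2
  # two-sided: double the smaller tail (with point mass at V2 included once)
  lo <- sum(probs[seq_len(V2 + 1L)])
  hi <- sum(probs[seq.int(V2 + 1L, total + 1L)])
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on `x - y` (or on `x` alone if `y` is
#' missing). Zero differences are handled by the Pratt method (ranked with
#' the rest, then dropped from the statistic). The null distribution is
#' enumerated exactly for up to `exact_limit` non-zero differences
#' (enumeration runs over sign assignments via a generating-function
#' convolution, so ties are handled exactly too); beyond that a normal
#' approximation with tie and zero corrections is used.
#'
#' @param x,y paired numeric vectors.
#' @param exact_limit largest number of non-zero pairs for which the exact
#'   null is enumerated (default 20, covering the typical cohort size).
#' @return list: `statistic` (V, sum of positive ranks), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 20L) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  if (!length(d)) sta_error("sta_validation_error", "no finite differences")
  st <- signed_rank_statistic(d)
  nnz <- sum(st$keep)
  if (nnz == 0L) {
    return(list(statistic = 0, p = 1, method = "wilcoxon-signed-rank/all-zero"))
  }
  ranks2 <- as.integer(round(2 * st$ranks[st$keep]))
  if (nnz <= exact_limit) {
    p <- exact_signed_rank_p(ranks2, as.integer(round(2 * st$V)))
    method <- "wilcoxon-signed-rank/exact-pratt"
  } else {
    mu <- sum(ranks2) / 2 / 2          # E[V] = sum(ranks)/2 (ranks2 doubled)
    v2 <- sum((ranks2 / 2)^2) / 4      # Var[V] = sum(r^2)/4
    z <- (st$V - mu) / sqrt(v2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "wilcoxon-signed-rank/normal-pratt"
  }
  list(statistic = st$V, p = p, method = method)
}

# ---- Friedman -------------------------------------------------------------

#' Friedman rank test for k related samples
#'
#' Rows of `mat` are blocks (shoulders), columns are treatments (landmarks).
#' Values are ranked within each block with average ranks for ties; the
#' chi-square statistic uses the standard tie correction. When every block
#' is fully tied the statistic is 0 and p = 1 by convention.
#'
#' @param mat n x k numeric matrix, n >= 2 blocks, k >= 2 treatments.
#' @return list: `statistic`, `df`, `p`.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) sta_error("sta_validation_error", "friedman needs >= 2 blocks and >= 2 treatments")
  ranks <- t(apply(mat, 1L, rank))
  Rj <- colSums(ranks)
  # tie correction: 1 - sum over blocks of sum(t^3 - t) / (n k (k^2-1))
  ties <- sum(apply(mat, 1L, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  }))
  denom <- 1 - ties / (n * k * (k^2 - 1))
  raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  if (denom <= 0) {
    return(list(statistic = 0, df = k - 1L, p = 1))   # all blocks fully tied
  }
  stat <- raw / denom
  list(statistic = stat, df = k - 1L, p = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

#' Compare the three scapular landmarks
#'
#' The omnibus Friedman test across AA, TS and AI (paired by shoulder),
#' followed — when the omnibus p is below `alpha` — by the three pairwise
#' Wilcoxon signed-rank tests with Bonferroni adjustment (m = 3,
#' `p_adjusted = min(1, 3 * p_raw)`).
#'
#' @param AA,TS,AI equal-length numeric vectors paired by shoulder, n >= 5.
#' @param alpha omnibus significance gate (default 0.05).
#' @return list with `friedman` (statistic, df, p) and `pairwise`, a
#'   data.frame of the pairwise results (empty when the omnibus gate fails).
#' @export
compare_three_landmarks <- function(AA, TS, AI, alpha = 0.05) {
  n <- length(AA)
  if (length(TS) != n || length(AI) != n) {
    sta_error("sta_validation_error", "samples must be paired (equal length)")
  }
  if (n < 5L) sta_error("sta_validation_error", "needs n >= 5 shoulders, got %d", n)
  fr <- friedman_rank_test(cbind(AA = AA, TS = TS, AI = AI))
  pairs <- list(c("AA", "TS"), c("AA", "AI"), c("TS", "AI"))
  samples <- list(AA = AA, TS = TS, AI = AI)
  if (fr$p < alpha) {
    pw <- do.call(rbind, lapply(pairs, function(pr) {
      w <- wilcoxon_signed_rank(samples[[pr[1L]]], samples[[pr[2L]]])
      data.frame(pair = paste(pr, collapse = "-"), statistic = w$statistic,
                 p_raw = w$p, p_adjusted = min(1, 3 * w$p),
                 method = paste0(w$method, "+bonferroni3"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    pw <- data.frame(pair = character(), statistic = numeric(),
                     p_raw = numeric(), p_adjusted = numeric(),
                     method = character(), stringsAsFactors = FALSE)
  }
  list(friedman = fr, pairwise = pw)
}

#' Paired t-test (bone-based vs marker-based angles)
#'
#' Two-sided paired t-test, reporting the mean difference and its standard
#' deviation alongside the test.
#'
#' @param bone,marker equal-length numeric vectors, n >= 3.
#' @return list: `mean_diff`, `sd_diff`, `n`, `statistic`, `df`, `p`.
#' @export
paired_t <- function(bone, marker) {
  n <- length(bone)
  if (length(marker) != n) sta_error("sta_validation_error", "paired samples must have equal length")
  if (n < 3L) sta_error("sta_validation_error", "paired t needs n >= 3")
  d <- bone - marker
  if (any(!is.finite(d))) sta_error("sta_validation_error", "non-finite differences")
  sdd <- stats::sd(d)
  if (sdd == 0) sta_error("sta_validation_error", "zero-variance differences: t undefined")
  tval <- mean(d) / (sdd / sqrt(n))
  list(mean_diff = mean(d), sd_diff = sdd, n = n, statistic = tval,
       df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1L))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks, with a two-sided p-value from
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` (the approximation
#' SPSS and most packages use in the presence of ties).
#'
#' @param x,y equal-length numeric vectors, n >= 5.
#' @return list: `rho`, `p`, `n`.
#' @export
spearman_rank <- function(x, y) {
  n <- length(x)
  if (length(y) != n) sta_error("sta_validation_error", "x and y must have equal length")
  if (n < 5L) sta_error("sta_validation_error", "spearman needs n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    sta_error("sta_validation_error", "undefined correlation: constant vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# ---- ICC ------------------------------------------------------------------

icc_mean_squares <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(n = n, k = k,
       BMS = ss_rows / (n - 1),                 # between-subject
       JMS = ss_cols / (k - 1),                 # between-rater
       EMS = ss_err / ((n - 1) * (k - 1)),      # residual (two-way)
       WMS = (ss_cols + ss_err) / (n * (k - 1)))# within-subject (one-way)
}

#' Intraclass correlation coefficients ICC(1,1) and ICC(2,1)
#'
#' Single-rater intraclass correlation from the Shrout-Fleiss ANOVA
#' formulations: model (1,1) is one-way random
#' `(BMS - WMS) / (BMS + (k-1) WMS)`; model (2,1) is two-way random,
#' absolute agreement,
#' `(BMS - EMS) / (BMS + (k-1) EMS + k (JMS - EMS) / n)`. 95% confidence
#' intervals use the Shrout-Fleiss F-distribution formulas (the (2,1)
#' interval uses the Satterthwaite degrees of freedom).
#'
#' @param mat n x k matrix: rows = subjects (n >= 5), columns = raters
#'   (k >= 2); no missing cells.
#' @param model `"1,1"` (one-way: each subject rated by different raters /
#'   test-retest) or `"2,1"` (two-way: every rater rates every subject).
#' @param conf confidence level (default 0.95).
#' @return list: `model`, `icc`, `ci` (length-2), `n`, `k`.
#' @export
icc <- function(mat, model = c("2,1", "1,1"), conf = 0.95) {
  model <- match.arg(model)
  mat <- as.matrix(mat)
  if (anyNA(mat)) sta_error("sta_validation_error", "ICC requires a complete matrix (no imputation)")
  if (nrow(mat) < 5L || ncol(mat) < 2L) {
    sta_error("sta_validation_error", "ICC needs >= 5 subjects and >= 2 raters")
  }
  ms <- icc_mean_squares(mat)
  n <- ms$n; k <- ms$k
  a2 <- (1 - conf) / 2
  if (model == "1,1") {
    est <- (ms$BMS - ms$WMS) / (ms$BMS + (k - 1) * ms$WMS)
    Fobs <- ms$BMS / ms$WMS
    if (!is.finite(Fobs)) {
      ci <- c(NA_real_, NA_real_)   # zero within-subject variance
    } else {
      FL <- Fobs / stats::qf(1 - a2, n - 1, n * (k - 1))
      FU <- Fobs * stats::qf(1 - a2, n * (k - 1), n - 1)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    }
  } else {
    est <- (ms$BMS - ms$EMS) /
      (ms$BMS + (k - 1) * ms$EMS + k * (ms$JMS - ms$EMS) / n)
    # Satterthwaite df for the rater+error composite
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * ms$JMS + b * ms$EMS)^2 /
      ((a * ms$JMS)^2 / (k - 1) + (b * ms$EMS)^2 / ((n - 1) * (k - 1)))
    if (!is.finite(v) || v <= 0) {
      ci <- c(NA_real_, NA_real_)   # degenerate (e.g. perfect agreement)
    } else {
      F1 <- stats::qf(1 - a2, n - 1, v)
      F2 <- stats::qf(1 - a2, v, n - 1)
      lo <- n * (ms$BMS - F1 * ms$EMS) /
        (F1 * (k * ms$JMS + (k * n - k - n) * ms$EMS) + n * ms$BMS)
      hi <- n * (F2 * ms$BMS - ms$EMS) /
        (k * ms$JMS + (k * n - k - n) * ms$EMS + n * F2 * ms$BMS)
      ci <- c(lo, hi)
    }
  }
  list(model = model, icc = est, ci = ci, n = n, k = k)
}
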