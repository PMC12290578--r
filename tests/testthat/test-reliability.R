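icc_oracle <- function(m) {
  # independent two-way ANOVA decomposition via lm/anova
  df <- data.frame(v = as.vector(m),
                   p = factor(rep(seq_len(nrow(m)), ncol(m))),
                   s = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  av <- stats::anova(stats::lm(v ~ p + s, df))
  bms <- av["p", "Mean Sq"]; ems <- av["Residuals", "Mean Sq"]
  (bms - ems) / (bms + (ncol(m) - 1) * ems)
}

test_that("icc31 matches the ANOVA oracle and handles edge cases", {
  # duplicated column with spread -> EMS = 0 -> ICC = 1
  m1 <- cbind(1:5, 1:5)
  f1 <- icc31(m1)
  expect_equal(f1$icc, 1)
  expect_equal(f1$ci, c(1, 1))

  # concordant triple plus one discordant pair
  m2 <- rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 1))
  expect_equal(icc31(m2)$icc, icc_oracle(m2), tolerance = 1e-10)

  set.seed(14)
  for (i in 1:100) {
    m <- matrix(rnorm(10), 5, 2)
    expect_equal(icc31(m)$icc, icc_oracle(m), tolerance = 1e-10)
  }

  # missing sessions are dropped participant-wise
  m3 <- rbind(c(1, 1), c(2, 2.2), c(3, 2.9), c(4, NA), c(5, 5.1))
  f3 <- icc31(m3)
  expect_equal(f3$n_used, 4)
  expect_equal(f3$icc, icc_oracle(m3[-4, ]), tolerance = 1e-10)

  expect_error(icc31(matrix(1, 5, 2)), "identical")
  expect_error(icc31(matrix(rnorm(4), 2, 2)), "at least 3")
  expect_error(icc31(matrix(rnorm(5), 5, 1)), "at least 2")

  # tidy data-frame interface agrees with the matrix interface
  df <- data.frame(participant = rep(1:5, 2),
                   session = rep(1:2, each = 5),
                   value = c(m2[1:4, 1], 9, m2[1:4, 2], 9.5))
  mm <- cbind(c(m2[1:4, 1], 9), c(m2[1:4, 2], 9.5))
  expect_equal(icc31(df)$icc, icc31(mm)$icc)
})

test_that("ICC estimator recovers simulated variance components", {
  set.seed(90)
  rho <- 0.778
  est <- replicate(300, {
    b <- rnorm(40, 0, 0.3)
    icc31(b + matrix(rnorm(80, 0, 0.16), 40, 2))$icc
  })
  expect_lt(abs(mean(est) - 0.09 / (0.09 + 0.0256)), 0.03)
  # F-interval coverage near nominal
  cov <- replicate(300, {
    b <- rnorm(40, 0, 0.3)
    f <- icc31(b + matrix(rnorm(80, 0, 0.16), 40, 2))
    f$ci[1] <= rho && rho <= f$ci[2]
  })
  expect_gt(mean(cov), 0.90)
})

test_that("Cicchetti bands are half-open and lower-inclusive", {
  expect_equal(categorize_icc(c(0.39, 0.4, 0.59, 0.6, 0.74, 0.75, 1)),
               c("poor", "fair", "fair", "good", "good", "excellent",
                 "excellent"))
  expect_equal(categorize_icc(-0.2), "poor")
  expect_equal(categorize_icc(0.72), "good")
  expect_error(categorize_icc(1.5))
})

test_that("tidy and glance expose the fit components", {
  f <- icc31(cbind(c(1, 2, 3, 5), c(1.1, 2.2, 2.8, 4.9)))
  td <- tidy(f)
  expect_named(td, c("icc", "conf.low", "conf.high", "category", "n", "k"))
  expect_equal(td$icc, f$icc)
  expect_true(td$conf.low <= td$icc && td$icc <= td$conf.high)
  gl <- glance(f)
  expect_equal(gl$bms >= 0 && gl$ems >= 0, TRUE)
})

test_that("trial splitting follows parity and halves", {
  oe <- split_trials(20, "odd_even")
  expect_equal(oe[[1]], seq(1, 19, by = 2))
  expect_equal(oe[[2]], seq(2, 20, by = 2))
  el <- split_trials(20, "early_late")
  expect_equal(el[[1]], 1:10)
  expect_equal(el[[2]], 11:20)
  sched <- toy_schedule(c(20, 40, 60))
  expect_equal(split_trials(sched, "odd_even")[[1]], c(1, 3))
})

test_that("split-half ICC averages day-wise estimates", {
  # identical subsets -> ICC 1 on both days
  d <- expand.grid(participant = 1:6, day = 1:2, subset = 1:2)
  d$value <- rep(rnorm(6), 4) + 0.1 * d$participant
  d$value <- ave(d$value, d$participant, d$day, FUN = function(x) x[1])
  sh <- split_half_icc(d)
  expect_equal(sh$icc, 1)
  expect_equal(nrow(sh$per_day), 2)

  # independent pure-noise subsets -> ICC near 0 on average
  set.seed(55)
  null_icc <- replicate(200, {
    dn <- expand.grid(participant = 1:12, day = 1, subset = 1:2)
    dn$value <- rnorm(24)
    split_half_icc(dn)$icc
  })
  expect_lt(abs(mean(null_icc)), 0.08)
})

test_that("session difference test matches the textbook formula", {
  m <- cbind(c(10, 12, 9, 11, 13), c(9, 11, 9, 10, 11))
  out <- session_difference_test(m)
  expect_equal(out$t, sqrt(10), tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(-sqrt(10), 4), tolerance = 1e-10)
  expect_equal(out$df, 4)

  same <- cbind(1:5, 1:5)
  out0 <- session_difference_test(same)
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
  expect_error(session_difference_test(cbind(1:5, 1:5 + 2)),
               "zero variance")
})

test_that("directed correlations report one-tailed p-values", {
  x <- 1:10
  expect_equal(correlate_measures(x, 2 * x)$r, 1)
  r1 <- correlate_measures(x, x + rnorm(10, sd = 2), 1)
  r2 <- correlate_measures(x, -(x + rnorm(10, sd = 2)), -1)
  expect_lt(r2$r, 0)

  # one-tailed p agrees with a permutation reference on an n = 20 toy
  set.seed(33)
  xx <- rnorm(20); yy <- 0.4 * xx + rnorm(20)
  got <- correlate_measures(xx, yy, 1)
  perm <- replicate(1e4, cor(xx, sample(yy)))
  p_perm <- mean(perm >= got$r)
  expect_lt(abs(got$p_one_tailed - p_perm), 0.02)

  expect_error(correlate_measures(1:2, 1:2), "at least 3")
  expect_error(correlate_measures(rep(1, 5), 1:5), "constant")
  # delegation: QC-difference correlation equals a positive-direction call
  expect_equal(qc_difference_correlation(abs(xx), abs(yy))$r,
               correlate_measures(abs(xx), abs(yy), 1)$r)
})
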