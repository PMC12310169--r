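test_that("uncensored pooled fit is nearly unbiased and matches sample moments", {
  set.seed(9)
  biases <- t(vapply(1:200, function(i) {
    x <- rnorm(8, 7, 1)
    f <- pooled_cdf_fit(data.frame(b_th_mt = x, censored_at_mt = NA_real_))
    c(f$mean - 7, f$sd - 1)
  }, numeric(2)))
  expect_lt(abs(mean(biases[, 1])), 0.1)
  expect_lt(abs(mean(biases[, 2])), 0.15)

  # with zero censoring, both fit routes agree with each other and with the
  # sample moments of a larger draw
  set.seed(10)
  x <- rnorm(60, 5, 0.8)
  thr <- data.frame(b_th_mt = x, censored_at_mt = NA_real_)
  lsq <- pooled_cdf_fit(thr)
  mle <- pooled_cdf_fit(thr, method = "censored-mle")
  expect_equal(lsq$mean, mean(x), tolerance = 0.05)
  expect_equal(lsq$sd, sd(x), tolerance = 0.1)
  expect_equal(mle$mean, mean(x), tolerance = 1e-3)
  expect_equal(lsq$mean, mle$mean, tolerance = 0.05)
})

test_that("degenerate and invalid threshold tables are handled", {
  eq <- data.frame(b_th_mt = rep(6, 8), censored_at_mt = NA_real_)
  f <- pooled_cdf_fit(eq)
  expect_equal(f$mean, 6)
  expect_equal(f$sd, 1e-3)
  expect_equal(cohort_cv(list(mean = 6, sd = 0)), 0)
  allc <- data.frame(b_th_mt = rep(NA_real_, 4), censored_at_mt = rep(8, 4))
  expect_error(pooled_cdf_fit(allc), "censored")
  one <- data.frame(b_th_mt = c(5, NA), censored_at_mt = c(NA, 8))
  expect_error(pooled_cdf_fit(one), "one observed")
})

test_that("raising the ceiling improves the censored fit on fixed cohorts", {
  set.seed(21)
  cohorts <- replicate(60, rnorm(8, 7, 1.5), simplify = FALSE)
  mae <- function(prob) {
    ceil <- qnorm(prob, 7, 1.5)
    errs <- vapply(cohorts, function(x) {
      obs <- x[x <= ceil]
      if (length(obs) < 2) return(NA_real_)
      thr <- data.frame(b_th_mt = ifelse(x <= ceil, x, NA),
                        censored_at_mt = ifelse(x <= ceil, NA, ceil))
      abs(pooled_cdf_fit(thr, method = "censored-mle")$mean - mean(x))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  m <- c(mae(0.4), mae(0.7), mae(0.99))
  expect_true(all(diff(m) < 0))
})

test_that("percent change matches the study's headline arithmetic", {
  expect_equal(signif(percent_change(5.11, 7.09), 3), 38.7)
  expect_equal(signif(percent_change(13.9, 15.3), 3), 10.1)
  expect_equal(signif(percent_change(6.14, 5.67), 2), -7.7)
  expect_equal(percent_change(4, 4), 0)
  # forward and backward changes compose to the identity
  for (pair in list(c(5.11, 7.09), c(2, 10), c(8, 7.5))) {
    p1 <- percent_change(pair[1], pair[2])
    p2 <- percent_change(pair[2], pair[1])
    expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1, tolerance = 1e-12)
  }
})

test_that("frequency comparison reproduces the pooled-variance t-test", {
  idt <- compare_frequencies(c(3, 3, 3), c(3, 3, 3))
  expect_equal(idt$t, 0)
  expect_equal(idt$p, 1)

  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  res <- compare_frequencies(a, b)
  # hand-computed pooled-variance t statistic
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$t, -2.1909, tolerance = 1e-4)
  expect_equal(res$p, 2 * pt(t_hand, 6), tolerance = 1e-12)
  expect_equal(res$df, 6)
  welch <- compare_frequencies(a, b, var_equal = FALSE)
  expect_lt(welch$df, 6 + 1e-9)
  expect_error(compare_frequencies(1, c(1, 2)), "at least 2")
})

test_that("the 25.3 vs 88.1 kHz contrast is well-powered at the study's spread", {
  set.seed(31)
  rej <- 0L
  for (i in 1:1000) {
    a <- rnorm(8, 5.11, 0.62)
    b <- rnorm(8, 7.09, 1.53)
    rej <- rej + (compare_frequencies(a, b)$p < 0.05)
  }
  expect_gt(rej / 1000, 0.8)
})

test_that("Bland-Altman summary gives mean difference and limits of agreement", {
  pairs <- data.frame(test = c(6.14, 10, 12), retest = c(5.67, 10, 12))
  s <- test_retest(pairs)
  expect_equal(signif(s$percent_change[1], 2), -7.7)
  ident <- test_retest(data.frame(test = c(5, 7), retest = c(5, 7)))
  expect_equal(ident$mean_difference, 0)
  expect_equal(ident$loa_lower, 0)
  expect_equal(ident$loa_upper, 0)
  # differences {+1, -1}: mean 0, sample SD sqrt(2)
  pm <- test_retest(data.frame(test = c(5, 5), retest = c(6, 4)))
  expect_equal(pm$mean_difference, 0)
  expect_equal(pm$loa_upper, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(pm$loa_lower, -1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(test_retest(data.frame(test = 1, retest = 2)), "2 pairs")
})

test_that("cohort CV reproduces the printed spread summaries", {
  expect_equal(signif(cohort_cv(list(mean = 5.11, sd = 0.62)), 3), 12.1)
  expect_equal(signif(cohort_cv(list(mean = 7.09, sd = 1.53)), 3), 21.6)
  expect_error(cohort_cv(list(mean = 0, sd = 1)), "positive")
})
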