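test_that("the truth curve reduces to the hyperbolic SDC and is calibrated", {
  f <- 10^seq(2.3, 5, by = 0.05)
  p0 <- truth_params(a = 0)
  expect_equal(true_threshold_curve(f, p0),
               hyperbolic_threshold(f, p0$B_rheo, p0$tau_chron))
  p <- truth_params()
  # ~39% rise from 25.3 to 88.1 kHz
  ratio <- true_threshold_curve(88100, p) / true_threshold_curve(25300, p)
  expect_equal(ratio, 1.39, tolerance = 0.005)
  # grid-search oracle: the minimum lies between 16.9 and 25.3 kHz
  grid <- seq(10e3, 50e3, by = 100)
  fmin <- grid[which.min(true_threshold_curve(grid, p))]
  expect_gte(fmin, 16900)
  expect_lte(fmin, 25300)
  # strictly decreasing below the knee
  below <- f[f <= p$f_k]
  expect_true(all(diff(true_threshold_curve(below, p)) < 0))
})

test_that("cohort sampling gives reproducible, width-scaled subject curves", {
  spec <- cohort_spec(seed = 7)
  co1 <- sample_cohort(spec)
  co2 <- sample_cohort(spec)
  expect_identical(co1$b_true_mt, co2$b_true_mt)
  expect_equal(co1$b_width_mt, 0.03 * co1$b_true_mt)
  # cv = 0 collapses the cohort onto the population curve
  co0 <- sample_cohort(cohort_spec(inter_subject_cv = 0, seed = 1))
  at25 <- co0$b_true_mt[co0$frequency_hz == 25300]
  expect_equal(max(at25) - min(at25), 0)
  # subject factors scale all frequencies together
  s1 <- co1[co1$subject_id == "s01", ]
  expect_equal(s1$b_true_mt / true_threshold_curve(s1$frequency_hz, spec$truth),
               rep(s1$subject_scale[1], nrow(s1)))
})

test_that("cross-subject spread lands in the study's observed CV range", {
  inb <- vapply(1:500, function(i) {
    co <- sample_cohort(cohort_spec(seed = i))
    x <- co$b_true_mt[co$frequency_hz == 25300]
    cv <- 100 * sd(x) / mean(x)
    cv >= 9 && cv <= 23
  }, logical(1))
  expect_gte(mean(inb), 0.85)
})

test_that("simulated experiments censor where the amplifier limits bind", {
  # unlimited amplifier: nothing is censored
  spec <- cohort_spec(seed = 3, frequencies = c(700, 25300),
                      ceilings = c("700" = Inf, "25300" = Inf))
  ex <- simulate_experiment(spec, retest_frequencies = NULL)
  expect_equal(sum(!is.na(ex$thresholds$censored_at_mt)), 0L)
  # ceiling at the population 40th percentile at 700 Hz: ~5 of 8 censored
  ncens <- vapply(1:30, function(s) {
    sp <- cohort_spec(seed = s, frequencies = 700)
    e <- simulate_experiment(sp, retest_frequencies = NULL)
    sum(!is.na(e$thresholds$censored_at_mt))
  }, numeric(1))
  expect_gt(mean(ncens), 3.8)
  expect_lt(mean(ncens), 5.8)
})

test_that("titration recovers every uncensored subject threshold to 2 widths", {
  ex <- simulate_experiment(cohort_spec(seed = 1))
  thr <- ex$thresholds[ex$thresholds$run_id == 1L, ]
  m <- merge(thr, ex$cohort, by = c("subject_id", "frequency_hz"))
  obs <- m[!is.na(m$b_th_mt), ]
  expect_gt(nrow(obs), 100)
  expect_true(all(abs(obs$b_th_mt - obs$b_true_mt) <= 2 * obs$b_width_mt.y))
})

test_that("subject response streams follow the generating sigmoid exactly", {
  # a titration re-run with the same derived seed reproduces responses drawn
  # from sigmoid_probability at the recorded amplitudes
  bt <- 9; bw <- 0.27
  run <- run_titration(function(B) sigmoid_probability(B, bt, bw), 4040,
                       titration_protocol(), seed = 99)
  set.seed(99)
  replay <- vapply(run$responses$amplitude_mt, function(a)
    rbinom(1, 1, sigmoid_probability(a, bt, bw)), integer(1))
  expect_identical(run$responses$response, replay)
})

test_that("wider sigmoids increase the spread of recovered thresholds", {
  spread <- function(wf) {
    ests <- vapply(1:30, function(i) {
      r <- run_titration(function(B) sigmoid_probability(B, 10, wf * 10),
                         4040, titration_protocol(), seed = 400 + i)
      r$fit$B_th
    }, numeric(1))
    var(ests)
  }
  expect_gt(spread(0.08), spread(0.01))
})

test_that("retest runs are recorded for the designated subjects and frequencies", {
  ex <- simulate_experiment(cohort_spec(seed = 5))
  r2 <- ex$thresholds[ex$thresholds$run_id == 2L, ]
  expect_equal(sort(unique(r2$frequency_hz)), c(1760, 25300))
  expect_equal(sort(unique(r2$subject_id)), sprintf("s%02d", 2:6))
  # retest draws a fresh response stream: estimates differ but stay close
  r1 <- ex$thresholds[ex$thresholds$run_id == 1L &
                        ex$thresholds$frequency_hz %in% c(1760, 25300) &
                        ex$thresholds$subject_id %in% sprintf("s%02d", 2:6), ]
  j <- merge(r1, r2, by = c("subject_id", "frequency_hz"))
  expect_true(all(abs(j$b_th_mt.x - j$b_th_mt.y) / j$b_th_mt.x < 0.10))
})
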