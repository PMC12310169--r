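test_that("natural time constant and resonance follow the circuit identities", {
  cfg <- circuit_config(L = 0.87e-3, C = 23.3e-9, R = 2.757)
  tau <- natural_time_constant(cfg)
  expect_equal(signif(tau, 3), 631e-6)
  # expressed in cycles of the resonant frequency near 35.4 kHz
  expect_equal(signif(tau * 35400, 3), 22.3)
  cfg2 <- circuit_config(L = 0.87e-3, C = 23.3e-9, R = 2 * 2.757)
  expect_equal(natural_time_constant(cfg2), tau / 2)
  expect_error(natural_time_constant(circuit_config(R = 1, tuned = FALSE)),
               "tuned")

  # bank capacitors hit the printed resonances with the derived inductance
  expect_lt(abs(resonant_frequency(0.87e-3, 45.6e-9) / 25.3e3 - 1), 0.005)
  expect_lt(abs(resonant_frequency(0.87e-3, 3.73e-9) / 88.1e3 - 1), 0.005)
  expect_equal(resonant_frequency(1e-3, 4e-9),
               2 * resonant_frequency(1e-3, 16e-9))
  expect_error(resonant_frequency(-1, 1e-9), "positive")
})

test_that("pulse duration arithmetic", {
  expect_equal(pulse_duration(200), 1280)
  expect_equal(signif(pulse_duration(88100), 3), 2.91)
  expect_equal(pulse_duration(1000, 0), 0)
  expect_error(pulse_duration(-5), "positive")
})

test_that("shaped voltage degenerates and asymptotes correctly", {
  cfg <- circuit_config(L = 0.87e-3, C = 45.6e-9, R = 2)
  tau_nat <- natural_time_constant(cfg)
  f <- resonant_frequency(cfg$L, cfg$C)
  # tau_des equal to tau_nat: envelope coefficient vanishes, pure step sine
  sp <- pulse_spec(f, n_cycles = 16, tau_des_cycles = tau_nat * f, V0 = 3)
  v <- shaped_voltage(sp, cfg)
  expect_equal(v$values, 3 * sin(2 * pi * f * v$times), tolerance = 1e-12)
  # amplitude approaches V0 at late times
  sp2 <- pulse_spec(f, n_cycles = 256, tau_des_cycles = 25, V0 = 3)
  v2 <- shaped_voltage(sp2, cfg)
  late <- v2$values[v2$times > 200 / f]
  expect_equal(max(abs(late)), 3, tolerance = 1e-3)
  # tau_des below tau_nat is flagged
  expect_warning(shaped_voltage(pulse_spec(f, 16, tau_des_cycles = 1), cfg),
                 "tau_des")
})

test_that("RK4 circuit integration matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  cfg <- circuit_config(L = 0.87e-3, C = 45.6e-9, R = 2.1)
  f <- resonant_frequency(cfg$L, cfg$C)
  sp <- pulse_spec(f, n_cycles = 30, V0 = 5)
  v <- shaped_voltage(sp, cfg)
  cur <- simulate_current(cfg, v)
  vfun <- attr(v, "fun")
  deriv <- function(t, x, p)
    list(c(di = (vfun(t) - cfg$R * x[1] - x[2] / cfg$C) / cfg$L, dq = x[1]))
  sol <- deSolve::lsoda(c(i = 0, q = 0), v$times, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(cur$values - sol[, "i"])) / max(abs(sol[, "i"])), 1e-5)
})

test_that("step-voltage response at resonance ramps with tau = 2L/R", {
  cfg <- circuit_config(L = 0.87e-3, C = 45.6e-9, R = 2.5)
  f <- resonant_frequency(cfg$L, cfg$C)
  sp <- pulse_spec(f, n_cycles = 256,
                   tau_des_cycles = natural_time_constant(cfg) * f, V0 = 8)
  fit <- fit_current_waveform(simulate_current(cfg, shaped_voltage(sp, cfg)))
  expect_lt(abs(fit$tau_fit / natural_time_constant(cfg) - 1), 0.01)
  # steady-state amplitude V0 / R at resonance
  expect_lt(abs(fit$I0_fit / (8 / cfg$R) - 1), 0.01)
  # tuned at resonance: phase within 2 degrees of zero
  expect_lt(abs(fit$phi) * 180 / pi, 2)
  # zero voltage in, zero current out
  z <- simulate_current(cfg, make_trace(seq(0, 1e-3, 1e-6), rep(0, 1001),
                                        "voltage"))
  expect_equal(max(abs(z$values)), 0)
})

test_that("current waveform fitting recovers generating parameters", {
  f <- 25.3e3; tau <- 25 / f
  tt <- seq(0, 100 / f, length.out = 100 * 128)
  # noiseless round trip
  fit <- fit_current_waveform(make_trace(tt, ramped_sine(tt, 10, tau, f, 0)))
  expect_lt(abs(fit$I0_fit / 10 - 1), 1e-6)
  expect_lt(abs(fit$tau_fit / tau - 1), 1e-6)
  expect_lt(abs(fit$f_fit / f - 1), 1e-6)
  expect_lt(abs(fit$phi), 1e-6)
  # 1% white noise: I0 and tau within 2% in every one of 100 seeded runs
  set.seed(5)
  ok <- 0L
  for (i in 1:100) {
    y <- ramped_sine(tt, 10, tau, f) + rnorm(length(tt), 0, 0.1)
    ft <- fit_current_waveform(make_trace(tt, y))
    ok <- ok + (abs(ft$I0_fit / 10 - 1) < 0.02 && abs(ft$tau_fit / tau - 1) < 0.02)
  }
  expect_gte(ok, 95L)
})

test_that("untuned shaping yields the target ramp and inductive phase lag", {
  cfg <- circuit_config(L = 0.87e-3, R = 2, tuned = FALSE)
  sp <- pulse_spec(200, V0 = 10)
  fit <- fit_current_waveform(simulate_current(cfg, shaped_voltage(sp, cfg)))
  expect_lt(abs(fit$tau_cycles / 25 - 1), 0.02)
  # current lags voltage by arctan(2 pi f L / R)
  expect_lt(abs(fit$phi + atan(2 * pi * 200 * cfg$L / cfg$R)) * 180 / pi, 2)
})

test_that("series resistance is recovered from fitted voltage and current", {
  expect_equal(series_resistance(10, 100), 0.1)
  expect_equal(series_resistance(3 * 10, 3 * 100), 0.1)
  expect_error(series_resistance(10, 0), "positive")
  cfg <- circuit_config(L = 0.87e-3, C = 101e-9, R = 1.7)
  f <- resonant_frequency(cfg$L, cfg$C)
  sp <- pulse_spec(f, n_cycles = 256, V0 = 6)
  v <- shaped_voltage(sp, cfg)
  ifit <- fit_current_waveform(simulate_current(cfg, v))
  V0 <- fit_steady_amplitude(v)
  expect_lt(abs(series_resistance(V0, ifit$I0_fit) / cfg$R - 1), 0.01)
})

test_that("resonance sweep localises f_res to within the grid refinement", {
  cfg <- circuit_config(L = 0.87e-3, C = 45.6e-9, R = 2)
  f_true <- resonant_frequency(cfg$L, cfg$C)
  f_hat <- find_resonance(cfg, center = f_true + 90, span = 400, n_points = 20)
  expect_lt(abs(f_hat - f_true), 20)
  expect_equal(attr(f_hat, "grid_resolution_hz"), 20)
  expect_error(find_resonance(circuit_config(R = 1, tuned = FALSE), 1000),
               "no resonance")
  expect_warning(find_resonance(cfg, center = f_true + 1000, span = 400),
                 "boundary")
})

test_that("all ten tuned bank settings shape to a tight 25-cycle ramp", {
  bank <- tuned_bank()
  # resonances span the tuned stimulus range
  expect_equal(signif(max(bank$f_res_hz), 3), 88300)
  cycles <- vapply(c(1L, 5L, 10L), function(i) {
    cfg <- circuit_config(L = 0.87e-3, C = bank$C_F[i], R = bank$R_ohm[i])
    sp <- pulse_spec(bank$f_res_hz[i], n_cycles = 256, V0 = 10)
    fit_current_waveform(simulate_current(cfg, shaped_voltage(sp, cfg)))$tau_cycles
  }, numeric(1))
  expect_true(all(abs(cycles / 25 - 1) < 0.02))
})
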