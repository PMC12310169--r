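#' Drive circuit configuration
#'
#' Series model of the coil drive: inductance L, series resistance R, and, in
#' tuned mode, a series capacitance C that cancels the coil reactance at the
#' resonant frequency. Untuned mode (no capacitor) is used for the
#' sub-kilohertz stimulus frequencies.
#'
#' @param L Inductance (H).
#' @param C Capacitance (F); required iff `tuned`.
#' @param R Series resistance (Ohm).
#' @param tuned Logical; `TRUE` for the series-resonant configuration.
#' @return Object of class `circuit_config`.
#' @export
circuit_config <- function(L = 0.87e-3, C = NULL, R = 1, tuned = !is.null(C)) {
  if (L <= 0 || R <= 0) stop("L and R must be positive")
  if (tuned) {
    if (is.null(C) || C <= 0) stop("tuned configuration requires C > 0")
  } else if (!is.null(C)) {
    stop("untuned configuration must not specify C")
  }
  structure(list(L = L, C = C, R = R, tuned = tuned), class = "circuit_config")
}

#' Stimulus pulse specification
#'
#' A sinusoidal pulse of `n_cycles` cycles at frequency `f`, amplitude-shaped
#' by an exponential ramp-up envelope with time constant `tau_des_cycles`
#' cycles. The experiment's pulses use 256 cycles and a 25-cycle ramp-up at
#' every frequency so that all pulses share the same waveform shape.
#'
#' @param f Stimulus frequency (Hz).
#' @param n_cycles Number of sinusoid cycles in the pulse.
#' @param tau_des_cycles Desired ramp-up time constant, in cycles.
#' @param V0 Steady-state voltage amplitude (V).
#' @param sample_rate Sampling rate (Hz); at least 64 samples per cycle.
#' @return Object of class `pulse_spec`.
#' @export
pulse_spec <- function(f, n_cycles = 256L, tau_des_cycles = 25,
                       V0 = 1, sample_rate = 256 * f) {
  if (f <= 0) stop("f must be positive")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (tau_des_cycles <= 0) stop("tau_des_cycles must be positive")
  if (sample_rate < 64 * f) stop("sample_rate must be at least 64 samples per cycle")
  structure(list(f = f, n_cycles = as.integer(n_cycles),
                 tau_des_cycles = tau_des_cycles, V0 = V0,
                 sample_rate = sample_rate), class = "pulse_spec")
}

waveform_trace <- function(times, values, kind = c("voltage", "current"),
                           fun = NULL) {
  kind <- match.arg(kind)
  structure(list(times = times, values = values, kind = kind),
            class = "waveform_trace", fun = fun)
}

#' @export
print.waveform_trace <- function(x, ...) {
  cat(sprintf("%s trace: %d samples over %.4g s, peak %.4g\n",
              x$kind, length(x$times), max(x$times), max(abs(x$values))))
  invisible(x)
}

#' Natural ramp-up time constant of the resonant circuit
#'
#' At resonance the current envelope of the series RLC circuit ramps up as
#' `1 - exp(-t/tau_nat)` with `tau_nat = 2 L / R`.
#'
#' @param cfg A tuned [circuit_config()].
#' @return Time constant in seconds.
#' @export
natural_time_constant <- function(cfg) {
  stopifnot(inherits(cfg, "circuit_config"))
  if (!cfg$tuned)
    stop("natural_time_constant is defined by 2L/R only for the tuned (resonant) configuration")
  2 * cfg$L / cfg$R
}

#' Series-resonant frequency
#'
#' @param L Inductance (H).
#' @param C Capacitance (F).
#' @return `1 / (2 * pi * sqrt(L * C))` in Hz.
#' @export
resonant_frequency <- function(L, C) {
  if (any(L <= 0) || any(C <= 0)) stop("L and C must be positive")
  1 / (2 * pi * sqrt(L * C))
}

#' Total pulse duration
#'
#' @param f Stimulus frequency (Hz).
#' @param n_cycles Number of cycles.
#' @return Duration `n_cycles / f` in milliseconds.
#' @export
pulse_duration <- function(f, n_cycles = 256) {
  if (any(f <= 0)) stop("f must be positive")
  1000 * n_cycles / f
}

#' Shaped drive voltage waveform
#'
#' Synthesises the amplitude-modulated voltage that forces the current
#' envelope to ramp with the desired time constant. In tuned mode the
#' envelope pre-compensates the circuit's natural ramp-up:
#' `v(t) = V0 (1 - (tau_des - tau_nat)/tau_des * exp(-t/tau_des)) sin(2 pi f t)`;
#' in untuned mode the envelope is applied directly:
#' `v(t) = V0 (1 - exp(-t/tau_des)) sin(2 pi f t)`.
#' Tuned shaping assumes `tau_des >= tau_nat` (otherwise the required
#' envelope overshoots the amplifier's steady-state voltage; a warning is
#' issued).
#'
#' @param spec A [pulse_spec()].
#' @param cfg A [circuit_config()].
#' @return A voltage `waveform_trace`; the analytic voltage function is
#'   attached as attribute `fun` for exact sub-step evaluation by
#'   [simulate_current()].
#' @export
shaped_voltage <- function(spec, cfg) {
  stopifnot(inherits(spec, "pulse_spec"), inherits(cfg, "circuit_config"))
  tau_des <- spec$tau_des_cycles / spec$f
  n <- round(spec$n_cycles * spec$sample_rate / spec$f)
  times <- (seq_len(n) - 1L) / spec$sample_rate
  if (cfg$tuned) {
    tau_nat <- natural_time_constant(cfg)
    if (tau_des < tau_nat)
      warning("tau_des < tau_nat: envelope coefficient is negative (voltage overshoot required)")
    coefp <- (tau_des - tau_nat) / tau_des
    fun <- function(t) spec$V0 * (1 - coefp * exp(-t / tau_des)) * sin(2 * pi * spec$f * t)
  } else {
    fun <- function(t) spec$V0 * (1 - exp(-t / tau_des)) * sin(2 * pi * spec$f * t)
  }
  waveform_trace(times, fun(times), "voltage", fun = fun)
}

## Classical fixed-step RK4 for the linear series circuit driven by v(t).
## Because the ODE is linear, the RK4 update is an affine map
## x_{n+1} = M x_n + w1 v(t_n) + w23 v(t_n + h/2) + w4 v(t_{n+1})
## whose matrices depend only on the step h; they are precomputed once and
## the step loop reduces to scalar arithmetic. This is algebraically
## identical to running classical RK4 step by step.
rk4_linear <- function(A, bcol, x0, times, vfun) {
  h <- times[2L] - times[1L]
  d <- nrow(A)
  I <- diag(d)
  A2 <- A %*% A; A3 <- A2 %*% A; A4 <- A3 %*% A
  M <- I + h * A + h^2 / 2 * A2 + h^3 / 6 * A3 + h^4 / 24 * A4
  W1 <- h / 6 * (I + h * A + h^2 / 2 * A2 + h^3 / 4 * A3)
  W2 <- h / 6 * (2 * I + h * A + h^2 / 2 * A2)
  W3 <- h / 6 * (2 * I + h * A)
  W4 <- h / 6 * I
  w1 <- (W1 %*% bcol)[, 1L]
  w23 <- ((W2 + W3) %*% bcol)[, 1L]
  w4 <- (W4 %*% bcol)[, 1L]
  n <- length(times)
  v <- vfun(times)
  vh <- vfun(times + h / 2)
  out <- matrix(0, n, d)
  x <- x0
  out[1L, ] <- x
  for (i in seq_len(n - 1L)) {
    x <- M %*% x + w1 * v[i] + w23 * vh[i] + w4 * v[i + 1L]
    out[i + 1L, ] <- x
  }
  out
}

#' Simulate the circuit current response
#'
#' Integrates the series circuit ODE (`L di/dt + R i + q/C = v(t)` in tuned
#' mode, `L di/dt + R i = v(t)` untuned) from zero initial conditions with a
#' fixed-step classical 4th-order Runge-Kutta scheme at the trace's sampling
#' rate. If the voltage trace carries its analytic generator function
#' (as traces from [shaped_voltage()] do) it is evaluated exactly at the RK4
#' half-steps; otherwise the half-step voltage is linearly interpolated.
#'
#' @param cfg A [circuit_config()].
#' @param voltage A voltage `waveform_trace` with uniform sampling.
#' @return A current `waveform_trace` on the same time grid.
#' @export
simulate_current <- function(cfg, voltage) {
  stopifnot(inherits(cfg, "circuit_config"), inherits(voltage, "waveform_trace"))
  times <- voltage$times
  n <- length(times)
  if (n < 3L) stop("voltage trace too short to integrate")
  h <- diff(times)
  if (max(h) - min(h) > 1e-9 * mean(h)) stop("voltage trace must be uniformly sampled")
  vfun <- attr(voltage, "fun")
  if (is.null(vfun)) vfun <- stats::approxfun(times, voltage$values, rule = 2)
  if (cfg$tuned) {
    A <- matrix(c(-cfg$R / cfg$L, 1, -1 / (cfg$L * cfg$C), 0), 2L, 2L)
    bcol <- matrix(c(1 / cfg$L, 0), 2L, 1L)
    x0 <- c(0, 0)
  } else {
    A <- matrix(-cfg$R / cfg$L, 1L, 1L)
    bcol <- matrix(1 / cfg$L, 1L, 1L)
    x0 <- 0
  }
  sr <- 1 / (times[2L] - times[1L])
  ## RK4 on the oscillatory system needs a small phase step for stability
  lam <- if (cfg$tuned) 1 / sqrt(cfg$L * cfg$C) else cfg$R / cfg$L
  if (lam / sr > 2.8) stop("integration step too large for circuit dynamics (undersampled)")
  out <- rk4_linear(A, bcol, x0, times, vfun)
  waveform_trace(times, out[, 1L], "current")
}

#' Fit the ramped-sinusoid current model to a trace
#'
#' Nonlinear least-squares fit of
#' `i(t) = I0 (1 - exp(-t/tau)) sin(2 pi f t + phi)` giving the amplitude,
#' ramp-up time constant, frequency and phase of a measured or simulated
#' current waveform. Starting values are derived from the trace itself
#' (zero-crossing count for f, per-cycle envelope for I0 and tau, quadrature
#' regression for phi) and refined with Levenberg-Marquardt.
#'
#' @param trace A current `waveform_trace` covering at least ~3 ramp-up time
#'   constants.
#' @param model `"shaped"` (ramp set by the designed envelope) or
#'   `"natural"` (ramp set by 2L/R); the functional form is identical, the
#'   label is kept for bookkeeping.
#' @return Object of class `waveform_fit`: `I0_fit` (A), `tau_fit` (s),
#'   `tau_cycles`, `f_fit` (Hz), `phi` (rad, in (-pi, pi]), `rms_residual`,
#'   `converged`.
#' @export
fit_current_waveform <- function(trace, model = c("shaped", "natural")) {
  model <- match.arg(model)
  stopifnot(inherits(trace, "waveform_trace"))
  t <- trace$times; y <- trace$values
  n <- length(t)
  if (n < 64L) stop("trace too short to fit")
  ## frequency guess: zero crossings over the steady-state half
  tail_i <- seq.int(floor(n / 2) + 1L, n)
  ys <- y[tail_i]; ts <- t[tail_i]
  sgn <- sign(ys); sgn[sgn == 0] <- 1
  crossings <- sum(abs(diff(sgn)) > 0)
  f0 <- crossings / (2 * (ts[length(ts)] - ts[1L]))
  if (!is.finite(f0) || f0 <= 0) stop("could not estimate frequency from trace")
  ## quadrature regression on the tail for amplitude and phase
  X <- cbind(sin(2 * pi * f0 * ts), cos(2 * pi * f0 * ts))
  ab <- stats::coef(stats::lm.fit(X, ys))
  I0g <- sqrt(sum(ab^2))
  phig <- unname(atan2(ab[2L], ab[1L]))
  ## envelope per cycle for the tau guess
  cyc <- floor(t * f0)
  env <- tapply(abs(y), cyc, max)
  tc <- tapply(t, cyc, mean)
  frac <- 1 - as.numeric(env) / I0g
  keep <- frac > 0.05 & frac < 0.95
  taug <- if (sum(keep) >= 3) {
    sl <- unname(stats::coef(stats::lm(log(frac[keep]) ~ tc[keep]))[2L])
    if (is.finite(sl) && sl < 0) -1 / sl else 5 / f0
  } else 5 / f0
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * (1 - exp(-t / tau)) * sin(2 * pi * f * t + phi),
                      data = data.frame(t = t, y = y),
                      start = list(I0 = I0g, tau = taug, f = f0, phi = phig),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop(sprintf(paste0("current waveform fit failed to converge: %s ",
                        "(starting values: I0 = %.4g, tau = %.4g s, f = %.4g Hz, phi = %.3f rad)"),
                 conditionMessage(fit), I0g, taug, f0, phig))
  p <- stats::coef(fit)
  ## normalise the sign/phase conventions: I0 >= 0, phi in (-pi, pi]
  if (p[["I0"]] < 0) { p[["I0"]] <- -p[["I0"]]; p[["phi"]] <- p[["phi"]] + pi }
  if (p[["tau"]] <= 0 || p[["f"]] <= 0)
    stop(sprintf("current waveform fit did not converge to a physical solution (tau = %.3g s, f = %.3g Hz)",
                 p[["tau"]], p[["f"]]))
  phi <- (p[["phi"]] + pi) %% (2 * pi) - pi
  if (phi <= -pi) phi <- phi + 2 * pi
  structure(list(I0_fit = p[["I0"]], tau_fit = p[["tau"]],
                 tau_cycles = p[["tau"]] * p[["f"]], f_fit = p[["f"]],
                 phi = phi,
                 rms_residual = sqrt(mean(stats::residuals(fit)^2)),
                 converged = TRUE, model = model),
            class = "waveform_fit")
}

#' @export
print.waveform_fit <- function(x, ...) {
  cat(sprintf("waveform fit: I0 = %.4g A, tau = %.4g s (%.2f cycles), f = %.6g Hz, phi = %.3f rad, rms = %.3g\n",
              x$I0_fit, x$tau_fit, x$tau_cycles, x$f_fit, x$phi, x$rms_residual))
  invisible(x)
}

#' Steady-state sinusoid amplitude of a trace
#'
#' Fits a plain sinusoid to the steady-state portion of a waveform (the
#' final quarter of the samples by default) by quadrature least squares at
#' the trace's estimated frequency, as used to obtain the steady-state
#' voltage amplitude entering [series_resistance()].
#'
#' @param trace A `waveform_trace`.
#' @param fraction Final fraction of samples regarded as steady state.
#' @return Amplitude (same units as the trace).
#' @export
fit_steady_amplitude <- function(trace, fraction = 0.25) {
  stopifnot(inherits(trace, "waveform_trace"), fraction > 0, fraction <= 1)
  n <- length(trace$times)
  idx <- seq.int(floor(n * (1 - fraction)) + 1L, n)
  ts <- trace$times[idx]; ys <- trace$values[idx]
  ## frequency from linearly interpolated zero-crossing times: a plain
  ## crossing count is too coarse for a quadrature regression over many
  ## cycles (a 1% frequency error dephases the regressors completely)
  sgn <- sign(ys); sgn[sgn == 0] <- 1
  cross <- which(diff(sgn) != 0)
  if (length(cross) < 3L) stop("too few cycles in the steady-state window")
  tc <- ts[cross] - ys[cross] * (ts[cross + 1L] - ts[cross]) /
    (ys[cross + 1L] - ys[cross])
  f0 <- (length(tc) - 1L) / (2 * (tc[length(tc)] - tc[1L]))
  X <- cbind(sin(2 * pi * f0 * ts), cos(2 * pi * f0 * ts))
  ab <- stats::coef(stats::lm.fit(X, ys))
  sqrt(sum(ab^2))
}

#' Equivalent series resistance from fitted amplitudes
#'
#' At resonance the reactances cancel, so the steady-state ratio of fitted
#' voltage to fitted current amplitude is the circuit's series resistance.
#'
#' @param V0_fit Fitted steady-state voltage amplitude (V).
#' @param I0_fit Fitted steady-state current amplitude (A).
#' @return Resistance in Ohm.
#' @export
series_resistance <- function(V0_fit, I0_fit) {
  if (any(I0_fit <= 0)) stop("I0_fit must be positive")
  V0_fit / I0_fit
}

#' Locate the resonance by a frequency sweep
#'
#' Evaluates the steady-state current amplitude `V0 / |Z(f)|` of the series
#' circuit over a uniform sweep and refines the maximum with a three-point
#' parabolic interpolation, mirroring the experimental 20-point / 400 Hz
#' resonance search.
#'
#' @param cfg A tuned [circuit_config()].
#' @param center Sweep centre (Hz).
#' @param span Sweep width (Hz).
#' @param n_points Number of sweep points.
#' @return The refined resonance frequency (Hz), with attribute
#'   `grid_resolution_hz = span / n_points`. A maximum on the sweep boundary
#'   raises a warning and is flagged with attribute `at_boundary = TRUE`.
#' @export
find_resonance <- function(cfg, center, span = 400, n_points = 20L) {
  stopifnot(inherits(cfg, "circuit_config"))
  if (!cfg$tuned) stop("no resonance: circuit has no series capacitance")
  freqs <- seq(center - span / 2, center + span / 2, length.out = n_points)
  if (any(freqs <= 0)) stop("sweep extends to non-positive frequencies")
  w <- 2 * pi * freqs
  amp <- 1 / sqrt(cfg$R^2 + (w * cfg$L - 1 / (w * cfg$C))^2)
  k <- which.max(amp)
  at_boundary <- k == 1L || k == n_points
  if (at_boundary) {
    warning("resonance at sweep boundary; widen the sweep")
    f_hat <- freqs[k]
  } else {
    ## parabolic refinement through the three points around the maximum
    y1 <- amp[k - 1L]; y2 <- amp[k]; y3 <- amp[k + 1L]
    h <- freqs[2L] - freqs[1L]
    f_hat <- freqs[k] + h / 2 * (y1 - y3) / (y1 - 2 * y2 + y3)
  }
  structure(f_hat, grid_resolution_hz = span / n_points, at_boundary = at_boundary)
}

#' The experiment's tuned capacitor bank
#'
#' The ten series-capacitor settings of the switchable bank, with the
#' resulting resonant frequencies for the default coil inductance. The
#' inductance is not printed with the coil; the default 0.87 mH is a
#' least-squares fit of `1/((2 pi f_res)^2 C)` over the high-frequency
#' (C, f_res) pairs. Per-setting series resistances are chosen so that the
#' natural ramp-up time constant, expressed in cycles, interpolates (in log
#' frequency) between the two known anchors: 12.7 cycles at 4.04 kHz and
#' 22.3 cycles at 35.4 kHz, clamped outside.
#'
#' @param L Coil inductance (H).
#' @return data.frame with columns `C_F`, `f_res_hz`, `tau_nat_cycles`,
#'   `R_ohm`.
#' @export
tuned_bank <- function(L = 0.87e-3) {
  C <- c(3.73, 6.54, 12.1, 23.3, 45.6, 101, 453, 1870, 5020, 14400) * 1e-9
  f_res <- resonant_frequency(L, C)
  anchors_f <- log10(c(4040, 35400))
  anchors_c <- c(12.7, 22.3)
  sl <- diff(anchors_c) / diff(anchors_f)
  tau_cycles <- pmin(pmax(anchors_c[1L] + sl * (log10(f_res) - anchors_f[1L]),
                          anchors_c[1L]), anchors_c[2L])
  R <- 2 * L * f_res / tau_cycles
  data.frame(C_F = C, f_res_hz = f_res, tau_nat_cycles = tau_cycles, R_ohm = R)
}
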