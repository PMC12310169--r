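#' Hyperbolic strength-duration threshold
#'
#' The hyperbolic strength-duration curve (SDC) for sinusoidal stimuli:
#' `B_th(f) = B_rheo * (1 + 1 / (2 * tau_chron * f))`. The rheobase
#' `B_rheo` is the high-frequency threshold asymptote; the chronaxie
#' `tau_chron` is the duration at which the threshold is twice the rheobase.
#'
#' @param f Stimulus frequency (Hz).
#' @param B_rheo Rheobase (mT).
#' @param tau_chron Chronaxie (s).
#' @return Threshold in mT, vectorised over `f`.
#' @examples
#' hyperbolic_threshold(200, 6.27, 405e-6)  # 44.97 mT
#' @export
hyperbolic_threshold <- function(f, B_rheo, tau_chron) {
  if (any(f <= 0) || B_rheo <= 0 || tau_chron <= 0)
    stop("f, B_rheo and tau_chron must be positive")
  B_rheo * (1 + 1 / (2 * tau_chron * f))
}

#' Fit the hyperbolic strength-duration curve
#'
#' Unweighted nonlinear least squares of the hyperbolic SDC to mean
#' thresholds, using only frequencies at or below `cutoff` (the regime where
#' the hyperbolic model is expected to hold); residuals are reported for all
#' supplied frequencies so high-frequency deviations can be inspected.
#'
#' @param frequencies Frequencies (Hz).
#' @param mean_thresholds Mean thresholds (mT), same length.
#' @param cutoff Only `frequencies <= cutoff` enter the fit (Hz).
#' @return Object of class `sdc_fit`: `B_rheo` (mT), `tau_chron` (s),
#'   `fit_cutoff`, `residuals` (data.frame `frequency_hz`, `observed_mt`,
#'   `predicted_mt`, `residual_mt`, `in_fit`).
#' @export
fit_sdc <- function(frequencies, mean_thresholds, cutoff = 10e3) {
  stopifnot(length(frequencies) == length(mean_thresholds))
  in_fit <- frequencies <= cutoff
  if (sum(in_fit) < 3L) stop("need at least 3 frequencies at or below the cutoff")
  df <- data.frame(f = frequencies[in_fit], B = mean_thresholds[in_fit])
  fit <- tryCatch(
    minpack.lm::nlsLM(B ~ Brheo * (1 + 1 / (2 * tau * f)), data = df,
                      start = list(Brheo = min(df$B), tau = 200e-6),
                      lower = c(1e-9, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "SDC fit failed to converge: %s (starts: Brheo = %.3g, tau = 2e-4)",
      conditionMessage(e), min(df$B))))
  p <- stats::coef(fit)
  pred <- hyperbolic_threshold(frequencies, p[["Brheo"]], p[["tau"]])
  structure(list(B_rheo = p[["Brheo"]], tau_chron = p[["tau"]],
                 fit_cutoff = cutoff,
                 residuals = data.frame(frequency_hz = frequencies,
                                        observed_mt = mean_thresholds,
                                        predicted_mt = pred,
                                        residual_mt = mean_thresholds - pred,
                                        in_fit = in_fit)),
            class = "sdc_fit")
}

#' @export
print.sdc_fit <- function(x, ...) {
  cat(sprintf("hyperbolic SDC fit (f <= %g Hz): B_rheo = %.4g mT, tau_chron = %.4g us\n",
              x$fit_cutoff, x$B_rheo, x$tau_chron * 1e6))
  invisible(x)
}

#' IEC effective stimulus duration
#'
#' The IEC 60601-2-33 waveform-agnostic duration: the difference between
#' the amplitudes of the first two waveform peaks divided by the maximum
#' derivative of the waveform over that interval. Closed forms:
#' `t_eff = 1/(pi f) = (2/pi) t_pulse` for a sinusoid (with
#' `t_pulse = 1/(2f)`, the half-period), and `t_eff = t_pulse` for a
#' trapezoid (ramp time between plateaus). Generic sampled waveforms are
#' handled numerically: extrema located by sign changes of the discrete
#' derivative (with a plateau tolerance), then the IEC ratio.
#'
#' @param x For `kind = "sinusoid"`, the frequency (Hz); for
#'   `kind = "trapezoid"`, ignored (`t_pulse` must be given); for
#'   `kind = "generic"`, a `waveform_trace` (or list with `times`,
#'   `values`) containing at least two extrema.
#' @param kind Waveform kind.
#' @param t_pulse Pulse duration (s); required for trapezoids.
#' @param plateau_tol Relative derivative tolerance below which samples
#'   count as a plateau (generic kind).
#' @return List of class `effective_duration`: `t_eff` (s), `t_pulse` (s),
#'   `waveform_kind`.
#' @export
effective_duration <- function(x, kind = c("sinusoid", "trapezoid", "generic"),
                               t_pulse = NULL, plateau_tol = 1e-3) {
  kind <- match.arg(kind)
  if (kind == "sinusoid") {
    f <- x
    if (f <= 0) stop("frequency must be positive")
    out <- list(t_eff = 1 / (pi * f), t_pulse = 1 / (2 * f),
                waveform_kind = "sinusoid")
  } else if (kind == "trapezoid") {
    if (is.null(t_pulse) || t_pulse <= 0)
      stop("trapezoid requires a positive t_pulse")
    out <- list(t_eff = t_pulse, t_pulse = t_pulse, waveform_kind = "trapezoid")
  } else {
    tt <- x$times; v <- x$values
    dv <- diff(v) / diff(tt)
    thr <- plateau_tol * max(abs(dv))
    s <- sign(dv); s[abs(dv) < thr] <- 0
    ## first sample of each run of constant (nonzero) slope sign
    runs <- rle(s)
    ends <- cumsum(runs$lengths)
    ext <- integer(0)
    prev_sign <- 0
    for (j in seq_along(runs$values)) {
      sv <- runs$values[j]
      if (sv != 0) {
        if (prev_sign != 0 && sv != prev_sign)
          ext <- c(ext, ends[j] - runs$lengths[j] + 1L)
        prev_sign <- sv
      }
    }
    if (length(ext) < 2L) stop("waveform has fewer than 2 extrema")
    i1 <- ext[1L]; i2 <- ext[2L]
    amp_diff <- abs(v[i1] - v[i2])
    max_slope <- max(abs(dv[i1:(i2 - 1L)]))
    out <- list(t_eff = amp_diff / max_slope, t_pulse = tt[i2] - tt[i1],
                waveform_kind = "generic")
  }
  structure(out, class = "effective_duration")
}

#' Pulse-duration scaling-law parameters
#'
#' Parameters of the empirical sinusoidal-burst duration law
#' `B_norm(T_pulse) = 1 + alpha * exp(-(T_pulse/beta)^gamma)` relating the
#' rheobase-normalised threshold to the total pulse duration in
#' milliseconds (Saritas et al. forearm measurements; alpha = 0.44,
#' beta = 4.32 ms, gamma = 0.60).
#'
#' @param alpha Dimensionless amplitude of the short-pulse elevation.
#' @param beta Duration scale (ms).
#' @param gamma Stretching exponent in (0, 1].
#' @return Object of class `scaling_params`.
#' @export
scaling_params <- function(alpha = 0.44, beta = 4.32, gamma = 0.60) {
  if (alpha < 0 || beta <= 0 || gamma <= 0 || gamma > 1)
    stop("require alpha >= 0, beta > 0, 0 < gamma <= 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "scaling_params")
}

#' Duration normalisation factor
#'
#' `B_norm(T_pulse) = 1 + alpha * exp(-(T_pulse/beta)^gamma)`: the factor by
#' which a finite pulse of total duration `T_pulse` elevates the threshold
#' above its infinite-duration (rheobase) value.
#'
#' @param T_pulse_ms Total pulse duration in milliseconds (strictly; `beta`
#'   is in ms). `Inf` is allowed and gives 1.
#' @param params A [scaling_params()].
#' @return Dimensionless factor in (1, 1 + alpha].
#' @export
duration_norm <- function(T_pulse_ms, params = scaling_params()) {
  if (any(T_pulse_ms <= 0)) stop("T_pulse_ms must be positive")
  ifelse(is.infinite(T_pulse_ms), 1,
         1 + params$alpha * exp(-(T_pulse_ms / params$beta)^params$gamma))
}

#' Rescale a threshold to a different pulse duration
#'
#' Converts a threshold measured with total pulse duration `T_measured_ms`
#' to the threshold expected at `T_target_ms`, via the duration law:
#' `B_target = B_measured * B_norm(T_target) / B_norm(T_measured)`. An
#' infinite target rescales to the continuous-wave (rheobase-duration)
#' threshold.
#'
#' @param B_measured Measured threshold (mT).
#' @param T_measured_ms Duration of the measurement pulse (ms).
#' @param T_target_ms Target duration (ms); default `Inf`.
#' @param params A [scaling_params()].
#' @return Rescaled threshold (mT).
#' @examples
#' scale_to_duration(5.11, pulse_duration(25300))  # 4.72 mT
#' scale_to_duration(7.09, pulse_duration(88100))  # 5.91 mT
#' @export
scale_to_duration <- function(B_measured, T_measured_ms, T_target_ms = Inf,
                              params = scaling_params()) {
  if (any(B_measured <= 0)) stop("B_measured must be positive")
  B_measured * duration_norm(T_target_ms, params) / duration_norm(T_measured_ms, params)
}
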