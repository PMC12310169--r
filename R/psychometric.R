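#' Logistic response probability
#'
#' Probability that a subject reports a sensation at peak field amplitude B,
#' under the two-parameter psychometric sigmoid
#' `g(B) = 1 / (1 + exp(-(B - B_th) / B_width))`. `B_th` is the threshold
#' (probability 0.5) and `B_width` sets the sharpness of the transition from
#' non-stimulating to stimulating amplitudes.
#'
#' @param B Field amplitude(s) (mT, peak at coil centre).
#' @param B_th Threshold (mT).
#' @param B_width Width parameter (mT), > 0.
#' @return Probability in (0, 1), vectorised over `B`.
#' @examples
#' sigmoid_probability(8.23, 8.23, 0.1)          # 0.5 at threshold
#' sigmoid_probability(8.23 + 0.1 * log(3), 8.23, 0.1)  # 0.75
#' @export
sigmoid_probability <- function(B, B_th, B_width) {
  if (any(B_width <= 0)) stop("B_width must be positive")
  stats::plogis((B - B_th) / B_width)
}

## fast internal negative log-likelihood; s = 2*y - 1 (+1/-1 coding)
.sigmoid_nll <- function(amp, s, B_th, B_width) {
  z <- (amp - B_th) / B_width
  ## -sum(y*log(p) + (1-y)*log(1-p)), numerically stable form
  u <- -z * s
  sum(log1p(exp(-abs(z))) + u * (u > 0))
}

## core fitter on bare vectors (validation done by callers)
.fit_sigmoid_core <- function(amp, y, width_floor, ridge, maxit, reltol) {
  max_neg <- max(amp[y == 0L])
  min_pos <- min(amp[y == 1L])
  if (max_neg < min_pos) {
    gap <- min_pos - max_neg
    return(list(B_th = (max_neg + min_pos) / 2,
                B_width = max(width_floor, gap / 4),
                n_pulses = length(y), converged = TRUE,
                separation_flag = TRUE, logLik = 0))
  }
  s <- 2 * y - 1
  s_amp <- stats::sd(amp)
  obj <- function(p) {
    w <- exp(p[2L])
    .sigmoid_nll(amp, s, p[1L], w) + ridge * (s_amp / w)^2
  }
  start <- c((max_neg + min_pos) / 2,
             log(max(width_floor, (max_neg - min_pos) / 4, s_amp / 10)))
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = reltol))
  B_width <- max(exp(o$par[2L]), width_floor)
  list(B_th = o$par[1L], B_width = B_width,
       n_pulses = length(y), converged = o$convergence == 0,
       separation_flag = FALSE,
       logLik = -.sigmoid_nll(amp, s, o$par[1L], B_width))
}

#' Fit the psychometric sigmoid to binary responses
#'
#' Maximum-likelihood estimation of (B_th, B_width) from binary
#' stimulus-response pairs, optimised over (B_th, log B_width). Perfectly
#' separable data (every non-response amplitude below every response
#' amplitude) has a divergent unpenalised MLE; such runs return the midpoint
#' of the separating gap as threshold and `max(width_floor, gap/4)` as
#' width, flagged via `separation_flag`. A tiny scale-equivariant ridge on
#' `1/B_width` (`ridge * (sd(amplitude)/B_width)^2`) keeps near-separable
#' fits numerically stable.
#'
#' @param responses data.frame with columns `amplitude_mt` and `response`
#'   (0/1), e.g. from [run_titration()].
#' @param width_floor Lower bound for the reported width (mT).
#' @param ridge Ridge weight on `(sd(amplitude)/B_width)^2`; effectively
#'   pure ML at the default.
#' @return Object of class `sigmoid_fit`: `B_th`, `B_width` (mT),
#'   `n_pulses`, `converged`, `separation_flag`, `logLik`.
#' @export
fit_sigmoid <- function(responses, width_floor = 1e-3, ridge = 1e-6,
                        maxit = 1000, reltol = 1e-12) {
  amp <- responses$amplitude_mt
  y <- responses$response
  if (any(amp <= 0)) stop("amplitudes must be positive")
  if (!all(y %in% c(0, 1))) stop("responses must be binary (0/1)")
  if (!any(y == 1)) stop("cannot fit: no positive (stimulation) responses")
  if (!any(y == 0)) stop("cannot fit: no negative (no-stimulation) responses")
  structure(.fit_sigmoid_core(amp, as.integer(y), width_floor, ridge,
                              maxit, reltol),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit: B_th = %.4g mT, B_width = %.4g mT (%d pulses%s)\n",
              x$B_th, x$B_width, x$n_pulses,
              if (x$separation_flag) ", separable" else ""))
  invisible(x)
}

#' Titration protocol parameters
#'
#' The adaptive threshold search: a coarse upward amplitude ramp (~10 mT
#' steps below 1 kHz, ~5 mT above) until the first reported sensation, then
#' a fine up/down staircase with step `initial_estimate / fine_divisor`,
#' refitting the sigmoid after every response. A run whose coarse ramp
#' reaches the amplifier ceiling without any sensation is censored at the
#' ceiling.
#'
#' @param coarse_step_low_f Coarse step below `low_f_cutoff` (mT).
#' @param coarse_step_high_f Coarse step at or above `low_f_cutoff` (mT).
#' @param low_f_cutoff Frequency cutoff between the two coarse steps (Hz).
#' @param fine_divisor Fine step = initial estimate / `fine_divisor`.
#' @param n_fine_pulses Number of staircase pulses after the coarse ramp.
#' @param start_amplitude First coarse amplitude (mT); default one coarse
#'   step (resolved per frequency when `NULL`).
#' @param ceiling Maximum deliverable amplitude (mT); may be overridden per
#'   run.
#' @return Object of class `titration_protocol`.
#' @export
titration_protocol <- function(coarse_step_low_f = 10, coarse_step_high_f = 5,
                               low_f_cutoff = 1000, fine_divisor = 80,
                               n_fine_pulses = 24L, start_amplitude = NULL,
                               ceiling = Inf) {
  if (coarse_step_low_f <= 0 || coarse_step_high_f <= 0 || fine_divisor <= 0)
    stop("all steps must be positive")
  if (n_fine_pulses < 1) stop("n_fine_pulses must be >= 1")
  structure(list(coarse_step_low_f = coarse_step_low_f,
                 coarse_step_high_f = coarse_step_high_f,
                 low_f_cutoff = low_f_cutoff, fine_divisor = fine_divisor,
                 n_fine_pulses = as.integer(n_fine_pulses),
                 start_amplitude = start_amplitude, ceiling = ceiling),
            class = "titration_protocol")
}

coarse_step_for <- function(protocol, frequency) {
  if (frequency < protocol$low_f_cutoff) protocol$coarse_step_low_f
  else protocol$coarse_step_high_f
}

#' Run a virtual threshold titration
#'
#' Simulates the experimental protocol against a virtual subject described
#' by a response-probability curve: coarse upward ramp until the first
#' positive response (or the ceiling), then an up/down fine staircase around
#' the running threshold estimate, refitting the sigmoid after each
#' response. Censoring (no sensation below the ceiling) is a valid outcome,
#' not an error.
#'
#' @param true_curve Function mapping amplitude (mT) to response
#'   probability.
#' @param frequency Stimulus frequency (Hz); selects the coarse step and is
#'   recorded with each pulse.
#' @param protocol A [titration_protocol()].
#' @param seed Optional integer seed giving a reproducible pulse stream.
#' @param subject_id,run_id Identifiers recorded with each pulse.
#' @param ceiling Overrides `protocol$ceiling` (mT).
#' @return A list of class `titration_run`: `responses` (data.frame
#'   `subject_id, run_id, frequency_hz, amplitude_mt, response`),
#'   `censored`, and either `fit` (a `sigmoid_fit`) or `censored_at` (mT).
#' @export
run_titration <- function(true_curve, frequency, protocol = titration_protocol(),
                          seed = NULL, subject_id = "s1", run_id = 1L,
                          ceiling = protocol$ceiling) {
  stopifnot(is.function(true_curve), inherits(protocol, "titration_protocol"))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  step <- coarse_step_for(protocol, frequency)
  start <- if (is.null(protocol$start_amplitude)) step else protocol$start_amplitude
  if (start >= ceiling) stop("start_amplitude must lie below the ceiling")
  amps <- numeric(0); ys <- integer(0)
  present <- function(a) {
    y <- stats::rbinom(1L, 1L, true_curve(a))
    amps <<- c(amps, a); ys <<- c(ys, y)
    y
  }
  ## coarse ascent
  amp <- start
  first_pos <- NA_real_
  repeat {
    y <- present(amp)
    if (y == 1L) { first_pos <- amp; break }
    if (amp >= ceiling) break
    amp <- min(amp + step, ceiling)
  }
  mk_df <- function() data.frame(subject_id = subject_id, run_id = run_id,
                                 frequency_hz = frequency, amplitude_mt = amps,
                                 response = ys)
  if (is.na(first_pos)) {
    ## no sensation anywhere below (or at) the amplifier ceiling
    return(structure(list(responses = mk_df(), censored = TRUE,
                          censored_at = ceiling), class = "titration_run"))
  }
  ## fine staircase (a first positive exactly at the ceiling still gets the
  ## fine search: the threshold may sit just below the maximum output)
  fine_step <- first_pos / protocol$fine_divisor
  width_floor <- fine_step / 10
  est <- first_pos
  last_y <- 1L
  fit <- NULL
  refit <- function(final = FALSE) {
    if (!any(ys == 1L) || !any(ys == 0L)) return(NULL)
    ## interim refits only steer the staircase; coarse optimiser settings
    ## suffice there, the final estimate gets full precision
    if (final)
      structure(.fit_sigmoid_core(amps, ys, width_floor, 1e-6, 1000, 1e-12),
                class = "sigmoid_fit")
    else .fit_sigmoid_core(amps, ys, width_floor, 1e-6, 200, 1e-8)
  }
  for (k in seq_len(protocol$n_fine_pulses)) {
    a <- est + if (last_y == 1L) -fine_step else fine_step
    a <- min(max(a, fine_step), ceiling)
    last_y <- present(a)
    fit <- refit()
    est <- if (is.null(fit)) a else fit$B_th
  }
  ## a subject who only ever responded at the maximum output is censored:
  ## the threshold itself lies at or above the ceiling
  if (!any(ys == 1L & amps < ceiling * (1 - 1e-12)))
    return(structure(list(responses = mk_df(), censored = TRUE,
                          censored_at = ceiling), class = "titration_run"))
  ## degenerate staircases (threshold below the lowest amplitude visited)
  ## are extended downward until a non-response brackets the threshold
  extra <- 0L
  while (!any(ys == 0L) && extra < 50L) {
    est <- min(amps) - fine_step
    if (est <= 0) break
    last_y <- present(est)
    extra <- extra + 1L
  }
  fit <- refit(final = TRUE)
  if (is.null(fit))
    stop("titration failed to bracket the threshold (no negative responses)")
  structure(list(responses = mk_df(), censored = FALSE, fit = fit,
                 fine_step = fine_step), class = "titration_run")
}

#' @export
print.titration_run <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("titration: censored at %.3g mT after %d pulses\n",
                x$censored_at, nrow(x$responses)))
  } else {
    cat(sprintf("titration: B_th = %.4g mT after %d pulses\n",
                x$fit$B_th, nrow(x$responses)))
  }
  invisible(x)
}
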