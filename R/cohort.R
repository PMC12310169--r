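#' Ground-truth population threshold-curve parameters
#'
#' Generative stand-in for the observed non-monotonic threshold-frequency
#' relationship: a hyperbolic strength-duration backbone multiplied by a
#' smooth high-frequency rise,
#' `B(f) = B_rheo (1 + 1/(2 tau_chron f)) * (1 + a * max(0, ln(f/f_k))^q)`.
#' With `a = 0` the curve is the pure hyperbolic SDC. The defaults are
#' calibrated so the curve has its minimum near 20 kHz (between the 16.9 and
#' 25.3 kHz study frequencies) and rises by ~39% from 25.3 to 88.1 kHz,
#' matching the study's headline pattern: `a = 0.176` solves
#' `B(88.1 kHz)/B(25.3 kHz) = 1.39` exactly for `q = 2`.
#'
#' @param B_rheo Rheobase of the backbone (mT).
#' @param tau_chron Chronaxie of the backbone (s).
#' @param a Rise amplitude (0 disables the rise).
#' @param f_k Rise knee frequency (Hz).
#' @param q Rise exponent.
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(B_rheo = 4.4, tau_chron = 405e-6, a = 0.176,
                         f_k = 16.9e3, q = 2) {
  if (B_rheo <= 0 || tau_chron <= 0 || f_k <= 0 || q <= 0 || a < 0)
    stop("parameters must be positive (a may be zero)")
  structure(list(B_rheo = B_rheo, tau_chron = tau_chron, a = a,
                 f_k = f_k, q = q), class = "truth_params")
}

#' Population threshold curve of the synthetic cohort
#'
#' @param f Frequency (Hz), vectorised.
#' @param p A [truth_params()].
#' @return Threshold in mT.
#' @export
true_threshold_curve <- function(f, p = truth_params()) {
  stopifnot(inherits(p, "truth_params"))
  if (any(f <= 0)) stop("f must be positive")
  hyperbolic_threshold(f, p$B_rheo, p$tau_chron) *
    (1 + p$a * pmax(0, log(f / p$f_k))^p$q)
}

#' Synthetic cohort specification
#'
#' The study conditions for the virtual experiment: 8 subjects, the 16
#' stimulus frequencies (200 Hz to 88.1 kHz), a population threshold curve
#' ([truth_params()]), multiplicative lognormal inter-subject spread
#' (median 1) with coefficient of variation `inter_subject_cv`, per-subject
#' sigmoid widths proportional to the threshold, and per-frequency
#' amplifier ceilings. Default ceilings are finite only where the study saw
#' censoring: the population lognormal 75th percentile at 600 Hz (2/8
#' censored expected), and the 40th percentile at 700 Hz and 88.1 kHz (5/8
#' expected); infinite elsewhere.
#'
#' @param n_subjects Cohort size.
#' @param frequencies Stimulus frequencies (Hz), ascending.
#' @param truth A [truth_params()].
#' @param inter_subject_cv CV of the multiplicative subject factor, in
#'   \[0, 0.5\].
#' @param width_fraction Sigmoid width as a fraction of the true threshold.
#' @param ceilings Named numeric vector of per-frequency ceilings (mT);
#'   names are frequencies in Hz. `NULL` gives the defaults above.
#' @param seed Master seed for the cohort and all derived pulse streams.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 8L,
                        frequencies = c(200, 300, 400, 500, 600, 700,
                                        1760, 2590, 4040, 8050, 16900,
                                        25300, 35400, 49000, 66700, 88100),
                        truth = truth_params(),
                        inter_subject_cv = 0.15,
                        width_fraction = 0.03,
                        ceilings = NULL,
                        seed = 1L) {
  if (is.unsorted(frequencies, strictly = TRUE) || any(frequencies <= 0))
    stop("frequencies must be positive and strictly ascending")
  if (inter_subject_cv < 0 || inter_subject_cv > 0.5)
    stop("inter_subject_cv must be in [0, 0.5]")
  if (width_fraction <= 0) stop("width_fraction must be positive")
  if (is.null(ceilings)) {
    sdlog <- sqrt(log(1 + inter_subject_cv^2))
    ceilings <- rep(Inf, length(frequencies))
    names(ceilings) <- as.character(frequencies)
    qceil <- function(f, prob) true_threshold_curve(f, truth) *
      stats::qlnorm(prob, 0, sdlog)
    for (f in c(600, 700, 88100)) {
      key <- as.character(f)
      if (key %in% names(ceilings))
        ceilings[key] <- qceil(f, if (f == 600) 0.75 else 0.40)
    }
  } else {
    if (is.null(names(ceilings)) ||
        !all(as.character(frequencies) %in% names(ceilings)))
      stop("ceilings must be named by frequency (Hz) and cover all frequencies")
    if (any(ceilings <= 0)) stop("ceilings must be positive")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 frequencies = frequencies, truth = truth,
                 inter_subject_cv = inter_subject_cv,
                 width_fraction = width_fraction,
                 ceilings = ceilings, seed = as.integer(seed)),
            class = "cohort_spec")
}

## Deterministic per-(subject, frequency, run) seed stream derived from the
## master seed; keeps every titration reproducible in isolation. All
## arithmetic stays far below 2^31.
derive_seed <- function(master, subject, freq_index, run = 1L) {
  (((master %% 50021) * 65537 + subject * 2617 +
      freq_index * 131 + run * 19) %% 2147483629) + 1
}

#' Draw a cohort of virtual subjects
#'
#' Subject i's threshold curve is the population curve times a lognormal
#' factor `s_i` (median 1, CV = `inter_subject_cv`); the per-(subject,
#' frequency) sigmoid width is `width_fraction` times the true threshold.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame of class `cohort_truth` with one row per (subject,
#'   frequency): `subject_id`, `frequency_hz`, `b_true_mt`, `b_width_mt`,
#'   `subject_scale`, plus the spec as attribute.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sdlog <- sqrt(log(1 + spec$inter_subject_cv^2))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(derive_seed(spec$seed, 0L, 0L))
  s <- stats::rlnorm(spec$n_subjects, meanlog = 0, sdlog = sdlog)
  pop <- true_threshold_curve(spec$frequencies, spec$truth)
  df <- expand.grid(subject = seq_len(spec$n_subjects),
                    fi = seq_along(spec$frequencies), KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(subject_id = sprintf("s%02d", df$subject),
                    frequency_hz = spec$frequencies[df$fi],
                    b_true_mt = pop[df$fi] * s[df$subject],
                    b_width_mt = NA_real_,
                    subject_scale = s[df$subject])
  out$b_width_mt <- spec$width_fraction * out$b_true_mt
  out <- out[order(out$subject_id, out$frequency_hz), ]
  rownames(out) <- NULL
  structure(out, class = c("cohort_truth", "data.frame"), spec = spec)
}

#' Simulate the full titration experiment
#'
#' Runs the titration protocol for every (subject, frequency) of a virtual
#' cohort, with per-run derived seeds, the per-frequency amplifier
#' ceilings, and optional test-retest repeats. Each subject's response to a
#' pulse of amplitude B is Bernoulli with probability
#' [sigmoid_probability()]`(B, b_true, b_width)`.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [titration_protocol()].
#' @param cohort Optional pre-drawn [sample_cohort()] result (defaults to
#'   drawing from `spec`).
#' @param retest_frequencies Frequencies repeated for test-retest (run 2);
#'   default 1.76 and 25.3 kHz. Set `NULL` to disable.
#' @param retest_subjects Indices of the subjects retested (default 2:6,
#'   five subjects).
#' @return List of class `pns_experiment`: `responses` (every pulse),
#'   `thresholds` (one row per (subject, frequency, run): `b_th_mt` or
#'   `censored_at_mt`, plus `b_width_mt` and `n_pulses`), `cohort`, `spec`,
#'   `protocol`.
#' @export
simulate_experiment <- function(spec = cohort_spec(),
                                protocol = titration_protocol(),
                                cohort = sample_cohort(spec),
                                retest_frequencies = c(1760, 25300),
                                retest_subjects = 2:6) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(protocol, "titration_protocol"))
  runs <- data.frame(subject = rep(seq_len(spec$n_subjects),
                                   each = length(spec$frequencies)),
                     fi = rep(seq_along(spec$frequencies), spec$n_subjects),
                     run = 1L)
  if (!is.null(retest_frequencies)) {
    rs <- intersect(retest_subjects, seq_len(spec$n_subjects))
    fi2 <- match(retest_frequencies, spec$frequencies)
    if (anyNA(fi2)) stop("retest_frequencies must be study frequencies")
    runs <- rbind(runs, expand.grid(subject = rs, fi = fi2, run = 2L,
                                    KEEP.OUT.ATTRS = FALSE))
  }
  resp_list <- vector("list", nrow(runs))
  thr_list <- vector("list", nrow(runs))
  for (k in seq_len(nrow(runs))) {
    su <- runs$subject[k]; fi <- runs$fi[k]; rn <- runs$run[k]
    f <- spec$frequencies[fi]
    sid <- sprintf("s%02d", su)
    row <- cohort[cohort$subject_id == sid & cohort$frequency_hz == f, ][1L, ]
    curve <- local({
      bt <- row$b_true_mt; bw <- row$b_width_mt
      function(B) sigmoid_probability(B, bt, bw)
    })
    res <- run_titration(curve, f, protocol,
                         seed = derive_seed(spec$seed, su, fi, rn),
                         subject_id = sid, run_id = rn,
                         ceiling = unname(spec$ceilings[as.character(f)]))
    resp_list[[k]] <- res$responses
    thr_list[[k]] <- data.frame(
      subject_id = sid, frequency_hz = f, run_id = rn,
      b_th_mt = if (res$censored) NA_real_ else res$fit$B_th,
      b_width_mt = if (res$censored) NA_real_ else res$fit$B_width,
      censored_at_mt = if (res$censored) res$censored_at else NA_real_,
      n_pulses = nrow(res$responses))
  }
  structure(list(responses = do.call(rbind, resp_list),
                 thresholds = do.call(rbind, thr_list),
                 cohort = cohort, spec = spec, protocol = protocol),
            class = "pns_experiment")
}

#' @export
print.pns_experiment <- function(x, ...) {
  cat(sprintf("synthetic PNS experiment: %d subjects x %d frequencies, %d pulses, %d censored runs\n",
              x$spec$n_subjects, length(x$spec$frequencies),
              nrow(x$responses), sum(!is.na(x$thresholds$censored_at_mt))))
  invisible(x)
}
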