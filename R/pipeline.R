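#' Read a titration record CSV
#'
#' Expected columns: `subject_id`, `run_id`, `frequency_hz`,
#' `amplitude_mt`, `response`. Malformed rows (non-binary response,
#' non-positive amplitude or frequency) are rejected with their file line
#' numbers.
#'
#' @param path CSV path.
#' @return data.frame of validated records; an empty file yields an empty
#'   data.frame with a warning.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "run_id", "frequency_hz", "amplitude_mt", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("no titration records in ", path)
    return(df)
  }
  bad <- which(!(df$response %in% c(0, 1)) | !(df$amplitude_mt > 0) |
                 !(df$frequency_hz > 0) | is.na(df$amplitude_mt))
  if (length(bad))
    stop("malformed titration record(s) at file line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (response must be 0/1, amplitude and frequency positive)")
  df
}

## serialise numeric columns at full double precision so that re-ingesting
## a written table reproduces downstream fits bit-identically
.full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  df
}

#' @rdname read_titration_csv
#' @param records data.frame of titration records.
#' @param path Output path.
#' @export
write_titration_csv <- function(records, path) {
  utils::write.csv(.full_precision(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a subject-threshold table CSV
#'
#' Columns: `subject_id`, `frequency_hz`, `run_id`, `b_th_mt` (NA when
#' censored), `censored_at_mt` (NA when observed). Exactly one of the two
#' must be present in each row.
#'
#' @param path CSV path.
#' @return data.frame of thresholds.
#' @export
read_thresholds_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "frequency_hz", "b_th_mt", "censored_at_mt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(is.na(df$b_th_mt) == is.na(df$censored_at_mt))
  if (length(bad))
    stop("threshold row(s) at file line(s) ", paste(bad + 1L, collapse = ", "),
         " must have exactly one of b_th_mt / censored_at_mt")
  df
}

#' @rdname read_thresholds_csv
#' @param thresholds data.frame of thresholds.
#' @export
write_thresholds_csv <- function(thresholds, path) {
  utils::write.csv(.full_precision(thresholds), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full synthetic threshold study
#'
#' Chains the pipeline end to end: simulate the cohort and titrations, pool
#' per-frequency thresholds with the censoring-aware Gaussian fit, fit the
#' hyperbolic strength-duration curve to the low-frequency means, rescale
#' mean thresholds to infinite pulse duration, and compare 25.3 kHz against
#' the high frequencies with independent-samples t-tests. In the
#' comparisons, censored subjects enter at their ceiling amplitude - a
#' lower bound on their threshold, which is conservative for detecting the
#' high-frequency threshold increase.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [titration_protocol()].
#' @param seed Overrides `spec$seed` when not `NULL`.
#' @param sdc_cutoff Frequency cutoff for the SDC fit (Hz).
#' @param n_cycles Cycles per pulse, for duration rescaling.
#' @param reference_frequency Frequency the comparisons are anchored at (Hz).
#' @param compare_frequencies_hz High frequencies compared against the
#'   reference.
#' @return List of class `pns_pipeline`: `experiment`, `population`
#'   (per-frequency data.frame with mean, sd, cv, censored counts, scaled
#'   mean), `sdc`, `comparisons`, `minimum_frequency_hz`, `seed`.
#' @export
run_pipeline <- function(spec = cohort_spec(), protocol = titration_protocol(),
                         seed = NULL, sdc_cutoff = 10e3, n_cycles = 256,
                         reference_frequency = 25300,
                         compare_frequencies_hz = c(49000, 66700, 88100)) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  exper <- simulate_experiment(spec, protocol)
  thr <- exper$thresholds[exper$thresholds$run_id == 1L, ]
  pop_rows <- lapply(spec$frequencies, function(f) {
    sub <- thr[thr$frequency_hz == f, ]
    n_obs <- sum(!is.na(sub$b_th_mt))
    if (n_obs < 2L) {
      ## too heavily censored to pool at this frequency: keep the counts,
      ## leave the moments undetermined
      return(data.frame(frequency_hz = f, mean_mt = NA_real_, sd_mt = NA_real_,
                        cv_percent = NA_real_, n_observed = n_obs,
                        n_censored = nrow(sub) - n_obs))
    }
    fit <- pooled_cdf_fit(sub)
    if (!is.finite(fit$mean) || fit$mean <= 0) {
      ## unidentifiable under this censoring pattern
      return(data.frame(frequency_hz = f, mean_mt = NA_real_, sd_mt = NA_real_,
                        cv_percent = NA_real_, n_observed = fit$n_observed,
                        n_censored = fit$n_censored))
    }
    data.frame(frequency_hz = f, mean_mt = fit$mean, sd_mt = fit$sd,
               cv_percent = cohort_cv(fit), n_observed = fit$n_observed,
               n_censored = fit$n_censored)
  })
  population <- do.call(rbind, pop_rows)
  population$duration_ms <- pulse_duration(population$frequency_hz, n_cycles)
  population$mean_scaled_mt <- scale_to_duration(
    ifelse(is.na(population$mean_mt), 1, population$mean_mt),
    population$duration_ms)
  population$mean_scaled_mt[is.na(population$mean_mt)] <- NA_real_
  keep <- !is.na(population$mean_mt)
  sdc <- fit_sdc(population$frequency_hz[keep], population$mean_mt[keep],
                 cutoff = sdc_cutoff)
  ## group values for comparisons: observed thresholds, censored at ceiling
  group_at <- function(f) {
    sub <- thr[thr$frequency_hz == f, ]
    ifelse(is.na(sub$b_th_mt), sub$censored_at_mt, sub$b_th_mt)
  }
  ref <- group_at(reference_frequency)
  comparisons <- lapply(compare_frequencies_hz, function(f) {
    ct <- compare_frequencies(ref, group_at(f))
    dur <- pulse_duration(c(reference_frequency, f), n_cycles)
    cts <- compare_frequencies(scale_to_duration(ref, dur[1L]),
                               scale_to_duration(group_at(f), dur[2L]))
    data.frame(frequency_hz = f, t = ct$t, p = ct$p,
               t_scaled = cts$t, p_scaled = cts$p,
               percent_change = percent_change(mean(ref), mean(group_at(f))))
  })
  comparisons <- do.call(rbind, comparisons)
  structure(list(experiment = exper, population = population, sdc = sdc,
                 comparisons = comparisons,
                 minimum_frequency_hz =
                   population$frequency_hz[which.min(population$mean_mt)],
                 seed = spec$seed),
            class = "pns_pipeline")
}

#' @export
print.pns_pipeline <- function(x, ...) {
  cat(sprintf("PNS pipeline (seed %d)\n", x$seed))
  cat(sprintf("  threshold minimum at %.3g kHz\n", x$minimum_frequency_hz / 1000))
  cat(sprintf("  SDC (f <= %g Hz): B_rheo = %.3g mT, tau_chron = %.3g us\n",
              x$sdc$fit_cutoff, x$sdc$B_rheo, x$sdc$tau_chron * 1e6))
  for (i in seq_len(nrow(x$comparisons)))
    cat(sprintf("  vs %.3g kHz: +%.1f%%, p = %.4g (scaled p = %.4g)\n",
                x$comparisons$frequency_hz[i] / 1000,
                x$comparisons$percent_change[i], x$comparisons$p[i],
                x$comparisons$p_scaled[i]))
  invisible(x)
}
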