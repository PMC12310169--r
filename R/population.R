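#' Censoring-aware population threshold fit
#'
#' Estimates the population mean and SD of per-subject thresholds at one
#' frequency, assuming thresholds are normally distributed across subjects.
#' Subjects whose threshold exceeds the amplifier ceiling are right-censored:
#' they contribute to the denominator of the empirical cumulative fraction
#' (default method) or a survival term (ML method) but provide no threshold
#' value.
#'
#' The default `"cdf-lsq"` method fits the Gaussian CDF
#' `pnorm((B - mean)/sd)` by least squares to the empirical fraction
#' stimulated evaluated at the observed thresholds; `"censored-mle"`
#' maximises the right-censored Gaussian likelihood and serves as the
#' independent cross-check.
#'
#' @param thresholds data.frame with columns `b_th_mt` (NA when censored)
#'   and `censored_at_mt` (ceiling, NA when observed); typically one row per
#'   subject at a single frequency.
#' @param method `"cdf-lsq"` or `"censored-mle"`.
#' @param plotting Plotting positions for the empirical CDF: `"hazen"`
#'   ((i - 0.5)/n) or `"ecdf"` (i/n).
#' @param sd_floor Lower bound on the fitted SD (mT), keeping degenerate
#'   data well-defined.
#' @return Object of class `population_fit`: `mean`, `sd` (mT),
#'   `n_observed`, `n_censored`, `method`.
#' @export
pooled_cdf_fit <- function(thresholds, method = c("cdf-lsq", "censored-mle"),
                           plotting = c("hazen", "ecdf"), sd_floor = 1e-3) {
  method <- match.arg(method)
  plotting <- match.arg(plotting)
  obs <- thresholds$b_th_mt[!is.na(thresholds$b_th_mt)]
  cens <- thresholds$censored_at_mt[is.na(thresholds$b_th_mt)]
  if (length(obs) == 0L) stop("all subjects censored: population mean is not estimable")
  if (length(obs) == 1L) stop("only one observed threshold: sd is not identifiable")
  n <- length(obs) + length(cens)
  if (max(obs) - min(obs) < sd_floor) {
    return(structure(list(mean = mean(obs), sd = sd_floor,
                          n_observed = length(obs), n_censored = length(cens),
                          method = method), class = "population_fit"))
  }
  if (method == "cdf-lsq") {
    x <- sort(obs)
    Fhat <- if (plotting == "hazen") (seq_along(x) - 0.5) / n else seq_along(x) / n
    z <- stats::qnorm(Fhat)
    st <- unname(stats::coef(stats::lm(x ~ z)))
    obj <- function(p) sum((stats::pnorm((x - p[1L]) / exp(p[2L])) - Fhat)^2)
    o <- stats::optim(c(st[1L], log(max(st[2L], sd_floor))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    est <- c(o$par[1L], exp(o$par[2L]))
  } else {
    nll <- function(p) {
      mu <- p[1L]; s <- exp(p[2L])
      v <- -sum(stats::dnorm(obs, mu, s, log = TRUE))
      if (length(cens))
        v <- v - sum(stats::pnorm(cens, mu, s, lower.tail = FALSE, log.p = TRUE))
      v
    }
    o <- stats::optim(c(mean(obs), log(max(stats::sd(obs), sd_floor))), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    est <- c(o$par[1L], exp(o$par[2L]))
  }
  structure(list(mean = unname(est[1L]), sd = unname(max(est[2L], sd_floor)),
                 n_observed = length(obs), n_censored = length(cens),
                 method = method),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("population fit (%s): mean = %.4g mT, sd = %.4g mT (%d observed, %d censored)\n",
              x$method, x$mean, x$sd, x$n_observed, x$n_censored))
  invisible(x)
}

#' Percent change relative to a reference
#'
#' @param reference Reference value (> 0).
#' @param value New value.
#' @return `100 * (value / reference - 1)`.
#' @examples
#' percent_change(5.11, 7.09)  # 38.7
#' @export
percent_change <- function(reference, value) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (value / reference - 1)
}

#' Independent-samples t-test between two frequencies
#'
#' Two-sided comparison of per-subject thresholds measured at two
#' frequencies. Student's pooled-variance test by default, Welch optional.
#' Two identical constant groups (zero variance everywhere) are returned as
#' t = 0, p = 1 rather than an error.
#'
#' @param groupA,groupB Numeric vectors of thresholds (mT), each length >= 2.
#' @param var_equal Use the pooled-variance (Student) flavour.
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`, `method`.
#' @export
compare_frequencies <- function(groupA, groupB, var_equal = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      mean(groupA) == mean(groupB)) {
    return(list(t = 0, p = 1, df = length(groupA) + length(groupB) - 2,
                mean_a = mean(groupA), mean_b = mean(groupB),
                method = "degenerate (identical constant groups)"))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(groupA), mean_b = mean(groupB), method = tt$method)
}

#' Bland-Altman test-retest summary
#'
#' Agreement statistics for repeated threshold titrations: mean difference
#' (retest - test), 95% limits of agreement (mean +/- 1.96 sample SD of the
#' differences), and per-pair percent change relative to the first
#' measurement.
#'
#' @param pairs data.frame (or matrix) with columns `test` and `retest`
#'   (mT), one row per subject.
#' @return List of class `retest_summary`: `mean_difference`, `loa_lower`,
#'   `loa_upper`, `sd_difference`, `percent_change` (per pair), `n`.
#' @export
test_retest <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("test", "retest") %in% names(pairs)))
  if (nrow(pairs) < 2L) stop("need at least 2 pairs for limits of agreement")
  d <- pairs$retest - pairs$test
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_difference = m, sd_difference = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 percent_change = percent_change(pairs$test, pairs$retest),
                 n = nrow(pairs)),
            class = "retest_summary")
}

#' @export
print.retest_summary <- function(x, ...) {
  cat(sprintf("test-retest (n = %d): mean diff = %.3g mT, limits of agreement [%.3g, %.3g] mT\n",
              x$n, x$mean_difference, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Coefficient of variation of a population fit
#'
#' @param fit A [pooled_cdf_fit()] result (or any list with `mean` and
#'   `sd`).
#' @return `100 * sd / mean` in percent.
#' @export
cohort_cv <- function(fit) {
  if (fit$mean <= 0) stop("mean must be positive")
  100 * fit$sd / fit$mean
}
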