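# Lagged cardiorespiratory coupling: Spearman cross-correlation between the
# breathing signal and the smoothed heart-rate series over -30..+30 s.

#' Cardiorespiratory cross-correlation
#'
#' Spearman rank correlation between the breathing waveform and the smoothed
#' heart-rate series at every lag on the grid (default -30..+30 s in steps
#' of the 4 Hz resampling period). The coupling statistic is the signed
#' coefficient of maximum magnitude and its lag. Positive lag means that
#' heart-rate changes follow breathing changes, so respiratory sinus
#' arrhythmia driven by breathing yields a positive lag. Correlations are
#' computed on the shrinking overlap only, with no padding.
#'
#' @param breathing breathing signal: either a numeric vector with
#'   `breathing_fs` given, or a list with elements `x` and `fs` (e.g. the
#'   output of [simulate_breathing()]). Internally resampled onto the
#'   heart-rate grid.
#' @param hr a [rate_series()], already smoothed (see [smooth_rate()]).
#' @param lag_range lag window `c(lo, hi)` in seconds.
#' @param breathing_fs sampling rate of `breathing` when it is a bare
#'   numeric vector.
#' @return an object of class `cardioresp_corr` with `lags`, `rho`,
#'   `rho_max` (signed value at maximum magnitude), `lag_at_max`.
#' @export
cardioresp_correlation <- function(breathing, hr, lag_range = c(-30, 30),
                                   breathing_fs = NULL) {
  if (is.list(breathing)) { breathing_fs <- breathing$fs; breathing <- breathing$x }
  if (is.null(breathing_fs)) stop("breathing_fs required for a numeric vector")
  # resample breathing onto the heart-rate grid
  tb <- (seq_along(breathing) - 1) / breathing_fs
  b <- stats::approx(tb, breathing, xout = hr$t, rule = 2)$y
  n <- length(b)
  max_lag <- max(abs(lag_range))
  overlap_s <- n / hr$fs - max_lag
  if (overlap_s < 30) stop("overlap after maximal lag shorter than 30 s")
  if (overlap_s < 60) warning("overlap after maximal lag shorter than 60 s")
  if (stats::sd(b) < 1e-12 || stats::sd(hr$value) < 1e-12)
    stop("correlation undefined for constant input")
  xc <- spearman_xcorr(b, hr$value, hr$fs, lag_range)
  structure(xc, class = "cardioresp_corr")
}

#' @export
print.cardioresp_corr <- function(x, ...) {
  cat(sprintf("cardioresp_corr: rho_max = %.3f at lag %.2f s (%d lags)\n",
              x$rho_max, x$lag_at_max, length(x$lags)))
  invisible(x)
}

#' Surrogate null threshold for the coupling statistic
#'
#' Estimates the chance level of `|rho_max|` by recomputing the coupling
#' statistic on circular-shift surrogates of the breathing series (uniform
#' random shifts of at least `min_shift_s`), which preserve the marginal and
#' autocorrelation structure while destroying the cross-coupling. Returns
#' the 95th percentile of the surrogate distribution.
#'
#' @param breathing,hr,lag_range,breathing_fs as in
#'   [cardioresp_correlation()].
#' @param n_surrogates number of surrogates (> 0).
#' @param seed RNG seed for the shifts.
#' @param min_shift_s minimum circular shift (s).
#' @param probs quantile(s) of the surrogate `|rho_max|` distribution.
#' @return the surrogate threshold (95th percentile by default), with the
#'   surrogate values as attribute `surrogates`.
#' @export
coupling_null_threshold <- function(breathing, hr, n_surrogates = 100,
                                    seed = 1L, lag_range = c(-30, 30),
                                    breathing_fs = NULL, min_shift_s = 30,
                                    probs = 0.95) {
  if (n_surrogates < 1) stop("n_surrogates must be positive")
  if (is.list(breathing)) { breathing_fs <- breathing$fs; breathing <- breathing$x }
  if (is.null(breathing_fs)) stop("breathing_fs required for a numeric vector")
  tb <- (seq_along(breathing) - 1) / breathing_fs
  b <- stats::approx(tb, breathing, xout = hr$t, rule = 2)$y
  n <- length(b)
  min_k <- round(min_shift_s * hr$fs)
  if (2 * min_k >= n) stop("record too short for the minimum shift")
  with_seed(seed, {
    vals <- vapply(seq_len(n_surrogates), function(i) {
      k <- sample(min_k:(n - min_k), 1L)
      bs <- c(b[(k + 1L):n], b[seq_len(k)])
      abs(spearman_xcorr(bs, hr$value, hr$fs, lag_range)$rho_max)
    }, numeric(1))
    out <- stats::quantile(vals, probs, names = FALSE)
    attr(out, "surrogates") <- vals
    out
  })
}
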