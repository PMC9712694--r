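# Instantaneous rate series (rate = 1/IBI), smoothing, heart/breathing
# ratio, Burg autoregressive spectra and dominant-frequency extraction.

#' Rate series
#'
#' Time-stamped instantaneous rate on a uniform grid.
#'
#' @param t time stamps (s), uniform grid.
#' @param value rates (Hz).
#' @param fs grid rate (Hz).
#' @param source one of `"heart"`, `"breathing"`, `"ratio"`.
#' @return an object of class `rate_series`.
#' @export
rate_series <- function(t, value, fs, source = c("heart", "breathing", "ratio")) {
  source <- match.arg(source)
  stopifnot(length(t) == length(value))
  structure(list(t = t, value = value, fs = fs, source = source),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("rate_series (%s): %d samples at %g Hz, mean %.3f Hz\n",
              x$source, length(x$value), x$fs, mean(x$value)))
  invisible(x)
}

#' Instantaneous rate from inter-beat intervals
#'
#' The instantaneous rate `1/IBI` is assigned at each event time (at the end
#' of its interval) and resampled to a uniform grid by cubic-spline
#' interpolation; values are clipped to stay positive.
#'
#' @param annotations a [beat_annotations()] object with at least 2 events.
#' @param grid_fs output grid rate (Hz); 4 Hz puts the Nyquist comfortably
#'   above the 0.5 Hz band of interest.
#' @param source label for the output series.
#' @return a [rate_series()].
#' @export
ibi_to_rate <- function(annotations, grid_fs = 4, source = "heart") {
  times <- annotations$event_times
  if (length(times) < 2L) stop("need at least 2 events")
  t_ev <- times[-1L]
  r <- 1 / annotations$ibi
  grid <- seq(t_ev[1L], t_ev[length(t_ev)], by = 1 / grid_fs)
  v <- if (length(t_ev) >= 4L) stats::spline(t_ev, r, xout = grid, method = "fmm")$y
       else stats::approx(t_ev, r, xout = grid, rule = 2)$y
  rate_series(grid, pmax(v, 1e-9), grid_fs, source)
}

#' Smooth a rate series with a centred moving mean
#'
#' A 2-s moving mean removes components above ~0.5 Hz before lag analyses.
#' Windows are truncated at the edges; the series mean is preserved exactly.
#'
#' @param rate a [rate_series()].
#' @param window_s window length (s); must exceed the grid step.
#' @return the smoothed [rate_series()].
#' @export
smooth_rate <- function(rate, window_s = 2) {
  if (1 / rate$fs >= window_s) stop("grid step must be smaller than the window")
  k <- as.integer(round(window_s * rate$fs))
  v <- moving_mean(rate$value, k)
  v <- v + (mean(rate$value) - mean(v))   # edge truncation must not shift DC
  rate_series(rate$t, v, rate$fs, rate$source)
}

#' Heart/breathing rate ratio
#'
#' Pointwise ratio of two rate series on a common grid.
#'
#' @param hr,br [rate_series()] objects on the same grid.
#' @return a [rate_series()] with `source = "ratio"`.
#' @export
rate_ratio <- function(hr, br) {
  if (length(hr$t) != length(br$t) || max(abs(hr$t - br$t)) > 1e-9)
    stop("rate series must share a common grid")
  rate_series(hr$t, hr$value / br$value, hr$fs, "ratio")
}

#' Burg autoregressive power spectral density
#'
#' Fits an AR model of the given order to the mean-removed series by Burg's
#' recursion (via [stats::ar.burg()]) and evaluates the one-sided PSD
#' `sigma^2/fs / |1 - sum(a_k exp(-2 pi i f k / fs))|^2 * 2` on a dense
#' frequency grid from 0 to `fs/2`. The dominant frequency is the PSD
#' maximum inside 0--0.5 Hz.
#'
#' @param series numeric vector or [rate_series()]; IBI series interpolated
#'   to a uniform grid are the intended input for HRV spectra.
#' @param fs sampling rate (Hz); taken from the series if it is a
#'   [rate_series()].
#' @param order AR order (default 16, the standard HRV recommendation).
#' @param n_freq number of frequency-grid points (>= 1024 gives ~0.002 Hz
#'   bins at fs = 4 Hz).
#' @return an object of class `spectrum_result` with `freqs`, `psd`,
#'   `main_freq`, `ar_order`, `reflection` (partial autocorrelations, all in
#'   (-1, 1)), `fs`.
#' @export
burg_psd <- function(series, fs = NULL, order = 16, n_freq = 1024) {
  if (inherits(series, "rate_series")) {
    fs <- series$fs
    series <- series$value
  }
  if (is.null(fs)) stop("fs required for a plain numeric series")
  x <- as.numeric(series)
  if (length(x) <= 2 * order) stop("series too short for the AR order")
  if (stats::var(x) < 1e-24) stop("zero-variance series")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  freqs <- seq(0, fs / 2, length.out = n_freq)
  ek <- exp(-2i * pi * outer(freqs / fs, seq_len(order)))
  denom <- abs(1 - as.vector(ek %*% a))^2
  psd <- 2 * (fit$var.pred / fs) / denom
  res <- structure(list(freqs = freqs, psd = psd, main_freq = NA_real_,
                        ar_order = order,
                        reflection = as.numeric(fit$partialacf), fs = fs),
                   class = "spectrum_result")
  res$main_freq <- as.numeric(main_frequency(res))
  res
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the maximum PSD value inside the band (default 0--0.5 Hz,
#' the HRV range of interest). Ties break toward the lower frequency. If the
#' global spectral maximum lies outside the band the returned value carries
#' the attribute `low_confidence = TRUE`.
#'
#' @param spectrum a `spectrum_result` from [burg_psd()].
#' @param band frequency band `c(lo, hi)` in Hz.
#' @return the dominant frequency (Hz), possibly flagged `low_confidence`.
#' @export
main_frequency <- function(spectrum, band = c(0, 0.5)) {
  f <- spectrum$freqs
  if (band[1] < min(f) || band[2] > max(f)) stop("band outside spectrum range")
  inb <- which(f >= band[1] & f <= band[2])
  imax <- inb[which.max(spectrum$psd[inb])]       # first max = lower-freq tie
  out <- f[imax]
  if (which.max(spectrum$psd) != imax) attr(out, "low_confidence") <- TRUE
  out
}
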