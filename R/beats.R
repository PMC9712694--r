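# ECG / breathing preprocessing and event detection: Butterworth band-pass,
# two-pass template-matching peak detection, ectopic-interval detection and
# interpolation-based correction.

#' Beat annotations
#'
#' Container for detected event times (R-peaks or inhalation peaks), the
#' derived inter-beat intervals (IBIs), and per-interval ectopic/corrected
#' flags.
#'
#' @param event_times strictly increasing event times (s).
#' @return an object of class `beat_annotations` with fields `event_times`,
#'   `ibi` (first differences), `ectopic`, `corrected` (logical, one per
#'   interval).
#' @export
beat_annotations <- function(event_times) {
  if (is.unsorted(event_times, strictly = TRUE))
    stop("event_times must be strictly increasing")
  ibi <- diff(event_times)
  structure(list(event_times = event_times, ibi = ibi,
                 ectopic = logical(length(ibi)),
                 corrected = logical(length(ibi))),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("beat_annotations: %d events over %.1f s, median IBI %.3f s, %d ectopic, %d corrected\n",
              length(x$event_times), diff(range(x$event_times)),
              stats::median(x$ibi), sum(x$ectopic), sum(x$corrected)))
  invisible(x)
}

#' Band-pass filter an ECG trace
#'
#' Zero-phase (forward-backward) Butterworth band-pass of order 4 with
#' passband 0.5--45 Hz. Zero-phase filtering is used so that downstream lag
#' estimates are not biased by causal filter delay.
#'
#' @param ecg numeric ECG series.
#' @param fs sampling rate (Hz); must exceed 90 Hz so 45 Hz is inside the
#'   Nyquist range.
#' @param band passband edges (Hz).
#' @param order filter order (per direction).
#' @return filtered series, same length as the input.
#' @export
filter_ecg <- function(ecg, fs, band = c(0.5, 45), order = 4) {
  if (fs <= 2 * band[2]) stop("sampling rate too low for the upper band edge")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, ecg))
}

# Two-pass template-matching event detector.
# Pass 1: adaptive-threshold local maxima with a refractory period.
# Pass 2: the median beat template (+/- halfwidth) is correlated against the
# signal; events are re-picked where the normalised correlation exceeds
# `ncc_threshold`, then refined to the local signal maximum.
template_detect <- function(x, fs, refractory_s, halfwidth_s,
                            ncc_threshold = 0.6, amp_frac = 0.2,
                            what = "beat") {
  n <- length(x)
  xc <- x - stats::median(x)
  if (stats::sd(xc) < 1e-12) stop("signal unusable: flat input")
  # pass 1 -----------------------------------------------------------------
  is_max <- c(FALSE, xc[2:(n - 1)] > xc[1:(n - 2)] &
                xc[2:(n - 1)] >= xc[3:n], FALSE)
  thr <- 0.5 * stats::quantile(xc, 0.999, names = FALSE)
  cand <- which(is_max & xc > thr)
  if (length(cand) < 3L)
    stop(sprintf("signal unusable: fewer than 3 provisional %ss", what))
  refr <- round(refractory_s * fs)
  keep <- refractory_select(cand, xc[cand], refr)
  if (length(keep) < 3L)
    stop(sprintf("signal unusable: fewer than 3 provisional %ss", what))
  # template from provisional peaks ---------------------------------------
  half <- round(halfwidth_s * fs)
  inner <- keep[keep > half & keep <= n - half]
  if (length(inner) < 3L) stop("signal unusable: too few interior beats")
  win <- vapply(inner, function(i) xc[(i - half):(i + half)],
                numeric(2L * half + 1L))
  tpl <- apply(win, 1, stats::median)
  tpl <- tpl - mean(tpl)
  # waveform-consistency guard: beats must resemble their own template
  rs <- suppressWarnings(apply(win, 2, function(w) stats::cor(w, tpl)))
  if (!is.finite(stats::median(rs, na.rm = TRUE)) ||
      stats::median(rs, na.rm = TRUE) < 0.5)
    stop(sprintf("signal unusable: no consistent %s waveform", what))
  # pass 2: normalised cross-correlation of template against signal --------
  L <- length(tpl)
  num <- stats::filter(xc, rev(tpl), sides = 2)          # centred dot product
  ssq <- stats::filter(xc^2, rep(1, L), sides = 2)
  locmean <- stats::filter(xc, rep(1 / L, L), sides = 2)
  denom <- sqrt(pmax(ssq - L * locmean^2, 1e-12)) * sqrt(sum(tpl^2))
  ncc <- as.numeric(num - L * locmean * mean(tpl)) / as.numeric(denom)
  ncc[!is.finite(ncc)] <- 0
  is_nmax <- c(FALSE, ncc[2:(n - 1)] > ncc[1:(n - 2)] &
                 ncc[2:(n - 1)] >= ncc[3:n], FALSE)
  cand2 <- which(is_nmax & ncc > ncc_threshold)
  if (length(cand2) < 3L)
    stop(sprintf("signal unusable: template matching found fewer than 3 %ss", what))
  keep2 <- refractory_select(cand2, ncc[cand2], refr)
  # refine to the local signal maximum around each correlation peak
  r2 <- max(1L, round(half / 2))
  peaks <- vapply(keep2, function(i) {
    lo <- max(1L, i - r2); hi <- min(n, i + r2)
    as.integer(lo + which.max(xc[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  peaks <- peaks[c(TRUE, diff(peaks) > refr / 2)]
  # amplitude gate: band-limited noise can exceed the correlation threshold
  # on near-zero-energy windows; genuine events must also reach a fraction
  # of the provisional-beat amplitude
  amp_thr <- amp_frac * stats::median(xc[keep])
  peaks <- peaks[xc[peaks] >= amp_thr]
  if (length(peaks) < 3L)
    stop(sprintf("signal unusable: template matching found fewer than 3 %ss", what))
  (peaks - 1L) / fs
}

# Greedy refractory enforcement: walk candidates in time order; within the
# refractory window keep the larger-amplitude one.
refractory_select <- function(idx, amp, refr) {
  if (!length(idx)) return(integer(0))
  keep <- idx[1]; kamp <- amp[1]
  out <- integer(0)
  for (j in seq_along(idx)[-1]) {
    if (idx[j] - keep <= refr) {
      if (amp[j] > kamp) { keep <- idx[j]; kamp <- amp[j] }
    } else {
      out <- c(out, keep); keep <- idx[j]; kamp <- amp[j]
    }
  }
  c(out, keep)
}

#' Detect R-peaks by template matching
#'
#' Two-pass detection: provisional peaks from adaptive-threshold local maxima
#' with a 250 ms refractory period, then a median beat template (+/-100 ms)
#' correlated against the signal with peaks re-picked where the normalised
#' correlation exceeds 0.6. Signals without at least three consistent beats
#' raise an error.
#'
#' @param ecg_filtered band-passed ECG series.
#' @param fs sampling rate (Hz).
#' @param refractory_s minimum inter-beat spacing (s).
#' @param ncc_threshold normalised template-correlation threshold.
#' @return a [beat_annotations()] object.
#' @export
detect_r_peaks <- function(ecg_filtered, fs, refractory_s = 0.25,
                           ncc_threshold = 0.6) {
  if (length(ecg_filtered) < 10 * fs) stop("need at least 10 s of ECG")
  # R deflections tower over the baseline, so a strict amplitude gate (40%
  # of the provisional-beat amplitude) is safe and rejects noise bursts
  times <- template_detect(ecg_filtered, fs, refractory_s,
                           halfwidth_s = 0.1, ncc_threshold, amp_frac = 0.4,
                           what = "R-peak")
  beat_annotations(times)
}

#' Detect inhalation peaks by template matching
#'
#' The breathing trace is first smoothed with a 2-s moving mean, then the
#' same two-pass template scheme as [detect_r_peaks()] is applied with a
#' 1.5 s refractory period and a +/-1 s template window.
#'
#' @param breathing respiratory-belt series.
#' @param fs sampling rate (Hz).
#' @param refractory_s minimum inter-breath spacing (s).
#' @param ncc_threshold normalised template-correlation threshold.
#' @return a [beat_annotations()] object of inhalation-peak times.
#' @export
detect_breath_peaks <- function(breathing, fs, refractory_s = 1.5,
                                ncc_threshold = 0.6) {
  if (length(breathing) < 20 * fs) stop("need at least 20 s of breathing signal")
  sm <- moving_mean(breathing, as.integer(round(2 * fs)))
  # fast paced breathing (0.4 Hz) survives the 2-s smoothing at ~25% of the
  # slow-breathing amplitude, so the gate must stay permissive here
  times <- template_detect(sm, fs, refractory_s, halfwidth_s = 1,
                           ncc_threshold, amp_frac = 0.15,
                           what = "inhalation peak")
  beat_annotations(times)
}

#' Detect ectopic inter-beat intervals
#'
#' Flags interval indices at local maxima of the absolute IBI derivative
#' whose magnitude exceeds `median + 4 * MAD` of the derivative series (MAD
#' unscaled). An unqualified local-maximum rule would flag about half of all
#' intervals, so the robust amplitude criterion is required. Each flagged
#' derivative maximum is attributed to the adjacent interval deviating most
#' from the median IBI.
#'
#' @param annotations a [beat_annotations()] object with at least 4
#'   intervals.
#' @param n_mad threshold multiplier on the unscaled MAD.
#' @return sorted integer vector of ectopic interval indices.
#' @export
detect_ectopic <- function(annotations, n_mad = 4) {
  ibi <- annotations$ibi
  if (length(ibi) < 4L) stop("need at least 4 intervals")
  d <- abs(diff(ibi))
  med <- stats::median(d)
  mad_u <- stats::median(abs(d - med))
  thr <- med + n_mad * mad_u
  nd <- length(d)
  is_max <- d >= c(-Inf, d[-nd]) & d >= c(d[-1], -Inf)
  hits <- which(is_max & d > thr & d > 1e-12)
  if (!length(hits)) return(integer(0))
  med_ibi <- stats::median(ibi)
  idx <- vapply(hits, function(j) {
    cand <- c(j, j + 1L)
    cand[which.max(abs(ibi[cand] - med_ibi))]
  }, integer(1))
  sort(unique(idx))
}

#' Correct ectopic intervals by interpolation
#'
#' Flagged IBIs are replaced by cubic-spline interpolation over the
#' neighbouring unflagged intervals; event times are rebuilt cumulatively
#' from the corrected IBI series anchored at the first event. Deterministic
#' interpolation replaces interactive manual editing; flags are retained for
#' review.
#'
#' @param annotations a [beat_annotations()] object.
#' @param indices interval indices to correct (e.g. from
#'   [detect_ectopic()]).
#' @return a corrected [beat_annotations()] object with `ectopic` and
#'   `corrected` flags set.
#' @export
correct_ectopic <- function(annotations, indices) {
  ibi <- annotations$ibi
  if (!length(indices)) return(annotations)
  indices <- sort(unique(as.integer(indices)))
  if (any(indices < 1L | indices > length(ibi))) stop("invalid interval indices")
  good <- setdiff(seq_along(ibi), indices)
  if (length(good) < 2L) stop("uncorrectable: all intervals flagged")
  new_ibi <- ibi
  new_ibi[indices] <- stats::spline(good, ibi[good], xout = indices,
                                    method = "natural")$y
  if (any(new_ibi <= 0)) stop("correction produced non-positive intervals")
  out <- annotations
  out$ibi <- new_ibi
  out$event_times <- annotations$event_times[1L] + c(0, cumsum(new_ibi))
  out$ectopic[indices] <- TRUE
  out$corrected[indices] <- TRUE
  out
}
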