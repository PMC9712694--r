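# fNIRS processing: optical densities, modified Beer-Lambert inversion to
# oxyhemoglobin, band-pass filtering, Spearman channel connectivity, and
# PCA extraction of the breathing-locked hemodynamic response.

#' Convert light intensities to optical densities
#'
#' `OD(t) = -log10(I(t) / mean(I))` per channel and wavelength, so constant
#' intensity maps to zero OD and global intensity rescaling leaves OD
#' unchanged.
#'
#' @param intensity a time x channel matrix (one wavelength) or a time x
#'   channel x wavelength array; all values must be positive.
#' @return optical densities with the same shape.
#' @export
intensities_to_od <- function(intensity) {
  if (any(intensity <= 0)) stop("intensities must be positive")
  od_one <- function(m) {
    m <- as.matrix(m)
    -log10(sweep(m, 2, colMeans(m), "/"))
  }
  if (length(dim(intensity)) == 3L) {
    out <- intensity
    for (w in seq_len(dim(intensity)[3])) out[, , w] <- od_one(intensity[, , w])
    out
  } else od_one(intensity)
}

#' Modified Beer-Lambert inversion to hemoglobin concentrations
#'
#' Solves, per sample and channel, the 2x2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF`
#' for the oxy- and deoxyhemoglobin concentration changes, using tabulated
#' extinction coefficients at 760 and 840 nm (Gratzer/Prahl compilation),
#' the source-detector distance and a differential pathlength factor. Only
#' the oxyhemoglobin series is analysed downstream; HbR is retained in the
#' returned object.
#'
#' @param od time x channel x wavelength array of optical densities
#'   (wavelength order 760, 840 nm).
#' @param dpf differential pathlength factor (default 6; any consistent
#'   choice only rescales concentrations and cannot change rank-based
#'   results).
#' @param distance_cm source-detector separation (cm).
#' @param fs sampling rate (Hz), carried along for downstream stages.
#' @return an object of class `hbo_series`: list with `hbo` and `hbr`
#'   (time x channel matrices, micromolar), `dpf`, `distance_cm`, `fs`.
#' @export
od_to_hbo <- function(od, dpf = 6, distance_cm = 3.5, fs = 50) {
  if (length(dim(od)) != 3L || dim(od)[3] != 2L)
    stop("od must be a time x channel x 2-wavelength array")
  ext <- mbll_extinction() * 1e-6            # per micromolar
  E <- ext * distance_cm * dpf
  if (abs(det(E)) < 1e-18) stop("singular extinction matrix")
  Einv <- solve(E)
  hbo <- Einv[1, 1] * od[, , 1] + Einv[1, 2] * od[, , 2]
  hbr <- Einv[2, 1] * od[, , 1] + Einv[2, 2] * od[, , 2]
  structure(list(hbo = as.matrix(hbo), hbr = as.matrix(hbr), dpf = dpf,
                 distance_cm = distance_cm, fs = fs),
            class = "hbo_series")
}

#' Band-pass filter fNIRS hemoglobin series
#'
#' Zero-phase Butterworth band-pass of order 3 with passband 0.05--0.6 Hz,
#' removing very slow drifts and most of the cardiac pulse (~1.2 Hz is
#' attenuated more than tenfold).
#'
#' @param hbo an `hbo_series` or a time x channel matrix.
#' @param fs sampling rate (Hz); taken from the `hbo_series` if given.
#' @param band passband edges (Hz).
#' @param order filter order (per direction).
#' @return same type as the input, filtered.
#' @export
filter_fnirs <- function(hbo, fs = 50, band = c(0.05, 0.6), order = 3) {
  if (inherits(hbo, "hbo_series")) {
    out <- hbo
    out$hbo <- filter_fnirs(hbo$hbo, hbo$fs, band, order)
    out$hbr <- filter_fnirs(hbo$hbr, hbo$fs, band, order)
    return(out)
  }
  if (fs <= 2 * band[2]) stop("sampling rate too low for the upper band edge")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  apply(as.matrix(hbo), 2, function(col) as.numeric(signal::filtfilt(bf, col)))
}

#' Spearman channel connectivity
#'
#' Pairwise Spearman correlation over a segment for all channel pairs, with
#' the per-channel summary being the median of that channel's off-diagonal
#' coefficients.
#'
#' @param hbo an `hbo_series` or time x channel matrix (a segment of at
#'   least 30 s).
#' @param fs sampling rate (Hz), used for the minimum-length check.
#' @return an object of class `connectivity_result`: `matrix` (channel x
#'   channel, symmetric, unit diagonal) and `per_channel_median`.
#' @export
channel_connectivity <- function(hbo, fs = 50) {
  if (inherits(hbo, "hbo_series")) { fs <- hbo$fs; hbo <- hbo$hbo }
  hbo <- as.matrix(hbo)
  if (nrow(hbo) < 30 * fs) stop("segment must be at least 30 s long")
  m <- stats::cor(hbo, method = "spearman")
  med <- vapply(seq_len(ncol(m)), function(c) stats::median(m[c, -c]),
                numeric(1))
  structure(list(matrix = m, per_channel_median = med),
            class = "connectivity_result")
}

# Max-|rho| lagged Spearman correlation of each column of `scores` against
# `ref`, computed on decimated copies for speed (both signals are band
# limited well below the decimated Nyquist).
lagged_component_rho <- function(scores, ref, fs, lag_range, lag_step,
                                 decimate_to = 10) {
  dec <- max(1L, floor(fs / decimate_to))
  idx <- seq(1L, length(ref), by = dec)
  fs_d <- fs / dec
  refd <- ref[idx]
  t(vapply(seq_len(ncol(scores)), function(j) {
    xc <- spearman_xcorr(refd, scores[idx, j], fs_d, lag_range,
                         lag_step = max(lag_step, 1 / fs_d))
    c(rho = xc$rho_max, lag_s = xc$lag_at_max)
  }, numeric(2)))
}

#' Extract the breathing response from fNIRS channels by PCA
#'
#' A principal component analysis is computed on the z-scored matrix of the
#' HbO channels plus the breathing signal as an additional column
#' (correlation-matrix PCA: channels and breathing are in incommensurable
#' units). Each component score series is correlated with the breathing
#' signal by max-|rho| Spearman cross-correlation over lags -30..30 s;
#' components with |rho| > 0.6 are back-projected onto the HbO channels
#' (only -- reconstructing the breathing column itself would be circular)
#' and summed into the per-channel breathing response, returned in the
#' original concentration units.
#'
#' @param hbo an `hbo_series` or time x channel matrix (>= 100 s).
#' @param breathing breathing signal; resampled to the fNIRS rate
#'   internally.
#' @param fs fNIRS sampling rate (Hz).
#' @param breathing_fs sampling rate of `breathing` (defaults to `fs`; a
#'   list with `x`/`fs` is also accepted).
#' @param threshold component-selection threshold on |rho|.
#' @param lag_range lag window (s) for the component correlations.
#' @param lag_step lag grid step (s).
#' @param include_breathing_column if `FALSE`, the PCA uses the 23 channels
#'   only and breathing serves purely as the selection reference.
#' @return an object of class `breathing_response`: `response` (time x
#'   channel matrix, or NULL when empty), `selected` (data frame: component,
#'   rho, lag_s), `empty` flag.
#' @export
extract_breathing_response <- function(hbo, breathing, fs = 50,
                                       breathing_fs = NULL, threshold = 0.6,
                                       lag_range = c(-30, 30), lag_step = 0.5,
                                       include_breathing_column = TRUE) {
  if (inherits(hbo, "hbo_series")) { fs <- hbo$fs; hbo <- hbo$hbo }
  hbo <- as.matrix(hbo)
  if (nrow(hbo) < 100 * fs) stop("segment must be at least 100 s long")
  if (is.list(breathing)) { breathing_fs <- breathing$fs; breathing <- breathing$x }
  if (is.null(breathing_fs)) breathing_fs <- fs
  b <- resample_series(breathing, breathing_fs, fs, n_out = nrow(hbo))
  b <- as.numeric(scale(b))
  sds <- apply(hbo, 2, stats::sd)
  if (any(sds < 1e-15)) stop("constant fNIRS channel")
  X <- if (include_breathing_column) cbind(scale(hbo), b) else scale(hbo)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  comp <- lagged_component_rho(pc$x, b, fs, lag_range, lag_step)
  nch <- ncol(hbo)
  # circularity guard (column mode): a component loading almost exclusively
  # on the breathing column correlates with breathing by construction but
  # carries no hemodynamic content; back-projecting it would be vacuous
  hbo_load <- sqrt(colSums(pc$rotation[seq_len(nch), , drop = FALSE]^2))
  sel <- which(abs(comp[, "rho"]) > threshold & hbo_load > 0.5)
  selected <- data.frame(component = sel,
                         rho = comp[sel, "rho"],
                         lag_s = comp[sel, "lag_s"], row.names = NULL)
  if (!length(sel)) {
    return(structure(list(response = NULL, selected = selected, empty = TRUE,
                          fs = fs),
                     class = "breathing_response"))
  }
  recon_z <- pc$x[, sel, drop = FALSE] %*%
    t(pc$rotation[seq_len(nch), sel, drop = FALSE])
  response <- sweep(recon_z, 2, sds, "*")   # back to concentration units
  structure(list(response = response, selected = selected, empty = FALSE,
                 fs = fs),
            class = "breathing_response")
}

#' Per-channel lag of the extracted breathing response
#'
#' For each channel of a [extract_breathing_response()] result, the lag of
#' the maximum-|rho| Spearman cross-correlation against the chest-belt
#' breathing signal over -30..30 s. Positive lag means the channel response
#' follows breathing.
#'
#' @param response a non-empty `breathing_response`.
#' @param breathing breathing signal (vector, or list with `x`/`fs`).
#' @param breathing_fs sampling rate of `breathing` (defaults to the
#'   response rate).
#' @param lag_range lag window (s).
#' @param lag_step lag grid step (s); 0.1 s resolves sub-second lags.
#' @return numeric vector of per-channel lags (s), with per-channel |rho|
#'   as attribute `rho`.
#' @export
breathing_response_lag <- function(response, breathing, breathing_fs = NULL,
                                   lag_range = c(-30, 30), lag_step = 0.1) {
  if (response$empty) stop("empty breathing response")
  fs <- response$fs
  if (is.list(breathing)) { breathing_fs <- breathing$fs; breathing <- breathing$x }
  if (is.null(breathing_fs)) breathing_fs <- fs
  b <- resample_series(breathing, breathing_fs, fs, n_out = nrow(response$response))
  comp <- lagged_component_rho(response$response, b, fs, lag_range, lag_step)
  out <- comp[, "lag_s"]
  attr(out, "rho") <- comp[, "rho"]
  out
}
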