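# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation calls do not perturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Centered moving mean with windows truncated at the edges (O(n) via cumsum).
moving_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  h <- max(1L, floor((k - 1) / 2))   # odd effective window, centred
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Shift a series by `k` samples (positive k delays the series); edges padded
# with the boundary value so the length is preserved.
shift_series <- function(x, k) {
  n <- length(x)
  k <- as.integer(round(k))
  if (k == 0L || n == 0L) return(x)
  if (abs(k) >= n) return(rep(x[if (k > 0) 1L else n], n))
  if (k > 0) c(rep(x[1L], k), x[seq_len(n - k)])
  else c(x[(-k + 1L):n], rep(x[n], -k))
}

# Lagged Spearman cross-correlation between x and y on a shared uniform grid.
# Positive lag means y follows x: rho(lag) = spearman(x[t], y[t + lag]).
# Returns the full profile plus the signed coefficient of maximum magnitude.
spearman_xcorr <- function(x, y, fs, lag_range = c(-30, 30), lag_step = 1 / fs) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  lags <- seq(lag_range[1], lag_range[2], by = lag_step)
  ks <- as.integer(round(lags * fs))
  lags <- ks / fs
  rho <- vapply(ks, function(k) {
    if (k >= 0) {
      xi <- x[seq_len(n - k)]; yi <- y[(k + 1L):n]
    } else {
      xi <- x[(-k + 1L):n]; yi <- y[seq_len(n + k)]
    }
    if (length(xi) < 3L) return(NA_real_)
    suppressWarnings(stats::cor(xi, yi, method = "spearman"))
  }, numeric(1))
  if (all(is.na(rho))) stop("correlation undefined: constant or empty overlap")
  imax <- which.max(abs(rho))
  list(lags = lags, rho = rho, rho_max = rho[imax], lag_at_max = lags[imax])
}

# Interpolate a series sampled at fs_in onto a uniform fs_out grid (linear).
resample_series <- function(x, fs_in, fs_out, n_out = NULL) {
  t_in <- (seq_along(x) - 1) / fs_in
  if (is.null(n_out)) n_out <- floor(t_in[length(t_in)] * fs_out) + 1L
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}
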