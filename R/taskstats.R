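# Task-level markers and the nonparametric statistical layer: counting
# accuracy, transition epoch alignment with z-scoring, median/MAD
# aggregation, Wilcoxon signed-rank (normal approximation) with Monte-Carlo
# sign-flip correction, tie-corrected Friedman, Spearman p via the t
# approximation, and Bonferroni correction over channels.

#' Statistical outcome container
#'
#' @param statistic test statistic value.
#' @param z standard-normal (or t) deviate.
#' @param p two-sided p-value.
#' @param p_mc Monte-Carlo permutation p-value, or NULL.
#' @param significant logical significance flag.
#' @param correction one of `"none"`, `"monte_carlo"`, `"bonferroni_23"`.
#' @return an object of class `stat_outcome`.
#' @export
stat_outcome <- function(statistic, z, p, p_mc = NULL, significant = NA,
                         correction = "none") {
  stopifnot(p >= 0, p <= 1, is.null(p_mc) || (p_mc >= 0 && p_mc <= 1))
  structure(list(statistic = statistic, z = z, p = p, p_mc = p_mc,
                 significant = significant, correction = correction),
            class = "stat_outcome")
}

#' @export
print.stat_outcome <- function(x, ...) {
  cat(sprintf("stat_outcome: statistic = %.4g, z = %.4f, p = %.4g%s%s\n",
              x$statistic, x$z, x$p,
              if (!is.null(x$p_mc)) sprintf(", p_mc = %.4g", x$p_mc) else "",
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Heartbeat-counting accuracy
#'
#' `accuracy = 1 - (beats_ecg - beats_counted) / beats_ecg`, computed per
#' trial exactly as printed (no absolute value, so over-counting yields
#' scores above 1); the per-subject score is the mean over trials. A
#' symmetric variant using the absolute count error is available via
#' `absolute = TRUE`.
#'
#' @param counted reported heartbeat counts (>= 0), vectorised over trials.
#' @param ecg_beats ECG-detected beat counts (> 0).
#' @param absolute use `|beats_ecg - counted|` instead of the signed error.
#' @return per-trial accuracies.
#' @export
counting_accuracy <- function(counted, ecg_beats, absolute = FALSE) {
  if (any(ecg_beats <= 0)) stop("ecg_beats must be positive")
  if (any(counted < 0)) stop("counted must be non-negative")
  err <- if (absolute) abs(ecg_beats - counted) else ecg_beats - counted
  1 - err / ecg_beats
}

#' Align a marker series around transitions
#'
#' Extracts per-trial epochs of a marker (heart or breathing rate) around
#' event transitions on a common relative time grid, averages the trials,
#' and z-scores the average over the full window so the pre/post structure
#' of a response is comparable across subjects. Constant epochs are emitted
#' as zeros with a `degenerate` flag rather than NaN.
#'
#' @param marker a [rate_series()].
#' @param transition_times transition onsets (s).
#' @param window relative window `c(-w, +w)` in seconds.
#' @param smooth_s optional moving-mean smoothing (s) applied to the
#'   trial-averaged epoch before z-scoring (display parity).
#' @return an object of class `trial_epoch_set`: `aligned` (trial x time
#'   matrix, raw), `rel_t`, `avg`, `avg_z` (mean 0, sd 1 over the window),
#'   `window`, `normalized`, `degenerate`, `dropped` (count).
#' @export
align_transitions <- function(marker, transition_times, window = c(-30, 30),
                              smooth_s = NULL) {
  rel_t <- seq(window[1], window[2], by = 1 / marker$fs)
  rows <- list(); dropped <- 0L
  for (tt in transition_times) {
    tq <- tt + rel_t
    if (tq[1] < marker$t[1] - 1e-9 ||
        tq[length(tq)] > marker$t[length(marker$t)] + 1e-9) {
      dropped <- dropped + 1L
      warning(sprintf("transition at %.1f s lacks full window coverage; dropped", tt))
      next
    }
    rows[[length(rows) + 1L]] <- stats::approx(marker$t, marker$value,
                                               xout = tq, rule = 2)$y
  }
  if (!length(rows)) stop("no transition has full window coverage")
  aligned <- do.call(rbind, rows)
  avg <- colMeans(aligned)
  if (!is.null(smooth_s))
    avg <- moving_mean(avg, as.integer(round(smooth_s * marker$fs)))
  s <- stats::sd(avg)
  degenerate <- s < 1e-12
  avg_z <- if (degenerate) rep(0, length(avg)) else (avg - mean(avg)) / s
  structure(list(aligned = aligned, rel_t = rel_t, avg = avg, avg_z = avg_z,
                 window = window, normalized = TRUE, degenerate = degenerate,
                 dropped = dropped),
            class = "trial_epoch_set")
}

#' Group median and (unscaled) MAD
#'
#' The dispersion companion used throughout the group tables: the median
#' absolute deviation from the median, without the 1.4826 normal-consistency
#' factor.
#'
#' @param values numeric vector (n >= 1).
#' @return list with `median` and `mad`.
#' @export
group_median_mad <- function(values) {
  if (!length(values)) stop("empty input")
  med <- stats::median(values)
  list(median = med, mad = stats::median(abs(values - med)))
}

# Core of the paired Wilcoxon: returns the positive-rank sum, its null mean
# and tie-corrected SD for the non-zero differences d.
wilcoxon_parts <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  list(d = d, r = r, W = W, mu = mu, sigma = sqrt(sigma2), n = n)
}

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Signed-rank statistic with the tie-corrected normal approximation and a
#' two-sided p-value; zero differences are dropped. The signed z deviate is
#' reported (positive when `x` tends to exceed `y`), so swapping the inputs
#' negates z and preserves p.
#'
#' @param x,y paired samples (n >= 5 pairs).
#' @return a [stat_outcome()] with `statistic` = positive-rank sum.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 pairs")
  parts <- wilcoxon_parts(x - y)
  z <- (parts$W - parts$mu) / parts$sigma
  p <- 2 * stats::pnorm(-abs(z))
  stat_outcome(parts$W, z, min(p, 1), significant = p <= 0.05)
}

#' Monte-Carlo permutation correction of the paired Wilcoxon test
#'
#' The observed Wilcoxon normal-approximation p is compared against its
#' distribution under random sign flips of the paired differences (the
#' exchangeability structure of a paired design): for each of `n_perm`
#' permutations the Wilcoxon p is recomputed, and
#' `p_mc = (1 + #\{p_perm <= p_obs\}) / (n_perm + 1)` (the add-one estimator
#' avoids zero p-values). Significance is declared at `p_mc <= alpha`.
#'
#' @param x,y paired samples.
#' @param n_perm number of permutations (default 10000).
#' @param alpha significance level for the corrected decision.
#' @param seed RNG seed.
#' @return a [stat_outcome()] with `p` (observed), `p_mc`, and
#'   `correction = "monte_carlo"`.
#' @export
monte_carlo_correct <- function(x, y, n_perm = 10000, alpha = 0.05,
                                seed = 1L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 pairs")
  parts <- wilcoxon_parts(x - y)
  z_obs <- (parts$W - parts$mu) / parts$sigma
  p_obs <- min(2 * stats::pnorm(-abs(z_obs)), 1)
  n <- parts$n
  with_seed(seed, {
    # sign-flip the differences; ranks of |d| are flip-invariant, so each
    # permutation's Wilcoxon z (hence p) follows from its positive-rank sum
    flips <- matrix(stats::runif(n * n_perm) < 0.5, n, n_perm)
    pos <- matrix(parts$d > 0, n, n_perm)
    pos_perm <- xor(pos, flips)
    W_perm <- as.numeric(crossprod(parts$r, pos_perm))
    p_perm <- 2 * stats::pnorm(-abs((W_perm - parts$mu) / parts$sigma))
    p_mc <- (1 + sum(p_perm <= p_obs + 1e-12)) / (n_perm + 1)
    stat_outcome(parts$W, z_obs, p_obs, p_mc = p_mc,
                 significant = p_mc <= alpha, correction = "monte_carlo")
  })
}

#' Friedman test with tie correction
#'
#' Rank-based test for paired samples across multiple conditions: within
#' each subject the conditions are ranked, and the chi-square statistic is
#' computed with the standard tie correction; p comes from the chi-square
#' distribution with k-1 degrees of freedom.
#'
#' @param data subjects x conditions numeric matrix, complete cases only.
#' @return a [stat_outcome()].
#' @export
friedman_test <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("complete cases required")
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  R <- t(apply(data, 1, rank))
  Rj <- colSums(R)
  stat_raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  tie_sum <- sum(apply(data, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (C <= 0) return(stat_outcome(0, 0, 1, significant = FALSE))
  stat <- stat_raw / C
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  stat_outcome(stat, stats::qnorm(1 - p / 2) * sign(stat), p,
               significant = p <= 0.05)
}

#' Spearman correlation p-value via the t approximation
#'
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 degrees of freedom,
#' two-sided. Either supply paired samples, or a coefficient and sample
#' size directly.
#'
#' @param x,y paired samples (n >= 4), or NULL when `rho`/`n` are given.
#' @param rho Spearman coefficient (used with `n` when `x` is NULL).
#' @param n sample size accompanying `rho`.
#' @return a [stat_outcome()] with `statistic` = rho and `z` = the t
#'   deviate.
#' @export
spearman_p <- function(x = NULL, y = NULL, rho = NULL, n = NULL) {
  if (!is.null(x)) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    rho <- stats::cor(x, y, method = "spearman")
  }
  if (is.null(rho) || is.null(n)) stop("supply (x, y) or (rho, n)")
  if (n < 4L) stop("need at least 4 pairs")
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  stat_outcome(rho, tval, min(p, 1), significant = p <= 0.05)
}

#' Bonferroni correction over channels
#'
#' Flags channel c significant iff `p_c <= alpha / n_channels` (default
#' 0.05 / 23 for the 23-channel montage).
#'
#' @param p_values per-channel p-values.
#' @param alpha family-wise level.
#' @param n_channels number of channels in the family.
#' @return logical significance flags.
#' @export
bonferroni_channels <- function(p_values, alpha = 0.05,
                                n_channels = length(p_values)) {
  p_values <= alpha / n_channels
}
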