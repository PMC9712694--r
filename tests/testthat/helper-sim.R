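# Fixture builders shared across test files. All fixtures are generated in
# code under fixed seeds; no data files are stored.

# Minimal schedule of hand-specified events (defaults to a single rest).
make_schedule <- function(labels = "rest", durations = 300, rates = NA_real_) {
  n <- length(labels)
  start <- cumsum(c(0, durations))[seq_len(n)]
  sched <- data.frame(label = labels, start_s = start,
                      end_s = start + durations,
                      target_rate = if (n) rep_len(rates, n) else numeric(0),
                      counted = rep(NA_integer_, n),
                      confidence = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
  class(sched) <- c("protocol_schedule", "data.frame")
  sched
}

# Schedule with a short paced staircase (varying rates make lags identifiable).
make_paced_schedule <- function(step_s = 50,
                                rates = c(0.1, 0.2, 0.4, 0.2, 0.1),
                                rest_s = 30) {
  make_schedule(c("rest", rep("paced_step", length(rates))),
                c(rest_s, rep(step_s, length(rates))),
                c(NA, rates))
}

# Free-breathing recording pieces for detector tests.
make_cardio_sim <- function(seed = 1, duration = 300, rsa_gain = 0.15,
                            rsa_lag_s = 10, ecg_noise_sd = 0.05, ...) {
  cfg <- sim_config(seed = seed, rsa_gain = rsa_gain, rsa_lag_s = rsa_lag_s,
                    ecg_noise_sd = ecg_noise_sd, ...)
  sched <- make_schedule("rest", duration)
  br <- simulate_breathing(sched, cfg)
  beats <- simulate_heartbeats(br, cfg)
  ecg <- synthesize_ecg(beats, cfg, duration_s = duration)
  list(cfg = cfg, sched = sched, br = br, beats = beats, ecg = ecg)
}

# Frequency of the maximum FFT-periodogram peak (independent spectral oracle).
fft_peak <- function(x, fs, band = c(0, Inf)) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > band[1] & f <= min(band[2], fs / 2)
  f[keep][which.max(p[keep])]
}

# Fraction of events in `est` matching `truth` within tol (and vice versa).
match_rate <- function(truth, est, tol) {
  if (!length(truth) || !length(est)) return(c(sens = 0, ppv = 0))
  sens <- mean(vapply(truth, function(b) min(abs(est - b)) <= tol, logical(1)))
  ppv <- mean(vapply(est, function(b) min(abs(truth - b)) <= tol, logical(1)))
  c(sens = sens, ppv = ppv)
}
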