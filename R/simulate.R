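# Synthetic multimodal recordings with known ground truth: IPFM heartbeats
# with respiratory sinus arrhythmia, paced/free breathing, QRS-template ECG,
# and forward-modelled dual-wavelength fNIRS mixtures.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults describe a
#' resting adult: mean heart rate 1.2 Hz (72 bpm) modulated by respiratory
#' sinus arrhythmia (RSA) and a weak 0.1 Hz Mayer-wave component, free
#' breathing near 0.25 Hz, and 23 frontal fNIRS channels mixing a shared
#' neural slow wave, a lagged breathing component, cardiac pulse, and noise.
#'
#' @param duration_s record length in seconds (ignored when a schedule is
#'   supplied downstream).
#' @param mean_hr mean heart rate in Hz.
#' @param rsa_gain fractional heart-rate modulation depth driven by breathing.
#' @param rsa_lag_s delay (s) from breathing to the heart-rate modulation.
#' @param lf_gain fractional modulation depth of the 0.1 Hz low-frequency
#'   (Mayer-wave) component.
#' @param breathing_mode `"paced"` follows the schedule's paced steps,
#'   `"free"` ignores them.
#' @param free_breathing_rate breathing rate (Hz) outside paced steps.
#' @param ecg_noise_sd additive white-noise SD on the ECG, in units of the
#'   unit R-peak amplitude.
#' @param fnirs_breathing_gain per-channel breathing-component amplitude
#'   (micromolar); recycled to `n_channels`.
#' @param fnirs_breathing_lag_s per-channel breathing-component lag (s);
#'   recycled to `n_channels`.
#' @param fnirs_pulse_gain cardiac pulse amplitude in the fNIRS channels
#'   (micromolar).
#' @param fnirs_slow_gain amplitude of the shared slow (0.05--0.15 Hz)
#'   oscillation (micromolar).
#' @param fnirs_noise_sd per-channel white-noise SD (micromolar).
#' @param n_channels number of fNIRS channels.
#' @param fs_ecg ECG/breathing sampling rate (Hz).
#' @param fs_fnirs fNIRS sampling rate (Hz).
#' @param dpf differential pathlength factor used by the forward optical
#'   model (and to be used when inverting it).
#' @param distance_cm source--detector separation in cm.
#' @param seed integer seed; all generators are reproducible under it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(duration_s = 300,
                       mean_hr = 1.2,
                       rsa_gain = 0.15,
                       rsa_lag_s = 10,
                       lf_gain = 0.05,
                       breathing_mode = c("paced", "free"),
                       free_breathing_rate = 0.25,
                       ecg_noise_sd = 0.05,
                       fnirs_breathing_gain = 0.5,
                       fnirs_breathing_lag_s = seq(4.5, 5.5, length.out = 23),
                       fnirs_pulse_gain = 0.05,
                       fnirs_slow_gain = 0.3,
                       fnirs_noise_sd = 0.1,
                       n_channels = 23,
                       fs_ecg = 250,
                       fs_fnirs = 50,
                       dpf = 6,
                       distance_cm = 3.5,
                       seed = 1L) {
  breathing_mode <- match.arg(breathing_mode)
  cfg <- list(
    duration_s = duration_s, mean_hr = mean_hr, rsa_gain = rsa_gain,
    rsa_lag_s = rsa_lag_s, lf_gain = lf_gain, breathing_mode = breathing_mode,
    free_breathing_rate = free_breathing_rate, ecg_noise_sd = ecg_noise_sd,
    fnirs_breathing_gain = rep_len(fnirs_breathing_gain, n_channels),
    fnirs_breathing_lag_s = rep_len(fnirs_breathing_lag_s, n_channels),
    fnirs_pulse_gain = fnirs_pulse_gain, fnirs_slow_gain = fnirs_slow_gain,
    fnirs_noise_sd = fnirs_noise_sd, n_channels = as.integer(n_channels),
    fs_ecg = fs_ecg, fs_fnirs = fs_fnirs, dpf = dpf,
    distance_cm = distance_cm, seed = as.integer(seed)
  )
  if (cfg$mean_hr <= 0) stop("mean_hr must be positive")
  if (any(c(cfg$rsa_gain, cfg$lf_gain, cfg$ecg_noise_sd, cfg$fnirs_noise_sd,
            cfg$fnirs_breathing_gain, cfg$fnirs_pulse_gain,
            cfg$fnirs_slow_gain) < 0))
    stop("all gains and noise SDs must be non-negative")
  if (cfg$rsa_gain + cfg$lf_gain >= 1)
    stop("rsa_gain + lf_gain must be < 1 so the instantaneous rate stays positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the experimental protocol schedule
#'
#' Builds the event schedule of a full session: an initial rest, six
#' heartbeat-counting blocks of random duration (30--60 s) each followed by a
#' report gap, a rest, then the paced-breathing programme in which the step
#' sequences 0.1-0.2-0.4-0.2-0.1 Hz and 0.15-0.3-0.4-0.3-0.15 Hz (50 s per
#' step) each appear `n_repeats` times with 30 s rests inside a pair and a
#' 60 s rest between the two sequences. With the defaults every paced rate in
#' \{0.1, 0.15, 0.2, 0.3, 0.4\} Hz occurs exactly four times. Counting blocks
#' carry a simulated reported count and a 1--9 confidence rating.
#'
#' @param seed integer seed; identical seeds give identical schedules.
#' @param n_counting number of heartbeat-counting blocks (default 6).
#' @param n_repeats repetitions of each paced sequence (default 2).
#' @param rest_initial_s,rest_between_s,report_gap_s timing of rests and of
#'   the post-block report window (s).
#' @return a `protocol_schedule`: a data frame with columns `label`
#'   (`rest`/`counting`/`report`/`paced_step`), `start_s`, `end_s`,
#'   `target_rate` (Hz, paced steps only), `counted`, `confidence`.
#' @export
generate_protocol <- function(seed = 1L, n_counting = 6L, n_repeats = 2L,
                              rest_initial_s = 180, rest_between_s = 60,
                              report_gap_s = 15) {
  with_seed(seed, {
    rows <- list()
    t <- 0
    add <- function(label, dur, rate = NA_real_, counted = NA_integer_,
                    conf = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        label = label, start_s = t, end_s = t + dur, target_rate = rate,
        counted = counted, confidence = conf, stringsAsFactors = FALSE)
      t <<- t + dur
    }
    add("rest", rest_initial_s)
    durs <- stats::runif(n_counting, 30, 60)
    for (d in durs) {
      # reported counts emulate typical undercounting of felt heartbeats
      frac <- stats::runif(1, 0.55, 0.95)
      add("counting", d, counted = as.integer(round(d * 1.2 * frac)),
          conf = as.integer(sample(3:9, 1)))
      add("report", report_gap_s)
    }
    add("rest", rest_between_s)
    seqs <- list(c(0.1, 0.2, 0.4, 0.2, 0.1), c(0.15, 0.3, 0.4, 0.3, 0.15))
    for (b in seq_along(seqs)) {
      for (r in seq_len(n_repeats)) {
        for (f in seqs[[b]]) add("paced_step", 50, rate = f)
        if (r < n_repeats) add("rest", 30)
      }
      if (b < length(seqs)) add("rest", rest_between_s)
    }
    sched <- do.call(rbind, rows)
    class(sched) <- c("protocol_schedule", "data.frame")
    sched
  })
}

#' Simulate the breathing waveform for a schedule
#'
#' The waveform is a raised cosine per respiratory cycle driven by a phase
#' accumulator, so paced-step transitions are phase-continuous. During
#' `paced_step` events the instantaneous rate equals the target rate; outside
#' them it is the free rate with slow seeded jitter. Amplitude is normalised
#' to 1 (range 0--1, inhalation peaks at 1).
#'
#' @param schedule a `protocol_schedule`.
#' @param config a `sim_config`.
#' @return list with `x` (waveform), `fs`, `t`, and ground-truth
#'   `peak_times` (s) of the inhalation peaks.
#' @export
simulate_breathing <- function(schedule, config = sim_config()) {
  duration <- if (nrow(schedule)) max(schedule$end_s) else 0
  fs <- config$fs_ecg
  n <- floor(duration * fs)
  if (n == 0L)
    return(list(x = numeric(0), fs = fs, t = numeric(0), peak_times = numeric(0)))
  t <- (seq_len(n) - 1) / fs
  with_seed(config$seed, {
    jitter <- moving_mean(stats::rnorm(n), as.integer(10 * fs))
    jitter <- if (stats::sd(jitter) > 0) jitter / stats::sd(jitter) else jitter
    rate <- config$free_breathing_rate * (1 + 0.05 * jitter)
    if (config$breathing_mode == "paced") {
      paced <- schedule[schedule$label == "paced_step", , drop = FALSE]
      for (i in seq_len(nrow(paced))) {
        idx <- t >= paced$start_s[i] & t < paced$end_s[i]
        rate[idx] <- paced$target_rate[i]
      }
    }
    phase <- cumsum(rate) / fs
    x <- 0.5 - 0.5 * cos(2 * pi * phase)
    # inhalation peaks: phase crossings of k + 1/2, linearly interpolated
    ph <- phase - 0.5
    k <- floor(ph)
    cross <- which(diff(k) >= 1)
    peak_times <- vapply(cross, function(i) {
      target <- k[i] + 1
      t[i] + (target - ph[i]) / (ph[i + 1L] - ph[i]) / fs
    }, numeric(1))
    list(x = x, fs = fs, t = t, peak_times = peak_times)
  })
}

#' Simulate heartbeat times with an IPFM model
#'
#' Integral pulse frequency modulation: a beat is emitted whenever the
#' running integral of the instantaneous rate
#' `m(t) = mean_hr * (1 + rsa_gain * b(t - rsa_lag_s) + lf_gain * sin(2*pi*0.1*t))`
#' crosses a successive integer, where `b` is the unit-normalised breathing
#' waveform. This realises respiratory sinus arrhythmia (heart rate rising
#' on inspiration) at a configurable gain and lag. Integration runs on the
#' breathing sample grid (4 ms at the default 250 Hz) with linear
#' interpolation of the crossing time.
#'
#' @param breathing result of [simulate_breathing()] (or a list with `x`,
#'   `fs`).
#' @param config a `sim_config`.
#' @return numeric vector of beat times in seconds.
#' @export
simulate_heartbeats <- function(breathing, config = sim_config()) {
  if (config$mean_hr <= 0) stop("mean_hr must be positive")
  if (config$rsa_gain + config$lf_gain >= 1)
    stop("rsa_gain + lf_gain must be < 1")
  x <- breathing$x
  fs <- breathing$fs
  if (length(x) == 0L) return(numeric(0))
  b <- x - mean(x)
  m <- max(abs(b))
  if (m > 0) b <- b / m
  b <- shift_series(b, config$rsa_lag_s * fs)
  t <- (seq_along(x) - 1) / fs
  rate <- config$mean_hr *
    (1 + config$rsa_gain * b + config$lf_gain * sin(2 * pi * 0.1 * t))
  phi <- cumsum(rate) / fs
  k <- floor(phi)
  cross <- which(diff(k) >= 1)
  vapply(cross, function(i) {
    target <- k[i] + 1
    t[i] + (target - phi[i]) / (phi[i + 1L] - phi[i]) / fs
  }, numeric(1))
}

# Fixed QRS-like template on the ECG grid: dominant R deflection (Gaussian,
# sigma 8 ms) flanked by small Q and S dips; total width ~80 ms.
qrs_template <- function(fs) {
  tt <- seq(-0.04, 0.04, by = 1 / fs)
  r <- exp(-0.5 * (tt / 0.008)^2)
  q <- -0.15 * exp(-0.5 * ((tt + 0.025) / 0.008)^2)
  s <- -0.2 * exp(-0.5 * ((tt - 0.025) / 0.008)^2)
  r + q + s
}

#' Synthesize an ECG trace from beat times
#'
#' Places a fixed QRS-like template (unit R amplitude, ~80 ms wide) at each
#' beat time on the ECG sampling grid and adds white noise of SD
#' `config$ecg_noise_sd`. R maxima land within one sample of the requested
#' times.
#'
#' @param beat_times strictly increasing beat times (s).
#' @param config a `sim_config`.
#' @param duration_s optional record length; defaults to covering the last
#'   beat plus one second (or `config$duration_s` if no beats).
#' @return list with `x` (ECG series), `fs`, `t`.
#' @export
synthesize_ecg <- function(beat_times, config = sim_config(),
                           duration_s = NULL) {
  if (is.unsorted(beat_times, strictly = TRUE))
    stop("beat_times must be strictly increasing")
  fs <- config$fs_ecg
  if (is.null(duration_s))
    duration_s <- if (length(beat_times)) max(beat_times) + 1 else config$duration_s
  n <- floor(duration_s * fs)
  x <- numeric(n)
  tpl <- qrs_template(fs)
  half <- (length(tpl) - 1L) %/% 2L
  for (bt in beat_times) {
    c0 <- round(bt * fs) + 1L
    lo <- c0 - half; hi <- c0 + half
    sel <- lo:hi
    keep <- sel >= 1L & sel <= n
    x[sel[keep]] <- x[sel[keep]] + tpl[keep]
  }
  with_seed(config$seed + 1L, {
    if (config$ecg_noise_sd > 0) x <- x + stats::rnorm(n, 0, config$ecg_noise_sd)
    list(x = x, fs = fs, t = (seq_len(n) - 1) / fs)
  })
}

# Extinction coefficients (cm^-1 M^-1, decadic) for oxy-/deoxyhemoglobin at
# the two laser wavelengths, from the Gratzer/Prahl compilation of hemoglobin
# absorption spectra. Rows: wavelength; columns: HbO2, HbR.
mbll_extinction <- function() {
  matrix(c(586.0, 1548.52,
           1058.0, 693.04),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "840"), c("HbO", "HbR")))
}

#' Simulate fNIRS channels and their forward optical densities
#'
#' Each channel mixes (i) a shared band-limited 0.05--0.15 Hz "neural" slow
#' oscillation with seeded per-channel weights, (ii) the breathing waveform
#' delayed by a per-channel lag and scaled by a per-channel gain, (iii) a
#' cardiac pulse train at the beat times, and (iv) white noise. The forward
#' optical-density pair at 760/840 nm is computed from the modified
#' Beer-Lambert law with `HbR = -0.3 * HbO` (HbR exists only to make the
#' two-wavelength inversion non-trivial; analyses use HbO).
#'
#' @param breathing result of [simulate_breathing()].
#' @param beat_times heartbeat times (s).
#' @param config a `sim_config`.
#' @return list with `hbo` (time x channel matrix, micromolar), `od` (time x
#'   channel x wavelength array), `fs`, and `truth` (injected per-channel
#'   breathing components, gains, lags, slow wave and weights).
#' @export
simulate_fnirs <- function(breathing, beat_times, config = sim_config()) {
  if (length(config$fnirs_breathing_gain) != config$n_channels ||
      length(config$fnirs_breathing_lag_s) != config$n_channels)
    stop("per-channel gain/lag vectors must have length n_channels")
  fs <- config$fs_fnirs
  nch <- config$n_channels
  b50 <- resample_series(breathing$x, breathing$fs, fs)
  n <- length(b50)
  if (n == 0L)
    return(list(hbo = matrix(0, 0, nch), od = array(0, c(0, nch, 2)),
                fs = fs, truth = NULL))
  bc <- b50 - mean(b50)
  m <- max(abs(bc)); if (m > 0) bc <- bc / m
  t <- (seq_len(n) - 1) / fs
  with_seed(config$seed + 2L, {
    # shared slow wave, band-limited to 0.05-0.15 Hz
    slow <- numeric(n)
    if (config$fnirs_slow_gain > 0 && n > 50L) {
      w <- stats::rnorm(n)
      bf <- signal::butter(2, c(0.05, 0.15) / (fs / 2), type = "pass")
      slow <- signal::filtfilt(bf, w)
      s <- stats::sd(slow); if (s > 0) slow <- slow / s
    }
    weights <- stats::runif(nch, 0.3, 1)
    # smooth cardiac pulse: raised cosine of width 0.4 s at each beat
    pulse <- numeric(n)
    if (config$fnirs_pulse_gain > 0 && length(beat_times)) {
      half <- round(0.2 * fs)
      kern <- 0.5 + 0.5 * cos(pi * seq(-half, half) / half)
      for (bt in beat_times) {
        c0 <- round(bt * fs) + 1L
        sel <- (c0 - half):(c0 + half)
        keep <- sel >= 1L & sel <= n
        pulse[sel[keep]] <- pulse[sel[keep]] + kern[keep]
      }
    }
    breath_comp <- vapply(seq_len(nch), function(c) {
      config$fnirs_breathing_gain[c] *
        shift_series(bc, config$fnirs_breathing_lag_s[c] * fs)
    }, numeric(n))
    hbo <- breath_comp +
      outer(slow, weights * config$fnirs_slow_gain) +
      matrix(pulse * config$fnirs_pulse_gain, n, nch) +
      matrix(stats::rnorm(n * nch, 0, config$fnirs_noise_sd), n, nch)
    hbr <- -0.3 * hbo
    ext <- mbll_extinction()
    pl <- config$distance_cm * config$dpf          # effective pathlength, cm
    od <- array(0, c(n, nch, 2),
                dimnames = list(NULL, NULL, c("760", "840")))
    od[, , 1] <- (ext["760", "HbO"] * hbo + ext["760", "HbR"] * hbr) * 1e-6 * pl
    od[, , 2] <- (ext["840", "HbO"] * hbo + ext["840", "HbR"] * hbr) * 1e-6 * pl
    list(hbo = hbo, od = od, fs = fs,
         truth = list(breathing_component = breath_comp,
                      gains = config$fnirs_breathing_gain,
                      lags_s = config$fnirs_breathing_lag_s,
                      slow = slow, weights = weights))
  })
}

#' Simulate a complete multimodal recording
#'
#' Chains the generators: protocol schedule, breathing, IPFM heartbeats, ECG
#' and fNIRS, and packs the result with the ground truth kept in a separate
#' `truth` element that no analysis stage may consume.
#'
#' @param config a `sim_config`.
#' @param schedule optional pre-built `protocol_schedule`; by default
#'   [generate_protocol()] is called with `config$seed`.
#' @param fnirs logical; generate the fNIRS modality (default TRUE).
#' @return a `multimodal_recording`: list with `ecg`, `breathing`,
#'   `fnirs_hbo`, `fnirs_od`, `fs_ecg`, `fs_fnirs`, `schedule`, `truth`.
#' @export
simulate_recording <- function(config = sim_config(), schedule = NULL,
                               fnirs = TRUE) {
  if (is.null(schedule)) schedule <- generate_protocol(config$seed)
  br <- simulate_breathing(schedule, config)
  beats <- simulate_heartbeats(br, config)
  ecg <- synthesize_ecg(beats, config, duration_s = max(schedule$end_s))
  fn <- if (fnirs) simulate_fnirs(br, beats, config) else NULL
  rec <- list(
    ecg = ecg$x, breathing = br$x,
    fnirs_hbo = if (fnirs) fn$hbo else NULL,
    fnirs_od = if (fnirs) fn$od else NULL,
    fs_ecg = config$fs_ecg, fs_fnirs = config$fs_fnirs,
    schedule = schedule, config = config,
    truth = list(beat_times = beats, breath_peak_times = br$peak_times,
                 fnirs = if (fnirs) fn$truth else NULL)
  )
  class(rec) <- "multimodal_recording"
  rec
}
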