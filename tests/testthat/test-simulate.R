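# Generators: protocol schedule, breathing waveform, IPFM heartbeats,
# ECG synthesis, fNIRS forward model.

test_that("protocol schedule has the designed block structure", {
  sched <- generate_protocol(1)
  expect_false(is.unsorted(sched$start_s))
  expect_true(all(sched$end_s > sched$start_s))
  expect_true(all(diff(sched$start_s) >= diff(sched$end_s) - 1e-9) ||
                all(sched$start_s[-1] >= sched$end_s[-nrow(sched)] - 1e-9))
  cnt <- sched[sched$label == "counting", ]
  expect_equal(nrow(cnt), 6)
  durs <- cnt$end_s - cnt$start_s
  expect_true(all(durs >= 30 & durs <= 60))
  expect_true(all(!is.na(cnt$counted) & cnt$counted >= 0))
  expect_true(all(cnt$confidence %in% 1:9))
  paced <- sched[sched$label == "paced_step", ]
  expect_true(all(paced$end_s - paced$start_s == 50))
  expect_equal(as.integer(table(paced$target_rate)), rep(4L, 5))
  expect_equal(sort(unique(paced$target_rate)), c(0.1, 0.15, 0.2, 0.3, 0.4))
})

test_that("protocol generation is deterministic under a seed", {
  expect_identical(generate_protocol(42), generate_protocol(42))
  expect_false(identical(generate_protocol(1), generate_protocol(2)))
})

test_that("breathing waveform is paced where scheduled and normalized", {
  cfg <- sim_config(seed = 5)
  sched <- make_paced_schedule()
  br <- simulate_breathing(sched, cfg)
  expect_equal(length(br$x), 280 * cfg$fs_ecg)
  expect_true(max(br$x) <= 1 + 1e-9 && min(br$x) >= -1e-9)
  # ~10 inhalation peaks in a 50-s 0.2 Hz step
  step <- sched[sched$label == "paced_step" & sched$target_rate == 0.2, ][1, ]
  n_peaks <- sum(br$peak_times >= step$start_s & br$peak_times < step$end_s)
  expect_true(abs(n_peaks - 10) <= 1)
  # FFT periodogram oracle: paced 0.1 Hz segment peaks at 0.1 Hz
  s01 <- sched[sched$label == "paced_step" & sched$target_rate == 0.1, ][1, ]
  seg <- br$x[(round(s01$start_s * cfg$fs_ecg) + 1):round(s01$end_s * cfg$fs_ecg)]
  expect_lt(abs(fft_peak(seg, cfg$fs_ecg, band = c(0.02, 1)) - 0.1), 0.021)
})

test_that("zero-duration schedule yields an empty series", {
  sched <- make_schedule(character(0), numeric(0))
  br <- simulate_breathing(sched, sim_config())
  expect_length(br$x, 0)
  expect_length(br$peak_times, 0)
  expect_length(simulate_heartbeats(br, sim_config()), 0)
})

test_that("constant-rate IPFM emits beats at exactly the mean rate", {
  cfg <- sim_config(seed = 2, rsa_gain = 0, lf_gain = 0, mean_hr = 1.2)
  sched <- make_schedule("rest", 60)
  br <- simulate_breathing(sched, cfg)
  beats <- simulate_heartbeats(br, cfg)
  expect_true(abs(length(beats) - 72) <= 1)
  expect_true(all(abs(diff(beats) - 1 / 1.2) < 1 / cfg$fs_ecg))
})

test_that("IPFM beat count equals the integrated rate (conservation)", {
  for (s in 1:5) {
    cfg <- sim_config(seed = s, rsa_gain = 0.15, lf_gain = 0.05)
    sched <- make_schedule("rest", 120)
    br <- simulate_breathing(sched, cfg)
    beats <- simulate_heartbeats(br, cfg)
    b <- br$x - mean(br$x); b <- b / max(abs(b))
    b <- interopipe:::shift_series(b, cfg$rsa_lag_s * cfg$fs_ecg)
    t <- (seq_along(b) - 1) / cfg$fs_ecg
    total <- sum(cfg$mean_hr * (1 + cfg$rsa_gain * b +
                                  cfg$lf_gain * sin(2 * pi * 0.1 * t))) / cfg$fs_ecg
    expect_true(abs(length(beats) - floor(total)) <= 1)
    # mean rate within 2% of mean_hr at modest gains
    expect_lt(abs(length(beats) / 120 - cfg$mean_hr) / cfg$mean_hr, 0.02)
  }
})

test_that("RSA modulation appears in the IBI series at the breathing rate", {
  cfg <- sim_config(seed = 3, rsa_gain = 0.1, lf_gain = 0, rsa_lag_s = 0,
                    breathing_mode = "paced")
  sched <- make_schedule(c("rest", "paced_step"), c(10, 200), c(NA, 0.1))
  br <- simulate_breathing(sched, cfg)
  beats <- simulate_heartbeats(br, cfg)
  ann <- beat_annotations(beats)
  # interpolate IBIs to a uniform grid and locate the spectral peak by FFT
  grid <- seq(ann$event_times[2], max(ann$event_times), by = 0.25)
  ibi_u <- stats::spline(ann$event_times[-1], ann$ibi, xout = grid)$y
  expect_lt(abs(fft_peak(ibi_u, 4, band = c(0.03, 0.5)) - 0.1), 0.015)
})

test_that("injected RSA lag is recoverable by a brute-force lag scan", {
  cfg <- sim_config(seed = 4, rsa_gain = 0.15, lf_gain = 0, rsa_lag_s = 10)
  sched <- make_schedule("rest", 300)
  br <- simulate_breathing(sched, cfg)
  beats <- simulate_heartbeats(br, cfg)
  ann <- beat_annotations(beats)
  hr <- ibi_to_rate(ann)
  b4 <- stats::approx((seq_along(br$x) - 1) / cfg$fs_ecg, br$x,
                      xout = hr$t, rule = 2)$y
  lag_grid <- seq(0, 20, by = 0.25)
  cc <- vapply(lag_grid, function(L) {
    k <- round(L * 4); n <- length(b4)
    stats::cor(b4[seq_len(n - k)], hr$value[(k + 1):n])
  }, numeric(1))
  expect_lt(abs(lag_grid[which.max(cc)] - 10), 1)
})

test_that("IPFM rejects invalid configurations", {
  cfg <- sim_config(seed = 1)
  cfg$mean_hr <- -1
  br <- simulate_breathing(make_schedule("rest", 30), sim_config(seed = 1))
  expect_error(simulate_heartbeats(br, cfg), "positive")
  expect_error(sim_config(rsa_gain = 0.6, lf_gain = 0.5), "< 1")
  expect_error(sim_config(rsa_gain = -0.1), "non-negative")
})

test_that("ECG synthesis places R maxima at the requested beat times", {
  cfg <- sim_config(seed = 1, ecg_noise_sd = 0)
  beats <- seq(0.5, 29.5, by = 0.8)
  ecg <- synthesize_ecg(beats, cfg, duration_s = 30)
  for (bt in beats[1:10]) {
    win <- round(bt * 250) + (-10:10)
    tmax <- (win[which.max(ecg$x[win + 1])]) / 250
    expect_lt(abs(tmax - bt), 1.5 / 250)
  }
  # empty beat list: pure noise
  cfg2 <- sim_config(seed = 1, ecg_noise_sd = 0.1)
  e2 <- synthesize_ecg(numeric(0), cfg2, duration_s = 10)
  expect_lt(max(abs(e2$x)), 1)
  expect_gt(stats::sd(e2$x), 0.05)
  expect_error(synthesize_ecg(c(1, 0.5), cfg), "increasing")
})

test_that("fNIRS forward model is consistent and invertible", {
  cfg <- sim_config(seed = 6, fnirs_breathing_gain = 0, fnirs_pulse_gain = 0,
                    fnirs_slow_gain = 0, fnirs_noise_sd = 0)
  sched <- make_schedule("rest", 60)
  br <- simulate_breathing(sched, cfg)
  fn <- simulate_fnirs(br, numeric(0), cfg)
  expect_true(all(fn$hbo == 0))
  expect_true(all(fn$od == 0))
  # round trip through the Beer-Lambert inversion
  cfg2 <- sim_config(seed = 6)
  fn2 <- simulate_fnirs(br, simulate_heartbeats(br, cfg2), cfg2)
  hb <- od_to_hbo(fn2$od, dpf = cfg2$dpf, distance_cm = cfg2$distance_cm)
  expect_lt(max(abs(hb$hbo - fn2$hbo)), 1e-6)
})

test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 9)
  sched <- make_paced_schedule(step_s = 30)
  r1 <- simulate_recording(cfg, sched)
  r2 <- simulate_recording(cfg, sched)
  expect_identical(r1$ecg, r2$ecg)
  expect_identical(r1$breathing, r2$breathing)
  expect_identical(r1$fnirs_od, r2$fnirs_od)
  expect_identical(r1$truth, r2$truth)
})
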