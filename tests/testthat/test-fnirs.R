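# Optical densities, Beer-Lambert inversion, filtering, connectivity, and
# PCA breathing-response extraction.

test_that("optical density definition and invariances", {
  I <- matrix(100, 500, 3)
  expect_true(all(intensities_to_od(I) == 0))
  I2 <- I; I2[100, 2] <- mean(I2[, 2]) / 10 * (500 / (499 + 0.1))  # approx
  I3 <- matrix(rexp(1500) + 1, 500, 3)
  expect_equal(intensities_to_od(I3), intensities_to_od(2 * I3), tolerance = 1e-12)
  expect_error(intensities_to_od(I - 200), "positive")
  # one sample at a tenth of the mean gives OD ~ 1 there
  I4 <- matrix(100, 1000, 1); I4[500, 1] <- 10
  od <- intensities_to_od(I4)
  expect_lt(abs(od[500, 1] - 1), 0.05)
})

test_that("Beer-Lambert inversion is linear and scales with DPF", {
  set.seed(4)
  od <- array(rnorm(200 * 3 * 2, sd = 0.01), c(200, 3, 2))
  z <- od_to_hbo(array(0, c(10, 2, 2)))
  expect_true(all(z$hbo == 0))
  a <- od_to_hbo(od); b <- od_to_hbo(2 * od)
  expect_equal(2 * a$hbo, b$hbo, tolerance = 1e-12)
  # linearity across two inputs
  od2 <- array(rnorm(200 * 3 * 2, sd = 0.01), c(200, 3, 2))
  ab <- od_to_hbo(od + od2)
  expect_equal(ab$hbo, a$hbo + od_to_hbo(od2)$hbo, tolerance = 1e-10)
  half <- od_to_hbo(od, dpf = 12)
  expect_equal(half$hbo, a$hbo / 2, tolerance = 1e-12)
  expect_error(od_to_hbo(od[, , 1, drop = FALSE]), "wavelength")
})

test_that("fNIRS band-pass removes pulse and DC but keeps the breathing band", {
  fs <- 50
  t <- seq(0, 120, by = 1 / fs)
  mid <- seq(20 * fs, 100 * fs)
  pulse <- sin(2 * pi * 1.2 * t)
  breath <- sin(2 * pi * 0.2 * t)
  expect_lte(max(abs(filter_fnirs(cbind(pulse), fs)[mid, 1])), 0.1)
  expect_gte(max(abs(filter_fnirs(cbind(breath), fs)[mid, 1])), 0.9)
  # a DC offset is removed up to slowly decaying filter transients
  dc <- filter_fnirs(cbind(rep(5, length(t))), fs)
  expect_lt(abs(mean(dc[mid, 1])), 0.05)
  expect_lt(max(abs(dc[mid, 1])), 0.1)
})

test_that("channel connectivity matrix is symmetric with unit diagonal", {
  set.seed(5)
  fs <- 50
  shared <- sin(2 * pi * 0.1 * seq(0, 60, by = 1 / fs))
  x <- sapply(1:6, function(i) shared + 0.5 * rnorm(length(shared)))
  cn <- channel_connectivity(x, fs)
  expect_equal(cn$matrix, t(cn$matrix))
  expect_true(all(diag(cn$matrix) == 1))
  expect_true(all(abs(cn$matrix) <= 1))
  # identical channels: all ones
  same <- channel_connectivity(cbind(shared, shared, shared), fs)
  expect_true(all(abs(same$matrix - 1) < 1e-12))
  expect_equal(same$per_channel_median, rep(1, 3))
  # independent channels: low off-diagonal medians
  noise <- matrix(rnorm(60 * fs * 5), ncol = 5)
  expect_lt(max(abs(channel_connectivity(noise, fs)$per_channel_median)), 0.2)
  expect_error(channel_connectivity(noise[1:100, ], fs), "30 s")
})

test_that("connectivity is invariant under channel-wise monotone transforms", {
  set.seed(6)
  x <- matrix(rnorm(40 * 50 * 4), ncol = 4) + sin(seq_len(40 * 50) / 100)
  cn1 <- channel_connectivity(x, 50)
  y <- x
  y[, 1] <- exp(x[, 1]); y[, 2] <- x[, 2]^3; y[, 3] <- 2 * x[, 3] + 7
  cn2 <- channel_connectivity(y, 50)
  expect_equal(cn1$matrix, cn2$matrix, tolerance = 1e-12)
})

test_that("raising the shared-component gain increases connectivity", {
  meds <- vapply(c(0.1, 0.4, 1), function(g) {
    stats::median(vapply(1:8, function(s) {
      cfg <- sim_config(seed = s, fnirs_slow_gain = g, n_channels = 8,
                        fnirs_breathing_gain = 0.1,
                        fnirs_breathing_lag_s = 5)
      br <- simulate_breathing(make_schedule("rest", 60), cfg)
      fn <- simulate_fnirs(br, numeric(0), cfg)
      mean(channel_connectivity(fn$hbo, 50)$per_channel_median)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("PCA extractor recovers an injected breathing component", {
  cfg <- sim_config(seed = 7, fnirs_breathing_gain = 1, fnirs_noise_sd = 0.1,
                    n_channels = 12,
                    fnirs_breathing_lag_s = seq(4.5, 5.5, length.out = 12))
  sched <- make_paced_schedule(step_s = 40, rest_s = 20)
  br <- simulate_breathing(sched, cfg)
  beats <- simulate_heartbeats(br, cfg)
  fn <- simulate_fnirs(br, beats, cfg)
  hbf <- filter_fnirs(od_to_hbo(fn$od))
  resp <- extract_breathing_response(hbf$hbo, list(x = br$x, fs = 250))
  expect_false(resp$empty)
  expect_true(all(abs(resp$selected$rho) > 0.6))
  truth_f <- filter_fnirs(fn$truth$breathing_component, fs = 50)
  rhos <- vapply(seq_len(ncol(truth_f)), function(c)
    stats::cor(resp$response[, c], truth_f[, c], method = "spearman"),
    numeric(1))
  expect_gte(min(rhos), 0.9)
  lags <- breathing_response_lag(resp, list(x = br$x, fs = 250))
  expect_lte(max(abs(lags - cfg$fnirs_breathing_lag_s)), 0.5)
})

test_that("channels with distinct injected lags keep their ordering", {
  cfg <- sim_config(seed = 9, fnirs_breathing_gain = 1, fnirs_noise_sd = 0.1,
                    n_channels = 6,
                    fnirs_breathing_lag_s = rep(c(2, 8), c(2, 4)))
  sched <- make_paced_schedule(step_s = 40, rest_s = 20)
  br <- simulate_breathing(sched, cfg)
  fn <- simulate_fnirs(br, numeric(0), cfg)
  hbf <- filter_fnirs(od_to_hbo(fn$od))
  resp <- extract_breathing_response(hbf$hbo, list(x = br$x, fs = 250))
  lags <- breathing_response_lag(resp, list(x = br$x, fs = 250))
  expect_true(all(lags[1:2] < lags[3:6]))
  expect_lte(max(abs(lags - cfg$fnirs_breathing_lag_s)), 0.5)
})

test_that("without injected breathing the extractor mostly returns empty", {
  empty <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = 500 + s, fnirs_breathing_gain = 0,
                      n_channels = 8, fnirs_breathing_lag_s = 0)
    br <- simulate_breathing(make_schedule("rest", 300), cfg)
    fn <- simulate_fnirs(br, numeric(0), cfg)
    resp <- extract_breathing_response(filter_fnirs(fn$hbo, 50),
                                       list(x = br$x, fs = 250))
    resp$empty
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("a channel equal to breathing is reproduced almost exactly", {
  set.seed(10)
  fs <- 50
  t <- seq(0, 150, by = 1 / fs)
  b <- sin(2 * pi * 0.25 * t) + 0.2 * sin(2 * pi * 0.05 * t)
  x <- cbind(b, sapply(1:4, function(i) 0.3 * rnorm(length(t))))
  resp <- extract_breathing_response(x, b, fs = fs)
  expect_false(resp$empty)
  expect_gt(stats::cor(resp$response[, 1], b), 0.99)
})

test_that("PCA matches a direct eigendecomposition oracle on a small instance", {
  set.seed(11)
  fs <- 50
  t <- seq(0, 120, by = 1 / fs)
  b <- sin(2 * pi * 0.25 * t)
  x <- sapply(1:5, function(i)
    i / 5 * interopipe:::shift_series(b, i * 10) + 0.2 * rnorm(length(t)))
  Z <- cbind(scale(x), as.numeric(scale(b)))
  ev <- eigen(crossprod(Z) / (nrow(Z) - 1))
  pc <- stats::prcomp(Z, center = FALSE)
  expect_equal(pc$sdev^2, ev$values, tolerance = 1e-8)
  # reconstruction residual orthogonal to the retained scores
  resp <- extract_breathing_response(x, b, fs = fs)
  sel <- resp$selected$component
  scores <- pc$x[, sel, drop = FALSE]
  # orthogonality of scores with the un-reconstructed remainder
  Zrec <- pc$x[, sel, drop = FALSE] %*% t(pc$rotation[, sel, drop = FALSE])
  R <- Z - Zrec
  expect_lt(max(abs(crossprod(scores, R))), 1e-6)
})
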