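# End-to-end study orchestration on a synthetic cohort: simulate -> beats ->
# rates -> cardiorespiratory coupling -> fNIRS -> group statistics.

#' Study configuration
#'
#' Collects every stage parameter of the full pipeline with the defaults
#' used throughout: ECG band 0.5--45 Hz order 4, fNIRS band 0.05--0.6 Hz
#' order 3, Burg order 16, 4 Hz rate grid, lags -30..+30 s, PCA selection
#' threshold 0.6, 10,000 permutations at alpha 0.05, channel-wise Bonferroni
#' 0.05/23, and a cohort of 19 subjects of whom 12 carry fNIRS.
#'
#' @param n_subjects cohort size.
#' @param n_fnirs number of subjects with fNIRS recordings.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param grid_fs uniform rate-grid sampling rate (Hz).
#' @param ar_order Burg AR order.
#' @param lag_range cross-correlation lag window (s).
#' @param pca_threshold |rho| threshold for breathing-component selection.
#' @param n_perm Monte-Carlo permutations.
#' @param alpha significance level.
#' @param sim list of overrides passed to [sim_config()].
#' @param protocol list of overrides passed to [generate_protocol()].
#' @return a `study_config` list.
#' @export
study_config <- function(n_subjects = 19, n_fnirs = 12, seed = 1L,
                         grid_fs = 4, ar_order = 16, lag_range = c(-30, 30),
                         pca_threshold = 0.6, n_perm = 10000, alpha = 0.05,
                         sim = list(), protocol = list()) {
  structure(list(n_subjects = n_subjects, n_fnirs = n_fnirs,
                 seed = as.integer(seed), grid_fs = grid_fs,
                 ar_order = ar_order, lag_range = lag_range,
                 pca_threshold = pca_threshold, n_perm = n_perm,
                 alpha = alpha, sim = sim, protocol = protocol),
            class = "study_config")
}

#' HRV (or breathing-variability) spectrum from beat annotations
#'
#' Interpolates the inter-beat-interval series to a uniform grid
#' (cubic spline, 4 Hz default), optionally restricted to a time window,
#' and estimates its Burg power spectrum. The interval series -- not the
#' rate series -- is the conventional input for HRV spectra.
#'
#' @param annotations a [beat_annotations()] object.
#' @param grid_fs interpolation grid rate (Hz).
#' @param order Burg AR order.
#' @param t_range optional `c(lo, hi)` window (s) of event times to use.
#' @return a `spectrum_result` (see [burg_psd()]).
#' @export
hrv_spectrum <- function(annotations, grid_fs = 4, order = 16,
                         t_range = NULL) {
  t_ev <- annotations$event_times[-1L]
  ibi <- annotations$ibi
  if (!is.null(t_range)) {
    keep <- t_ev >= t_range[1] & t_ev <= t_range[2]
    t_ev <- t_ev[keep]; ibi <- ibi[keep]
  }
  if (length(t_ev) < 4L) stop("too few events in the window")
  grid <- seq(t_ev[1L], t_ev[length(t_ev)], by = 1 / grid_fs)
  v <- stats::spline(t_ev, ibi, xout = grid, method = "fmm")$y
  burg_psd(v, fs = grid_fs, order = order)
}

#' Analyze one multimodal recording
#'
#' Runs the single-subject pipeline: ECG filtering, R-peak detection,
#' ectopic correction, instantaneous heart and breathing rates,
#' cardiorespiratory coupling, per-counting-block accuracy, per-paced-rate
#' HRV main frequencies, and (when fNIRS is present) the Beer-Lambert
#' inversion, band-pass, channel connectivity and PCA breathing response.
#'
#' @param rec a `multimodal_recording`.
#' @param config a [study_config()].
#' @return list of per-subject markers (rates, accuracy, coupling, paced
#'   main frequencies, fNIRS summaries).
#' @export
analyze_recording <- function(rec, config = study_config()) {
  ecg_f <- filter_ecg(rec$ecg, rec$fs_ecg)
  ann <- detect_r_peaks(ecg_f, rec$fs_ecg)
  ann <- correct_ectopic(ann, detect_ectopic(ann))
  hr <- ibi_to_rate(ann, config$grid_fs, source = "heart")
  hr_s <- smooth_rate(hr, 2)
  bann <- detect_breath_peaks(rec$breathing, rec$fs_ecg)
  br <- ibi_to_rate(bann, config$grid_fs, source = "breathing")
  sched <- rec$schedule
  rests <- sched[sched$label == "rest", , drop = FALSE]
  rest1 <- rests[1L, ]
  in_win <- function(rs, lo, hi) rs$value[rs$t >= lo & rs$t < hi]
  cr <- cardioresp_correlation(list(x = rec$breathing, fs = rec$fs_ecg), hr_s,
                               config$lag_range)
  # heartbeat-counting accuracy per block
  blocks <- sched[sched$label == "counting", , drop = FALSE]
  acc <- conf <- numeric(0)
  if (nrow(blocks)) {
    nb <- vapply(seq_len(nrow(blocks)), function(i)
      sum(ann$event_times >= blocks$start_s[i] &
            ann$event_times < blocks$end_s[i]), numeric(1))
    acc <- counting_accuracy(blocks$counted, nb)
    conf <- blocks$confidence
  }
  # HRV main frequency per paced breathing rate, averaged over the trials
  paced <- sched[sched$label == "paced_step", , drop = FALSE]
  mainfreq <- NULL
  if (nrow(paced)) {
    mf <- vapply(seq_len(nrow(paced)), function(i) {
      sp <- hrv_spectrum(ann, config$grid_fs, config$ar_order,
                         t_range = c(paced$start_s[i], paced$end_s[i]))
      as.numeric(main_frequency(sp))
    }, numeric(1))
    mainfreq <- vapply(split(mf, paced$target_rate), mean, numeric(1))
  }
  rest_mf <- tryCatch(as.numeric(main_frequency(
    hrv_spectrum(ann, config$grid_fs, config$ar_order,
                 t_range = c(rest1$start_s, rest1$end_s)))),
    error = function(e) NA_real_)
  out <- list(
    mean_hr = mean(hr$value), mean_br = mean(br$value),
    rest_hr = mean(in_win(hr, rest1$start_s, rest1$end_s)),
    rest_br = mean(in_win(br, rest1$start_s, rest1$end_s)),
    counting_hr = if (nrow(blocks)) mean(unlist(lapply(seq_len(nrow(blocks)),
      function(i) in_win(hr, blocks$start_s[i], blocks$end_s[i])))) else NA_real_,
    accuracy = if (length(acc)) mean(acc) else NA_real_,
    confidence = if (length(conf)) mean(conf) else NA_real_,
    rho_max = cr$rho_max, lag_at_max = cr$lag_at_max,
    mainfreq_paced = mainfreq, mainfreq_rest = rest_mf,
    n_ectopic = sum(ann$ectopic)
  )
  if (!is.null(rec$fnirs_od)) {
    hb <- od_to_hbo(rec$fnirs_od, fs = rec$fs_fnirs)
    hbf <- filter_fnirs(hb)
    conn <- channel_connectivity(hbf$hbo, fs = rec$fs_fnirs)
    resp <- extract_breathing_response(hbf$hbo,
                                       list(x = rec$breathing, fs = rec$fs_ecg),
                                       fs = rec$fs_fnirs,
                                       threshold = config$pca_threshold,
                                       lag_range = config$lag_range)
    lags <- if (!resp$empty)
      breathing_response_lag(resp, list(x = rec$breathing, fs = rec$fs_ecg),
                             lag_range = config$lag_range)
    else rep(NA_real_, ncol(hbf$hbo))
    out$fnirs <- list(connectivity_median = conn$per_channel_median,
                      response_empty = resp$empty,
                      n_components = nrow(resp$selected),
                      response_lag_s = as.numeric(lags))
  }
  out
}

#' Run the full study on a synthetic cohort
#'
#' Simulates `n_subjects` protocol-structured recordings (the first
#' `n_fnirs` with fNIRS), runs [analyze_recording()] on each, and assembles
#' the group tables: median +/- MAD of heart/breathing rates and counting
#' accuracy, per-paced-rate HRV main frequencies with Monte-Carlo-corrected
#' Wilcoxon contrasts against rest, the cardiorespiratory coupling summary,
#' and the fNIRS connectivity/breathing-response summary. Fully
#' deterministic under the configured seed.
#'
#' @param config a [study_config()].
#' @return list with `subjects` (per-subject data frame), `rates`,
#'   `accuracy`, `mainfreq` (per paced rate), `coupling`, `fnirs`,
#'   `provenance`.
#' @export
run_study <- function(config = study_config()) {
  subs <- lapply(seq_len(config$n_subjects), function(s) {
    seed_s <- config$seed + 101L * s
    sim <- do.call(sim_config, utils::modifyList(list(seed = seed_s),
                                                 config$sim))
    sched <- do.call(generate_protocol,
                     utils::modifyList(list(seed = seed_s), config$protocol))
    rec <- simulate_recording(sim, sched, fnirs = s <= config$n_fnirs)
    analyze_recording(rec, config)
  })
  g <- function(field) vapply(subs, function(s) s[[field]], numeric(1))
  subjects <- data.frame(
    subject = seq_len(config$n_subjects),
    mean_hr = g("mean_hr"), mean_br = g("mean_br"),
    rest_hr = g("rest_hr"), rest_br = g("rest_br"),
    counting_hr = g("counting_hr"),
    accuracy = g("accuracy"), confidence = g("confidence"),
    rho_max = g("rho_max"), lag_at_max = g("lag_at_max"),
    n_ectopic = g("n_ectopic")
  )
  mm <- function(x) group_median_mad(x[is.finite(x)])
  rates_tab <- list(rest_hr = mm(subjects$rest_hr),
                    rest_br = mm(subjects$rest_br),
                    counting_hr = mm(subjects$counting_hr))
  acc_tab <- list(accuracy = mm(subjects$accuracy),
                  confidence = mm(subjects$confidence),
                  accuracy_vs_confidence =
                    if (config$n_subjects >= 4)
                      spearman_p(subjects$accuracy, subjects$confidence)
                    else NULL)
  # paced main frequencies: subjects x rate matrix, contrasted against rest
  rates_paced <- sort(unique(unlist(lapply(subs, function(s)
    as.numeric(names(s$mainfreq_paced))))))
  mainfreq <- NULL
  if (length(rates_paced)) {
    mfm <- t(vapply(subs, function(s)
      s$mainfreq_paced[as.character(rates_paced)], numeric(length(rates_paced))))
    colnames(mfm) <- as.character(rates_paced)
    mainfreq <- lapply(as.character(rates_paced), function(r) {
      res <- mm(mfm[, r])
      res$wilcoxon_vs_rest <-
        if (config$n_subjects >= 5)
          monte_carlo_correct(mfm[, r], g("mainfreq_rest"),
                              n_perm = config$n_perm, alpha = config$alpha,
                              seed = config$seed)
        else NULL
      res
    })
    names(mainfreq) <- as.character(rates_paced)
  }
  coupling <- list(rho_max = mm(subjects$rho_max),
                   lag_s = mm(subjects$lag_at_max))
  fnirs_tab <- NULL
  if (config$n_fnirs > 0) {
    fn <- lapply(subs[seq_len(config$n_fnirs)], `[[`, "fnirs")
    conn_med <- vapply(fn, function(f) stats::median(f$connectivity_median),
                       numeric(1))
    lag_med <- vapply(fn, function(f)
      stats::median(f$response_lag_s, na.rm = TRUE), numeric(1))
    fnirs_tab <- list(connectivity_median = mm(conn_med),
                      response_lag_s = mm(lag_med[is.finite(lag_med)]),
                      n_empty_responses = sum(vapply(fn, `[[`,
                                                     logical(1), "response_empty")))
  }
  list(subjects = subjects, rates = rates_tab, accuracy = acc_tab,
       mainfreq = mainfreq, coupling = coupling, fnirs = fnirs_tab,
       provenance = list(seed = config$seed, config = unclass(config),
                         package_version =
                           as.character(utils::packageVersion("interopipe")),
                         r_version = R.version.string))
}
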