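# Recording readers/writers: one CSV per modality plus JSON sidecars for
# events, sampling metadata and (synthetic-only) ground truth.

#' Write a multimodal recording to a directory
#'
#' Emits `ecg.csv` and `breathing.csv` (`t_s`, value), `fnirs_hbo.csv`
#' (`t_s`, `ch01`...), `fnirs_od760.csv` / `fnirs_od840.csv` when present,
#' an `events.json` sidecar (label, onset, duration, attributes), a
#' `meta.json` with sampling rates and channel counts, and -- for synthetic
#' recordings -- a `truth.json` kept separate from the analysed signals.
#'
#' @param rec a `multimodal_recording`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t_ecg <- (seq_along(rec$ecg) - 1) / rec$fs_ecg
  utils::write.csv(data.frame(t_s = t_ecg, ecg = rec$ecg),
                   file.path(dir, "ecg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t_s = t_ecg, breathing = rec$breathing),
                   file.path(dir, "breathing.csv"), row.names = FALSE)
  if (!is.null(rec$fnirs_hbo)) {
    nch <- ncol(rec$fnirs_hbo)
    t_fn <- (seq_len(nrow(rec$fnirs_hbo)) - 1) / rec$fs_fnirs
    cn <- sprintf("ch%02d", seq_len(nch))
    hbo <- as.data.frame(rec$fnirs_hbo); names(hbo) <- cn
    utils::write.csv(cbind(t_s = t_fn, hbo),
                     file.path(dir, "fnirs_hbo.csv"), row.names = FALSE)
    for (w in c(1, 2)) {
      od <- as.data.frame(rec$fnirs_od[, , w]); names(od) <- cn
      utils::write.csv(cbind(t_s = t_fn, od),
                       file.path(dir, sprintf("fnirs_od%s.csv",
                                              c("760", "840")[w])),
                       row.names = FALSE)
    }
  }
  ev <- rec$schedule
  events <- lapply(seq_len(nrow(ev)), function(i) {
    e <- list(label = ev$label[i], onset = ev$start_s[i],
              duration = ev$end_s[i] - ev$start_s[i])
    if (!is.na(ev$target_rate[i])) e$target_rate <- ev$target_rate[i]
    if (!is.na(ev$counted[i])) e$counted <- ev$counted[i]
    if (!is.na(ev$confidence[i])) e$confidence <- ev$confidence[i]
    e
  })
  jsonlite::write_json(events, file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(fs_ecg = rec$fs_ecg, fs_fnirs = rec$fs_fnirs,
               n_ecg = length(rec$ecg),
               n_fnirs = if (!is.null(rec$fnirs_hbo)) nrow(rec$fnirs_hbo) else 0L,
               n_channels = if (!is.null(rec$fnirs_hbo)) ncol(rec$fnirs_hbo) else 0L)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(rec$truth))
    jsonlite::write_json(rec$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multimodal recording from a directory
#'
#' Inverse of [write_recording()]: validates that every present modality has
#' the length announced in `meta.json` (errors name the offending file) and
#' reparses the event sidecar into a `protocol_schedule`.
#'
#' @param dir directory written by [write_recording()].
#' @return a `multimodal_recording`.
#' @export
read_recording <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing file: %s", f))
    p
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  ecg <- utils::read.csv(need("ecg.csv"))
  if (nrow(ecg) != meta$n_ecg)
    stop(sprintf("length mismatch in ecg.csv: %d rows, expected %d",
                 nrow(ecg), meta$n_ecg))
  br <- utils::read.csv(need("breathing.csv"))
  if (nrow(br) != meta$n_ecg)
    stop(sprintf("length mismatch in breathing.csv: %d rows, expected %d",
                 nrow(br), meta$n_ecg))
  hbo <- od <- NULL
  if (meta$n_fnirs > 0) {
    hb <- utils::read.csv(need("fnirs_hbo.csv"))
    if (nrow(hb) != meta$n_fnirs)
      stop(sprintf("length mismatch in fnirs_hbo.csv: %d rows, expected %d",
                   nrow(hb), meta$n_fnirs))
    hbo <- as.matrix(hb[, -1, drop = FALSE])
    dimnames(hbo) <- NULL
    od <- array(0, c(meta$n_fnirs, meta$n_channels, 2),
                dimnames = list(NULL, NULL, c("760", "840")))
    for (w in c(1, 2)) {
      f <- sprintf("fnirs_od%s.csv", c("760", "840")[w])
      odf <- utils::read.csv(need(f))
      if (nrow(odf) != meta$n_fnirs)
        stop(sprintf("length mismatch in %s: %d rows, expected %d",
                     f, nrow(odf), meta$n_fnirs))
      od[, , w] <- as.matrix(odf[, -1, drop = FALSE])
    }
  }
  events <- jsonlite::read_json(need("events.json"))
  sched <- do.call(rbind, lapply(events, function(e) {
    data.frame(label = e$label, start_s = e$onset,
               end_s = e$onset + e$duration,
               target_rate = if (is.null(e$target_rate)) NA_real_ else e$target_rate,
               counted = if (is.null(e$counted)) NA_integer_ else as.integer(e$counted),
               confidence = if (is.null(e$confidence)) NA_integer_ else as.integer(e$confidence),
               stringsAsFactors = FALSE)
  }))
  class(sched) <- c("protocol_schedule", "data.frame")
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  rec <- list(ecg = ecg$ecg, breathing = br$breathing, fnirs_hbo = hbo,
              fnirs_od = od, fs_ecg = meta$fs_ecg, fs_fnirs = meta$fs_fnirs,
              schedule = sched, config = NULL, truth = truth)
  class(rec) <- "multimodal_recording"
  rec
}
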