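#' Read and write recordings as raw float32 + JSON sidecar
#'
#' Recordings are stored as headerless little-endian float32 samples
#' (`<stem>.f32`) with a JSON sidecar (`<stem>.json`) holding the sample rate
#' and channel count, a common interchange format for single-channel
#' electrophysiology traces.
#'
#' @param rec An `eod_recording`.
#' @param stem Path stem; `.f32` and `.json` extensions are appended.
#' @return `write_recording()` returns `stem` invisibly; `read_recording()`
#'   returns an `eod_recording`.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eod_recording"))
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(sample_rate = rec$sample_rate, channels = 1L,
         n_samples = length(rec$samples), dtype = "float32le"),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  con <- file(paste0(stem, ".f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = meta$n_samples, size = 4,
               endian = "little")
  new_eod_recording(x, meta$sample_rate)
}

#' Write / read an S2 schedule as JSON
#'
#' @param s2 An `s2_schedule`.
#' @param path Output JSON path.
#' @return `write_s2_schedule()` returns `path` invisibly;
#'   `read_s2_schedule()` returns an `s2_schedule` (without template).
#' @export
write_s2_schedule <- function(s2, path) {
  stopifnot(inherits(s2, "s2_schedule"))
  jsonlite::write_json(
    list(times = s2$times, period = s2$period, amplitude = s2$amplitude),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_s2_schedule
#' @export
read_s2_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(times = as.numeric(x$times), period = x$period,
                 amplitude = x$amplitude, template = NULL),
            class = "s2_schedule")
}

#' Write ground truth (pulses and events) to CSV/JSON
#'
#' Pulses go to `<stem>_pulses.csv` (columns `time_s`, `amplitude`,
#' `event_id`, where `event_id` marks membership in an injected event) and
#' the event table to `<stem>_events.json`.
#'
#' @param truth An `eod_truth`.
#' @param stem Path stem.
#' @return `stem`, invisibly.
#' @export
write_ground_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "eod_truth"))
  pulses <- truth$pulses
  pulses$event_id <- NA_integer_
  if (nrow(truth$events)) {
    for (i in seq_len(nrow(truth$events))) {
      inside <- pulses$time >= truth$events$start_time[i] &
        pulses$time <= truth$events$end_time[i]
      pulses$event_id[inside] <- truth$events$event_id[i]
    }
  }
  names(pulses)[names(pulses) == "time"] <- "time_s"
  utils::write.csv(pulses, paste0(stem, "_pulses.csv"), row.names = FALSE)
  jsonlite::write_json(truth$events, paste0(stem, "_events.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(stem)
}
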