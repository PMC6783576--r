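#' Trial analysis configuration
#'
#' Bundles the tunable parameters of every pipeline stage. `species_mode`
#' selects the chirp threshold: `"default"` uses 10% rIPI (suited to highly
#' regular dischargers such as *Microsternarchus* and *Steatogenys*);
#' `"brachy"` uses 25%, required by the larger gradual frequency shifts of
#' *Brachyhypopomus*.
#'
#' @param species_mode `"default"` or `"brachy"`.
#' @param detect_threshold Pulse-detection threshold (fraction of max |amp|).
#' @param refractory Pulse-detection refractory period, seconds.
#' @param chirp_threshold_pct rIPI chirp threshold, percent; derived from
#'   `species_mode` when `NULL`.
#' @param short_latency_cutoff Short-latency chirp cutoff, seconds.
#' @param burst_max_normal_gap Maximum normal intervals inside a burst episode.
#' @param rise_cv_threshold Block-CV threshold for rises, percent.
#' @param rise_threshold_pct Baseline-increase threshold for rises, percent.
#' @param rise_min_duration Minimum rise duration, seconds.
#' @param interruption_gap_factor Gap threshold (multiple of local median IPI).
#' @param jamming_window,jamming_overlap Jamming window length (s) and overlap.
#' @param jamming_reps Shuffles per permutation null.
#' @param baseline_window Baseline-statistics window, seconds.
#' @param seed Integer seed for all stochastic stages.
#' @return A `trial_config` list.
#' @export
trial_config <- function(species_mode = c("default", "brachy"),
                         detect_threshold = 0.3, refractory = 0.001,
                         chirp_threshold_pct = NULL,
                         short_latency_cutoff = 0.1,
                         burst_max_normal_gap = 2,
                         rise_cv_threshold = 5, rise_threshold_pct = 25,
                         rise_min_duration = 0.5,
                         interruption_gap_factor = 2.5,
                         jamming_window = 0.4, jamming_overlap = 0.5,
                         jamming_reps = 10000, baseline_window = 60,
                         seed = 1L) {
  species_mode <- match.arg(species_mode)
  chirp_threshold_pct <- chirp_threshold_pct %||%
    switch(species_mode, default = 10, brachy = 25)
  cfg <- list(species_mode = species_mode,
              detect_threshold = detect_threshold, refractory = refractory,
              chirp_threshold_pct = chirp_threshold_pct,
              short_latency_cutoff = short_latency_cutoff,
              burst_max_normal_gap = burst_max_normal_gap,
              rise_cv_threshold = rise_cv_threshold,
              rise_threshold_pct = rise_threshold_pct,
              rise_min_duration = rise_min_duration,
              interruption_gap_factor = interruption_gap_factor,
              jamming_window = jamming_window,
              jamming_overlap = jamming_overlap,
              jamming_reps = jamming_reps,
              baseline_window = baseline_window,
              seed = as.integer(seed))
  stopifnot(all(vapply(cfg[c("detect_threshold", "chirp_threshold_pct",
                             "rise_cv_threshold", "rise_threshold_pct",
                             "rise_min_duration", "interruption_gap_factor",
                             "jamming_window", "baseline_window")],
                       function(v) is.numeric(v) && v > 0, logical(1))))
  structure(cfg, class = "trial_config")
}

#' Analyze one playback trial end to end
#'
#' Runs the full pipeline: stimulus-artifact subtraction, pulse detection,
#' interval-series construction, chirp/burst detection, rise and interruption
#' detection, the sliding-window jamming profile, and circular statistics of
#' chirp start phases. Identical inputs and seed give an identical report.
#'
#' @param rec An `eod_recording` (or `NULL` when `train` is given directly).
#' @param s2 An [s2_schedule()] with its rendering template.
#' @param config A [trial_config()].
#' @param pretest Optional one-row [baseline_stats()] tibble from intertrial
#'   recording; computed from the trial's own intervals when omitted.
#' @param train Optional pulse-train tibble, bypassing detection (used when
#'   timings were logged directly by the acquisition system).
#' @return A `trial_report`: list with `baseline`, `pulses`, `intervals`,
#'   `chirps`, `bursts`, `rises`, `interruptions`, `jamming`,
#'   `jamming_spans`, `chirp_phase`, and `provenance` (config hash, seed,
#'   package version).
#' @examples
#' trial <- synth_trial(55, 10, dF = 3, seed = 7, render = FALSE,
#'   events = list(list(type = "chirp", onset_time = 5, ipi_reduction = 40)))
#' rep <- run_trial(NULL, trial$s2, trial_config(seed = 7),
#'                  train = trial$truth$pulses)
#' rep$chirps$n_eods
#' @export
run_trial <- function(rec, s2, config = trial_config(), pretest = NULL,
                      train = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (is.null(train)) {
    stopifnot(inherits(rec, "eod_recording"))
    clean <- remove_artifact(rec, s2)
    train <- detect_pulses(clean, threshold = config$detect_threshold,
                           refractory = config$refractory)
  } else {
    clean <- rec
  }
  empty <- nrow(train) < 2
  if (empty) {
    warning("fewer than 2 pulses detected; returning an empty report")
  }
  intervals <- if (!empty) compute_intervals(train) else NULL
  baseline <- if (!empty) {
    tryCatch(baseline_stats(intervals, window = config$baseline_window),
             error = function(e) NULL)
  }
  pretest <- pretest %||% baseline
  chirps <- if (!empty) {
    detect_chirps(intervals, threshold_pct = config$chirp_threshold_pct,
                  s2 = s2, short_latency_cutoff = config$short_latency_cutoff)
  } else chirp_table_prototype()
  bursts <- if (!empty) {
    detect_burst_episodes(intervals,
                          threshold_pct = config$chirp_threshold_pct,
                          max_normal_gap = config$burst_max_normal_gap)
  }
  rises <- if (!empty && !is.null(pretest)) {
    detect_rises(intervals, pretest,
                 cv_threshold = config$rise_cv_threshold,
                 rise_threshold_pct = config$rise_threshold_pct,
                 min_duration = config$rise_min_duration)
  }
  interruptions <- if (!empty) {
    detect_interruptions(train, rec = clean,
                         gap_factor = config$interruption_gap_factor)
  }
  jamming <- if (!empty) {
    jamming_profile(train, s2, window = config$jamming_window,
                    overlap = config$jamming_overlap,
                    reps = config$jamming_reps, seed = config$seed)
  }
  chirp_phase <- if (nrow(chirps) >= 1) {
    tryCatch(chirp_phase_stats(chirps), error = function(e) NULL)
  }
  structure(
    list(baseline = baseline, pulses = train, intervals = intervals,
         chirps = chirps, bursts = bursts, rises = rises,
         interruptions = interruptions, jamming = jamming,
         jamming_spans = if (!is.null(jamming)) summarize_jamming(jamming),
         chirp_phase = chirp_phase,
         provenance = list(
           config = unclass(config),
           config_hash = rlang::hash(unclass(config)),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("chirpjar")))),
    class = "trial_report"
  )
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report>\n")
  if (!is.null(x$baseline)) {
    cat(sprintf("  baseline: %.2f Hz (rIPI SD %.3f%%)\n",
                x$baseline$mean_freq, x$baseline$ripi_sd))
  }
  cat(sprintf("  %d pulses | %d chirps | %d burst episodes | %d rises | %d interruptions\n",
              nrow(x$pulses), nrow(x$chirps),
              if (is.null(x$bursts)) 0L else nrow(x$bursts),
              if (is.null(x$rises)) 0L else nrow(x$rises),
              if (is.null(x$interruptions)) 0L else nrow(x$interruptions)))
  if (!is.null(x$jamming)) {
    cat(sprintf("  jamming: %d/%d windows significant\n",
                sum(x$jamming$significant), nrow(x$jamming)))
  }
  invisible(x)
}

#' Tidy a trial report into its chirp event table
#'
#' @param x A `trial_report`.
#' @param table Which table to extract: `"chirps"`, `"bursts"`, `"rises"`,
#'   `"interruptions"`, `"jamming"`, `"intervals"`, `"pulses"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @exportS3Method generics::tidy
tidy.trial_report <- function(x, table = "chirps", ...) {
  tab <- x[[table]]
  if (is.null(tab)) return(tibble::tibble())
  tibble::as_tibble(tab)
}

#' One-row summary of a trial report
#'
#' @param x A `trial_report`.
#' @param ... Unused.
#' @return A one-row tibble with event counts, baseline frequency, chirp
#'   rate, and the fraction of significant jamming windows.
#' @exportS3Method generics::glance
glance.trial_report <- function(x, ...) {
  dur <- if (!is.null(x$intervals)) max(x$intervals$t_end) else NA_real_
  tibble::tibble(
    n_pulses = nrow(x$pulses),
    mean_freq = if (!is.null(x$baseline)) x$baseline$mean_freq else NA_real_,
    n_chirps = nrow(x$chirps),
    chirps_per_second = nrow(x$chirps) / dur,
    n_bursts = if (is.null(x$bursts)) 0L else nrow(x$bursts),
    n_rises = if (is.null(x$rises)) 0L else nrow(x$rises),
    n_interruptions = if (is.null(x$interruptions)) 0L
      else nrow(x$interruptions),
    prop_jamming_significant = if (is.null(x$jamming)) NA_real_
      else mean(x$jamming$significant),
    config_hash = x$provenance$config_hash
  )
}

#' Analyze a batch of trials and aggregate per subject
#'
#' Runs [run_trial()] over a list of trials and aggregates: per-trial event
#' counts, per-subject chirp counts/rates and pooled circular statistics of
#' chirp phases. Failing trials are skipped with their error logged in the
#' `skipped` element.
#'
#' @param trials A list; each element a list with `rec` (or `train`), `s2`,
#'   optionally `subject` and `config`.
#' @param config Default [trial_config()] for trials without their own.
#' @return A list: `per_trial` (tibble of glances plus `subject`/`trial`),
#'   `per_subject` (tibble with chirp totals, means and pooled circular
#'   stats), `reports` (list of `trial_report`s), `skipped`.
#' @export
run_batch <- function(trials, config = trial_config()) {
  reports <- list()
  skipped <- list()
  rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    res <- tryCatch(
      run_trial(tr$rec %||% NULL, tr$s2, tr$config %||% config,
                train = tr$train %||% NULL),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1]] <-
        list(trial = i, reason = conditionMessage(res))
      next
    }
    reports[[length(reports) + 1]] <- res
    g <- glance(res)
    g$trial <- i
    g$subject <- tr$subject %||% "subject1"
    rows[[length(rows) + 1]] <- g
  }
  per_trial <- dplyr::bind_rows(rows)
  per_subject <- NULL
  if (nrow(per_trial)) {
    per_subject <- per_trial |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(n_trials = dplyr::n(),
                       total_chirps = sum(.data$n_chirps),
                       mean_chirps_per_trial = mean(.data$n_chirps),
                       n_rises = sum(.data$n_rises),
                       n_interruptions = sum(.data$n_interruptions),
                       .groups = "drop")
    pooled <- purrr::map_dfr(unique(per_trial$subject), function(sub) {
      idx <- which(per_trial$subject == sub)
      ang <- purrr::map(reports[idx], ~ .x$chirps$start_phase)
      ang <- unlist(ang)
      ang <- ang[!is.na(ang)]
      if (!length(ang)) {
        return(tibble::tibble(subject = sub, mean_angle = NA_real_,
                              resultant_r = NA_real_, rayleigh_p = NA_real_,
                              n = 0L))
      }
      cs <- circular_summary(ang)
      tibble::tibble(subject = sub, mean_angle = cs$mean_angle,
                     resultant_r = cs$resultant_r,
                     rayleigh_p = cs$rayleigh_p, n = cs$n)
    })
    per_subject <- dplyr::left_join(per_subject, pooled, by = "subject")
  }
  list(per_trial = per_trial, per_subject = per_subject,
       reports = reports, skipped = skipped)
}

#' Write a trial report to disk as CSV + JSON
#'
#' Event tables go to `<stem>_<table>.csv`; baseline, circular summaries and
#' provenance to `<stem>_report.json`.
#'
#' @param report A `trial_report`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_trial_report <- function(report, stem) {
  stopifnot(inherits(report, "trial_report"))
  for (tab in c("pulses", "intervals", "chirps", "bursts", "rises",
                "interruptions", "jamming")) {
    if (!is.null(report[[tab]])) {
      utils::write.csv(report[[tab]], paste0(stem, "_", tab, ".csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(baseline = report$baseline,
         chirp_phase = if (!is.null(report$chirp_phase))
           report$chirp_phase["pooled"],
         provenance = report$provenance),
    paste0(stem, "_report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(stem)
}
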