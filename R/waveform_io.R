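# Waveform / annotation / cohort containers and their plain-text readers
# and writers. Formats are deliberately diffable text: waveforms are
# `time_s,ppg_au` CSV, annotations key:value text, cohort metadata one CSV.

#' Construct a uniformly sampled PPG waveform recording
#'
#' @param samples Numeric vector of PPG samples (AU); all finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param t0 Time of the first sample (s).
#' @return An object of class `waveform_recording`.
#' @export
waveform_recording <- function(samples, sampling_rate, t0 = 0) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop_format("waveform samples must be finite numerics")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_format("sampling_rate must be positive")
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate, t0 = t0),
            class = "waveform_recording")
}

#' Sample times of a recording
#' @param rec A `waveform_recording`.
#' @return Numeric vector of sample times (s).
#' @export
waveform_times <- function(rec) {
  rec$t0 + (seq_along(rec$samples) - 1) / rec$sampling_rate
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf("waveform_recording: %d samples @ %g Hz (%.1f s from t0 = %g)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$t0))
  invisible(x)
}

#' Construct a Valsalva maneuver annotation
#'
#' Windows are half-open intervals `[start, end)` in seconds from the
#' recording origin, ordered rest < strain < recovery and disjoint.
#'
#' @param rest_window,strain_window,recovery_window Numeric `c(start, end)`.
#' @param target_mouth_pressure Target oral pressure during strain (mmHg).
#' @return An object of class `maneuver_annotation`.
#' @export
maneuver_annotation <- function(rest_window, strain_window, recovery_window,
                                target_mouth_pressure = 25) {
  w <- list(rest = rest_window, strain = strain_window,
            recovery = recovery_window)
  for (nm in names(w)) {
    v <- w[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || v[2] <= v[1]) {
      stop_format(sprintf("%s_window must be a finite interval [start, end)",
                          nm))
    }
  }
  if (w$rest[2] > w$strain[1] || w$strain[2] > w$recovery[1]) {
    stop_format("annotation windows must be disjoint and ordered rest < strain < recovery")
  }
  structure(list(rest_window = as.numeric(rest_window),
                 strain_window = as.numeric(strain_window),
                 recovery_window = as.numeric(recovery_window),
                 target_mouth_pressure = target_mouth_pressure),
            class = "maneuver_annotation")
}

#' Write / read a waveform as `time_s,ppg_au` delimited text
#'
#' Samples are written with 6 significant digits, times with microsecond
#' resolution; reading validates the header, finiteness of every sample
#' (naming the first offending row), and uniform time spacing to within
#' 1e-6 s, and infers the sampling rate from the spacing.
#'
#' @param rec A `waveform_recording`.
#' @param path File path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns a `waveform_recording`.
#' @export
write_waveform <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_recording"))
  tt <- waveform_times(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,ppg_au", con)
  writeLines(paste(sprintf("%.6f", tt),
                   formatC(signif(rec$samples, 6), format = "g", digits = 6),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("waveform file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("time_s", "ppg_au"))) {
    stop_format(sprintf("waveform file %s: header must be 'time_s,ppg_au'",
                        basename(path)))
  }
  bad <- which(!is.finite(df$ppg_au))
  if (length(bad)) {
    stop_format(sprintf("waveform file %s: non-finite sample at row %d",
                        basename(path), bad[1]))
  }
  if (nrow(df) < 2) stop_format("waveform file must contain at least 2 samples")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stop_format(sprintf("waveform file %s: non-monotone time at row %d",
                        basename(path), which(dt <= 0)[1] + 1))
  }
  if (max(abs(dt - stats::median(dt))) > 1e-6) {
    stop_format(sprintf("waveform file %s: non-uniform sampling at row %d",
                        basename(path),
                        which.max(abs(dt - stats::median(dt))) + 1))
  }
  waveform_recording(df$ppg_au, sampling_rate = 1 / stats::median(dt),
                     t0 = df$time_s[1])
}

#' Write / read a maneuver annotation as key:value text
#'
#' @param ann A `maneuver_annotation`.
#' @param path File path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a `maneuver_annotation`.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "maneuver_annotation"))
  rec <- list(
    rest_start = ann$rest_window[1], rest_end = ann$rest_window[2],
    strain_start = ann$strain_window[1], strain_end = ann$strain_window[2],
    recovery_start = ann$recovery_window[1],
    recovery_end = ann$recovery_window[2],
    target_mouth_pressure = ann$target_mouth_pressure
  )
  writeLines(paste0(names(rec), ": ", vapply(rec, format, "", digits = 12)),
             path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("annotation file not found: %s", path))
  }
  kv <- yaml::read_yaml(path)
  need <- c("rest_start", "rest_end", "strain_start", "strain_end",
            "recovery_start", "recovery_end", "target_mouth_pressure")
  if (!all(need %in% names(kv))) {
    stop_format(sprintf("annotation file %s: missing keys: %s",
                        basename(path),
                        paste(setdiff(need, names(kv)), collapse = ", ")))
  }
  maneuver_annotation(
    rest_window = c(kv$rest_start, kv$rest_end),
    strain_window = c(kv$strain_start, kv$strain_end),
    recovery_window = c(kv$recovery_start, kv$recovery_end),
    target_mouth_pressure = kv$target_mouth_pressure
  )
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Produces `cohort.csv` (subject metadata), one waveform CSV and one
#' annotation file per trial (`<subject>_trial<k>.csv` / `.ann`), and
#' `provenance.json` holding the generating seed and full configuration.
#'
#' @param cohort A `ppg_cohort` from [simulate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    age = vapply(cohort, `[[`, 0, "age"),
    bnp = vapply(cohort, `[[`, 0, "bnp"),
    filling_pressure = vapply(cohort, `[[`, 0, "filling_pressure"),
    overload_15 = vapply(cohort, `[[`, NA, "overload_15"),
    overload_10 = vapply(cohort, `[[`, NA, "overload_10")
  )
  paths <- file.path(dir, "cohort.csv")
  utils::write.csv(format(meta, digits = 12, scientific = FALSE,
                          trim = TRUE),
                   paths, row.names = FALSE, quote = FALSE)
  for (s in cohort) {
    for (j in seq_along(s$trials)) {
      wf <- file.path(dir, sprintf("%s_trial%d.csv", s$subject_id, j))
      an <- file.path(dir, sprintf("%s_trial%d.ann", s$subject_id, j))
      write_waveform(s$trials[[j]]$recording, wf)
      write_annotation(s$trials[[j]]$annotation, an)
      paths <- c(paths, wf, an)
    }
  }
  cfg <- attr(cohort, "config")
  prov <- list(seed = if (!is.null(cfg)) cfg$seed else NA,
               config = if (!is.null(cfg)) unclass(cfg) else NULL)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, file.path(dir, "provenance.json")))
}

#' Read a cohort directory back into a `ppg_cohort`
#'
#' Validates subject-id uniqueness, resolves every trial file (a missing
#' file is a linkage error naming subject and trial), and recomputes the
#' overload flags from the stored filling pressure, raising on mismatch.
#'
#' @param dir Directory written by [write_cohort()].
#' @param n_trials Trials expected per subject; inferred from the files of
#'   the first subject when `NULL`.
#' @return A `ppg_cohort`.
#' @export
read_cohort <- function(dir, n_trials = NULL) {
  meta_path <- file.path(dir, "cohort.csv")
  if (!file.exists(meta_path)) {
    stop_format(sprintf("cohort metadata not found: %s", meta_path))
  }
  meta <- utils::read.csv(meta_path)
  if (anyDuplicated(meta$subject_id)) {
    stop_format("duplicate subject_id in cohort.csv")
  }
  if (is.null(n_trials)) {
    n_trials <- length(list.files(
      dir, pattern = sprintf("^%s_trial[0-9]+\\.csv$", meta$subject_id[1])))
    if (n_trials < 1) {
      stop_format(sprintf("no trial files found for subject %s",
                          meta$subject_id[1]))
    }
  }
  cohort <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject_id[i]
    p <- meta$filling_pressure[i]
    for (flag in c(15, 10)) {
      stored <- meta[[sprintf("overload_%d", flag)]][i]
      if (!identical(as.logical(stored), p > flag)) {
        stop_format(sprintf(
          "subject %s: stored overload_%d flag inconsistent with filling pressure %.2f",
          sid, flag, p))
      }
    }
    trials <- vector("list", n_trials)
    for (j in seq_len(n_trials)) {
      wf <- file.path(dir, sprintf("%s_trial%d.csv", sid, j))
      an <- file.path(dir, sprintf("%s_trial%d.ann", sid, j))
      if (!file.exists(wf) || !file.exists(an)) {
        stop_format(sprintf("subject %s trial %d: missing trial file", sid, j))
      }
      trials[[j]] <- list(recording = read_waveform(wf),
                          annotation = read_annotation(an))
    }
    cohort[[i]] <- list(subject_id = sid, age = meta$age[i],
                        bnp = meta$bnp[i], filling_pressure = p,
                        overload_15 = p > 15, overload_10 = p > 10,
                        trials = trials)
  }
  prov_path <- file.path(dir, "provenance.json")
  cfg <- NULL
  if (file.exists(prov_path)) {
    prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
    if (!is.null(prov$config)) {
      cfg <- structure(prov$config, class = "sim_config")
    }
  }
  structure(cohort, class = "ppg_cohort", config = cfg)
}
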