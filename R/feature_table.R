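# Subject-level feature aggregation and candidate-pool expansion: ten base
# features (six window aggregates, three end-Valsalva/end-rest ratios, age),
# their squares, and all pairwise interactions.

# the nine waveform bases, subject-level
WAVEFORM_BASES <- c("amp_rest", "amp_vals", "sd_rest", "sd_vals",
                    "width_rest", "width_vals",
                    "ratio_rms", "ratio_auc", "ratio_amplitude")

#' Average trial features across a subject's valid trials
#'
#' Arithmetic mean of each subject-level feature across trials. Trials that
#' failed extraction are simply not passed in; zero valid trials is an
#' error, so callers can drop (and log) the subject.
#'
#' @param trials A list of [trial_features()] objects (the subject's valid
#'   trials).
#' @return A named numeric vector over `amp_rest`, `amp_vals`, `sd_rest`,
#'   `sd_vals`, `width_rest`, `width_vals`, `ratio_rms`, `ratio_auc`,
#'   `ratio_amplitude`.
#' @export
aggregate_trials <- function(trials) {
  trials <- Filter(Negate(is.null), trials)
  if (length(trials) < 1) {
    stop_usage("no valid trials to aggregate for this subject")
  }
  rows <- vapply(trials, function(tf) {
    stopifnot(inherits(tf, "trial_features"))
    c(amp_rest = tf$end_rest$mean_amplitude,
      amp_vals = tf$end_valsalva$mean_amplitude,
      sd_rest = tf$end_rest$sd_amplitude,
      sd_vals = tf$end_valsalva$sd_amplitude,
      width_rest = tf$end_rest$mean_width,
      width_vals = tf$end_valsalva$mean_width,
      ratio_rms = tf$ratio_rms,
      ratio_auc = tf$ratio_auc,
      ratio_amplitude = tf$ratio_amplitude)
  }, numeric(length(WAVEFORM_BASES)))
  rowMeans(rows)
}

#' Extract the subject-level feature table from a cohort
#'
#' Runs [trial_features()] on every trial of every subject, averages each
#' subject's valid trials with [aggregate_trials()], and returns one row
#' per subject together with age, BNP, filling pressure and overload
#' labels. Trials whose extraction fails are skipped with a message;
#' subjects with no valid trial are dropped with a message.
#'
#' @param cohort A `ppg_cohort`.
#' @param window_len Analysis window length (s) passed to
#'   [trial_features()].
#' @return A data.frame with columns `subject_id`, `age`, `bnp`,
#'   `filling_pressure`, `overload_15`, `overload_10` and the nine
#'   waveform base features.
#' @export
cohort_features <- function(cohort, window_len = 5) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- lapply(cohort, function(s) {
    tfs <- lapply(seq_along(s$trials), function(j) {
      tryCatch(
        suppressMessages(trial_features(s$trials[[j]]$recording,
                                        s$trials[[j]]$annotation,
                                        window_len = window_len)),
        error = function(e) {
          message(sprintf("subject %s trial %d dropped: %s",
                          s$subject_id, j, conditionMessage(e)))
          NULL
        })
    })
    tfs <- Filter(Negate(is.null), tfs)
    if (length(tfs) == 0) {
      message(sprintf("subject %s dropped: no valid trials", s$subject_id))
      return(NULL)
    }
    feats <- aggregate_trials(tfs)
    cbind(data.frame(subject_id = s$subject_id, age = s$age, bnp = s$bnp,
                     filling_pressure = s$filling_pressure,
                     overload_15 = s$overload_15,
                     overload_10 = s$overload_10),
          as.data.frame(as.list(feats)))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

canonical_ix <- function(a, b) {
  p <- sort(c(a, b))
  sprintf("ix(%s,%s)", p[1], p[2])
}

#' Expand subject features into the candidate pool for forward selection
#'
#' Bases are the nine waveform features plus age (10); the pool adds every
#' square `sq(x)` and every pairwise product `ix(x,y)` (interaction names
#' are canonicalized with their arguments in lexicographic order), giving
#' `b + b + b(b-1)/2 = 65` columns in deterministic order: bases, squares,
#' interactions, each lexicographic.
#'
#' @param features A data.frame from [cohort_features()] (or with the same
#'   columns).
#' @return An object of class `feature_matrix`: a list with `x` (numeric
#'   matrix subjects x features), `feature_names`, `subject_ids`, `target`
#'   (filling pressure, mmHg), `labels_15`, `labels_10`, `bnp`, `age`.
#' @export
build_candidate_pool <- function(features) {
  need <- c("subject_id", "age", "filling_pressure", WAVEFORM_BASES)
  if (!all(need %in% names(features))) {
    stop_usage(sprintf("features table missing columns: %s",
                       paste(setdiff(need, names(features)), collapse = ", ")))
  }
  bases <- sort(c(WAVEFORM_BASES, "age"))
  base_m <- as.matrix(features[, bases])
  if (any(!is.finite(base_m))) {
    stop_usage("non-finite values in base features; drop failed subjects first")
  }
  sq <- base_m^2
  colnames(sq) <- sprintf("sq(%s)", bases)
  pairs <- utils::combn(bases, 2)
  ix <- apply(pairs, 2, function(p) base_m[, p[1]] * base_m[, p[2]])
  if (is.null(dim(ix))) ix <- matrix(ix, nrow = 1)
  colnames(ix) <- apply(pairs, 2, function(p) sprintf("ix(%s,%s)", p[1], p[2]))
  x <- cbind(base_m, sq[, sort(colnames(sq)), drop = FALSE],
             ix[, sort(colnames(ix)), drop = FALSE])
  stopifnot(!anyDuplicated(colnames(x)))
  structure(list(
    x = x,
    feature_names = colnames(x),
    subject_ids = features$subject_id,
    target = features$filling_pressure,
    labels_15 = if ("overload_15" %in% names(features)) {
      features$overload_15
    } else features$filling_pressure > 15,
    labels_10 = if ("overload_10" %in% names(features)) {
      features$overload_10
    } else features$filling_pressure > 10,
    bnp = features$bnp,
    age = features$age
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

# the fixed three-feature constructions of the final models, per analysis
# case; interactions are looked up under their canonical names
FINAL_FEATURE_SETS <- list(
  regression = list(c("ratio_rms", "ratio_auc"),
                    c("sd_rest", "age"),
                    c("amp_vals", "ratio_auc")),
  classify_15 = list(c("width_rest", "ratio_auc"),
                     c("amp_vals", "sd_vals"),
                     c("sd_vals", "age")),
  classify_10 = list(c("amp_rest", "width_rest"),
                     c("amp_vals", "age"),
                     "age")
)

#' Restrict the candidate pool to a final model's fixed three features
#'
#' Returns the pre-specified three-feature set for each analysis case:
#' for the regression of filling pressure, the interactions
#' `ratio_rms x ratio_auc`, `sd_rest x age` and `amp_vals x ratio_auc`;
#' for classification at the 15 mmHg cutoff, `width_rest x ratio_auc`,
#' `amp_vals x sd_vals` and `sd_vals x age`; for the 10 mmHg sensitivity
#' cutoff, `amp_rest x width_rest`, `amp_vals x age` and bare `age`.
#'
#' @param fm A `feature_matrix` from [build_candidate_pool()].
#' @param case One of `"regression"`, `"classify_15"`, `"classify_10"`.
#' @return A `feature_matrix` with exactly 3 columns in the stated order.
#' @export
final_model_features <- function(fm, case = c("regression", "classify_15",
                                              "classify_10")) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(case) != 1 || !case %in% names(FINAL_FEATURE_SETS)) {
    stop_usage("case must be one of 'regression', 'classify_15', 'classify_10'")
  }
  cols <- vapply(FINAL_FEATURE_SETS[[case]], function(def) {
    if (length(def) == 1) def else canonical_ix(def[1], def[2])
  }, "")
  missing <- setdiff(cols, fm$feature_names)
  if (length(missing)) {
    stop_usage(sprintf("pool is missing feature(s): %s",
                       paste(missing, collapse = ", ")))
  }
  out <- fm
  out$x <- fm$x[, cols, drop = FALSE]
  out$feature_names <- cols
  out
}
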