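# Beat detection and per-beat / per-window / per-trial PPG features:
# amplitude (peak minus foot), width at half height, area under the curve,
# amplitude SD, and window RMS power, plus end-strain / end-rest ratios.

#' Detect beats in a PPG recording
#'
#' The recording is detrended with a centered 1.5 s moving average and
#' lightly smoothed; candidate peaks are local maxima with a refractory
#' spacing of at least 0.33 s (<= 180 beats/min), kept when they exceed an
#' adaptive threshold of 25% of the 99.5th percentile of the detrended
#' signal (scale-invariant, so scaling a recording leaves the detected
#' indices unchanged). Peak indices are then refined to the local maximum
#' of the raw signal within +/- 0.1 s, and beat feet are the raw-signal
#' minima between consecutive peaks. A beat is (foot, peak, next foot);
#' the first and last detected peaks, which lack a flanking foot, do not
#' form beats.
#'
#' @param rec A `waveform_recording` of at least 3 s.
#' @return A data.frame with one row per beat: `foot_index`, `peak_index`,
#'   `next_foot_index` (1-based sample indices) and `peak_time` (s).
#' @export
detect_beats <- function(rec) {
  stopifnot(inherits(rec, "waveform_recording"))
  fs <- rec$sampling_rate
  x <- rec$samples
  n <- length(x)
  if (n < 3 * fs) stop_detection("recording shorter than 3 s")

  ds <- x - rolling_mean(x, max(3, odd(round(1.5 * fs))))
  sm <- rolling_mean(ds, max(3, odd(round(0.05 * fs))))

  pk <- pracma::findpeaks(sm, minpeakdistance = max(2, round(0.33 * fs)))
  if (is.null(pk) || nrow(pk) < 3) {
    stop_detection("fewer than 3 candidate peaks detected")
  }
  thr <- 0.25 * stats::quantile(sm, 0.995, names = FALSE)
  idx <- sort(pk[pk[, 1] >= thr, 2])
  if (length(idx) < 3) stop_detection("fewer than 3 beats exceed threshold")

  # refine each peak to the raw-signal local maximum within +/- 0.1 s
  half <- as.integer(max(1, round(0.1 * fs)))
  idx <- vapply(as.integer(idx), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  idx <- unique(idx)
  m <- length(idx)
  if (m < 3) stop_detection("fewer than 2 beats detected")

  # feet: raw-signal minima between consecutive peaks
  feet <- vapply(seq_len(m - 1), function(i) {
    lo <- as.integer(idx[i]); hi <- as.integer(idx[i + 1])
    lo + which.min(x[lo:hi]) - 1L
  }, integer(1))

  beats <- data.frame(
    foot_index = feet[seq_len(m - 2)],
    peak_index = idx[2:(m - 1)],
    next_foot_index = feet[2:(m - 1)]
  )
  beats$peak_time <- rec$t0 + (beats$peak_index - 1) / fs
  if (nrow(beats) < 2) stop_detection("fewer than 2 beats detected")
  beats
}

odd <- function(k) if (k %% 2 == 0) k + 1 else k

# centered moving average with edge values carried outward
rolling_mean <- function(x, w) {
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y <- as.numeric(y)
  nas <- is.na(y)
  if (any(nas)) {
    first <- which(!nas)[1]
    last <- rev(which(!nas))[1]
    y[seq_len(first - 1)] <- y[first]
    y[seq(last + 1, length.out = length(y) - last)] <- y[last]
  }
  y
}

#' Per-beat metrics: amplitude, half-height width, area under the curve
#'
#' Amplitude is `sample[peak] - sample[foot]`; width is the time between
#' the up- and down-crossings of the half-amplitude level above the foot,
#' linearly interpolated between samples; AUC is the trapezoidal integral
#' of the foot-level-subtracted signal over `[foot, next_foot)`.
#'
#' @param rec A `waveform_recording`.
#' @param beats A beat data.frame from [detect_beats()] (or a single-row
#'   subset).
#' @return The beat data.frame with added columns `amplitude` (AU),
#'   `width` (s), `auc` (AU s). Beats whose half-height level is never
#'   crossed get `width = NA` (they are dropped, with a message, by the
#'   window aggregators).
#' @export
beat_metrics <- function(rec, beats) {
  stopifnot(inherits(rec, "waveform_recording"))
  x <- rec$samples
  fs <- rec$sampling_rate
  nb <- nrow(beats)
  amp <- width <- auc <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    ft <- beats$foot_index[b]; pk <- beats$peak_index[b]
    nf <- beats$next_foot_index[b]
    if (!(ft < pk && pk < nf)) stop_usage("invalid beat indices")
    a <- x[pk] - x[ft]
    if (a <= 0) next
    amp[b] <- a
    level <- x[ft] + a / 2

    seg_l <- x[ft:pk]
    below_l <- which(seg_l < level)
    seg_r <- x[pk:nf]
    below_r <- which(seg_r < level)
    if (length(below_l) && length(below_r)) {
      jl <- max(below_l)                       # last below-level before peak
      tl <- (ft + jl - 1) + (level - seg_l[jl]) / (seg_l[jl + 1] - seg_l[jl])
      jr <- min(below_r)                       # first below-level after peak
      tr <- (pk + jr - 2) + (level - seg_r[jr - 1]) / (seg_r[jr] - seg_r[jr - 1])
      width[b] <- (tr - tl) / fs
    }
    y <- x[ft:nf] - x[ft]
    auc[b] <- pracma::trapz(seq_along(y) / fs, y)
  }
  beats$amplitude <- amp
  beats$width <- width
  beats$auc <- auc
  beats
}

#' Aggregate beat metrics over a time window
#'
#' Uses beats whose peak time lies in the half-open window `[start, end)`.
#' Amplitude mean/SD use the n-1 sample SD; `rms_power` is the
#' root-mean-square of the mean-subtracted raw samples within the window.
#' Beats with missing metrics (dropped widths) are excluded with a message.
#'
#' @param rec A `waveform_recording`.
#' @param beats Output of [beat_metrics()].
#' @param window Numeric `c(start, end)` in seconds (recording time).
#' @param window_id Label, e.g. `"end_rest"` or `"end_valsalva"`.
#' @return A list of class `window_features`: `window_id`,
#'   `mean_amplitude`, `sd_amplitude`, `mean_width`, `mean_auc`,
#'   `rms_power`, `n_beats`.
#' @export
window_features <- function(rec, beats, window, window_id = "window") {
  stopifnot(inherits(rec, "waveform_recording"))
  sel <- beats$peak_time >= window[1] & beats$peak_time < window[2]
  w <- beats[sel, , drop = FALSE]
  dropped <- !stats::complete.cases(w[, c("amplitude", "width", "auc")])
  if (any(dropped)) {
    message(sprintf("window %s: dropping %d beat(s) with failed metrics",
                    window_id, sum(dropped)))
    w <- w[!dropped, , drop = FALSE]
  }
  if (nrow(w) < 2) {
    stop_windowing(sprintf("window %s [%g, %g): fewer than 2 usable beats",
                           window_id, window[1], window[2]))
  }
  tt <- waveform_times(rec)
  in_w <- tt >= window[1] & tt < window[2]
  xs <- rec$samples[in_w]
  structure(list(
    window_id = window_id,
    mean_amplitude = mean(w$amplitude),
    sd_amplitude = stats::sd(w$amplitude),
    mean_width = mean(w$width),
    mean_auc = mean(w$auc),
    rms_power = sqrt(mean((xs - mean(xs))^2)),
    n_beats = nrow(w)
  ), class = "window_features")
}

#' Per-trial features: end-rest and end-strain windows plus their ratios
#'
#' Detects beats, computes per-beat metrics, aggregates them over the last
#' `window_len` seconds of the rest window (`end_rest`) and of the strain
#' window (`end_valsalva`), and forms the end-Valsalva / end-rest ratios of
#' RMS power, mean AUC and mean amplitude. With this orientation a normal
#' physiologic response gives ratios below 1 and a blunted (volume
#' overloaded) response ratios near 1.
#'
#' @param rec A `waveform_recording`.
#' @param ann A `maneuver_annotation` whose windows lie inside the
#'   recording.
#' @param window_len Analysis window length (s); must not exceed the rest
#'   or strain window length. Default 5 s, targeting the end-strain phase
#'   where the amplitude response is maximal.
#' @return A list of class `trial_features`: `end_rest` and `end_valsalva`
#'   ([window_features()] objects) and `ratio_rms`, `ratio_auc`,
#'   `ratio_amplitude`.
#' @export
trial_features <- function(rec, ann, window_len = 5) {
  stopifnot(inherits(rec, "waveform_recording"),
            inherits(ann, "maneuver_annotation"))
  t_end <- rec$t0 + length(rec$samples) / rec$sampling_rate
  if (ann$rest_window[1] < rec$t0 || ann$recovery_window[2] > t_end + 1e-9) {
    stop_windowing("annotation windows extend beyond the recording")
  }
  if (window_len > diff(ann$rest_window) ||
      window_len > diff(ann$strain_window)) {
    stop_windowing("window_len exceeds the rest or strain window length")
  }
  beats <- beat_metrics(rec, detect_beats(rec))
  w_rest <- c(ann$rest_window[2] - window_len, ann$rest_window[2])
  w_vals <- c(ann$strain_window[2] - window_len, ann$strain_window[2])
  er <- window_features(rec, beats, w_rest, "end_rest")
  ev <- window_features(rec, beats, w_vals, "end_valsalva")
  structure(list(
    end_rest = er,
    end_valsalva = ev,
    ratio_rms = ev$rms_power / er$rms_power,
    ratio_auc = ev$mean_auc / er$mean_auc,
    ratio_amplitude = ev$mean_amplitude / er$mean_amplitude
  ), class = "trial_features")
}
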