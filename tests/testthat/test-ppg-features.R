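# Beat detection and feature extraction: ground-truth recovery, closed-form
# beat geometry, dense-grid oracles, scale/shift invariances.

test_that("detector recovers zero-noise beats with accurate peak times", {
  tr <- zero_noise_trial(pressure = 12, heart_rate = 60)
  beats <- detect_beats(tr$recording)
  in_rest <- beats$peak_time < 30
  expect_lte(abs(sum(in_rest) - 30), 1)
  err <- vapply(beats$peak_time,
                function(t) min(abs(t - tr$truth$peak_times)), numeric(1))
  expect_lt(max(err), 0.020)
})

test_that("detector recall and precision are at least 95% across 50-110 bpm", {
  for (hr in c(50, 70, 90, 110)) {
    tr <- zero_noise_trial(pressure = 14, heart_rate = hr, seed = hr)
    beats <- detect_beats(tr$recording)
    truth <- tr$truth$peak_times
    # interior ground-truth peaks (first/last beats form no (foot, peak, foot))
    truth <- truth[truth > min(beats$peak_time) - 0.3 &
                     truth < max(beats$peak_time) + 0.3]
    matched_det <- vapply(beats$peak_time,
                          function(t) min(abs(t - truth)) < 0.1, logical(1))
    matched_tru <- vapply(truth,
                          function(t) min(abs(t - beats$peak_time)) < 0.1,
                          logical(1))
    expect_gte(mean(matched_det), 0.95)  # precision
    expect_gte(mean(matched_tru), 0.95)  # recall
  }
})

test_that("constant and too-short signals are detection errors", {
  flat <- waveform_recording(rep(1, 1000), 100)
  expect_error(detect_beats(flat), class = "ppgv_detection_error")
  short <- waveform_recording(sin(1:100), 100)
  expect_error(detect_beats(short), class = "ppgv_detection_error")
})

test_that("amplitude scaling leaves detected beat indices unchanged", {
  tr <- zero_noise_trial(pressure = 10, heart_rate = 72)
  b1 <- detect_beats(tr$recording)
  scaled <- tr$recording
  scaled$samples <- scaled$samples * 10
  b2 <- detect_beats(scaled)
  expect_identical(b1$peak_index, b2$peak_index)
  expect_identical(b1$foot_index, b2$foot_index)
})

test_that("triangle pulse gives closed-form amplitude, width and AUC", {
  # isosceles triangle: base 1 s, height 2 AU, on a zero baseline @ 100 Hz
  fs <- 100
  up <- seq(0, 2, length.out = 51)
  down <- seq(2, 0, length.out = 51)[-1]
  x <- c(0, up, down, 0)
  rec <- waveform_recording(x, fs)
  beats <- data.frame(foot_index = 2L, peak_index = 52L,
                      next_foot_index = 102L,
                      peak_time = 51 / fs)
  m <- beat_metrics(rec, beats)
  expect_equal(m$amplitude, 2)
  expect_equal(m$width, 0.5)
  expect_equal(m$auc, 1.0)
})

test_that("beat metrics are homogeneous in amplitude, width invariant", {
  tr <- zero_noise_trial(pressure = 12, heart_rate = 66)
  beats <- detect_beats(tr$recording)
  m1 <- beat_metrics(tr$recording, beats)
  scaled <- tr$recording
  scaled$samples <- scaled$samples * 3.7
  m2 <- beat_metrics(scaled, beats)
  expect_equal(m2$amplitude, 3.7 * m1$amplitude)
  expect_equal(m2$auc, 3.7 * m1$auc)
  expect_equal(m2$width, m1$width)
})

test_that("template beat metrics match a 10 kHz dense-grid oracle", {
  # one template beat, 1 s period, unit amplitude, sampled at 100 Hz
  fs <- 100
  u <- seq(0, 1, by = 1 / fs)
  x <- pulse_template(u)
  rec <- waveform_recording(x, fs)
  pk <- which.max(x)
  beats <- data.frame(foot_index = 1L, peak_index = as.integer(pk),
                      next_foot_index = length(x),
                      peak_time = (pk - 1) / fs)
  m <- beat_metrics(rec, beats)

  # oracle on a 10 kHz grid, straight from the template definition
  ud <- seq(0, 1, by = 1e-4)
  xd <- pulse_template(ud)
  amp_o <- max(xd) - xd[1]
  level <- xd[1] + amp_o / 2
  above <- which(xd >= level)
  width_o <- ud[max(above)] - ud[min(above)]
  auc_o <- pracma::trapz(ud, xd - xd[1])

  expect_equal(m$amplitude, amp_o, tolerance = 0.01)
  expect_equal(m$width, width_o, tolerance = 0.01)
  expect_equal(m$auc, auc_o, tolerance = 0.01)
})

test_that("window RMS of a pure sinusoid is A/sqrt(2)", {
  fs <- 100
  A <- 1.7
  t <- (0:999) / fs            # 10 s = 10 periods of a 1 Hz sinusoid
  rec <- waveform_recording(A * sin(2 * pi * t) + 5, fs)
  # feet at the sinusoid minima (t = 0.75, 1.75, ...), peaks at the maxima
  beats <- data.frame(foot_index = c(76L, 176L), peak_index = c(126L, 226L),
                      next_foot_index = c(176L, 276L),
                      peak_time = c(125, 225) / fs)
  beats <- beat_metrics(rec, beats)
  wf <- window_features(rec, beats, c(0, 10), "sine")
  expect_equal(wf$rms_power, A / sqrt(2), tolerance = 0.005)
})

test_that("identical beats give zero amplitude SD", {
  fs <- 100
  u <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- rep(pulse_template(u), 12)
  rec <- waveform_recording(x, fs)
  beats <- beat_metrics(rec, detect_beats(rec))
  wf <- window_features(rec, beats, c(0, 12), "flat")
  expect_equal(wf$sd_amplitude, 0, tolerance = 1e-10)
  expect_gte(wf$n_beats, 2)
})

test_that("zero-noise amplitudes match the analytic envelope within 2%", {
  tr <- zero_noise_trial(pressure = 8, heart_rate = 64)
  cfg <- sim_config(noise_sd = 0, drift_amplitude = 0)
  beats <- beat_metrics(tr$recording, detect_beats(tr$recording))
  r <- tr$truth$r_end
  env <- vapply(beats$peak_time, function(t) {
    s0 <- cfg$rest_s; s1 <- cfg$rest_s + cfg$strain_s
    if (t < s0) 1
    else if (t < s1) 1 - (1 - r) * min((t - s0) / (cfg$strain_s / 2), 1)
    else r + (1 - r) * min((t - s1) / 5, 1)
  }, numeric(1)) * cfg$baseline_amplitude
  expect_lt(max(abs(beats$amplitude - env) / env), 0.02)
})

test_that("strain-window mean amplitude equals r_end x baseline", {
  tr <- zero_noise_trial(pressure = 5, heart_rate = 68)
  beats <- beat_metrics(tr$recording, detect_beats(tr$recording))
  wf <- window_features(tr$recording, beats, c(35, 40), "end_valsalva")
  expect_equal(wf$mean_amplitude, tr$truth$r_end * 1, tolerance = 0.02)
})

test_that("trial ratios hit the envelope extremes at zero noise", {
  lo <- zero_noise_trial(pressure = 3, heart_rate = 62)
  tf <- trial_features(lo$recording, lo$annotation)
  expect_equal(tf$ratio_amplitude, 0.4, tolerance = 0.05 / 0.4)
  hi <- zero_noise_trial(pressure = 45, heart_rate = 62)
  tf2 <- trial_features(hi$recording, hi$annotation)
  for (rt in c(tf2$ratio_amplitude, tf2$ratio_rms, tf2$ratio_auc)) {
    expect_lt(abs(rt - 1), 0.05)
  }
})

test_that("scale equivariance and shift invariance of trial features", {
  tr <- zero_noise_trial(pressure = 13, heart_rate = 75)
  tf <- trial_features(tr$recording, tr$annotation)
  # scale: amplitude/AUC/RMS features scale by c, widths and ratios unchanged
  c_ <- 4.2
  scaled <- tr$recording
  scaled$samples <- scaled$samples * c_
  tfs <- trial_features(scaled, tr$annotation)
  expect_equal(tfs$end_rest$mean_amplitude, c_ * tf$end_rest$mean_amplitude)
  expect_equal(tfs$end_rest$mean_auc, c_ * tf$end_rest$mean_auc)
  expect_equal(tfs$end_rest$rms_power, c_ * tf$end_rest$rms_power)
  expect_equal(tfs$end_rest$mean_width, tf$end_rest$mean_width)
  expect_equal(tfs$ratio_amplitude, tf$ratio_amplitude)
  expect_equal(tfs$ratio_rms, tf$ratio_rms)
  expect_equal(tfs$ratio_auc, tf$ratio_auc)
  # shift: move t0 and the annotation windows together
  shift <- 17.3
  shifted <- tr$recording
  shifted$t0 <- shifted$t0 + shift
  ann <- tr$annotation
  ann2 <- maneuver_annotation(ann$rest_window + shift,
                              ann$strain_window + shift,
                              ann$recovery_window + shift,
                              ann$target_mouth_pressure)
  tft <- trial_features(shifted, ann2)
  expect_equal(tft$ratio_amplitude, tf$ratio_amplitude)
  expect_equal(tft$end_rest$mean_amplitude, tf$end_rest$mean_amplitude)
  expect_equal(tft$end_valsalva$rms_power, tf$end_valsalva$rms_power)
})

test_that("oversized analysis windows are windowing errors", {
  tr <- zero_noise_trial(pressure = 12, heart_rate = 60)
  expect_error(trial_features(tr$recording, tr$annotation, window_len = 31),
               class = "ppgv_windowing_error")
  beats <- beat_metrics(tr$recording, detect_beats(tr$recording))
  expect_error(window_features(tr$recording, beats, c(0, 0.5), "empty"),
               class = "ppgv_windowing_error")
})
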