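#' Simulation configuration for a synthetic Valsalva-PPG cohort
#'
#' Bundles every tunable of the cohort generator: the two-group filling
#' pressure mixture, the logistic map from filling pressure to end-strain
#' pulse-amplitude attenuation, the BNP model, pulse-train and noise
#' parameters, and the trial timing layout.
#'
#' The filling-pressure model is a two-component truncated-normal mixture:
#' with probability `prevalence_overload` a pressure is drawn from
#' `Normal(pressure_mean_overload, pressure_sd_overload)` truncated to lie
#' above `overload_threshold`, otherwise from
#' `Normal(pressure_mean_normal, pressure_sd_normal)` truncated to
#' `(0, overload_threshold]`. The defaults reproduce a cohort in which about
#' 35% of subjects are volume overloaded (filling pressure > 15 mmHg) with
#' group means/SDs of 23.67 (6.00) and 10.59 (3.02) mmHg.
#'
#' The pulse-amplitude response to strain is summarized by the end-strain
#' attenuation ratio `r_end = r_min + (1 - r_min) * plogis((P - p0)/s)`:
#' at low filling pressure the amplitude falls to about `r_min` of its
#' resting value (the normal physiologic response), while at high pressure
#' the response is blunted and `r_end` approaches 1. The midpoint `p0`
#' defaults to the 15 mmHg clinical overload cutoff so that the attenuation
#' is maximally informative exactly where the classification decision lives.
#'
#' BNP is log-linear in pressure with substantial log-scale noise, so that a
#' BNP-only regression of pressure is weakly predictive (cross-validated
#' R-squared around 0.2 at n = 200) - deliberately a weak comparator.
#'
#' @param prevalence_overload Probability a subject is volume overloaded.
#' @param pressure_mean_overload,pressure_sd_overload Mean/SD (mmHg) of the
#'   overloaded filling-pressure component.
#' @param pressure_mean_normal,pressure_sd_normal Mean/SD (mmHg) of the
#'   non-overloaded component.
#' @param overload_threshold Pressure cutoff (mmHg) separating the mixture
#'   components; also the primary classification cutoff.
#' @param heart_rate_mean,heart_rate_sd Subject-level heart rate
#'   distribution (beats/min).
#' @param hr_jitter_cv Coefficient of variation of beat-to-beat interval
#'   jitter (unitless).
#' @param baseline_amplitude Resting pulse amplitude (arbitrary PPG units).
#' @param r_min Attenuation floor: the end-strain/rest amplitude ratio
#'   approached at very low filling pressure (unitless, in (0, 1]).
#' @param p0 Attenuation midpoint (mmHg).
#' @param s Attenuation scale (mmHg); smaller values sharpen the transition.
#' @param bnp_intercept,bnp_slope Log-linear BNP model:
#'   `log BNP = bnp_intercept + bnp_slope * pressure + noise`
#'   (log pg/ml, log pg/ml per mmHg).
#' @param bnp_noise_sd SD of the log-BNP noise (log pg/ml).
#' @param noise_sd Additive white-noise SD on the waveform (AU).
#' @param drift_amplitude Amplitude of the slow sinusoidal baseline drift (AU).
#' @param drift_period_s Period of the baseline drift (s).
#' @param sampling_rate Waveform sampling rate (Hz).
#' @param rest_s,strain_s,recovery_s Durations (s) of the rest, strain and
#'   recovery phases of each trial. The strain defaults to the 10 s breath
#'   hold of the protocol.
#' @param inter_trial_rest_s Rest between consecutive trials (s); recorded as
#'   metadata only, the trials themselves are stored as separate recordings.
#' @param n_trials Valsalva trials per subject.
#' @param age_mean,age_sd Cohort age distribution (years), truncated to
#'   18-95 at draw time.
#' @param target_mouth_pressure Target oral pressure during strain (mmHg),
#'   carried on every annotation.
#' @param seed Integer seed from which all cohort randomness flows.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$prevalence_overload
#' @export
sim_config <- function(prevalence_overload = 0.35,
                       pressure_mean_overload = 23.67,
                       pressure_sd_overload = 6.00,
                       pressure_mean_normal = 10.59,
                       pressure_sd_normal = 3.02,
                       overload_threshold = 15,
                       heart_rate_mean = 72,
                       heart_rate_sd = 9,
                       hr_jitter_cv = 0.03,
                       baseline_amplitude = 1,
                       r_min = 0.4,
                       p0 = 15,
                       s = 3,
                       bnp_intercept = 4.5,
                       bnp_slope = 0.045,
                       bnp_noise_sd = 0.58,
                       noise_sd = 0.02,
                       drift_amplitude = 0.05,
                       drift_period_s = 12,
                       sampling_rate = 100,
                       rest_s = 30,
                       strain_s = 10,
                       recovery_s = 20,
                       inter_trial_rest_s = 60,
                       n_trials = 3,
                       age_mean = 62.6,
                       age_sd = 10.4,
                       target_mouth_pressure = 25,
                       seed = 1L) {
  cfg <- list(
    prevalence_overload = prevalence_overload,
    pressure_mean_overload = pressure_mean_overload,
    pressure_sd_overload = pressure_sd_overload,
    pressure_mean_normal = pressure_mean_normal,
    pressure_sd_normal = pressure_sd_normal,
    overload_threshold = overload_threshold,
    heart_rate_mean = heart_rate_mean,
    heart_rate_sd = heart_rate_sd,
    hr_jitter_cv = hr_jitter_cv,
    baseline_amplitude = baseline_amplitude,
    r_min = r_min,
    p0 = p0,
    s = s,
    bnp_intercept = bnp_intercept,
    bnp_slope = bnp_slope,
    bnp_noise_sd = bnp_noise_sd,
    noise_sd = noise_sd,
    drift_amplitude = drift_amplitude,
    drift_period_s = drift_period_s,
    sampling_rate = sampling_rate,
    rest_s = rest_s,
    strain_s = strain_s,
    recovery_s = recovery_s,
    inter_trial_rest_s = inter_trial_rest_s,
    n_trials = n_trials,
    age_mean = age_mean,
    age_sd = age_sd,
    target_mouth_pressure = target_mouth_pressure,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()]: probabilities in
#' (0, 1), the attenuation floor in (0, 1], a sampling rate of at least
#' 25 Hz, positive durations, and non-negative spreads. Called by every
#' generator entry point; users normally never call it directly.
#'
#' @param config An object of class `sim_config`.
#' @return `config`, invisibly, if valid; otherwise an error of class
#'   `ppgv_config_error`.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_config("`config` must be a sim_config object; see sim_config()")
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) stop_config(msg)
  with(config, {
    chk(is.numeric(prevalence_overload) && prevalence_overload > 0 &&
          prevalence_overload < 1,
        "prevalence_overload must lie strictly between 0 and 1")
    chk(r_min > 0 && r_min <= 1, "r_min must lie in (0, 1]")
    chk(sampling_rate >= 25, "sampling_rate must be at least 25 Hz")
    chk(strain_s > 0, "strain_s must be positive")
    chk(rest_s > 0 && recovery_s > 0, "rest_s and recovery_s must be positive")
    chk(all(c(pressure_sd_overload, pressure_sd_normal, heart_rate_sd,
              bnp_noise_sd, noise_sd, age_sd) >= 0),
        "all standard deviations must be non-negative")
    chk(pressure_mean_normal > 0 && pressure_mean_overload > 0 &&
          overload_threshold > 0,
        "pressure parameters must be positive")
    chk(heart_rate_mean > 0, "heart_rate_mean must be positive")
    chk(s > 0, "attenuation scale s must be positive")
    chk(n_trials >= 1, "n_trials must be at least 1")
    chk(baseline_amplitude > 0, "baseline_amplitude must be positive")
  })
  invisible(config)
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("ppgv_config_error", "error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("ppgv_format_error", "error")))
}

stop_modeling <- function(msg) {
  stop(errorCondition(msg, class = c("ppgv_modeling_error", "error")))
}

stop_detection <- function(msg) {
  stop(errorCondition(msg, class = c("ppgv_detection_error", "error")))
}

stop_windowing <- function(msg) {
  stop(errorCondition(msg, class = c("ppgv_windowing_error", "error")))
}

stop_usage <- function(msg) {
  stop(errorCondition(msg, class = c("ppgv_usage_error", "error")))
}
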