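# Shared fixtures, built in code.

# Short-trial configuration for cohort-level tests: 12 s rest, the standard
# 10 s strain, 8 s recovery. Halves synthesis/extraction cost without
# touching the physiology parameters under test.
fast_config <- function(...) {
  sim_config(rest_s = 12, strain_s = 10, recovery_s = 8, ...)
}

quiet_features <- function(cohort, window_len = 5) {
  suppressMessages(cohort_features(cohort, window_len = window_len))
}

# cohort -> candidate pool, messages silenced
make_pool <- function(n, seed, config = fast_config(seed = seed)) {
  build_candidate_pool(quiet_features(simulate_cohort(n, config)))
}

# single zero-noise trial plus its trial features
zero_noise_trial <- function(pressure, heart_rate = 60, seed = 1, ...) {
  cfg <- sim_config(noise_sd = 0, drift_amplitude = 0, seed = seed, ...)
  set.seed(seed)
  synthesize_trial(pressure, cfg, heart_rate = heart_rate)
}

# independent all-pairs AUROC oracle (ties count one half)
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}
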