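# memoised fixtures shared across test files (built once per test run)
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small noisy cohort: 3 subjects x 1 repetition, 45 s
tiny_cohort <- function() {
  memo("tiny", fixture_cohort(n_female = 1, n_male = 2, n_repetitions = 1,
                              duration = 45, seed = 42))
}

tiny_prepared <- function() {
  memo("tiny_prep", prepare_cohort(tiny_cohort()))
}

# configuration with all stochastic elements switched off
noisefree_config <- function(...) {
  resp_config(marker_noise_sd = 0, accel_noise_sd = 0, gyro_noise_sd = 0,
              dropout_prob = 0, rate_jitter_cv = 0, amp_jitter_cv = 0, ...)
}

# one noise-free 15-breaths/min sinusoidal trial (no harmonic, no offset)
sinusoid_trial <- function() {
  memo("sin_trial", {
    cfg <- noisefree_config(seed = 9, duration = 60, second_harmonic = 0,
                            rr_mean = 15, rr_sd = 0,
                            clock_offset_range = c(0, 0))
    subj <- withr::with_seed(9, generate_subject_params(cfg, n = 1, sex = "M"))
    generate_trial(subj, cfg, seed = 9)
  })
}

# noise-free trial with the default waveform and a nonzero clock offset
noisefree_trial <- function() {
  memo("nf_trial", {
    cfg <- noisefree_config(seed = 4, duration = 60)
    subj <- withr::with_seed(4, generate_subject_params(cfg, n = 1, sex = "F"))
    generate_trial(subj, cfg, seed = 4)
  })
}

# 2.5 Hz zero-lag filter + demean, the model-stage conditioning
lp_demean <- function(x, rate = 100, cutoff = 2.5) {
  y <- lowpass_zero_lag(tibble::tibble(time = seq_along(x) / rate, v = x),
                        cutoff, 4, rate = rate)$v
  y - mean(y)
}

# default 18 x 2 cohort and its LOOCV runs (used by the acceptance tests)
default_cohort <- function() {
  memo("default_cohort", generate_cohort(resp_config(seed = 20260919)))
}

default_prepared <- function() {
  memo("default_prep", prepare_cohort(default_cohort()))
}

default_loocv <- function(model) {
  memo(paste0("default_loocv_", model),
       run_loocv(default_cohort(), model, prepared = default_prepared()))
}
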