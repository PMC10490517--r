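# Shared synthetic cohorts, generated once per test run and cached.
# Scales are reduced relative to the full study protocol so the whole
# suite stays desk-sized; the class-conditional structure is unchanged.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- fn()
  .cohort_cache[[key]]
}

# strongly separable cohort: large band-power / heart-rate / SPR-rate
# contrasts, >= 150 segments per subject
strong_cohort_config <- function() {
  cohort_config(n_subjects = 5, manual_duration_s = 150,
                manual_duration_jitter_s = 5, adas_duration_s = 80,
                obstacle_positions_m = numeric(0),
                eeg_effect = 1.5, hr_manual_bpm = 95, hr_adas_bpm = 65,
                spr_rate_manual_per_min = 10, spr_rate_adas_per_min = 0.5,
                seed = 7)
}

# zero-effect cohort: identical class-conditional distributions; session
# durations chosen so each subject's test set is roughly class-balanced
# and chance level is interpretable as ~50%
null_cohort_config <- function() {
  cohort_config(n_subjects = 5, manual_duration_s = 40,
                manual_duration_jitter_s = 2, adas_duration_s = 120,
                obstacle_positions_m = numeric(0),
                eeg_effect = 0, hr_manual_bpm = 75, hr_adas_bpm = 75,
                spr_rate_manual_per_min = 3, spr_rate_adas_per_min = 3,
                seed = 11)
}

# tiny cohort for protocol-shape tests (fold structure, determinism)
micro_cohort_config <- function() {
  cohort_config(n_subjects = 3, n_manual_sessions = 2,
                manual_duration_s = 36, manual_duration_jitter_s = 2,
                adas_duration_s = 45, obstacle_positions_m = numeric(0),
                eeg_effect = 1.5, hr_manual_bpm = 95, hr_adas_bpm = 65,
                spr_rate_manual_per_min = 10, spr_rate_adas_per_min = 0.5,
                seed = 23)
}

strong_segments <- function() {
  cached("strong_segments", function() {
    preprocess_cohort(generate_cohort(strong_cohort_config()))
  })
}

null_segments <- function() {
  cached("null_segments", function() {
    preprocess_cohort(generate_cohort(null_cohort_config()))
  })
}

micro_segments <- function() {
  cached("micro_segments", function() {
    preprocess_cohort(generate_cohort(micro_cohort_config()))
  })
}

micro_clean <- function() {
  cached("micro_clean", function() {
    preprocess_cohort(generate_cohort(micro_cohort_config()),
                      segment = FALSE)
  })
}

# reduced-scale training recipes (few epochs, faster Adam steps); the
# architecture and protocol are unchanged
strong_spec <- function(arch, seed = 1L) {
  if (arch == "data_fusion") {
    model_spec("data_fusion", "eeg+spr+ecg", max_epochs = 10, patience = 10,
               learning_rate = 3e-3, seed = seed)
  } else {
    model_spec("feature_fusion", "eeg+spr+ecg", max_epochs = 8, patience = 8,
               learning_rate = 3e-3, seed = seed)
  }
}

micro_spec <- function(arch = "data_fusion", ...) {
  do.call(model_spec, utils::modifyList(
    list(arch = arch, sensors = "eeg+spr+ecg", max_epochs = 2, patience = 2,
         learning_rate = 3e-3), list(...)))
}

# quick separable segment set for model unit tests: short windows, class
# difference injected as an amplitude/frequency contrast in all channels
toy_segments <- function(n_per_class = 60, window = 100, seed = 5,
                         separable = TRUE) {
  set.seed(seed)
  n <- 2 * n_per_class
  dat <- array(stats::rnorm(n * window * 8), c(n, window, 8))
  label <- rep(0:1, each = n_per_class)
  if (separable) {
    t <- seq_len(window)
    for (i in which(label == 0)) {
      dat[i, , ] <- dat[i, , ] + 2 * sin(2 * pi * 10 * t / window)
    }
  }
  segment_set(dat, label,
              subject_id = rep(sprintf("T%02d", rep(1:4, length.out = n / 2)), 2),
              session = rep("Manual1", n), fs = window / 3, window_s = 3)
}

# cache for expensive acceptance-level results shared across test blocks
acceptance_loso <- function(arch, seed) {
  cached(paste0("loso_", arch, "_", seed), function() {
    loso_evaluate(strong_segments(), strong_spec(arch, seed = seed),
                  seed = seed)
  })
}
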