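small_cfg <- function(...) {
  do.call(cohort_config, utils::modifyList(
    list(n_subjects = 2, manual_duration_s = 30,
         manual_duration_jitter_s = 0, adas_duration_s = 40,
         obstacle_positions_m = c(200, 500), extra_rec_s = 0, seed = 3),
    list(...)))
}

test_that("session lengths and structure follow the configuration", {
  cfg <- small_cfg()
  sub <- generate_subject(cfg, "S01", seed_offset = 1)
  expect_named(sub$recordings, c("Manual1", "Manual2", "Manual3", "ADAS"))
  expect_equal(nrow(sub$recordings$Manual1$data), round(30 * 200))
  expect_equal(nrow(sub$recordings$ADAS$data), round(40 * 200))
  expect_equal(length(sub$traces$Manual1), nrow(sub$recordings$Manual1$data))
  expect_equal(sub$truth$Manual1$class, 0L)
  expect_equal(sub$truth$ADAS$class, 1L)
  # simulator positions are non-decreasing
  expect_false(is.unsorted(sub$traces$ADAS$longitudinal_position))
})

test_that("generation is bit-identical under one seed and differs across seeds", {
  a <- generate_subject(small_cfg(), "S01", seed_offset = 1)
  b <- generate_subject(small_cfg(), "S01", seed_offset = 1)
  expect_identical(a$recordings$Manual2$data, b$recordings$Manual2$data)
  expect_identical(a$truth, b$truth)
  c <- generate_subject(small_cfg(seed = 4), "S01", seed_offset = 1)
  expect_false(identical(a$recordings$Manual2$data,
                         c$recordings$Manual2$data))
})

test_that("clean ECG beat rate matches the configured heart rate within 2 bpm", {
  skip_if_not_installed("pracma")
  cfg <- cohort_config(n_subjects = 1, manual_duration_s = 60,
                       manual_duration_jitter_s = 0, adas_duration_s = 60,
                       hr_manual_bpm = 90, hr_adas_bpm = 70,
                       extra_rec_s = 0, seed = 9)
  sub <- generate_subject(cfg, "S01", seed_offset = 1, artifacts = FALSE)
  rate_of <- function(rec, hr) {
    x <- rec$data[, "ECG1"]
    pk <- pracma::findpeaks(x, minpeakheight = 0.5 * max(x),
                            minpeakdistance = round(0.5 * 60 / hr * 200))
    nrow(pk) / (nrow(rec$data) / 200) * 60
  }
  expect_lt(abs(rate_of(sub$recordings$Manual1, 90) - 90), 2)
  expect_lt(abs(rate_of(sub$recordings$ADAS, 70) - 70), 2)
})

test_that("artifact injection is the identity at zero rates and bookkeeps locations", {
  cfg0 <- small_cfg(blink_rate_per_min = 0, drift_amplitude_uv = 0,
                    pop_rate_per_min = 0, spr_spike_rate_per_min = 0,
                    ecg_wander_mv = 0, zero_gap_rate_per_min = 0)
  sub <- generate_subject(cfg0, "S01", seed_offset = 1, artifacts = FALSE)
  rec <- sub$recordings$Manual1
  out <- inject_artifacts(rec, cfg0, seed = 1)
  expect_identical(out$recording$data, rec$data)

  # blinks strictly increase frontal variance
  cfg_blink <- small_cfg(blink_rate_per_min = 20, drift_amplitude_uv = 0,
                         pop_rate_per_min = 0, spr_spike_rate_per_min = 0,
                         ecg_wander_mv = 0, zero_gap_rate_per_min = 0)
  out2 <- inject_artifacts(rec, cfg_blink, seed = 2)
  expect_gt(var(out2$recording$data[, "Fp1"]), var(rec$data[, "Fp1"]))
  expect_gt(length(out2$truth$blinks), 0)

  # recorded zero gaps contain only exact zeros
  cfg_gap <- small_cfg(blink_rate_per_min = 0, drift_amplitude_uv = 0,
                       pop_rate_per_min = 0, spr_spike_rate_per_min = 0,
                       ecg_wander_mv = 0, zero_gap_rate_per_min = 4)
  out3 <- inject_artifacts(rec, cfg_gap, seed = 3)
  expect_gt(length(out3$truth$zero_gaps), 0)
  for (g in out3$truth$zero_gaps) {
    seg <- out3$recording$data[g$start:(g$end - 1L), g$channels]
    expect_true(all(seg == 0))
  }
})

test_that("cohorts written to disk are complete and seed-deterministic", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, path = d1)
  generate_cohort(cfg, path = d2)
  subs <- list.dirs(d1, recursive = FALSE, full.names = FALSE)
  expect_length(subs, 2)
  expect_length(list.files(file.path(d1, subs[1]), pattern = "^(Manual|ADAS).*\\.csv$"),
                8)  # 4 sessions + 4 traces
  h1 <- tools::md5sum(list.files(d1, recursive = TRUE, full.names = TRUE))
  h2 <- tools::md5sum(list.files(d2, recursive = TRUE, full.names = TRUE))
  expect_identical(unname(h1[grep("csv$", names(h1))]),
                   unname(h2[grep("csv$", names(h2))]))

  d3 <- withr::local_tempdir()
  generate_cohort(small_cfg(seed = 99), path = d3)
  h3 <- tools::md5sum(list.files(d3, recursive = TRUE, full.names = TRUE))
  expect_false(identical(unname(h1[grep("Manual1.csv$", names(h1))]),
                         unname(h3[grep("Manual1.csv$", names(h3))])))
})

test_that("a written cohort reads back into an equivalent in-memory cohort", {
  cfg <- small_cfg()
  d <- withr::local_tempdir()
  mem <- generate_cohort(cfg, path = d)
  back <- read_cohort(d)
  expect_equal(names(back$subjects), names(mem$subjects))
  expect_equal(back$subjects$S01$recordings$ADAS$data,
               mem$subjects$S01$recordings$ADAS$data, tolerance = 1e-12)
  expect_equal(back$subjects$S02$traces$Manual3$longitudinal_position,
               mem$subjects$S02$traces$Manual3$longitudinal_position,
               tolerance = 1e-10)
})
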