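test_that("obstacle excision removes exactly the position-derived span", {
  fs <- 200
  dur <- 250                      # covers positions 0..5000 m at 20 m/s
  n <- dur * fs
  trace <- sim_trace(20 * (0:(n - 1)) / fs, fs = fs)
  set.seed(1)
  rec <- sync_recording(matrix(rnorm(n * 10), n, 10), fs = fs)

  out <- excise_obstacles(rec, trace, obstacle_positions_m = 2000,
                          span_m = 200, margin_m = 500)
  # positions 1500-2700 m at 20 m/s -> t in [75 s, 135 s), 60 s excised
  expect_equal(n - nrow(out$data), 60 * fs)
  kept <- c(1:(75 * fs), (135 * fs + 1):n)
  expect_identical(out$data, rec$data[kept, ])
  expect_equal(out$time, (seq_along(kept) - 1) / fs)

  # no obstacles, or an obstacle beyond the track end, is the identity
  expect_identical(excise_obstacles(rec, trace, numeric(0))$data, rec$data)
  expect_identical(excise_obstacles(rec, trace, 99000)$data, rec$data)

  short_trace <- sim_trace(20 * (0:99) / fs, fs = fs)
  expect_error(excise_obstacles(rec, short_trace, 2000), "alignment error")
})

test_that("segmentation cuts 600-sample windows and drops the remainder", {
  cs <- clean_session(matrix(rnorm(1930 * 8), 1930, 8), fs = 200,
                      subject_id = "S01", session = "Manual2")
  segs <- segment_and_label(cs, window_s = 3)
  expect_equal(length(segs), 3)
  expect_equal(dim(segs$data)[2], 600)
  expect_true(all(segs$label == 0))
  expect_equal(segs$data[2, , ], unname(cs$data[601:1200, ]), tolerance = 0)

  adas <- clean_session(matrix(rnorm(1400 * 8), 1400, 8), fs = 200,
                        subject_id = "S01", session = "ADAS")
  expect_true(all(segment_and_label(adas)$label == 1))

  # shorter than one window: empty set, not an error
  tiny <- clean_session(matrix(rnorm(100 * 8), 100, 8), fs = 200,
                        subject_id = "S01", session = "ADAS")
  expect_equal(length(segment_and_label(tiny)), 0)
})

test_that("the full session chain keeps channels synchronized and labeled", {
  cfg <- micro_cohort_config()
  coh <- generate_cohort(cfg)
  sub <- coh$subjects$S01
  clean <- preprocess_session(sub$recordings$ADAS, sub$traces$ADAS,
                              obstacle_positions_m = numeric(0),
                              segment = FALSE)
  expect_s3_class(clean, "clean_session")
  expect_equal(ncol(clean$data), 8)
  expect_equal(clean$label, 1L)
  expect_true(all(is.finite(clean$data)))
  # without excisable content the cleaned length equals the trace length
  expect_equal(nrow(clean$data), length(sub$traces$ADAS))
})

test_that("cohort segment count equals the sum of per-session floor counts", {
  clean <- micro_clean()
  segs <- micro_segments()
  expect_equal(length(segs),
               sum(vapply(clean, function(cs) nrow(cs$data) %/% 600L, 1L)))
  tab <- table(segs$subject_id)
  expect_length(tab, 3)
  # every subject contributes both classes
  for (s in unique(segs$subject_id)) {
    expect_setequal(unique(segs$label[segs$subject_id == s]), c(0L, 1L))
  }
})

test_that("excision removes obstacle windows jointly from all channels", {
  cfg <- cohort_config(n_subjects = 1, manual_duration_s = 120,
                       manual_duration_jitter_s = 0, adas_duration_s = 40,
                       obstacle_positions_m = 1500, mean_speed_mps = 30,
                       extra_rec_s = 0, seed = 13)
  coh <- generate_cohort(cfg)
  sub <- coh$subjects$S01
  params <- preprocess_params()
  clean <- preprocess_session(sub$recordings$Manual1, sub$traces$Manual1,
                              obstacle_positions_m = cfg$obstacle_positions_m,
                              params = params, segment = FALSE)
  pos <- sub$traces$Manual1$longitudinal_position
  inside <- sum(pos >= 1000 & pos < 2200)   # 1500 - 500 .. 1500 + 200 + 500
  expect_lte(nrow(clean$data), length(pos) - inside)
  expect_equal(ncol(clean$data), 8)
})

test_that("segment archives round-trip", {
  segs <- micro_segments()
  path <- withr::local_tempfile(fileext = ".rds")
  write_segments(segs, path)
  back <- read_segments(path)
  expect_identical(back$data, segs$data)
  expect_identical(back$label, segs$label)
})
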