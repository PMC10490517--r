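fs <- 200

# band-limited multichannel EEG surrogate with mild channel correlations
clean_eeg <- function(dur = 120, seed = 1) {
  set.seed(seed)
  n <- dur * fs
  shared <- asNamespace("engagefuse")$band_noise(n, fs, 4, 30)
  x <- sapply(1:6, function(i) {
    5 * asNamespace("engagefuse")$band_noise(n, fs, 4, 30) + 2 * shared
  })
  x
}

test_that("artifact-free signals pass through ASR nearly unchanged", {
  x <- clean_eeg()
  y <- asr_clean(x, fs)
  expect_equal(dim(y), dim(x))
  for (c in 1:6) expect_gt(cor(x[, c], y[, c]), 0.95)
})

test_that("high-amplitude bursts are suppressed without harming clean spans", {
  x <- clean_eeg(seed = 2)
  n <- nrow(x)
  bg_rms <- sqrt(mean(x^2))
  burst_idx <- integer(0)
  set.seed(3)
  for (b in 1:5) {
    start <- 10 * fs + (b - 1) * 20 * fs
    idx <- start:(start + 0.5 * fs - 1)
    burst_idx <- c(burst_idx, idx)
    ch <- sample(1:6, 1)
    x_burst <- 20 * bg_rms * sin(2 * pi * 9 * seq_along(idx) / fs)
    x[idx, ch] <- x[idx, ch] + x_burst
  }
  y <- asr_clean(x, fs)
  rms_in <- sqrt(mean(x[burst_idx, ]^2))
  rms_out <- sqrt(mean(y[burst_idx, ]^2))
  expect_lt(rms_out, 0.5 * rms_in)

  outside <- setdiff(seq_len(n), burst_idx)
  rms_out_clean <- sqrt(mean(y[outside, ]^2))
  rms_in_clean <- sqrt(mean(x[outside, ]^2))
  expect_lt(abs(rms_out_clean - rms_in_clean) / rms_in_clean, 0.10)
})

test_that("degenerate inputs are rejected", {
  x <- clean_eeg(dur = 60)
  x[, 3] <- 0
  expect_error(asr_clean(x, fs), "zero-variance")
  expect_error(asr_clean(clean_eeg(dur = 2), fs), "degenerate")
  expect_error(asr_params(cutoff_k = -1), "parameter error")
})
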