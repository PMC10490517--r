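fs <- 200
t10 <- (0:(10 * fs - 1)) / fs

rms <- function(x) sqrt(mean(x^2))

test_that("notch attenuates the 50 Hz tone and passes 10 Hz", {
  tone50 <- sin(2 * pi * 50 * t10)
  tone10 <- sin(2 * pi * 10 * t10)
  out50 <- notch_filter(tone50, fs)
  out10 <- notch_filter(tone10, fs)
  expect_lt(rms(out50), 0.01 * rms(tone50))          # >= 40 dB at band center
  expect_lt(abs(rms(out10) - rms(tone10)) / rms(tone10), 0.12)
  expect_equal(length(out50), length(tone50))
  expect_equal(notch_filter(numeric(500), fs), numeric(500))
  expect_error(notch_filter(tone50, fs, low = 90, high = 110),
               "parameter error")
})

test_that("EEG band-limiting rejects DC and drift while preserving mid-band", {
  x <- matrix(100, length(t10), 1)                   # DC offset channel
  out <- eeg_bandlimit(x, fs)
  expect_lt(mean(abs(out)), 1)                       # >= 40 dB DC rejection

  tone20 <- sin(2 * pi * 20 * t10)
  out20 <- eeg_bandlimit(matrix(tone20), fs)[, 1]
  core <- seq(2 * fs, 8 * fs)                        # avoid edge transients
  gain_db <- 20 * log10(rms(out20[core]) / rms(tone20[core]))
  expect_lt(abs(gain_db), 1)

  drifty <- tone20 + 5 * sin(2 * pi * 0.2 * t10)
  outd <- eeg_bandlimit(matrix(drifty), fs)[, 1]
  expect_gt(cor(outd[core], tone20[core]), 0.99)

  expect_error(eeg_bandlimit(matrix(rnorm(100)), fs), "length error")
  expect_error(eeg_bandlimit(matrix(tone20), fs, hp = 50, lp = 45),
               "parameter error")
})

synth_clean_ecg <- function(dur = 30, hr = 75, seed = 1) {
  set.seed(seed)
  asNamespace("engagefuse")$synth_ecg(dur * fs, fs, hr, rr_jitter = 0.02)
}

test_that("ECG high-pass removes baseline wander but keeps R-peak amplitude", {
  ecg <- synth_clean_ecg()
  n <- length(ecg)
  tt <- (0:(n - 1)) / fs
  wander <- 2 * sin(2 * pi * 0.2 * tt)
  noisy <- ecg + wander
  out <- ecg_highpass(noisy, fs)

  bp <- function(x, lo, hi) asNamespace("engagefuse")$band_power(x, fs, lo, hi)
  expect_lt(bp(out, 0, 0.4), 0.1 * bp(noisy, 0, 0.4))   # >= 90% removed

  # R-peak amplitudes, measured from each signal's own baseline
  clean_out <- ecg_highpass(ecg, fs)
  peaks_in <- which(ecg > 0.8 * max(ecg))
  amp_in <- ecg[peaks_in] - median(ecg)
  amp_out <- clean_out[peaks_in] - median(clean_out)
  expect_lt(max(abs(amp_out - amp_in) / amp_in), 0.05)

  expect_lt(max(abs(ecg_highpass(rep(3, 1000), fs))), 1e-3)
  expect_error(ecg_highpass(ecg, fs, fc = 150), "parameter error")
})

test_that("the higher-SNR ECG lead is selected with a stable tie-break", {
  ecg <- synth_clean_ecg()
  set.seed(2)
  noisy <- ecg + rnorm(length(ecg), sd = sd(ecg))   # ~0 dB added noise
  sel <- ecg_select(ecg, noisy, fs)
  expect_equal(sel$index, 1L)
  sel2 <- ecg_select(noisy, ecg, fs)
  expect_equal(sel2$index, 2L)

  tie <- ecg_select(ecg, ecg, fs)
  expect_equal(tie$index, 1L)

  flat <- ecg_select(rep(0, length(ecg)), ecg, fs)
  expect_equal(flat$index, 2L)
  expect_error(ecg_select(rep(1, 3000), rep(2, 3000), fs), "degenerate")
  expect_error(ecg_select(ecg, ecg[-1], fs), "shape error")
})

test_that("SPR fusion tracks the smoother channel and smooths switches", {
  tt <- (0:(30 * fs - 1)) / fs
  tonic <- 0.5 * sin(2 * pi * 0.05 * tt) + 0.2 * sin(2 * pi * 0.11 * tt)

  expect_equal(spr_fuse(tonic, tonic, fs), tonic)

  # large spike on channel 2: output follows channel 1 inside the spike
  spike_region <- seq(10 * fs, 11 * fs)
  spiky <- tonic
  spiky[spike_region] <- spiky[spike_region] + 5
  fused <- spr_fuse(tonic, spiky, fs)
  interior <- seq(10.2 * fs, 10.8 * fs)
  expect_lt(max(abs(fused[interior] - tonic[interior])), 0.05)

  # alternating spikes: fused output is smoother than either input
  s1 <- tonic; s2 <- tonic
  s1[seq(5 * fs, 5.2 * fs)] <- s1[seq(5 * fs, 5.2 * fs)] + 4
  s2[seq(15 * fs, 15.2 * fs)] <- s2[seq(15 * fs, 15.2 * fs)] + 4
  both <- spr_fuse(s1, s2, fs)
  expect_lt(max(abs(diff(both))),
            min(max(abs(diff(s1))), max(abs(diff(s2)))))
  expect_error(spr_fuse(s1, s2[-1], fs), "shape error")
})
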