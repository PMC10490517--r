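#' Power-line notch filter
#'
#' Zero-phase 4th-order Butterworth band-stop filter, by default spanning
#' 46-54 Hz to suppress 50 Hz mains interference. Applied forward-backward
#' so the signal stays time-aligned; length is preserved.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Sa/s.
#' @param low,high stop-band edges in Hz.
#' @param order Butterworth order per pass.
#' @return filtered vector of the same length.
#' @export
notch_filter <- function(x, fs, low = 46, high = 54, order = 4) {
  if (high >= fs / 2 || low <= 0 || low >= high)
    stop("parameter error: notch cutoffs must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "stop")
  filtfilt_padded(bf, x, pad = round(fs))
}

# zero-phase forward-backward IIR filtering with odd-reflection padding
# and steady-state initial conditions, so edge transients are suppressed
# rather than merely pushed into a pad
filtfilt_padded <- function(bf, x, pad = 0L) {
  b <- bf$b; a <- bf$a
  nfilt <- max(length(a), length(b))
  b <- c(b, numeric(nfilt - length(b)))
  a <- c(a, numeric(nfilt - length(a)))
  nord <- nfilt - 1L
  n <- length(x)
  p <- min(max(3L * nord, pad), n - 1L)
  if (p < 1) return(as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), x)))
  # zi: filter state that makes the response to a unit step constant
  amat <- diag(nord) -
    cbind(-a[2:nfilt], rbind(diag(1, nord - 1L), numeric(nord - 1L))[, seq_len(nord - 1L), drop = FALSE])
  zi <- solve(amat, b[2:nfilt] - b[1] * a[2:nfilt])
  xp <- c(ar_pad(x, p, head = TRUE), x, ar_pad(x, p, head = FALSE))
  y <- cpp_iir_filter(b, a, xp, zi * xp[1])
  y <- rev(cpp_iir_filter(b, a, rev(y), zi * y[length(y)]))
  as.numeric(y[(p + 1):(p + n)])
}

# autoregressive (Burg) continuation of a signal edge: unlike mirror
# padding it extends oscillations phase-coherently, so narrow-band
# filters see no discontinuity at the joints
ar_pad <- function(x, p, head) {
  n <- length(x)
  seg <- if (head) rev(x[seq_len(min(8L * p, n))]) else
    x[seq.int(n - min(8L * p, n) + 1L, n)]
  pred <- tryCatch({
    fit <- stats::ar(seg, order.max = min(16L, length(seg) %/% 4L),
                     method = "burg", aic = FALSE)
    as.numeric(stats::predict(fit, n.ahead = p, se.fit = FALSE))
  }, error = function(e) rep(seg[length(seg)], p))
  if (any(!is.finite(pred)) || max(abs(pred)) > 10 * (max(abs(seg)) + 1e-12))
    pred <- rep(seg[length(seg)], p)     # unstable fit: hold the edge value
  if (head) rev(pred) else pred
}

# windowed-sinc (Hamming) linear-phase FIR taps; n chosen from the
# transition bandwidth via the Hamming approximation N ~ 3.3 fs / tbw
fir_taps <- function(fs, fc, tbw, type) {
  n <- ceiling(3.3 * fs / tbw)
  if (n %% 2 == 1) n <- n + 1    # even order -> odd length, type I
  signal::fir1(n, fc / (fs / 2), type = type, window = signal::hamming(n + 1))
}

# single-pass FIR with group-delay compensation and reflected edge padding
fir_apply <- function(x, taps) {
  m <- (length(taps) - 1) / 2
  n <- length(x)
  pad_l <- rev(x[seq_len(min(m, n))])
  pad_r <- rev(x[seq.int(n - min(m, n) + 1L, n)])
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, taps, method = "convolution", sides = 2)
  as.numeric(y[(length(pad_l) + 1):(length(pad_l) + n)])
}

#' Band-limit EEG channels with linear-phase FIR filters
#'
#' Applies a 4 Hz high-pass (2 Hz transition band) followed by a 45 Hz
#' low-pass (5 Hz transition band), both windowed-sinc Hamming designs with
#' the group delay compensated, so EEG events stay time-aligned with the
#' SPR and ECG channels. DC and sub-1 Hz drift are strongly attenuated
#' while the 10-40 Hz band is preserved within 1 dB.
#'
#' @param eeg numeric matrix, samples x channels (or a vector).
#' @param fs sampling rate in Sa/s.
#' @param hp,lp high-pass and low-pass cutoff frequencies in Hz.
#' @return filtered matrix of the same shape.
#' @export
eeg_bandlimit <- function(eeg, fs, hp = 4, lp = 45) {
  eeg <- as.matrix(eeg)
  if (hp <= 0 || lp >= fs / 2 || hp >= lp)
    stop("parameter error: need 0 < hp < lp < fs/2")
  taps_hp <- fir_taps(fs, hp, tbw = 2, type = "high")
  taps_lp <- fir_taps(fs, lp, tbw = 5, type = "low")
  min_len <- 3 * length(taps_hp)
  if (nrow(eeg) < min_len)
    stop(sprintf("length error: signal (%d samples) shorter than 3x filter length (%d)",
                 nrow(eeg), min_len))
  apply(eeg, 2, function(v) fir_apply(fir_apply(v, taps_hp), taps_lp))
}

#' Remove ECG baseline drift with a zero-phase IIR high-pass
#'
#' Butterworth high-pass (default order 2, 0.5 Hz cutoff) applied
#' forward-backward: DC and respiration-band baseline wander are removed
#' while QRS morphology is preserved.
#'
#' @param ecg numeric vector.
#' @param fs sampling rate in Sa/s.
#' @param fc cutoff frequency in Hz.
#' @param order filter order per pass.
#' @return filtered vector.
#' @export
ecg_highpass <- function(ecg, fs, fc = 0.5, order = 2) {
  if (fc >= fs / 2 || fc <= 0)
    stop("parameter error: cutoff must lie in (0, fs/2)")
  bf <- signal::butter(order, fc / (fs / 2), type = "high")
  filtfilt_padded(bf, ecg, pad = round(3 * fs / fc))
}

# mean power of the periodogram inside [lo, hi] Hz
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  sel <- half & freq >= lo & freq <= hi
  if (!any(sel)) return(0)
  sum(sp[sel]) / n
}

#' Select the higher-SNR ECG lead
#'
#' The SNR of each lead is estimated as the power in the QRS band (5-25 Hz)
#' divided by the out-of-band power (below 0.5 Hz and above 40 Hz) plus a
#' robust broadband-noise term, the squared median absolute deviation of
#' the 40-100 Hz component. Ties keep the first lead.
#'
#' @param ecg1,ecg2 the two chest leads (equal length, at least 10 s).
#' @param fs sampling rate in Sa/s.
#' @return list with `signal` (the chosen lead), `index` (1 or 2) and
#'   `snr` (both SNR estimates).
#' @export
ecg_select <- function(ecg1, ecg2, fs) {
  if (length(ecg1) != length(ecg2))
    stop("shape error: ECG leads must have equal length")
  if (length(ecg1) < 10 * fs)
    stop("ECG leads must be at least 10 s long")
  if (stats::sd(ecg1) == 0 && stats::sd(ecg2) == 0)
    stop("degenerate input: both ECG leads are flat")
  snr_of <- function(x) {
    if (stats::sd(x) == 0) return(0)
    sig <- band_power(x, fs, 5, 25)
    out <- band_power(x, fs, 0, 0.5) + band_power(x, fs, 40, fs / 2)
    hf <- x - fir_apply(x, fir_taps(fs, 40, tbw = 8, type = "low"))
    noise <- stats::mad(hf)^2
    sig / (out + noise + 1e-12)
  }
  snr <- c(snr_of(ecg1), snr_of(ecg2))
  idx <- if (snr[2] > snr[1]) 2L else 1L
  list(signal = if (idx == 1L) ecg1 else ecg2, index = idx, snr = snr)
}

# centered moving average with edge padding
moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  k <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], k), x, rep(x[length(x)], k))
  cs <- cumsum(xp)
  (cs[(w):length(xp)] - c(0, cs[seq_len(length(xp) - w)])) / w
}

#' Fuse two SPR channels by local-energy selection
#'
#' Motion artifacts corrupt one hand at a time, so at each instant the fused
#' signal takes the value of the channel whose first difference has the
#' lower local energy over a sliding window - the smoother of the two. The
#' hard selection is smoothed by cross-fading over a short ramp so switches
#' introduce no discontinuities. Equal channels fuse to themselves.
#'
#' @param spr1,spr2 the right- and left-hand SPR channels (equal length).
#' @param fs sampling rate in Sa/s.
#' @param energy_window_s local-energy window length, seconds.
#' @param ramp_s cross-fade duration, seconds.
#' @return fused vector of the same length.
#' @export
spr_fuse <- function(spr1, spr2, fs, energy_window_s = 1, ramp_s = 0.1) {
  if (length(spr1) != length(spr2))
    stop("shape error: SPR channels must have equal length")
  w <- round(energy_window_s * fs)
  e1 <- moving_avg(c(0, diff(spr1))^2, w)
  e2 <- moving_avg(c(0, diff(spr2))^2, w)
  sel <- as.numeric(e2 < e1)           # 1 -> take spr2; ties keep spr1
  wt <- moving_avg(sel, round(ramp_s * fs))
  (1 - wt) * spr1 + wt * spr2
}
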