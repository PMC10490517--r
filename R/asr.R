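#' Parameters for artifact subspace reconstruction
#'
#' @param calibration_window_s total duration of the cleanest data used for
#'   calibration, seconds.
#' @param cutoff_k rejection threshold in standard deviations of the
#'   calibration component RMS (the conservative default 20 only removes
#'   gross artifacts).
#' @param processing_window_s sliding-window length for cleaning, seconds;
#'   windows overlap by 50\% and are blended with raised-cosine weights.
#' @param block_s window length used both for calibration selection and for
#'   component RMS statistics, seconds.
#' @param max_bad_channels_fraction largest fraction of components that may
#'   be reconstructed in one window; windows exceeding it are reconstructed
#'   only in the worst components up to the cap.
#' @return an object of class `asr_params`.
#' @export
asr_params <- function(calibration_window_s = 60, cutoff_k = 20,
                       processing_window_s = 0.5, block_s = 1,
                       max_bad_channels_fraction = 0.75) {
  if (cutoff_k <= 0) stop("parameter error: cutoff_k must be positive")
  if (calibration_window_s <= 0 || processing_window_s <= 0 || block_s <= 0)
    stop("parameter error: window lengths must be positive")
  structure(list(calibration_window_s = calibration_window_s,
                 cutoff_k = cutoff_k,
                 processing_window_s = processing_window_s,
                 block_s = block_s,
                 max_bad_channels_fraction = max_bad_channels_fraction),
            class = "asr_params")
}

pinv_mat <- function(a, tol = 1e-10) {
  s <- svd(a)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(a), nrow(a)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

sqrtm_sym <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' Clean EEG with artifact subspace reconstruction
#'
#' Standard ASR procedure: (1) the cleanest sub-windows of the recording
#' (lowest robust channel-RMS z-scores) are pooled as calibration data;
#' (2) the calibration covariance defines a mixing matrix and, per
#' principal component, a rejection threshold `mu + cutoff_k * sigma` of
#' the component RMS over calibration blocks; (3) each sliding processing
#' window is eigendecomposed, components whose variance exceeds the
#' projected threshold are reconstructed from the calibration subspace;
#' (4) overlapping windows are blended with raised-cosine weights. On
#' artifact-free data the output is essentially the input.
#'
#' @param eeg numeric matrix, samples x channels, already band-limited.
#' @param fs sampling rate in Sa/s.
#' @param params an [asr_params] object.
#' @param exclude logical vector (length `nrow(eeg)`) marking samples that
#'   must not enter the calibration data (e.g. amplitude-rejected blocks).
#' @return cleaned matrix of the same shape.
#' @export
asr_clean <- function(eeg, fs, params = asr_params(), exclude = NULL) {
  eeg <- as.matrix(eeg)
  n <- nrow(eeg); nc <- ncol(eeg)
  sds <- apply(eeg, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: zero-variance channel ", which(sds == 0)[1])
  blk <- max(2L, round(params$block_s * fs))
  n_blk <- n %/% blk
  if (n_blk < 2 || n < params$calibration_window_s * fs / 4)
    stop("degenerate input: not enough data for ASR calibration")

  # --- calibration selection: cleanest blocks by robust RMS z-score
  blk_idx <- function(b) ((b - 1L) * blk + 1L):(b * blk)
  rms <- matrix(0, n_blk, nc)
  usable <- rep(TRUE, n_blk)
  for (b in seq_len(n_blk)) {
    idx <- blk_idx(b)
    rms[b, ] <- sqrt(colMeans(eeg[idx, , drop = FALSE]^2))
    if (!is.null(exclude) && any(exclude[idx])) usable[b] <- FALSE
  }
  z <- apply(rms, 2, function(v) {
    m <- stats::median(v); s <- stats::mad(v)
    if (s == 0) s <- stats::sd(v) + 1e-12
    (v - m) / s
  })
  badness <- apply(abs(z), 1, max)
  ord <- order(badness)
  ord <- ord[usable[ord]]
  if (length(ord) < 2)
    stop("degenerate input: no usable calibration blocks")
  want <- max(2L, min(length(ord), ceiling(params$calibration_window_s / params$block_s)))
  calib_blocks <- sort(ord[seq_len(want)])
  calib <- do.call(rbind, lapply(calib_blocks, function(b) eeg[blk_idx(b), , drop = FALSE]))

  # --- calibration statistics
  c0 <- stats::cov(calib)
  ev0 <- eigen(c0, symmetric = TRUE)
  if (min(ev0$values) < 1e-10 * max(ev0$values))
    stop("degenerate input: rank-deficient calibration covariance")
  m_mix <- sqrtm_sym(c0)
  v0 <- ev0$vectors
  comp <- calib %*% v0
  nb <- nrow(comp) %/% blk
  comp_rms <- sapply(seq_len(nc), function(j) {
    vapply(seq_len(nb), function(b) sqrt(mean(comp[blk_idx(b), j]^2)),
           numeric(1))
  })
  mu <- colMeans(comp_rms)
  sg <- apply(comp_rms, 2, stats::sd)
  thr <- (mu + params$cutoff_k * sg)
  t_mat <- diag(thr, nc) %*% t(v0)          # threshold operator

  # --- sliding-window reconstruction with raised-cosine overlap-add
  nw <- max(4L, round(params$processing_window_s * fs))
  hop <- max(1L, nw %/% 2L)
  starts <- seq(1L, max(1L, n - nw + 1L), by = hop)
  if (starts[length(starts)] + nw - 1L < n)
    starts <- c(starts, n - nw + 1L)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 0.5) / nw)
  out <- matrix(0, n, nc)
  wsum <- numeric(n)
  max_dims <- max(1L, floor(params$max_bad_channels_fraction * nc))
  for (s0 in starts) {
    idx <- s0:(s0 + nw - 1L)
    xw <- eeg[idx, , drop = FALSE]
    cw <- crossprod(xw) / nw
    ew <- eigen(cw, symmetric = TRUE)
    proj_thr <- colSums((t_mat %*% ew$vectors)^2)
    keep <- ew$values < proj_thr
    bad <- which(!keep)
    if (length(bad) > max_dims) {
      # reconstruct only the strongest offenders up to the cap
      ratio <- ew$values[bad] / pmax(proj_thr[bad], 1e-300)
      keep[] <- TRUE
      keep[bad[order(ratio, decreasing = TRUE)][seq_len(max_dims)]] <- FALSE
    }
    if (all(keep)) {
      cl <- xw
    } else {
      vw <- ew$vectors
      a <- t(vw) %*% m_mix
      a[!keep, ] <- 0
      r_mat <- m_mix %*% pinv_mat(a) %*% t(vw)
      cl <- xw %*% t(r_mat)
    }
    out[idx, ] <- out[idx, ] + cl * win
    wsum[idx] <- wsum[idx] + win
  }
  out / pmax(wsum, 1e-12)
}
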