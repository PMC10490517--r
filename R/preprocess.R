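#' Preprocessing parameters
#'
#' Collects every tunable of the cleaning chain with its protocol default:
#' 46-54 Hz Butterworth notch, 4-45 Hz FIR EEG band, ASR defaults from
#' [asr_params()], a 500 uV automated amplitude-rejection criterion
#' (replacing manual visual inspection), 1 s local-energy window for SPR
#' fusion, 0.5 Hz ECG high-pass, 200 m obstacle span with 500 m margins,
#' and 3 s segmentation windows.
#'
#' @param notch_low,notch_high notch stop-band edges, Hz.
#' @param eeg_hp,eeg_lp EEG band limits, Hz.
#' @param asr an [asr_params] object.
#' @param amplitude_threshold_uv absolute EEG amplitude above which a 1 s
#'   block is rejected before ASR calibration and excised from all
#'   channels.
#' @param spr_energy_window_s SPR local-energy window, seconds.
#' @param ecg_fc ECG high-pass cutoff, Hz.
#' @param obstacle_span_m,obstacle_margin_m obstacle length and safety
#'   margin, meters.
#' @param window_s segmentation window, seconds.
#' @param apply_notch logical; the notch can be disabled when the acquisition
#'   chain already applied it.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(notch_low = 46, notch_high = 54,
                              eeg_hp = 4, eeg_lp = 45,
                              asr = asr_params(),
                              amplitude_threshold_uv = 500,
                              spr_energy_window_s = 1,
                              ecg_fc = 0.5,
                              obstacle_span_m = 200,
                              obstacle_margin_m = 500,
                              window_s = 3,
                              apply_notch = TRUE) {
  structure(list(notch_low = notch_low, notch_high = notch_high,
                 eeg_hp = eeg_hp, eeg_lp = eeg_lp, asr = asr,
                 amplitude_threshold_uv = amplitude_threshold_uv,
                 spr_energy_window_s = spr_energy_window_s,
                 ecg_fc = ecg_fc,
                 obstacle_span_m = obstacle_span_m,
                 obstacle_margin_m = obstacle_margin_m,
                 window_s = window_s, apply_notch = apply_notch),
            class = "preprocess_params")
}

# logical keep-mask over the first n samples given obstacle positions;
# intervals are half-open in position: [p - margin, p + span + margin)
obstacle_keep_mask <- function(trace, n, positions_m, span_m, margin_m) {
  pos <- trace$longitudinal_position[seq_len(n)]
  keep <- rep(TRUE, n)
  for (p in positions_m) {
    keep <- keep & !(pos >= p - margin_m & pos < p + span_m + margin_m)
  }
  keep
}

#' Excise obstacle-traversal windows from a recording
#'
#' Removes from every channel all samples whose longitudinal position lies
#' inside `[p - margin, p + span + margin)` for any obstacle start `p`
#' (drivers' evasive maneuvers generate motion artifacts there). The same
#' sample index set is removed from every channel, the remaining samples
#' are concatenated, and the time base is rebuilt.
#'
#' @param rec a [sync_recording] aligned to `trace`.
#' @param trace the [sim_trace] of the session.
#' @param obstacle_positions_m obstacle start positions, meters.
#' @param span_m obstacle length, meters.
#' @param margin_m margin removed before and after, meters.
#' @return the excised [sync_recording].
#' @export
excise_obstacles <- function(rec, trace, obstacle_positions_m,
                             span_m = 200, margin_m = 500) {
  stopifnot(inherits(rec, "sync_recording"), inherits(trace, "sim_trace"))
  n <- nrow(rec$data)
  if (length(trace) < n)
    stop("alignment error: trace shorter than recording")
  keep <- obstacle_keep_mask(trace, n, obstacle_positions_m, span_m, margin_m)
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$time <- (seq_len(nrow(rec$data)) - 1) / rec$fs
  rec
}

#' Construct a cleaned 8-channel session
#'
#' Container for the output of the cleaning chain: six cleaned EEG
#' channels, the fused SPR channel and the filtered ECG channel, with the
#' session's engagement label (0 = manual / high engagement, 1 = ADAS /
#' low engagement).
#'
#' @param data numeric matrix, samples x 8.
#' @param fs sampling rate in Sa/s.
#' @param subject_id,session metadata.
#' @param label engagement class (0 or 1); derived from the session name
#'   when missing.
#' @return an object of class `clean_session`.
#' @export
clean_session <- function(data, fs, subject_id, session, label = NULL) {
  data <- as.matrix(data)
  if (ncol(data) != 8L) stop("clean_session needs 8 channels")
  colnames(data) <- CLEAN_CHANNELS
  if (is.null(label)) label <- if (identical(session, "ADAS")) 1L else 0L
  structure(list(data = data, fs = fs, subject_id = subject_id,
                 session = session, label = as.integer(label)),
            class = "clean_session")
}

#' Cut a cleaned session into labeled non-overlapping segments
#'
#' Consecutive non-overlapping windows of `round(window_s * fs)` samples
#' (600 samples for 3 s at 200 Sa/s); the trailing partial window is
#' dropped. Manual sessions are labeled 0 (high engagement), the
#' autonomous session 1 (low engagement). Windows are cut within one
#' session only, never across excision joints of different sessions.
#'
#' @param clean a [clean_session].
#' @param window_s window length in seconds.
#' @return a [segment_set] (possibly with zero segments).
#' @export
segment_and_label <- function(clean, window_s = 3) {
  stopifnot(inherits(clean, "clean_session"))
  win <- round(window_s * clean$fs)
  n_seg <- nrow(clean$data) %/% win
  if (n_seg == 0) {
    return(segment_set(array(0, dim = c(0, win, 8)), integer(0),
                       character(0), character(0), clean$fs, window_s))
  }
  dat <- array(0, dim = c(n_seg, win, 8))
  for (i in seq_len(n_seg)) {
    dat[i, , ] <- clean$data[((i - 1) * win + 1):(i * win), ]
  }
  segment_set(dat, rep(clean$label, n_seg),
              rep(clean$subject_id, n_seg), rep(clean$session, n_seg),
              clean$fs, window_s)
}

#' Labeled segment collection
#'
#' @param data numeric array, segments x window_samples x 8 channels
#'   (channel order Fp1, Fp2, C3, C4, O1, O2, SPR, ECG).
#' @param label integer vector of engagement classes (0 high / 1 low).
#' @param subject_id,session character vectors parallel to segments.
#' @param fs sampling rate in Sa/s.
#' @param window_s window length in seconds.
#' @return an object of class `segment_set`.
#' @export
segment_set <- function(data, label, subject_id, session, fs, window_s) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 8,
            dim(data)[1] == length(label),
            length(label) == length(subject_id))
  if (length(data) && !all(is.finite(data)))
    stop("segment data contains non-finite values")
  structure(list(data = data, label = as.integer(label),
                 subject_id = as.character(subject_id),
                 session = as.character(session),
                 fs = fs, window_s = window_s),
            class = "segment_set")
}

#' @export
length.segment_set <- function(x) dim(x$data)[1]

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %d samples x 8 channels (%g s at %g Sa/s)\n",
              length(x), dim(x$data)[2], x$window_s, x$fs))
  if (length(x)) {
    cat(sprintf("  subjects: %s\n", paste(unique(x$subject_id), collapse = ", ")))
    tb <- table(factor(x$label, levels = c(0, 1)))
    cat(sprintf("  labels: %d high engagement (0), %d low engagement (1)\n",
                tb[["0"]], tb[["1"]]))
  }
  invisible(x)
}

#' Combine or subset segment sets
#'
#' @param ... segment sets with matching window geometry.
#' @return a single [segment_set].
#' @export
bind_segments <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, length, 1L) > 0]
  if (!length(xs)) stop("nothing to bind")
  win <- dim(xs[[1]]$data)[2]
  stopifnot(all(vapply(xs, function(x) dim(x$data)[2], 1L) == win))
  dat <- array(0, dim = c(sum(vapply(xs, length, 1L)), win, 8))
  off <- 0L
  for (x in xs) {
    dat[off + seq_len(length(x)), , ] <- x$data
    off <- off + length(x)
  }
  segment_set(dat,
              unlist(lapply(xs, `[[`, "label")),
              unlist(lapply(xs, `[[`, "subject_id")),
              unlist(lapply(xs, `[[`, "session")),
              xs[[1]]$fs, xs[[1]]$window_s)
}

#' @rdname bind_segments
#' @param x a [segment_set].
#' @param idx integer or logical index over segments.
#' @export
subset_segments <- function(x, idx) {
  segment_set(x$data[idx, , , drop = FALSE], x$label[idx],
              x$subject_id[idx], x$session[idx], x$fs, x$window_s)
}

#' Run the full cleaning chain on one session
#'
#' Fixed pipeline order: zero-gap repair and trace alignment, notch on all
#' channels, then in parallel EEG band-limiting plus ASR, SPR local-energy
#' fusion, and ECG lead selection plus high-pass; finally obstacle-window
#' excision (together with amplitude-rejected blocks) and segmentation.
#' All channels keep identical lengths after every stage, and excision
#' removes the same sample index set from every channel.
#'
#' @param rec a [sync_recording].
#' @param trace the session's [sim_trace].
#' @param obstacle_positions_m obstacle start positions, meters.
#' @param params a [preprocess_params].
#' @param segment logical; return segments (default) or the cleaned
#'   [clean_session] when `FALSE`.
#' @return a [segment_set] or a [clean_session].
#' @export
preprocess_session <- function(rec, trace, obstacle_positions_m = numeric(0),
                               params = preprocess_params(),
                               segment = TRUE) {
  stopifnot(inherits(rec, "sync_recording"))
  fs <- rec$fs
  rec <- interpolate_zero_gaps(rec)
  rec <- align_to_sim(rec, trace)
  x <- rec$data
  if (params$apply_notch) {
    x <- apply(x, 2, notch_filter, fs = fs,
               low = params$notch_low, high = params$notch_high)
  }
  eeg <- eeg_bandlimit(x[, EEG_CHANNELS], fs,
                       hp = params$eeg_hp, lp = params$eeg_lp)

  # automated stand-in for visual inspection: flag 1 s blocks with extreme
  # amplitude; they are excluded from ASR calibration and excised later
  n <- nrow(x)
  blk <- fs
  flagged <- rep(FALSE, n)
  n_blk <- n %/% blk
  for (b in seq_len(n_blk)) {
    idx <- ((b - 1L) * blk + 1L):(b * blk)
    if (max(abs(eeg[idx, ])) > params$amplitude_threshold_uv)
      flagged[idx] <- TRUE
  }
  eeg <- asr_clean(eeg, fs, params$asr, exclude = flagged)
  spr <- spr_fuse(x[, "SPR1"], x[, "SPR2"], fs,
                  energy_window_s = params$spr_energy_window_s)
  sel <- ecg_select(x[, "ECG1"], x[, "ECG2"], fs)
  ecg <- ecg_highpass(sel$signal, fs, fc = params$ecg_fc)

  clean <- cbind(eeg, SPR = spr, ECG = ecg)
  keep <- obstacle_keep_mask(trace, n, obstacle_positions_m,
                             params$obstacle_span_m,
                             params$obstacle_margin_m) & !flagged
  clean <- clean[keep, , drop = FALSE]
  cs <- clean_session(clean, fs, rec$subject_id, rec$session)
  if (segment) segment_and_label(cs, params$window_s) else cs
}

#' Preprocess a whole cohort
#'
#' Applies [preprocess_session()] to every session of an in-memory cohort
#' (as returned by [generate_cohort()]) and binds the segments.
#'
#' @param cohort list with `subjects` and `config` (see [generate_cohort()]).
#' @param params a [preprocess_params].
#' @param segment logical; segments (default) or cleaned sessions.
#' @param verbose print per-stage sample counts.
#' @return a [segment_set], or a list of [clean_session] objects.
#' @export
preprocess_cohort <- function(cohort, params = preprocess_params(),
                              segment = TRUE, verbose = FALSE) {
  obstacles <- cohort$config$obstacle_positions_m
  out <- list()
  for (sid in names(cohort$subjects)) {
    sub <- cohort$subjects[[sid]]
    for (sname in names(sub$recordings)) {
      res <- preprocess_session(sub$recordings[[sname]],
                                sub$traces[[sname]],
                                obstacle_positions_m = obstacles,
                                params = params, segment = segment)
      if (verbose) {
        n_raw <- nrow(sub$recordings[[sname]]$data)
        n_out <- if (segment) length(res) else nrow(res$data)
        message(sprintf("%s/%s: %d raw samples -> %s", sid, sname, n_raw,
                        if (segment) paste(n_out, "segments")
                        else paste(n_out, "cleaned samples")))
      }
      out[[paste(sid, sname, sep = "/")]] <- res
    }
  }
  if (segment) do.call(bind_segments, out) else out
}

#' Segment a list of cleaned sessions at a given window length
#'
#' Used by the window-length sweep: re-cuts already cleaned sessions
#' without re-running the filters.
#'
#' @param clean_list list of [clean_session] objects.
#' @param window_s window length in seconds.
#' @return a [segment_set].
#' @export
segment_cohort <- function(clean_list, window_s = 3) {
  do.call(bind_segments, lapply(clean_list, segment_and_label,
                                window_s = window_s))
}

#' Save / load a segment archive
#'
#' Segments are stored as a columnar container (the data array plus the
#' parallel label, subject and session vectors) in RDS form.
#'
#' @param segments a [segment_set].
#' @param path file path.
#' @return `read_segments()` returns the [segment_set].
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_set"))
  saveRDS(segments, path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "segment_set"))
  x
}
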