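#' Construct a synchronized multimodal recording
#'
#' A `sync_recording` holds one subject-session of the ten synchronized
#' biosignal channels (six EEG in microvolts, two SPR and two ECG in
#' millivolts) sampled on a common time base, normally at 200 Sa/s.
#'
#' @param data numeric matrix or data frame with the ten signal columns
#'   `Fp1, Fp2, C3, C4, O1, O2, SPR1, SPR2, ECG1, ECG2` (in this order).
#' @param fs sampling rate in Sa/s.
#' @param subject_id subject identifier string.
#' @param session session name, one of `"Manual1"`, `"Manual2"`, `"Manual3"`,
#'   `"ADAS"` (or another label for non-protocol data).
#' @param time optional time vector in seconds; rebuilt as `(0:(n-1))/fs`
#'   when omitted.
#' @return an object of class `sync_recording`: a list with elements
#'   `time`, `data` (n x 10 numeric matrix), `fs`, `subject_id`, `session`.
#' @export
sync_recording <- function(data, fs = 200, subject_id = "S01",
                           session = "Manual1", time = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) != 10L)
    stop("sync_recording needs 10 signal columns, got ", ncol(data))
  colnames(data) <- SYNC_COLUMNS[-1]
  if (is.null(time)) time <- (seq_len(nrow(data)) - 1) / fs
  if (length(time) != nrow(data))
    stop("time vector length does not match number of samples")
  structure(list(time = as.numeric(time), data = data, fs = fs,
                 subject_id = subject_id, session = session),
            class = "sync_recording")
}

#' @export
print.sync_recording <- function(x, ...) {
  cat(sprintf("<sync_recording> subject %s, session %s\n", x$subject_id, x$session))
  cat(sprintf("  %d samples at %g Sa/s (%.1f s), 10 channels\n",
              nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' @export
length.sync_recording <- function(x) nrow(x$data)

#' Read a synchronized recording from CSV
#'
#' The file dialect is comma-separated with a header row holding the eleven
#' canonical columns `time,Fp1,Fp2,C3,C4,O1,O2,SPR1,SPR2,ECG1,ECG2` in that
#' order. Values are parsed as floating point; no reordering or resampling is
#' performed, and the sampling rate is inferred from the median time step.
#'
#' @param path path to the CSV file.
#' @param subject_id,session metadata attached to the returned recording.
#' @return a [sync_recording].
#' @export
read_sync_csv <- function(path, subject_id = "S01", session = "Manual1") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  if (!identical(names(df), SYNC_COLUMNS)) {
    bad <- if (length(names(df)) != length(SYNC_COLUMNS)) {
      setdiff(union(names(df), SYNC_COLUMNS),
              intersect(names(df), SYNC_COLUMNS))
    } else names(df)[names(df) != SYNC_COLUMNS]
    stop("format error: column mismatch, offending column(s): ",
         paste(bad, collapse = ", "))
  }
  num <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df)), USE.NAMES = TRUE))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(df)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("parse error: non-numeric value in column '%s' at row %d",
                 colnames(num)[idx[1, 2]], idx[1, 1]))
  }
  tm <- num[, 1]
  fs <- if (length(tm) > 1) round(1 / stats::median(diff(tm))) else 200
  sync_recording(num[, -1, drop = FALSE], fs = fs, subject_id = subject_id,
                 session = session, time = tm)
}

#' Write a synchronized recording to CSV
#'
#' Inverse of [read_sync_csv()]; the round trip is lossless for finite values
#' (values are written with full double precision).
#'
#' @param rec a [sync_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sync_csv <- function(rec, path) {
  stopifnot(inherits(rec, "sync_recording"))
  df <- data.frame(time = rec$time, rec$data, check.names = FALSE)
  names(df) <- SYNC_COLUMNS
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a driving-simulator trace
#'
#' Vehicle-dynamics trace with longitudinal (along-track, meters,
#' non-decreasing) and lateral positions, sampled at the biosignal rate.
#'
#' @param longitudinal_position numeric vector, meters along the track.
#' @param lateral_position numeric vector (defaults to zeros).
#' @param fs sampling rate in Sa/s.
#' @param time optional time vector in seconds.
#' @return an object of class `sim_trace`.
#' @export
sim_trace <- function(longitudinal_position, lateral_position = NULL,
                      fs = 200, time = NULL) {
  n <- length(longitudinal_position)
  if (is.null(lateral_position)) lateral_position <- numeric(n)
  if (is.null(time)) time <- (seq_len(n) - 1) / fs
  if (is.unsorted(longitudinal_position))
    stop("longitudinal_position must be non-decreasing")
  structure(list(time = time,
                 longitudinal_position = as.numeric(longitudinal_position),
                 lateral_position = as.numeric(lateral_position), fs = fs),
            class = "sim_trace")
}

#' @export
length.sim_trace <- function(x) length(x$longitudinal_position)

#' Read / write simulator traces
#'
#' CSV dialect with header `time,longitudinal_position,lateral_position`.
#'
#' @param path file path.
#' @return [read_sim_csv()] returns a [sim_trace]; [write_sim_csv()] returns
#'   `path` invisibly.
#' @export
read_sim_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("time", "longitudinal_position", "lateral_position")
  if (!identical(names(df), need))
    stop("format error: expected columns ", paste(need, collapse = ","))
  fs <- if (nrow(df) > 1) round(1 / stats::median(diff(df$time))) else 200
  sim_trace(df$longitudinal_position, df$lateral_position, fs = fs,
            time = df$time)
}

#' @rdname read_sim_csv
#' @param trace a [sim_trace].
#' @export
write_sim_csv <- function(trace, path) {
  df <- data.frame(time = trace$time,
                   longitudinal_position = trace$longitudinal_position,
                   lateral_position = trace$lateral_position)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Repair dropped-sample zero runs by linear interpolation
#'
#' The acquisition GUI inserts literal zeros when a sensor packet is missed.
#' Every maximal run of exactly-zero samples (of length at least
#' `min_run_length`) strictly interior to a channel is replaced by linear
#' interpolation between the nearest nonzero neighbors; leading and trailing
#' zero runs are replaced by the nearest nonzero value. Channels without
#' zeros are returned unchanged, and the operation is idempotent.
#'
#' @param rec a [sync_recording].
#' @param min_run_length minimum zero-run length treated as dropped samples;
#'   the default 1 also repairs isolated zeros (biological signals are almost
#'   surely nonzero at float resolution).
#' @return the repaired [sync_recording].
#' @export
interpolate_zero_gaps <- function(rec, min_run_length = 1L) {
  stopifnot(inherits(rec, "sync_recording"))
  x <- rec$data
  for (j in seq_len(ncol(x))) {
    x[, j] <- interp_zero_runs_1d(x[, j], min_run_length,
                                  colnames(x)[j])
  }
  rec$data <- x
  rec
}

interp_zero_runs_1d <- function(v, min_run_length, name) {
  zero <- v == 0
  if (!any(zero)) return(v)
  if (all(zero)) stop("unrecoverable channel: '", name, "' is entirely zero")
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(v)
  for (k in which(r$values & r$lengths >= min_run_length)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L) {                       # leading run: constant extrapolation
      v[i0:i1] <- v[i1 + 1L]
    } else if (i1 == n) {                 # trailing run
      v[i0:i1] <- v[i0 - 1L]
    } else {                              # interior run: linear interpolation
      a <- v[i0 - 1L]; b <- v[i1 + 1L]
      w <- seq_len(i1 - i0 + 1L) / (i1 - i0 + 2L)
      v[i0:i1] <- a + (b - a) * w
    }
  }
  v
}

#' Align a recording to the simulator trace duration
#'
#' The simulator CSV length defines the session duration (the host clock is
#' more reliable than the sensor clocks), so the recording is truncated to
#' the trace's sample count and its time base rebuilt from zero with step
#' `1/fs`. Sample values are never modified. A recording shorter than the
#' trace by more than `tol_s` seconds raises an alignment error; a smaller
#' deficit keeps the recording's own length.
#'
#' @param rec a [sync_recording].
#' @param trace a [sim_trace] started synchronously with `rec`.
#' @param tol_s tolerated deficit in seconds (default 1).
#' @return the aligned [sync_recording].
#' @export
align_to_sim <- function(rec, trace, tol_s = 1) {
  stopifnot(inherits(rec, "sync_recording"), inherits(trace, "sim_trace"))
  n_rec <- nrow(rec$data)
  n_tr <- length(trace)
  if (n_rec < n_tr - tol_s * rec$fs)
    stop(sprintf("alignment error: recording (%d samples) shorter than trace (%d) by more than %g s",
                 n_rec, n_tr, tol_s))
  n <- min(n_rec, n_tr)
  rec$data <- rec$data[seq_len(n), , drop = FALSE]
  rec$time <- (seq_len(n) - 1) / rec$fs
  rec
}
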