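#' Configuration for a synthetic driving cohort
#'
#' Defines the study conditions emulated by the generator: a cohort of
#' subjects who each complete three ~7 min manual driving sessions on a
#' highway with six road-works obstacles (200 m span, 2 km apart, first at
#' 2 km, driven at ~120 km/h) and one ~20 min autonomous (ADAS) session.
#' Manual driving induces high mental engagement, autonomous driving low
#' engagement; the generator encodes that contrast as class-dependent EEG
#' band powers (frontal theta up, occipital alpha down under high
#' engagement), heart rate, and electrodermal phasic event rate.
#'
#' @param n_subjects number of subjects (study condition: 19).
#' @param fs sampling rate in Sa/s.
#' @param n_manual_sessions number of manual sessions per subject.
#' @param manual_duration_s nominal manual session duration, seconds.
#' @param manual_duration_jitter_s uniform jitter on manual durations,
#'   seconds (sessions last "approximately" 7 min).
#' @param adas_duration_s autonomous session duration, seconds.
#' @param obstacle_positions_m start positions of the obstacles, meters.
#' @param obstacle_span_m obstacle length, meters.
#' @param mean_speed_mps mean longitudinal speed, m/s (~120 km/h).
#' @param eeg_effect relative engagement shift of EEG band powers: under
#'   high engagement frontal theta power is multiplied by `1 + eeg_effect`
#'   and occipital alpha power divided by it. 0 removes the EEG contrast.
#' @param hr_manual_bpm,hr_adas_bpm heart rate per class, beats/min.
#' @param spr_rate_manual_per_min,spr_rate_adas_per_min phasic skin
#'   potential response rate per class, events/min.
#' @param blink_rate_per_min eye-blink artifact rate on Fp1/Fp2.
#' @param drift_amplitude_uv RMS of low-frequency drift artifact on C3/C4,
#'   microvolts.
#' @param pop_rate_per_min electrode pop/displacement artifact rate on O1/O2.
#' @param spr_spike_rate_per_min motion-spike artifact rate on one SPR
#'   channel at a time.
#' @param ecg_wander_mv amplitude of respiration-band baseline wander added
#'   to the ECG leads, millivolts (0 disables).
#' @param zero_gap_rate_per_min rate of dropped-packet zero runs per sensor
#'   group.
#' @param zero_gap_max_samples maximum zero-run length, samples.
#' @param extra_rec_s maximum surplus recording duration beyond the
#'   simulator trace (the acquisition dataset runs slightly long), seconds.
#' @param seed integer seed; together with the config it fully determines
#'   the generated cohort.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 19L, fs = 200,
                          n_manual_sessions = 3L,
                          manual_duration_s = 420,
                          manual_duration_jitter_s = 15,
                          adas_duration_s = 1200,
                          obstacle_positions_m = seq(2000, by = 2000,
                                                     length.out = 6),
                          obstacle_span_m = 200,
                          mean_speed_mps = 33.3,
                          eeg_effect = 0.5,
                          hr_manual_bpm = 85, hr_adas_bpm = 70,
                          spr_rate_manual_per_min = 6,
                          spr_rate_adas_per_min = 1.5,
                          blink_rate_per_min = 14,
                          drift_amplitude_uv = 40,
                          pop_rate_per_min = 0.5,
                          spr_spike_rate_per_min = 1,
                          ecg_wander_mv = 0.25,
                          zero_gap_rate_per_min = 0.2,
                          zero_gap_max_samples = 30L,
                          extra_rec_s = 0.5,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), fs = fs,
              n_manual_sessions = as.integer(n_manual_sessions),
              manual_duration_s = manual_duration_s,
              manual_duration_jitter_s = manual_duration_jitter_s,
              adas_duration_s = adas_duration_s,
              obstacle_positions_m = obstacle_positions_m,
              obstacle_span_m = obstacle_span_m,
              mean_speed_mps = mean_speed_mps,
              eeg_effect = eeg_effect,
              hr_manual_bpm = hr_manual_bpm, hr_adas_bpm = hr_adas_bpm,
              spr_rate_manual_per_min = spr_rate_manual_per_min,
              spr_rate_adas_per_min = spr_rate_adas_per_min,
              blink_rate_per_min = blink_rate_per_min,
              drift_amplitude_uv = drift_amplitude_uv,
              pop_rate_per_min = pop_rate_per_min,
              spr_spike_rate_per_min = spr_spike_rate_per_min,
              ecg_wander_mv = ecg_wander_mv,
              zero_gap_rate_per_min = zero_gap_rate_per_min,
              zero_gap_max_samples = as.integer(zero_gap_max_samples),
              extra_rec_s = extra_rec_s,
              seed = as.integer(seed))
  if (cfg$n_subjects < 1L) stop("config error: n_subjects must be >= 1")
  if (cfg$manual_duration_s <= 0 || cfg$adas_duration_s <= 0 || cfg$fs <= 0)
    stop("config error: durations and fs must be positive")
  if (cfg$n_manual_sessions < 1L)
    stop("config error: need at least one manual session")
  structure(cfg, class = "cohort_config")
}

session_names <- function(cfg) {
  c(paste0("Manual", seq_len(cfg$n_manual_sessions)), "ADAS")
}

# deterministic per-(subject, session, purpose) substream seed, < 2^31
derive_seed <- function(seed, subject_offset, session_idx, purpose = 0L) {
  (abs(seed) %% 65011) * 33013 + subject_offset * 1021 +
    session_idx * 131 + purpose * 17
}

# unit-RMS Gaussian noise with FFT-shaped amplitude spectrum; computed at
# the next highly-composite length and truncated, so the transforms stay
# O(n log n) for arbitrary durations
fft_shaped_noise <- function(n, fs, gain_fun) {
  np <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(np)
  wf <- stats::fft(w)
  k <- seq_len(np) - 1
  freq <- ifelse(k <= np / 2, k, k - np) * fs / np
  g <- gain_fun(abs(freq))
  x <- Re(stats::fft(wf * g, inverse = TRUE))[seq_len(n)] / np
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

band_noise <- function(n, fs, lo, hi) {
  fft_shaped_noise(n, fs, function(f) as.numeric(f >= lo & f <= hi))
}

pink_noise <- function(n, fs) {
  fft_shaped_noise(n, fs, function(f) 1 / sqrt(pmax(f, 0.5)))
}

slow_noise <- function(n, fs, hi = 0.1) {
  fft_shaped_noise(n, fs, function(f) as.numeric(f > 0 & f <= hi))
}

# one EEG channel in microvolts: 1/f background + class-weighted rhythms
synth_eeg_channel <- function(n, fs, channel, high_engagement, eeg_effect) {
  frontal <- channel %in% c("Fp1", "Fp2")
  occipital <- channel %in% c("O1", "O2")
  p_delta <- 4
  p_theta <- 4
  p_alpha <- if (occipital) 9 else 4
  p_beta <- 2.5
  if (high_engagement) {
    if (frontal) p_theta <- p_theta * sqrt(1 + eeg_effect)
    if (occipital) p_alpha <- p_alpha / sqrt(1 + eeg_effect)
    p_beta <- p_beta * sqrt(1 + 0.5 * eeg_effect)
  }
  p_delta * band_noise(n, fs, 1, 4) +
    p_theta * band_noise(n, fs, 4, 8) +
    p_alpha * band_noise(n, fs, 8, 13) +
    p_beta * band_noise(n, fs, 13, 30) +
    3 * pink_noise(n, fs)
}

# PQRST train in millivolts at a given heart rate with RR jitter
synth_ecg <- function(n, fs, hr_bpm, rr_jitter = 0.03) {
  dur <- n / fs
  rr_mean <- 60 / hr_bpm
  n_beats <- ceiling(dur / rr_mean) + 3L
  rr <- rr_mean * (1 + rr_jitter * stats::rnorm(n_beats))
  rr <- pmax(rr, 0.3)
  beats <- cumsum(c(stats::runif(1, 0, rr_mean), rr[-1]))
  beats <- beats[beats < dur + 0.5]
  x <- numeric(n)
  comps <- list(c(0.15, -0.20, 0.030),   # P
                c(-0.15, -0.025, 0.012), # Q
                c(1.00, 0.00, 0.012),    # R
                c(-0.25, 0.030, 0.014),  # S
                c(0.35, 0.25, 0.060))    # T
  t <- (seq_len(n) - 1) / fs
  for (b in beats) {
    i0 <- max(1L, floor((b - 0.4) * fs)); i1 <- min(n, ceiling((b + 0.5) * fs))
    if (i0 > i1) next
    tt <- t[i0:i1] - b
    seg <- 0
    for (cmp in comps) seg <- seg + cmp[1] * exp(-(tt - cmp[2])^2 / (2 * cmp[3]^2))
    x[i0:i1] <- x[i0:i1] + seg
  }
  x
}

# phasic electrodermal response: fast rise, slow exponential decay
spr_phasic_template <- function(fs, dur_s = 6) {
  t <- seq(0, dur_s, by = 1 / fs)
  v <- exp(-t / 2.5) - exp(-t / 0.3)
  v / max(v)
}

# shared SPR activity (tonic + phasic, millivolts) before per-hand noise
synth_spr_shared <- function(n, fs, rate_per_min) {
  tonic <- 0.8 * slow_noise(n, fs, hi = 0.05)
  x <- tonic
  if (rate_per_min > 0) {
    dur_min <- n / fs / 60
    k <- stats::rpois(1, rate_per_min * dur_min)
    if (k > 0) {
      onsets <- sort(stats::runif(k, 0, n / fs - 1))
      tmpl <- spr_phasic_template(fs)
      for (on in onsets) {
        amp <- 0.6 * stats::runif(1, 0.6, 1.4)
        i0 <- floor(on * fs) + 1L
        i1 <- min(n, i0 + length(tmpl) - 1L)
        x[i0:i1] <- x[i0:i1] + amp * tmpl[seq_len(i1 - i0 + 1L)]
      }
    }
  }
  x
}

# simulator trace: near-constant speed with slow fluctuation
synth_trace <- function(n, fs, mean_speed) {
  v <- mean_speed * (1 + 0.05 * slow_noise(n, fs, hi = 0.05))
  v <- pmax(v, 1)
  pos <- cumsum(v) / fs
  pos <- pos - pos[1]
  sim_trace(pos, 0.2 * slow_noise(n, fs, hi = 0.2), fs = fs)
}

#' Generate one subject's four sessions
#'
#' Produces the three manual sessions and the autonomous (ADAS) session for
#' one subject: synchronized 10-channel recordings, matching simulator
#' traces, and the ground truth used by downstream tests (per-session
#' engagement class, obstacle sample windows, injected artifact locations).
#' EEG channels are sums of band-limited rhythms over a 1/f background with
#' class-dependent band powers; ECG is a Gaussian-bump PQRST train at the
#' class heart rate with RR jitter; the two SPR channels share one tonic +
#' phasic process and differ in per-hand noise and artifacts.
#'
#' @param config a [cohort_config].
#' @param subject_id subject identifier string.
#' @param seed_offset integer offset identifying the subject's random
#'   substream.
#' @param artifacts logical; inject artifacts and zero gaps (default TRUE).
#' @return a list with elements `recordings` (list of [sync_recording]),
#'   `traces` (list of [sim_trace]) and `truth` (per-session ground truth).
#' @export
generate_subject <- function(config, subject_id, seed_offset = 0L,
                             artifacts = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  fs <- config$fs
  sessions <- session_names(config)
  recordings <- list(); traces <- list(); truth <- list()
  for (si in seq_along(sessions)) {
    sname <- sessions[si]
    manual <- sname != "ADAS"
    set.seed(derive_seed(config$seed, seed_offset, si, 0L))
    dur <- if (manual) {
      config$manual_duration_s +
        stats::runif(1, -1, 1) * config$manual_duration_jitter_s
    } else config$adas_duration_s
    n <- round(dur * fs)
    extra <- if (config$extra_rec_s > 0)
      sample.int(max(1L, round(config$extra_rec_s * fs)), 1L) else 0L
    n_rec <- n + extra
    trace <- synth_trace(n, fs, config$mean_speed_mps)

    eeg <- vapply(EEG_CHANNELS, function(ch)
      synth_eeg_channel(n_rec, fs, ch, manual, config$eeg_effect),
      numeric(n_rec))
    hr <- if (manual) config$hr_manual_bpm else config$hr_adas_bpm
    ecg0 <- synth_ecg(n_rec, fs, hr)
    ecg <- cbind(ECG1 = ecg0 + 0.02 * stats::rnorm(n_rec),
                 ECG2 = 0.75 * ecg0 + 0.02 * stats::rnorm(n_rec))
    rate <- if (manual) config$spr_rate_manual_per_min else
      config$spr_rate_adas_per_min
    spr0 <- synth_spr_shared(n_rec, fs, rate)
    spr <- cbind(SPR1 = spr0 + 0.02 * stats::rnorm(n_rec),
                 SPR2 = spr0 + 0.02 * stats::rnorm(n_rec))

    rec <- sync_recording(cbind(eeg, spr, ecg), fs = fs,
                          subject_id = subject_id, session = sname)
    gt <- list(session = sname, subject_id = subject_id,
               class = if (manual) 0L else 1L,
               obstacle_windows = obstacle_sample_windows(
                 trace, config$obstacle_positions_m,
                 config$obstacle_span_m, margin_m = 0),
               artifacts = NULL)
    if (artifacts) {
      ia <- inject_artifacts(rec, config,
                             seed = derive_seed(config$seed, seed_offset,
                                                si, 1L))
      rec <- ia$recording
      gt$artifacts <- ia$truth
    }
    recordings[[sname]] <- rec
    traces[[sname]] <- trace
    truth[[sname]] <- gt
  }
  list(recordings = recordings, traces = traces, truth = truth)
}

# sample index windows [start, end) where the vehicle is inside
# [p - margin, p + span + margin) for each obstacle start p
obstacle_sample_windows <- function(trace, positions_m, span_m, margin_m) {
  pos <- trace$longitudinal_position
  out <- list()
  for (p in positions_m) {
    inside <- pos >= (p - margin_m) & pos < (p + span_m + margin_m)
    if (!any(inside)) next
    out[[length(out) + 1L]] <- c(start = min(which(inside)),
                                 end = max(which(inside)) + 1L)
  }
  out
}

#' Inject artifacts into a recording
#'
#' Adds the artifact classes seen in real sessions at the configured rates:
#' blink transients on Fp1/Fp2, low-frequency drift on C3/C4, electrode
#' pop/step artifacts on O1/O2, motion spikes on one SPR channel at a time,
#' respiration-band baseline wander on the ECG leads, and dropped-packet
#' zero runs (exact zeros) per sensor group. All rates 0 returns the input
#' unchanged. The returned ground truth records every injected location.
#'
#' @param rec a [sync_recording].
#' @param config a [cohort_config] carrying the artifact rates.
#' @param seed integer seed for the artifact substream.
#' @return list with `recording` (corrupted copy) and `truth` (locations).
#' @export
inject_artifacts <- function(rec, config, seed = 0L) {
  stopifnot(inherits(rec, "sync_recording"))
  set.seed(seed)
  fs <- rec$fs
  n <- nrow(rec$data)
  dur_min <- n / fs / 60
  x <- rec$data
  truth <- list(blinks = integer(0), pops = integer(0),
                drift_channels = character(0),
                spr_spikes = list(), zero_gaps = list())

  poisson_onsets <- function(rate_per_min) {
    k <- stats::rpois(1, max(rate_per_min, 0) * dur_min)
    if (k == 0) return(integer(0))
    sort(sample.int(n - 2 * fs, k) + fs)
  }

  if (config$blink_rate_per_min > 0) {
    on <- poisson_onsets(config$blink_rate_per_min)
    tmpl <- 120 * exp(-((seq(-0.15, 0.15, by = 1 / fs))^2) / (2 * 0.05^2))
    for (i in on) {
      idx <- i:(i + length(tmpl) - 1L)
      amp <- stats::runif(1, 0.7, 1.3)
      x[idx, "Fp1"] <- x[idx, "Fp1"] + amp * tmpl
      x[idx, "Fp2"] <- x[idx, "Fp2"] + 0.9 * amp * tmpl
    }
    truth$blinks <- on
  }
  if (config$drift_amplitude_uv > 0) {
    for (ch in c("C3", "C4")) {
      x[, ch] <- x[, ch] + config$drift_amplitude_uv * slow_noise(n, fs, 0.3)
    }
    truth$drift_channels <- c("C3", "C4")
  }
  if (config$pop_rate_per_min > 0) {
    on <- poisson_onsets(config$pop_rate_per_min)
    for (i in on) {
      decay <- 180 * sign(stats::rnorm(1)) *
        exp(-(seq_len(min(3 * fs, n - i + 1L)) - 1) / (1.0 * fs))
      ch <- sample(c("O1", "O2"), 1)
      x[i:(i + length(decay) - 1L), ch] <-
        x[i:(i + length(decay) - 1L), ch] + decay
    }
    truth$pops <- on
  }
  if (config$spr_spike_rate_per_min > 0) {
    on <- poisson_onsets(config$spr_spike_rate_per_min)
    tmpl <- 2.5 * exp(-abs(seq(-0.2, 0.2, by = 1 / fs)) / 0.04)
    hand <- 1L
    for (i in on) {
      ch <- SPR_CHANNELS[hand]
      idx <- i:(i + length(tmpl) - 1L)
      x[idx, ch] <- x[idx, ch] + tmpl * stats::runif(1, 0.6, 1.4)
      truth$spr_spikes[[length(truth$spr_spikes) + 1L]] <-
        list(channel = ch, start = i, end = i + length(tmpl))
      hand <- 3L - hand  # alternate hands
    }
  }
  if (config$ecg_wander_mv > 0) {
    t <- (seq_len(n) - 1) / fs
    wander <- config$ecg_wander_mv *
      sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi)) +
      0.3 * config$ecg_wander_mv * slow_noise(n, fs, 0.15)
    x[, "ECG1"] <- x[, "ECG1"] + wander
    x[, "ECG2"] <- x[, "ECG2"] + 0.8 * wander
  }
  if (config$zero_gap_rate_per_min > 0) {
    groups <- list(eeg = EEG_CHANNELS, spr1 = "SPR1", spr2 = "SPR2",
                   ecg = ECG_CHANNELS)
    for (g in names(groups)) {
      on <- poisson_onsets(config$zero_gap_rate_per_min)
      for (i in on) {
        len <- sample(4:config$zero_gap_max_samples, 1)
        i1 <- min(n, i + len - 1L)
        x[i:i1, groups[[g]]] <- 0
        truth$zero_gaps[[length(truth$zero_gaps) + 1L]] <-
          list(channels = groups[[g]], start = i, end = i1 + 1L)
      }
    }
  }
  rec$data <- x
  list(recording = rec, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Runs [generate_subject()] for every subject of the configuration. With
#' `path = NULL` the cohort is returned in memory; with a path, one folder
#' per subject is written containing the session CSVs (the synchronized
#' recording dialect), the simulator trace CSVs, a ground-truth JSON
#' sidecar per session, and a cohort-level `manifest.json` recording the
#' config, seed and package version. Output is fully determined by the
#' config seed.
#'
#' @param config a [cohort_config].
#' @param path optional output directory.
#' @param artifacts logical, forwarded to [generate_subject()].
#' @return invisibly, a list with `subjects` (named list of per-subject
#'   results) and `config`; when `path` is given, also `path`.
#' @export
generate_cohort <- function(config, path = NULL, artifacts = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  subjects <- list()
  for (i in seq_along(ids)) {
    subjects[[ids[i]]] <- generate_subject(config, ids[i], seed_offset = i,
                                           artifacts = artifacts)
  }
  out <- list(subjects = subjects, config = config)
  if (!is.null(path)) {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
      stop("I/O error: cannot create output directory ", path)
    for (sid in ids) {
      sdir <- file.path(path, sid)
      dir.create(sdir, showWarnings = FALSE)
      sub <- subjects[[sid]]
      for (sname in names(sub$recordings)) {
        write_sync_csv(sub$recordings[[sname]],
                       file.path(sdir, paste0(sname, ".csv")))
        write_sim_csv(sub$traces[[sname]],
                      file.path(sdir, paste0(sname, "_trace.csv")))
        jsonlite::write_json(sub$truth[[sname]],
                             file.path(sdir, paste0(sname, "_truth.json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    manifest <- list(config = unclass(config), seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("engagefuse")),
                     created = "synthetic cohort")
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$path <- path
  }
  invisible(out)
}
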