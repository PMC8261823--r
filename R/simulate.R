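#' Configuration for the synthetic recording simulator
#'
#' The simulator emulates the statistical structure of clinical wearable
#' recordings: slow electrode baseline drift, measurement noise, sporadic
#' step-like ordinary eye movements (saccades), seconds-long predominantly
#' vertical oscillatory nystagmus bursts that begin only after a supine head
#' manoeuvre, supine episodes without nystagmus (class 2), and extreme class
#' imbalance. Defaults target the clinical regime: a single 3-30 s episode
#' in a 12 h recording gives an expected nystagmus fraction of about 0.04%
#' of samples, the same order as the roughly 0.03% observed clinically.
#'
#' @param duration_s recording length in seconds.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param n_nystagmus_episodes number of nystagmus bursts.
#' @param episode_duration_s length-2 range (s) episode durations are drawn
#'   from.
#' @param nystagmus_freq_hz length-2 range (Hz) of burst oscillation
#'   frequency; 2-5 Hz is typical of positional nystagmus.
#' @param nystagmus_amp burst amplitude of the vertical channel, in units of
#'   `noise_std` (an SNR control).
#' @param vertical_dominance ratio of vertical to horizontal burst amplitude
#'   (> 1; positional nystagmus is mostly vertical).
#' @param n_negative_supine_events supine (Dix-Hallpike-like) episodes
#'   without nystagmus, labelled class 2.
#' @param drift_scale standard deviation of the baseline-wander component
#'   (EOG units); set 0 to disable.
#' @param noise_std white measurement noise standard deviation (EOG units).
#' @param saccade_rate_hz Poisson rate of step-like gaze shifts; 0 disables.
#' @param n_confuser_episodes oscillatory non-nystagmus eye-movement
#'   episodes (walking-induced vestibulo-ocular oscillation, visual
#'   tracking): bursts matching the nystagmus in frequency band, amplitude
#'   and vertical dominance, but occurring with the wearer upright and
#'   labelled 0. These reproduce the clinical property that eye movement
#'   alone is not distinctive enough to identify positional nystagmus —
#'   only the coincidence with supine posture is.
#' @param confuser_duration_s length-2 range (s) of confuser durations.
#' @param supine_hold_s length-2 range (s) of the supine hold for negative
#'   events.
#' @param accel_noise_g accelerometer noise standard deviation in g; 0 gives
#'   the noise-free unit-gravity orientation trace.
#' @param jerk if TRUE bursts use a sawtooth (jerk-like) waveform instead of
#'   the default enveloped sinusoid.
#' @param fs_eog,fs_accel sampling rates (Hz).
#' @param file_id,subject_id identifiers for the generated recording.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(duration_s = 43200, seed = 1L,
                      n_nystagmus_episodes = 1L,
                      episode_duration_s = c(3, 30),
                      nystagmus_freq_hz = c(2, 5),
                      nystagmus_amp = 4,
                      vertical_dominance = 2.5,
                      n_negative_supine_events = 2L,
                      drift_scale = 5,
                      noise_std = 1,
                      saccade_rate_hz = 0.2,
                      n_confuser_episodes = 12L,
                      confuser_duration_s = c(5, 15),
                      supine_hold_s = c(10, 25),
                      accel_noise_g = 0.02,
                      jerk = FALSE,
                      fs_eog = 41.67, fs_accel = 20,
                      file_id = "sim1", subject_id = "simsubj") {
  cfg <- list(
    duration_s = duration_s, seed = as.integer(seed),
    n_nystagmus_episodes = as.integer(n_nystagmus_episodes),
    episode_duration_s = as.numeric(episode_duration_s),
    nystagmus_freq_hz = as.numeric(nystagmus_freq_hz),
    nystagmus_amp = nystagmus_amp,
    vertical_dominance = vertical_dominance,
    n_negative_supine_events = as.integer(n_negative_supine_events),
    drift_scale = drift_scale, noise_std = noise_std,
    saccade_rate_hz = saccade_rate_hz,
    n_confuser_episodes = as.integer(n_confuser_episodes),
    confuser_duration_s = as.numeric(confuser_duration_s),
    supine_hold_s = as.numeric(supine_hold_s),
    accel_noise_g = accel_noise_g, jerk = isTRUE(jerk),
    fs_eog = fs_eog, fs_accel = fs_accel,
    file_id = as.character(file_id), subject_id = as.character(subject_id))
  class(cfg) <- "SimConfig"
  stopifnot(
    cfg$duration_s > 0,
    cfg$n_nystagmus_episodes >= 0L, cfg$n_negative_supine_events >= 0L,
    length(cfg$episode_duration_s) == 2L,
    all(cfg$episode_duration_s > 0),
    diff(cfg$episode_duration_s) >= 0,
    length(cfg$nystagmus_freq_hz) == 2L, all(cfg$nystagmus_freq_hz > 0),
    cfg$nystagmus_amp > 0, cfg$vertical_dominance >= 1,
    cfg$drift_scale >= 0, cfg$noise_std > 0, cfg$saccade_rate_hz >= 0,
    cfg$n_confuser_episodes >= 0L, all(cfg$confuser_duration_s > 0),
    all(cfg$supine_hold_s > 0), cfg$accel_noise_g >= 0,
    cfg$fs_eog > cfg$fs_accel, cfg$fs_accel > 0)
  cfg
}

#' High-SNR validation preset
#'
#' Short recordings with large, frequent vertical bursts and matched
#' negative supine events: the easy regime used for end-to-end pipeline
#' validation, where the detector is expected to perform well within a small
#' training budget.
#'
#' @inheritParams simConfig
#' @export
easyRegimeConfig <- function(seed = 1L, file_id = "easy1",
                             subject_id = "simsubj",
                             duration_s = 720) {
  simConfig(
    duration_s = duration_s, seed = seed,
    n_nystagmus_episodes = 4L, episode_duration_s = c(18, 25),
    nystagmus_freq_hz = c(2, 5), nystagmus_amp = 8, vertical_dominance = 3,
    n_negative_supine_events = 2L, drift_scale = 5, noise_std = 1,
    saccade_rate_hz = 0.4, n_confuser_episodes = 7L,
    confuser_duration_s = c(6, 14), supine_hold_s = c(10, 18),
    file_id = file_id, subject_id = subject_id)
}

# Dix-Hallpike kinematics are reduced to fixed constants: a 2 s smooth
# rotation of the gravity vector, a 1 s latency between reaching the supine
# pose and burst onset, and a 2 s supine tail after the burst.
.ROT_S <- 2
.LATENCY_S <- 1
.POST_S <- 2
.GAP_S <- 2

# Non-overlapping placement by rejection sampling. spans are the total
# occupied lengths; returns start times (s).
.placeEvents <- function(duration, spans) {
  starts <- numeric(0)
  ends <- numeric(0)
  for (sp in spans) {
    hi <- duration - sp - 1
    if (hi <= 1)
      stop("configuration error: events do not fit within the recording")
    ok <- FALSE
    for (try in seq_len(2000L)) {
      s <- stats::runif(1, 1, hi)
      if (!any(s < ends + .GAP_S & s + sp + .GAP_S > starts)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("configuration error: could not place events without overlap")
    starts <- c(starts, s)
    ends <- c(ends, s + sp)
  }
  starts
}

# Spherical interpolation between unit vectors (keeps |g| = 1 throughout).
.slerp <- function(u, v, a) {
  th <- acos(min(1, max(-1, sum(u * v))))
  (outer(u, sin((1 - a) * th)) + outer(v, sin(a * th))) / sin(th)
}

.UPRIGHT <- c(0, 0, 1)
.SUPINE <- c(sqrt(0.5), 0.5, 0.5)  # supine, 45 degrees yawed; unit norm

#' Simulate one labelled recording
#'
#' Generates an [EogRecording-class] and aligned [LabelTrack-class] under the
#' model described in [simConfig()]: EOG = low-frequency drift + white noise
#' + sporadic saccade steps + enveloped oscillatory bursts during nystagmus
#' episodes (vertical amplitude `vertical_dominance` times the horizontal);
#' the accelerometer is a unit-gravity orientation trace that rotates from
#' upright to a supine, 45-degree-yawed pose over 2 s, holds through each
#' episode, and returns, plus optional noise. Bursts start 1 s after the
#' supine pose is reached. Labels are 1 during bursts, 2 during supine
#' intervals without nystagmus, 0 elsewhere.
#'
#' @param cfg a [simConfig()] object.
#' @return list with elements `recording` and `labels`.
#' @export
simulateRecording <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  dur <- cfg$duration_s
  L <- round(dur * cfg$fs_eog)
  La <- round(dur * cfg$fs_accel)
  tE <- (seq_len(L) - 1L) / cfg$fs_eog
  tA <- (seq_len(La) - 1L) / cfg$fs_accel

  # --- event schedule ---------------------------------------------------
  epDur <- stats::runif(cfg$n_nystagmus_episodes,
                        cfg$episode_duration_s[1], cfg$episode_duration_s[2])
  negDur <- stats::runif(cfg$n_negative_supine_events,
                         cfg$supine_hold_s[1], cfg$supine_hold_s[2])
  confDur <- stats::runif(cfg$n_confuser_episodes,
                          cfg$confuser_duration_s[1],
                          cfg$confuser_duration_s[2])
  posSpan <- .ROT_S + .LATENCY_S + epDur + .POST_S + .ROT_S
  negSpan <- .ROT_S + negDur + .ROT_S
  starts <- .placeEvents(dur, c(posSpan, negSpan, confDur))
  nPos <- cfg$n_nystagmus_episodes
  events <- list()
  for (i in seq_len(nPos)) {
    s <- starts[i]
    events[[i]] <- list(
      rotStart = s, supStart = s + .ROT_S,
      onset = s + .ROT_S + .LATENCY_S,
      offset = s + .ROT_S + .LATENCY_S + epDur[i],
      supEnd = s + .ROT_S + .LATENCY_S + epDur[i] + .POST_S,
      positive = TRUE)
  }
  for (j in seq_len(cfg$n_negative_supine_events)) {
    s <- starts[nPos + j]
    events[[nPos + j]] <- list(
      rotStart = s, supStart = s + .ROT_S,
      onset = NA, offset = NA, supEnd = s + .ROT_S + negDur[j],
      positive = FALSE)
  }

  # --- labels -----------------------------------------------------------
  labels <- integer(L)
  for (ev in events) {
    sup <- tE >= ev$supStart & tE < ev$supEnd
    labels[sup] <- 2L
  }
  for (ev in events) {
    if (ev$positive)
      labels[tE >= ev$onset & tE < ev$offset] <- 1L
  }

  # --- accelerometer (orientation trace) --------------------------------
  orient <- matrix(.UPRIGHT, nrow = 3L, ncol = La)
  for (ev in events) {
    upIdx <- which(tA >= ev$rotStart & tA < ev$supStart)
    if (length(upIdx))
      orient[, upIdx] <- .slerp(.UPRIGHT, .SUPINE,
                                (tA[upIdx] - ev$rotStart) / .ROT_S)
    holdIdx <- which(tA >= ev$supStart & tA < ev$supEnd)
    orient[, holdIdx] <- .SUPINE
    dnIdx <- which(tA >= ev$supEnd & tA < ev$supEnd + .ROT_S)
    if (length(dnIdx))
      orient[, dnIdx] <- .slerp(.SUPINE, .UPRIGHT,
                                (tA[dnIdx] - ev$supEnd) / .ROT_S)
  }
  accel <- orient + matrix(stats::rnorm(3L * La, 0, cfg$accel_noise_g),
                           nrow = 3L)

  # --- EOG components ---------------------------------------------------
  drift <- function() {
    if (cfg$drift_scale <= 0) return(numeric(L))
    rw <- cumsum(stats::rnorm(L))
    lp <- signal::butter(2, min(0.05 / (cfg$fs_eog / 2), 0.99), type = "low")
    d <- as.numeric(signal::filter(lp, rw))
    sdd <- stats::sd(d)
    if (sdd > 0) d / sdd * cfg$drift_scale else d
  }
  saccades <- function() {
    n <- stats::rpois(1, cfg$saccade_rate_hz * dur)
    h <- numeric(L); v <- numeric(L)
    if (n > 0) {
      at <- sort(ceiling(stats::runif(n, 0, L - 1)))
      r <- stats::runif(n, 2, 8) * cfg$noise_std
      phi <- stats::runif(n, 0, 2 * pi)
      ih <- numeric(L); iv <- numeric(L)
      for (k in seq_len(n)) {
        ih[at[k] + 1L] <- ih[at[k] + 1L] + r[k] * cos(phi[k])
        iv[at[k] + 1L] <- iv[at[k] + 1L] + r[k] * sin(phi[k])
      }
      h <- cumsum(ih); v <- cumsum(iv)
    }
    list(h = h, v = v)
  }
  eogH <- drift() + stats::rnorm(L, 0, cfg$noise_std)
  eogV <- drift() + stats::rnorm(L, 0, cfg$noise_std)
  sac <- saccades()
  eogH <- eogH + sac$h
  eogV <- eogV + sac$v

  vAmp <- cfg$nystagmus_amp * cfg$noise_std
  hAmp <- vAmp / cfg$vertical_dominance
  for (ev in events) {
    if (!ev$positive) next
    idx <- which(tE >= ev$onset & tE < ev$offset)
    if (!length(idx)) next
    f <- stats::runif(1, cfg$nystagmus_freq_hz[1], cfg$nystagmus_freq_hz[2])
    ph <- stats::runif(1, 0, 2 * pi)
    tt <- tE[idx] - ev$onset
    wave <- if (cfg$jerk) 2 * ((f * tt + ph / (2 * pi)) %% 1) - 1
            else sin(2 * pi * f * tt + ph)
    # half-second raised-cosine onset/offset ramps
    ramp <- pmin(1, pmin(tt, max(tt) - tt) / 0.5)
    env <- 0.5 - 0.5 * cos(pi * pmin(1, ramp))
    eogV[idx] <- eogV[idx] + vAmp * env * wave
    eogH[idx] <- eogH[idx] + hAmp * env * wave
  }

  # oscillatory non-nystagmus artefacts (walking-induced vestibulo-ocular
  # oscillation, visual tracking): same band, amplitude and vertical
  # dominance as the nystagmus bursts, but with the wearer upright, label 0.
  # In the EOG channels alone these are indistinguishable from nystagmus;
  # only the head orientation separates them.
  nEv <- cfg$n_nystagmus_episodes + cfg$n_negative_supine_events
  for (j in seq_len(cfg$n_confuser_episodes)) {
    onset <- starts[nEv + j]
    idx <- which(tE >= onset & tE < onset + confDur[j])
    if (!length(idx)) next
    f <- stats::runif(1, cfg$nystagmus_freq_hz[1], cfg$nystagmus_freq_hz[2])
    ph <- stats::runif(1, 0, 2 * pi)
    tt <- tE[idx] - onset
    wave <- sin(2 * pi * f * tt + ph)
    ramp <- pmin(1, pmin(tt, max(tt) - tt) / 0.5)
    env <- 0.5 - 0.5 * cos(pi * pmin(1, ramp))
    eogV[idx] <- eogV[idx] + vAmp * env * wave
    eogH[idx] <- eogH[idx] + hAmp * env * wave
  }

  rec <- EogRecording(cfg$file_id, cfg$subject_id,
                      eogH = eogH, eogV = eogV,
                      accelX = accel[1, ], accelY = accel[2, ],
                      accelZ = accel[3, ],
                      fsEog = cfg$fs_eog, fsAccel = cfg$fs_accel)
  list(recording = rec, labels = new("LabelTrack", labels = labels))
}

#' Simulate a dataset of recordings on disk
#'
#' Writes one recording/label file pair per configuration into `outDir` and
#' returns (and writes) the dataset manifest.
#'
#' @param cfgs list of [simConfig()] objects with distinct `file_id`s; at
#'   least 2 so train/test folds are possible.
#' @param outDir output directory (created if needed).
#' @return the manifest data.frame (also written to `outDir/manifest.csv`).
#' @export
simulateDataset <- function(cfgs, outDir) {
  stopifnot(length(cfgs) >= 2L)
  ids <- vapply(cfgs, function(cfg) cfg$file_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate file_ids in simulation configs")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cfgs, function(cfg) {
    sim <- simulateRecording(cfg)
    recPath <- file.path(outDir, paste0(cfg$file_id, ".rec"))
    labPath <- file.path(outDir, paste0(cfg$file_id, ".lab"))
    writeRecording(sim$recording, recPath)
    writeLabels(sim$labels, labPath)
    data.frame(file_id = cfg$file_id, subject_id = cfg$subject_id,
               recording = paste0(cfg$file_id, ".rec"),
               labels = paste0(cfg$file_id, ".lab"))
  })
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  readManifest(file.path(outDir, "manifest.csv"))
}
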