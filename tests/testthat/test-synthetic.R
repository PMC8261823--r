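test_that("event-free configurations yield all-zero labels", {
  sim <- simulateRecording(simConfig(duration_s = 120, seed = 3,
                                     n_nystagmus_episodes = 0L,
                                     n_negative_supine_events = 0L,
                                     n_confuser_episodes = 0L))
  expect_true(all(labelValues(sim$labels) == 0L))
})

test_that("episode counts and durations match the configuration", {
  cfg <- simConfig(duration_s = 600, seed = 11,
                   n_nystagmus_episodes = 2L,
                   episode_duration_s = c(5, 5),
                   n_negative_supine_events = 1L,
                   n_confuser_episodes = 0L)
  sim <- simulateRecording(cfg)
  lab <- labelValues(sim$labels)
  r <- rle(lab)
  runs1 <- which(r$values == 1L)
  expect_length(runs1, 2L)
  expect_true(all(abs(r$lengths[runs1] - 5 * cfg$fs_eog) <= 1))
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- easyRegimeConfig(seed = 9, duration_s = 400)
  a <- simulateRecording(cfg)
  b <- simulateRecording(cfg)
  expect_identical(a$recording@eogH, b$recording@eogH)
  expect_identical(a$recording@accelZ, b$recording@accelZ)
  expect_identical(labelValues(a$labels), labelValues(b$labels))
})

test_that("noise-free gravity magnitude is 1 g at every sample", {
  cfg <- simConfig(duration_s = 300, seed = 21, n_nystagmus_episodes = 2L,
                   episode_duration_s = c(5, 10),
                   n_negative_supine_events = 2L, n_confuser_episodes = 0L,
                   accel_noise_g = 0)
  rec <- simulateRecording(cfg)$recording
  g <- sqrt(rec@accelX^2 + rec@accelY^2 + rec@accelZ^2)
  expect_lt(max(abs(g - 1)), 1e-12)
})

test_that("drift is genuinely below the 0.25 Hz high-pass cut-off", {
  # isolate the drift component: no events, no saccades, negligible noise
  cfg <- simConfig(duration_s = 600, seed = 31,
                   n_nystagmus_episodes = 0L,
                   n_negative_supine_events = 0L, n_confuser_episodes = 0L,
                   saccade_rate_hz = 0, drift_scale = 5, noise_std = 1e-9)
  rec <- simulateRecording(cfg)$recording
  drift <- rec@eogH
  filtered <- highpassFilter(drift, rec@fsEog)
  # skip the causal filter's startup transient
  keep <- -(seq_len(round(10 * rec@fsEog)))
  expect_lt(var(filtered[keep]), 0.1 * var(drift[keep]))
})

test_that("every nystagmus run is preceded within 2 s by supine posture", {
  cfg <- easyRegimeConfig(seed = 17, duration_s = 480)
  sim <- simulateRecording(cfg)
  rec <- sim$recording
  lab <- labelValues(sim$labels)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onsets <- starts[r$values == 1L]
  expect_gt(length(onsets), 0L)
  supine <- c(sqrt(0.5), 0.5, 0.5)
  for (o in onsets) {
    tOn <- (o - 1) / rec@fsEog
    win <- which(abs((seq_along(rec@accelX) - 1) / rec@fsAccel -
                       (tOn - 1)) < 1)
    d <- sqrt((rec@accelX[win] - supine[1])^2 +
              (rec@accelY[win] - supine[2])^2 +
              (rec@accelZ[win] - supine[3])^2)
    expect_lt(min(d), 0.2)
  }
})

test_that("impossible event placements raise a configuration error", {
  expect_error(
    simulateRecording(simConfig(duration_s = 30, seed = 1,
                                n_nystagmus_episodes = 4L,
                                episode_duration_s = c(10, 10),
                                n_confuser_episodes = 0L)),
    "configuration error")
})

test_that("simulateDataset writes parseable files and a manifest", {
  dir <- withr::local_tempdir()
  cfgs <- lapply(1:3, function(i)
    simConfig(duration_s = 30, seed = i, n_nystagmus_episodes = 0L,
              n_negative_supine_events = 0L, n_confuser_episodes = 0L,
              file_id = paste0("f", i)))
  man <- simulateDataset(cfgs, dir)
  expect_identical(nrow(man), 3L)
  rec <- readRecording(man$recording[2])
  expect_identical(fileId(rec), "f2")
  lab <- readLabels(man$labels[2], rec)
  expect_length(labelValues(lab), length(rec@eogH))
  # distinct seeds give pairwise distinct signals
  r1 <- readRecording(man$recording[1])
  expect_false(identical(r1@eogH, rec@eogH))
  expect_error(simulateDataset(cfgs[1], dir))
  cfgs[[2]]$file_id <- "f1"
  expect_error(simulateDataset(cfgs, dir), "duplicate")
})

test_that("default conditions reproduce the extreme clinical imbalance", {
  # pooled label-1 fraction over several default 12 h recordings is of the
  # order of 0.03%
  pos <- 0; tot <- 0
  for (i in 1:4) {
    sim <- simulateRecording(simConfig(seed = 400L + i))
    lab <- labelValues(sim$labels)
    pos <- pos + sum(lab == 1L)
    tot <- tot + length(lab)
  }
  frac <- 100 * pos / tot
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
})
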