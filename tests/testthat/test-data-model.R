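randomRecording <- function(seed = 1L, ne = 400L, na = 192L) {
  set.seed(seed)
  EogRecording("f1", "s1",
               eogH = rnorm(ne), eogV = rnorm(ne),
               accelX = rnorm(na), accelY = rnorm(na), accelZ = rnorm(na))
}

test_that("recording write/read round-trips exactly", {
  for (seed in 1:3) {
    rec <- randomRecording(seed)
    path <- withr::local_tempfile(fileext = ".rec")
    writeRecording(rec, path)
    back <- readRecording(path)
    expect_identical(back@eogH, rec@eogH)
    expect_identical(back@eogV, rec@eogV)
    expect_identical(back@accelX, rec@accelX)
    expect_identical(back@accelY, rec@accelY)
    expect_identical(back@accelZ, rec@accelZ)
    expect_identical(back@fsEog, rec@fsEog)
    expect_identical(back@fsAccel, rec@fsAccel)
    expect_identical(fileId(back), "f1")
    expect_identical(subjectId(back), "s1")
  }
})

test_that("recording invariants are enforced", {
  expect_error(EogRecording("f", "s", eogH = 1:400, eogV = 1:399,
                            accelX = 1:10, accelY = 1:10, accelZ = 1:10),
               "equal length")
  expect_error(EogRecording("f", "s", eogH = 1:4, eogV = 1:4,
                            accelX = 1, accelY = 1, accelZ = 1),
               "two samples")
  expect_error(EogRecording("f", "s", eogH = 1:4, eogV = 1:4,
                            accelX = 1:2, accelY = 1:2, accelZ = 1:2,
                            fsEog = 20, fsAccel = 41.67),
               "fsEog > fsAccel")
  expect_error(EogRecording("f", "s", eogH = c(1, NaN), eogV = c(1, 2),
                            accelX = 1:2, accelY = 1:2, accelZ = 1:2),
               "non-finite")
})

test_that("malformed recording files are rejected with line information", {
  path <- withr::local_tempfile()
  writeLines(character(0), path)
  expect_error(readRecording(path), "empty file")

  rec <- randomRecording(2, ne = 10L, na = 5L)
  writeRecording(rec, path)
  lines <- readLines(path)
  # drop one eog_v field
  lines[8] <- "1,0.5"
  writeLines(lines, path)
  expect_error(readRecording(path), "line 8")

  writeRecording(rec, path)
  lines <- readLines(path)
  lines[9] <- "2,abc,0.1"
  writeLines(lines, path)
  expect_error(readRecording(path), "line 9")

  expect_error(readRecording(withr::local_tempfile()), "no such file")
})

test_that("NaN samples are not representable on disk", {
  rec <- randomRecording(3)
  rec@eogH[5] <- NaN
  expect_error(writeRecording(rec, withr::local_tempfile()), "non-finite")
})

test_that("labels round-trip and are validated against their recording", {
  rec <- randomRecording(4, ne = 400L)
  lab <- LabelTrack(sample(0:2, 400, replace = TRUE), rec)
  path <- withr::local_tempfile()
  writeLabels(lab, path)
  expect_identical(labelValues(readLabels(path, rec)), labelValues(lab))

  writeLines(as.character(rep(0L, 399)), path)
  expect_error(readLabels(path, rec), "399 labels for 400")
  writeLines(c(as.character(rep(0L, 399)), "3"), path)
  expect_error(readLabels(path, rec), "outside")
  expect_error(LabelTrack(rep(0L, 399), rec), "does not match")
  expect_error(LabelTrack(c(0L, 5L)), "values in")
})

test_that("recording durations on both streams agree for simulator output", {
  sim <- simulateRecording(simConfig(duration_s = 60, seed = 5,
                                     n_nystagmus_episodes = 0L,
                                     n_negative_supine_events = 0L,
                                     n_confuser_episodes = 0L))
  rec <- sim$recording
  durE <- length(rec@eogH) / rec@fsEog
  durA <- length(rec@accelX) / rec@fsAccel
  expect_lt(abs(durE - durA), 1 / rec@fsAccel)
})

test_that("manifest round-trips and rejects duplicates", {
  man <- data.frame(file_id = c("a", "b"), subject_id = c("s", "s"),
                    recording = c("a.rec", "b.rec"),
                    labels = c("a.lab", "b.lab"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeManifest(man, path)
  back <- readManifest(path)
  expect_identical(back$file_id, man$file_id)
  # relative paths are anchored at the manifest directory
  expect_true(all(startsWith(back$recording, dirname(path))))

  man$file_id <- c("a", "a")
  writeManifest(man, path)
  expect_error(readManifest(path), "duplicate")
})
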