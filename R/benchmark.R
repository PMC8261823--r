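#' Published clinical benchmark of the CAVA detection system
#'
#' Reference numbers from the published clinical evaluation of the wearable
#' CAVA nystagmus-detection system that this package re-implements, for
#' regression-testing the metric arithmetic without access to the (private)
#' clinical recordings:
#'
#' * `experiments` — pooled frame-level confusion counts for the four
#'   reported configurations (1D CNN baseline; 2D CNN on eye movement only;
#'   2D CNN on accelerometer only; 2D CNN on both), with the reported
#'   sensitivity (integer percent) and F1 (2 decimals).
#' * `networks` — counts for the five individual ensemble members of the
#'   combined-feature configuration.
#' * `durations` — per-file non-nystagmus and nystagmus durations (seconds)
#'   of the 13 clinical recording files.
#'
#' @return a list of three data.frames as described above.
#' @export
clinicalBenchmark <- function() {
  experiments <- data.frame(
    experiment = c("1d_velocity_accelerometer", "2d_eye_movement",
                   "2d_accelerometer", "2d_velocity_accelerometer"),
    tp = c(13L, 0L, 56L, 73L),
    tn = c(222261L, 222483L, 221963L, 222515L),
    fp = c(272L, 50L, 570L, 18L),
    fn = c(128L, 141L, 85L, 68L),
    sensitivity = c(9, 0, 40, 52),
    specificity = c(100, 100, 100, 100),
    f1 = c(0.06, 0.00, 0.15, 0.63))
  networks <- data.frame(
    network = 1:5,
    tp = c(51L, 50L, 66L, 64L, 75L),
    tn = c(222457L, 222491L, 222469L, 222146L, 222502L),
    fp = c(76L, 42L, 64L, 387L, 31L),
    fn = c(90L, 91L, 75L, 77L, 66L),
    sensitivity = c(36, 35, 47, 45, 53),
    specificity = c(100, 100, 100, 100, 100),
    f1 = c(0.38, 0.43, 0.49, 0.22, 0.61))
  durations <- data.frame(
    file_id = 1:13,
    subject_id = c("1+2", "3", "3", "4", "5", "5", "5", "5", "5", "5",
                   "5", "5", "5"),
    non_nystagmus_s = vapply(
      c("00:16:28", "01:48:39", "24:01:15", "00:23:18", "24:01:15",
        "00:08:18", "00:23:32", "00:28:16", "24:01:03", "24:00:10",
        "24:00:45", "24:01:00", "24:00:39"), parseDuration, numeric(1),
      USE.NAMES = FALSE),
    nystagmus_s = vapply(
      c("00:00:00", "00:00:00", "00:00:00", "00:00:25", "00:00:30",
        "00:00:19", "00:00:11", "00:00:31", "00:00:10", "00:00:19",
        "00:00:08", "00:00:13", "00:00:13"), parseDuration, numeric(1),
      USE.NAMES = FALSE))
  list(experiments = experiments, networks = networks,
       durations = durations)
}

#' Parse an hh:mm:ss duration to seconds
#'
#' @param x character scalar "hh:mm:ss" (hours may exceed 24).
#' @return duration in seconds.
#' @export
parseDuration <- function(x) {
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) != 3L || anyNA(p)) stop(sprintf("bad duration: %s", x))
  p[1] * 3600 + p[2] * 60 + p[3]
}

#' Nystagmus prevalence of a dataset
#'
#' Percentage of recording time labelled nystagmus. Applied to the
#' [clinicalBenchmark()] durations this reproduces the extreme clinical
#' imbalance of about 0.03%.
#'
#' @param durations data.frame with columns `non_nystagmus_s` and
#'   `nystagmus_s`.
#' @return percentage of total duration that is nystagmus.
#' @export
nystagmusPrevalence <- function(durations = clinicalBenchmark()$durations) {
  pos <- sum(durations$nystagmus_s)
  100 * pos / (pos + sum(durations$non_nystagmus_s))
}
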