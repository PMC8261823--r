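#' Butterworth high-pass drift removal
#'
#' Removes the slow electrode baseline wander that EOG recordings display,
#' with a second-order Butterworth high-pass at 0.25 Hz by default. The
#' filter is applied causally (forward only) with zero initial state, as a
#' streaming device would; the startup transient (a few seconds at 0.25 Hz)
#' is accepted. Set `zeroPhase = TRUE` for forward-backward filtering when
#' phase linearity matters more than causality.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param cutoff -3 dB cut-off frequency, Hz.
#' @param order filter order.
#' @param zeroPhase use two-pass zero-phase filtering instead of causal.
#' @return filtered signal, same length as `x`.
#' @export
highpassFilter <- function(x, fs, cutoff = 0.25, order = 2L,
                           zeroPhase = FALSE) {
  if (length(x) <= 3L * order)
    stop("signal too short for the filter's initial conditions")
  if (fs <= 2 * cutoff)
    stop("sampling rate must exceed twice the cut-off frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  if (zeroPhase) as.numeric(signal::filtfilt(bf, x))
  else as.numeric(signal::filter(bf, x))
}

#' Align the accelerometer onto the EOG timebase
#'
#' Linearly interpolates the three accelerometer channels from their own
#' sample grid onto the EOG sample times and stacks them under the two EOG
#' channels, which are passed through [highpassFilter()]. The accelerometer
#' channels are not filtered. EOG times beyond the final accelerometer
#' sample are clamped to the nearest accelerometer value (never an error).
#' Both streams are taken to start at t = 0.
#'
#' @param rec an [EogRecording-class].
#' @inheritParams highpassFilter
#' @return an [AlignedRecording-class] with 5 equal-length channels in fixed
#'   order (eog_h, eog_v, accel_x, accel_y, accel_z).
#' @export
alignAccelerometer <- function(rec, cutoff = 0.25, order = 2L,
                               zeroPhase = FALSE) {
  validObject(rec)
  L <- length(rec@eogH)
  tE <- (seq_len(L) - 1L) / rec@fsEog
  tA <- (seq_len(length(rec@accelX)) - 1L) / rec@fsAccel
  interp <- function(y)
    stats::approx(tA, y, xout = tE, method = "linear", rule = 2)$y
  ch <- rbind(
    highpassFilter(rec@eogH, rec@fsEog, cutoff, order, zeroPhase),
    highpassFilter(rec@eogV, rec@fsEog, cutoff, order, zeroPhase),
    interp(rec@accelX), interp(rec@accelY), interp(rec@accelZ))
  rownames(ch) <- .channelOrder
  new("AlignedRecording", channels = ch, fs = rec@fsEog, fileId = rec@fileId)
}

#' Write or read an aligned recording
#'
#' Plain-text: `#` header (fs, file_id), then comma-separated rows
#' `t_index,eog_h,eog_v,accel_x,accel_y,accel_z` at full stored precision.
#'
#' @param aligned an [AlignedRecording-class].
#' @param path file path.
#' @export
writeAlignedRecording <- function(aligned, path) {
  ch <- aligned@channels
  lines <- c(
    sprintf("# fs: %s", .fmt(aligned@fs)),
    sprintf("# file_id: %s", aligned@fileId),
    "t_index,eog_h,eog_v,accel_x,accel_y,accel_z",
    paste(0:(ncol(ch) - 1L), .fmt(ch[1, ]), .fmt(ch[2, ]), .fmt(ch[3, ]),
          .fmt(ch[4, ]), .fmt(ch[5, ]), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeAlignedRecording
#' @export
readAlignedRecording <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fs <- as.numeric(.headerValue(lines, "fs", path))
  fid <- .headerValue(lines, "file_id", path)
  hdr <- which(lines == "t_index,eog_h,eog_v,accel_x,accel_y,accel_z")
  if (length(hdr) != 1L)
    stop(sprintf("%s: missing aligned-recording column header", path))
  m <- .parseSection(lines, hdr + 1L, length(lines), 6L, "aligned", path)
  ch <- t(m[, 2:6, drop = FALSE])
  rownames(ch) <- .channelOrder
  new("AlignedRecording", channels = ch, fs = fs, fileId = fid)
}
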