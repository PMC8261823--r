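#' First-difference velocity of a signal
#'
#' Adjacent-sample differencing; a leading zero keeps the output the same
#' length as the input. Velocity makes nystagmus beats more consistent
#' between examples and further suppresses any residual baseline.
#'
#' @param x numeric vector, length at least 1.
#' @return numeric vector: `c(0, diff(x))`.
#' @export
velocity <- function(x) {
  if (!length(x)) stop("velocity of an empty signal is undefined")
  c(0, diff(x))
}

.unitRows <- function(m) {
  n2 <- sqrt(rowSums(m^2))
  n2[n2 == 0] <- 1  # degenerate all-zero rows are left as zero vectors
  m / n2
}

#' Cut an aligned recording into feature frames
#'
#' Slides a `window`-sample window (default 400 samples = 9.6 s at 41.67 Hz)
#' with 75% overlap (hop = 100 samples) over the five aligned channels. Per
#' frame, the two EOG rows are velocity-transformed and the three
#' accelerometer rows enter raw; every row is then normalised to a unit L2
#' vector (all-zero rows stay zero). Trailing samples that do not fill a
#' final window are discarded.
#'
#' Two label views are attached: the training label is the modal sample
#' label within the window (ties resolved to the larger label value, so
#' informative classes are preferred), and the testing label is 1 if any
#' covered sample is nystagmus, else 0 — training sees only unambiguous
#' examples while testing counts every nystagmus sample.
#'
#' @param aligned an [AlignedRecording-class].
#' @param labels the matching [LabelTrack-class].
#' @param window window length in samples.
#' @param overlapFraction fractional overlap of consecutive windows.
#' @return a [FrameSet-class].
#' @export
makeFrames <- function(aligned, labels, window = 400L,
                       overlapFraction = 0.75) {
  validObject(aligned)
  lab <- labels@labels
  L <- ncol(aligned@channels)
  if (length(lab) != L)
    stop("label track length does not match the aligned recording")
  window <- as.integer(window)
  if (L < window)
    stop("recording shorter than one analysis window")
  hop <- as.integer(round(window * (1 - overlapFraction)))
  if (hop < 1L) stop("overlap too large: hop below one sample")
  n <- (L - window) %/% hop + 1L
  starts <- (seq_len(n) - 1L) * hop

  ch <- aligned@channels
  # whole-signal first differences; per-frame the leading element is zeroed,
  # which equals velocity() applied to each segment
  dv <- ch
  dv[1:2, ] <- cbind(c(0, 0), t(diff(t(ch[1:2, , drop = FALSE]))))

  feats <- array(0, dim = c(5L, window, n))
  trainL <- integer(n)
  testL <- integer(n)
  for (i in seq_len(n)) {
    idx <- (starts[i] + 1L):(starts[i] + window)
    seg <- dv[, idx]
    seg[1:2, 1L] <- 0
    feats[, , i] <- .unitRows(seg)
    sl <- lab[idx]
    counts <- tabulate(sl + 1L, 3L)
    trainL[i] <- max(which(counts == max(counts))) - 1L
    testL[i] <- as.integer(any(sl == 1L))
  }
  new("FrameSet", features = feats, trainLabels = trainL,
      testLabels = testL, startSamples = starts, window = window,
      hop = hop, fileId = aligned@fileId)
}

#' Concatenate frame sets
#'
#' Stacks frames of several [FrameSet-class] objects (e.g. the training
#' files of a fold). Start offsets are kept per frame but lose their global
#' ordering; provenance becomes the concatenation of file ids.
#'
#' @param ... FrameSet objects with equal row and window dimensions.
#' @return a [FrameSet-class].
#' @export
combineFrameSets <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && is.list(fs[[1]]))
    fs <- fs[[1]]
  stopifnot(length(fs) >= 1L)
  d1 <- dim(fs[[1]]@features)
  for (f in fs)
    if (!identical(dim(f@features)[1:2], d1[1:2]) ||
        f@window != fs[[1]]@window)
      stop("frame sets have incompatible shapes")
  feats <- array(unlist(lapply(fs, function(f) f@features)),
                 dim = c(d1[1], d1[2], sum(vapply(fs, nFrames, 1L))))
  new("FrameSet", features = feats,
      trainLabels = unlist(lapply(fs, function(f) f@trainLabels)),
      testLabels = unlist(lapply(fs, function(f) f@testLabels)),
      startSamples = unlist(lapply(fs, function(f) f@startSamples)),
      window = fs[[1]]@window, hop = fs[[1]]@hop,
      fileId = paste(vapply(fs, function(f) f@fileId, character(1)),
                     collapse = "+"))
}

#' Restrict a frame set to a channel subset
#'
#' Keeps only the EOG rows (`"eog"`), only the accelerometer rows
#' (`"accel"`), or all five (`"all"`); used for the single-modality ablation
#' experiments.
#'
#' @param frames a [FrameSet-class] with the full 5-row layout.
#' @param channels one of "all", "eog", "accel".
#' @return a [FrameSet-class] with 5, 2 or 3 feature rows.
#' @export
subsetChannels <- function(frames, channels = c("all", "eog", "accel")) {
  channels <- match.arg(channels)
  if (channels == "all") return(frames)
  rows <- if (channels == "eog") 1:2 else 3:5
  if (dim(frames@features)[1] != 5L)
    stop("channel subsetting expects the full 5-row frame layout")
  new(class(frames)[[1]],
      frames,
      features = frames@features[rows, , , drop = FALSE])
}

#' Write or read a frame container file
#'
#' Plain-text tensor format: a `#`-prefixed shape/metadata header, one line
#' of labels per view, then one line per frame of whitespace-separated
#' feature values (row-major within the frame).
#'
#' @param frames a [FrameSet-class].
#' @param path file path.
#' @export
writeFrameSet <- function(frames, path) {
  d <- dim(frames@features)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# shape: %d %d %d", d[1], d[2], d[3]),
    sprintf("# window: %d", frames@window),
    sprintf("# hop: %d", frames@hop),
    sprintf("# file_id: %s", frames@fileId),
    paste(frames@trainLabels, collapse = " "),
    paste(frames@testLabels, collapse = " "),
    paste(frames@startSamples, collapse = " ")), con)
  for (i in seq_len(d[3]))
    writeLines(paste(.fmt(as.vector(t(frames@features[, , i]))),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname writeFrameSet
#' @export
readFrameSet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  shape <- as.integer(strsplit(.headerValue(lines, "shape", path),
                               " ")[[1]])
  window <- as.integer(.headerValue(lines, "window", path))
  hop <- as.integer(.headerValue(lines, "hop", path))
  fid <- .headerValue(lines, "file_id", path)
  body <- lines[!startsWith(lines, "#")]
  num <- function(s) as.numeric(strsplit(trimws(s), " +")[[1]])
  trainL <- as.integer(num(body[1]))
  testL <- as.integer(num(body[2]))
  starts <- as.integer(num(body[3]))
  feats <- array(0, dim = shape)
  for (i in seq_len(shape[3]))
    feats[, , i] <- matrix(num(body[3L + i]), nrow = shape[1],
                           byrow = TRUE)
  new("FrameSet", features = feats, trainLabels = trainL,
      testLabels = testL, startSamples = starts, window = window,
      hop = hop, fileId = fid)
}
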