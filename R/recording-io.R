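#' Construct a recording object
#'
#' @param fileId,subjectId identifiers.
#' @param eogH,eogV horizontal/vertical eye-movement channels (equal length).
#' @param accelX,accelY,accelZ accelerometer channels in g (equal length).
#' @param fsEog,fsAccel sampling rates in Hz. The defaults follow the device:
#'   41.67 Hz for EOG (so 400 samples span exactly 9.6 s) and 20 Hz for the
#'   accelerometer.
#' @return an [EogRecording-class] object.
#' @export
EogRecording <- function(fileId, subjectId, eogH, eogV, accelX, accelY,
                         accelZ, fsEog = 41.67, fsAccel = 20) {
  new("EogRecording",
      fileId = as.character(fileId), subjectId = as.character(subjectId),
      eogH = as.numeric(eogH), eogV = as.numeric(eogV),
      accelX = as.numeric(accelX), accelY = as.numeric(accelY),
      accelZ = as.numeric(accelZ),
      fsEog = as.numeric(fsEog), fsAccel = as.numeric(fsAccel))
}

#' Construct a label track
#'
#' @param labels vector of per-sample labels in \{0,1,2\}.
#' @param recording optionally, the [EogRecording-class] the labels belong
#'   to; if given, the length must match its EOG channels.
#' @return a [LabelTrack-class] object.
#' @export
LabelTrack <- function(labels, recording = NULL) {
  lt <- new("LabelTrack", labels = as.integer(labels))
  if (!is.null(recording) &&
      length(lt@labels) != length(recording@eogH))
    stop(sprintf("label count (%d) does not match EOG length (%d)",
                 length(lt@labels), length(recording@eogH)))
  lt
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write a recording to the columnar text format
#'
#' The format is plain text: `#`-prefixed header lines carrying the sampling
#' rates and identifiers, then an EOG section (`t_index,eog_h,eog_v`) and an
#' ACCEL section (`t_index,ax,ay,az`). Values are stored with 17 significant
#' digits so [readRecording()] reproduces the object exactly.
#'
#' @param rec an [EogRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
  validObject(rec)
  ne <- length(rec@eogH)
  na <- length(rec@accelX)
  lines <- c(
    sprintf("# fs_eog: %s", .fmt(rec@fsEog)),
    sprintf("# fs_accel: %s", .fmt(rec@fsAccel)),
    sprintf("# file_id: %s", rec@fileId),
    sprintf("# subject_id: %s", rec@subjectId),
    "# EOG",
    "t_index,eog_h,eog_v",
    paste(0:(ne - 1L), .fmt(rec@eogH), .fmt(rec@eogV), sep = ","),
    "# ACCEL",
    "t_index,ax,ay,az",
    paste(0:(na - 1L), .fmt(rec@accelX), .fmt(rec@accelY),
          .fmt(rec@accelZ), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

.headerValue <- function(lines, key, path) {
  pat <- sprintf("^# %s: *(.*)$", key)
  hit <- grep(pat, lines)
  if (length(hit) != 1L)
    stop(sprintf("%s: expected exactly one '# %s:' header line", path, key))
  sub(pat, "\\1", lines[hit])
}

.parseSection <- function(lines, first, last, ncols, section, path) {
  if (first > last)
    stop(sprintf("%s: empty %s section", path, section))
  rows <- strsplit(lines[first:last], ",", fixed = TRUE)
  bad <- which(lengths(rows) != ncols)
  if (length(bad))
    stop(sprintf("%s: line %d: expected %d comma-separated fields",
                 path, first + bad[1] - 1L, ncols))
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = ncols, byrow = TRUE)
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(apply(m, 1L, function(r) anyNA(r) || any(!is.finite(r))))[1]
    stop(sprintf("%s: line %d: non-numeric or non-finite value",
                 path, first + bad - 1L))
  }
  m
}

#' Read a recording from the columnar text format
#'
#' @param path file written by [writeRecording()] (or the simulator).
#' @return an [EogRecording-class]; malformed input raises an error naming
#'   the offending line.
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  fsEog <- suppressWarnings(as.numeric(.headerValue(lines, "fs_eog", path)))
  fsAccel <- suppressWarnings(as.numeric(.headerValue(lines, "fs_accel", path)))
  if (is.na(fsEog) || is.na(fsAccel))
    stop(sprintf("%s: non-numeric sampling rate in header", path))
  fid <- .headerValue(lines, "file_id", path)
  sid <- .headerValue(lines, "subject_id", path)
  eogAt <- which(lines == "# EOG")
  accAt <- which(lines == "# ACCEL")
  if (length(eogAt) != 1L || length(accAt) != 1L || accAt < eogAt)
    stop(sprintf("%s: expected one '# EOG' then one '# ACCEL' section", path))
  if (!identical(lines[eogAt + 1L], "t_index,eog_h,eog_v"))
    stop(sprintf("%s: line %d: bad EOG column header", path, eogAt + 1L))
  if (!identical(lines[accAt + 1L], "t_index,ax,ay,az"))
    stop(sprintf("%s: line %d: bad ACCEL column header", path, accAt + 1L))
  eog <- .parseSection(lines, eogAt + 2L, accAt - 1L, 3L, "EOG", path)
  acc <- .parseSection(lines, accAt + 2L, length(lines), 4L, "ACCEL", path)
  EogRecording(fid, sid,
               eogH = eog[, 2], eogV = eog[, 3],
               accelX = acc[, 2], accelY = acc[, 3], accelZ = acc[, 4],
               fsEog = fsEog, fsAccel = fsAccel)
}

#' Read or write per-sample labels
#'
#' Label files hold one integer (0, 1 or 2) per line, aligned 1:1 with the
#' EOG rows of their recording.
#'
#' @param path label file path.
#' @param rec the [EogRecording-class] the labels annotate; lengths must
#'   agree.
#' @return [readLabels()] returns a [LabelTrack-class]; [writeLabels()]
#'   returns `path` invisibly.
#' @export
readLabels <- function(path, rec) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  raw <- readLines(path, warn = FALSE)
  vals <- suppressWarnings(as.integer(raw))
  if (anyNA(vals))
    stop(sprintf("%s: line %d: non-integer label", path, which(is.na(vals))[1]))
  if (!all(vals %in% 0:2))
    stop(sprintf("%s: line %d: label outside {0,1,2}",
                 path, which(!(vals %in% 0:2))[1]))
  if (length(vals) != length(rec@eogH))
    stop(sprintf("%s: %d labels for %d EOG samples",
                 path, length(vals), length(rec@eogH)))
  new("LabelTrack", labels = vals)
}

#' @rdname readLabels
#' @param lab a [LabelTrack-class].
#' @export
writeLabels <- function(lab, path) {
  writeLines(as.character(lab@labels), path)
  invisible(path)
}

#' Write per-frame predictions
#'
#' Comma-separated records `frame_index,start_sample,end_sample,class`,
#' 0-based sample offsets, end exclusive.
#'
#' @param classes integer vector of predicted frame classes.
#' @param frames the [FrameSet-class] the predictions refer to.
#' @param path output path.
#' @export
writePredictions <- function(classes, frames, path) {
  stopifnot(length(classes) == nFrames(frames))
  df <- data.frame(
    frame_index = seq_along(classes) - 1L,
    start_sample = frames@startSamples,
    end_sample = frames@startSamples + frames@window,
    class = as.integer(classes))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a dataset manifest
#'
#' A manifest lists the recording/label file pairs of a dataset: columns
#' `file_id`, `subject_id`, `recording`, `labels` (paths relative to the
#' manifest's directory or absolute).
#'
#' @param path manifest CSV path.
#' @return a data.frame with the four columns above and unique `file_id`s.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file_id", "subject_id", "recording", "labels")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: manifest must have columns %s", path,
                 paste(need, collapse = ", ")))
  df$file_id <- as.character(df$file_id)
  if (anyDuplicated(df$file_id))
    stop(sprintf("%s: duplicate file_id", path))
  base <- dirname(path)
  for (col in c("recording", "labels")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  df
}

#' @rdname readManifest
#' @param manifest manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
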