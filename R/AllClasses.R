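#' @import methods
NULL

#' Dual-rate eye-movement and accelerometer recording
#'
#' Container for one wearable recording: two electrooculography (EOG)
#' channels sampled at the device rate (default 41.67 Hz, so that a
#' 400-sample analysis window spans 9.6 s) and three accelerometer channels
#' sampled more slowly (default 20 Hz). EOG amplitudes are treated as
#' dimensionless; acceleration is in g. Both streams are assumed to start at
#' the same instant.
#'
#' @slot fileId character scalar identifying the recording file.
#' @slot subjectId character scalar identifying the wearer.
#' @slot eogH,eogV numeric vectors, horizontal and vertical eye movement,
#'   equal length, no missing values.
#' @slot fsEog EOG sampling rate in Hz.
#' @slot accelX,accelY,accelZ numeric vectors of acceleration (g), equal
#'   length.
#' @slot fsAccel accelerometer sampling rate in Hz; must be below `fsEog`.
#' @export
setClass("EogRecording",
  slots = c(
    fileId = "character", subjectId = "character",
    eogH = "numeric", eogV = "numeric", fsEog = "numeric",
    accelX = "numeric", accelY = "numeric", accelZ = "numeric",
    fsAccel = "numeric"
  )
)

setValidity("EogRecording", function(object) {
  msg <- character()
  if (length(object@fileId) != 1L || !nzchar(object@fileId))
    msg <- c(msg, "fileId must be a non-empty character scalar")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a character scalar")
  if (length(object@eogH) != length(object@eogV))
    msg <- c(msg, "eogH and eogV must have equal length")
  if (length(object@eogH) < 1L)
    msg <- c(msg, "EOG channels must contain at least one sample")
  la <- c(length(object@accelX), length(object@accelY), length(object@accelZ))
  if (length(unique(la)) != 1L)
    msg <- c(msg, "accelerometer channels must have equal length")
  if (la[1] < 2L)
    msg <- c(msg, "accelerometer channels must contain at least two samples")
  if (!(length(object@fsEog) == 1L && length(object@fsAccel) == 1L &&
        is.finite(object@fsEog) && is.finite(object@fsAccel) &&
        object@fsEog > object@fsAccel && object@fsAccel > 0))
    msg <- c(msg, "sampling rates must satisfy fsEog > fsAccel > 0")
  sig <- c(object@eogH, object@eogV, object@accelX, object@accelY,
           object@accelZ)
  if (anyNA(sig) || any(!is.finite(sig)))
    msg <- c(msg, "signals must not contain missing or non-finite values")
  if (length(msg)) msg else TRUE
})

#' Per-sample ternary ground-truth labels
#'
#' One label per EOG sample: 0 = non-nystagmus, 1 = nystagmus, 2 = supine
#' (Dix-Hallpike posture) without nystagmus.
#'
#' @slot labels integer vector with values in \{0, 1, 2\}.
#' @export
setClass("LabelTrack", slots = c(labels = "integer"))

setValidity("LabelTrack", function(object) {
  if (anyNA(object@labels) || !all(object@labels %in% 0:2))
    return("labels must take values in {0, 1, 2}")
  TRUE
})

#' Five-channel recording on the common EOG timebase
#'
#' Produced by [alignAccelerometer()]: drift-filtered EOG plus accelerometer
#' channels linearly interpolated onto the EOG sample grid. Channel order is
#' fixed: eog_h, eog_v, accel_x, accel_y, accel_z.
#'
#' @slot channels 5-by-L numeric matrix, rows in the fixed order above.
#' @slot fs common sampling rate (the EOG rate), Hz.
#' @slot fileId provenance identifier.
#' @export
setClass("AlignedRecording",
  slots = c(channels = "matrix", fs = "numeric", fileId = "character")
)

.channelOrder <- c("eog_h", "eog_v", "accel_x", "accel_y", "accel_z")

setValidity("AlignedRecording", function(object) {
  msg <- character()
  if (nrow(object@channels) != 5L)
    msg <- c(msg, "channels must have exactly 5 rows")
  if (!identical(rownames(object@channels), .channelOrder))
    msg <- c(msg, sprintf("channel rows must be named, in order: %s",
                          paste(.channelOrder, collapse = ", ")))
  if (!(length(object@fs) == 1L && is.finite(object@fs) && object@fs > 0))
    msg <- c(msg, "fs must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Stack of windowed feature frames
#'
#' Each frame is an R-by-W matrix (R = 5 for the full channel set) whose rows
#' are unit L2 vectors (or all-zero for degenerate constant segments): the
#' velocity of the two filtered EOG channels and the three raw interpolated
#' accelerometer channels. Frames carry two label views: a training label by
#' majority vote of the covered samples (ternary) and a testing label that is
#' positive if any covered sample is nystagmus (binary).
#'
#' @slot features numeric array \[rows, window, N\].
#' @slot trainLabels integer N-vector in \{0,1,2\}.
#' @slot testLabels integer N-vector in \{0,1\}.
#' @slot startSamples integer N-vector of 0-based window offsets (-1 marks a
#'   synthetic frame with no position in the recording).
#' @slot window,hop window length and hop in samples.
#' @slot fileId provenance identifier.
#' @export
setClass("FrameSet",
  slots = c(
    features = "array", trainLabels = "integer", testLabels = "integer",
    startSamples = "integer", window = "integer", hop = "integer",
    fileId = "character"
  )
)

setValidity("FrameSet", function(object) {
  msg <- character()
  d <- dim(object@features)
  if (length(d) != 3L)
    msg <- c(msg, "features must be a 3-d array [rows, window, frames]")
  else {
    n <- d[3]
    if (d[2] != object@window)
      msg <- c(msg, "features column count must equal window")
    if (length(object@trainLabels) != n || length(object@testLabels) != n ||
        length(object@startSamples) != n)
      msg <- c(msg, "label and offset lengths must equal the frame count")
  }
  if (!all(object@trainLabels %in% 0:2))
    msg <- c(msg, "trainLabels must take values in {0, 1, 2}")
  if (!all(object@testLabels %in% 0:1))
    msg <- c(msg, "testLabels must take values in {0, 1}")
  if (length(msg)) msg else TRUE
})

#' Frame set after SMOTE class balancing
#'
#' A [FrameSet] whose training classes have been equalised by synthetic
#' minority oversampling; `syntheticMask` flags the generated frames. The
#' original frames appear unmodified, in their original order, first.
#'
#' @slot syntheticMask logical per-frame flag, TRUE for SMOTE-generated
#'   frames.
#' @export
setClass("BalancedFrameSet",
  contains = "FrameSet",
  slots = c(syntheticMask = "logical")
)

setValidity("BalancedFrameSet", function(object) {
  if (length(object@syntheticMask) != dim(object@features)[3])
    return("syntheticMask length must equal the frame count")
  TRUE
})

#' A small convolutional frame classifier
#'
#' Parameter state, architecture/training configuration and per-epoch
#' training log of one network. Create with [buildNetwork()] and fit with
#' [trainNetwork()].
#'
#' @slot params list of conv kernels/biases and dense weights/biases.
#' @slot config the network configuration list from [networkConfig()].
#' @slot trainingLog data.frame with one row per completed epoch (loss,
#'   accuracy); zero rows for an untrained network.
#' @export
setClass("TrainedNetwork",
  slots = c(params = "list", config = "list", trainingLog = "data.frame")
)

#' Fused ensemble prediction for one frame sequence
#'
#' @slot memberTracks integer matrix, members-by-frames, raw ternary votes.
#' @slot fusedTrack integer frame classes after majority vote.
#' @slot binaryTrack fused track with supine class 2 remapped to 0.
#' @slot sievedTrack binary track after run-length open/close filtering.
#' @export
setClass("EnsemblePrediction",
  slots = c(
    memberTracks = "matrix", fusedTrack = "integer",
    binaryTrack = "integer", sievedTrack = "integer"
  )
)

setValidity("EnsemblePrediction", function(object) {
  n <- ncol(object@memberTracks)
  if (length(object@fusedTrack) != n || length(object@binaryTrack) != n ||
      length(object@sievedTrack) != n)
    return("all tracks must share the member-track frame count")
  if (any(object@binaryTrack > 1L) || any(object@sievedTrack > 1L))
    return("binary and sieved tracks must be 0/1")
  TRUE
})
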