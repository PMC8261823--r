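#' Accessors for the pipeline containers
#'
#' Small accessor generics in place of direct slot access.
#'
#' @param x an object from this package.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fileId", function(x) standardGeneric("fileId"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("labelValues", function(x) standardGeneric("labelValues"))
#' @rdname accessors
#' @export
setGeneric("channelMatrix", function(x) standardGeneric("channelMatrix"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameFeatures", function(x) standardGeneric("frameFeatures"))
#' @rdname accessors
#' @export
setGeneric("trainLabels", function(x) standardGeneric("trainLabels"))
#' @rdname accessors
#' @export
setGeneric("testLabels", function(x) standardGeneric("testLabels"))
#' @rdname accessors
#' @export
setGeneric("startSamples", function(x) standardGeneric("startSamples"))
#' @rdname accessors
#' @export
setGeneric("syntheticMask", function(x) standardGeneric("syntheticMask"))
#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setGeneric("memberTracks", function(x) standardGeneric("memberTracks"))
#' @rdname accessors
#' @export
setGeneric("fusedTrack", function(x) standardGeneric("fusedTrack"))
#' @rdname accessors
#' @export
setGeneric("binaryTrack", function(x) standardGeneric("binaryTrack"))
#' @rdname accessors
#' @export
setGeneric("sievedTrack", function(x) standardGeneric("sievedTrack"))

#' @rdname accessors
#' @export
setMethod("fileId", "EogRecording", function(x) x@fileId)
#' @rdname accessors
#' @export
setMethod("fileId", "AlignedRecording", function(x) x@fileId)
#' @rdname accessors
#' @export
setMethod("fileId", "FrameSet", function(x) x@fileId)
#' @rdname accessors
#' @export
setMethod("subjectId", "EogRecording", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("labelValues", "LabelTrack", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("channelMatrix", "AlignedRecording", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EogRecording", function(x) x@fsEog)
#' @rdname accessors
#' @export
setMethod("samplingRate", "AlignedRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSet", function(x) dim(x@features)[3])
#' @rdname accessors
#' @export
setMethod("frameFeatures", "FrameSet", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("trainLabels", "FrameSet", function(x) x@trainLabels)
#' @rdname accessors
#' @export
setMethod("testLabels", "FrameSet", function(x) x@testLabels)
#' @rdname accessors
#' @export
setMethod("startSamples", "FrameSet", function(x) x@startSamples)
#' @rdname accessors
#' @export
setMethod("syntheticMask", "BalancedFrameSet", function(x) x@syntheticMask)
#' @rdname accessors
#' @export
setMethod("trainingLog", "TrainedNetwork", function(x) x@trainingLog)
#' @rdname accessors
#' @export
setMethod("memberTracks", "EnsemblePrediction", function(x) x@memberTracks)
#' @rdname accessors
#' @export
setMethod("fusedTrack", "EnsemblePrediction", function(x) x@fusedTrack)
#' @rdname accessors
#' @export
setMethod("binaryTrack", "EnsemblePrediction", function(x) x@binaryTrack)
#' @rdname accessors
#' @export
setMethod("sievedTrack", "EnsemblePrediction", function(x) x@sievedTrack)

setMethod("show", "EogRecording", function(object) {
  cat(sprintf(
    "EogRecording '%s' (subject %s)\n  EOG: %d samples @ %.2f Hz (%.1f s)\n  accel: %d samples @ %.2f Hz\n",
    object@fileId, object@subjectId, length(object@eogH), object@fsEog,
    length(object@eogH) / object@fsEog, length(object@accelX),
    object@fsAccel))
})

setMethod("show", "LabelTrack", function(object) {
  tab <- tabulate(object@labels + 1L, 3L)
  cat(sprintf(
    "LabelTrack: %d samples (class 0: %d, 1: %d, 2: %d)\n",
    length(object@labels), tab[1], tab[2], tab[3]))
})

setMethod("show", "AlignedRecording", function(object) {
  cat(sprintf(
    "AlignedRecording '%s': 5 x %d @ %.2f Hz\n",
    object@fileId, ncol(object@channels), object@fs))
})

setMethod("show", "FrameSet", function(object) {
  d <- dim(object@features)
  tab <- tabulate(object@trainLabels + 1L, 3L)
  cat(sprintf(
    "%s '%s': %d frames of %d x %d (train classes 0/1/2: %d/%d/%d; %d positive test frames)\n",
    class(object), object@fileId, d[3], d[1], d[2], tab[1], tab[2], tab[3],
    sum(object@testLabels)))
})

setMethod("show", "TrainedNetwork", function(object) {
  ep <- nrow(object@trainingLog)
  cat(sprintf(
    "TrainedNetwork (%s mode, seed %d): %s\n",
    object@config$mode, object@config$seed,
    if (ep == 0L) "untrained"
    else sprintf("%d epochs, final loss %.4f, accuracy %.3f", ep,
                 object@trainingLog$loss[ep], object@trainingLog$accuracy[ep])))
})

setMethod("show", "EnsemblePrediction", function(object) {
  cat(sprintf(
    "EnsemblePrediction: %d members x %d frames; %d positive after sieve\n",
    nrow(object@memberTracks), ncol(object@memberTracks),
    sum(object@sievedTrack)))
})
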