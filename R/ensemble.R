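#' Majority-vote fusion of member classifications
#'
#' Per frame, the plurality class over the member tracks wins. An odd member
#' count is required (it precludes two-way ties in the binary case), but a
#' three-class plurality can still tie (e.g. votes 2-2-1 over five members);
#' such ties resolve to class 0, the conservative clinical default, under
#' `tieRule = "class0"`, or to the lowest tied class index under
#' `tieRule = "lowest"`.
#'
#' @param tracks integer matrix of votes, members by frames (values 0/1/2),
#'   or a list of equal-length member tracks.
#' @param tieRule `"class0"` or `"lowest"`.
#' @return integer fused track.
#' @export
majorityVote <- function(tracks, tieRule = c("class0", "lowest")) {
  tieRule <- match.arg(tieRule)
  if (is.list(tracks)) {
    if (length(unique(lengths(tracks))) != 1L)
      stop("member tracks must have equal length")
    tracks <- do.call(rbind, tracks)
  }
  if (nrow(tracks) %% 2L == 0L)
    stop("an odd number of members is required to avoid binary ties")
  if (!all(tracks %in% 0:2))
    stop("votes must take values in {0, 1, 2}")
  apply(tracks, 2L, function(v) {
    counts <- tabulate(v + 1L, 3L)
    winners <- which(counts == max(counts)) - 1L
    if (length(winners) == 1L) winners
    else if (tieRule == "class0") 0L
    else min(winners)
  })
}

#' Remap the supine class to negative
#'
#' Class 2 (supine without nystagmus) exists only to help the networks
#' separate nystagmus from ordinary supine eye movements; for scoring it is
#' folded into class 0.
#'
#' @param track integer track with values in \{0,1,2\}.
#' @return binary track (2 -> 0, 1 -> 1, 0 -> 0).
#' @export
remapClass2 <- function(track) {
  stopifnot(all(track %in% 0:2))
  as.integer(ifelse(track == 2L, 0L, track))
}

#' Run-length (sieve) filtering of a binary track
#'
#' Morphological smoothing of the frame-classification sequence: first every
#' maximal run of 1s shorter than `openLen` is removed (opening), then every
#' maximal internal run of 0s — bounded by 1s on both sides — shorter than
#' `closeLen` is filled (closing). A length of 0 disables that pass.
#' Opening is applied before closing.
#'
#' @param binary integer/logical vector of 0s and 1s.
#' @param openLen minimum surviving positive run length (frames).
#' @param closeLen minimum surviving internal negative gap (frames).
#' @return filtered binary integer vector.
#' @export
sieveFilter <- function(binary, openLen = 2L, closeLen = 2L) {
  stopifnot(openLen >= 0L, closeLen >= 0L)
  b <- as.integer(binary)
  stopifnot(all(b %in% 0:1))
  if (!length(b)) return(b)
  r <- rle(b)
  r$values[r$values == 1L & r$lengths < openLen] <- 0L
  b <- inverse.rle(r)
  r <- rle(b)
  k <- length(r$values)
  if (k > 2L) {
    internal <- seq_len(k) > 1L & seq_len(k) < k
    r$values[internal & r$values == 0L & r$lengths < closeLen] <- 1L
  }
  inverse.rle(r)
}

#' Train an ensemble of seeded networks
#'
#' Builds and trains one network per seed on the same balanced frames; the
#' seeds are the only source of diversity between members.
#'
#' @param frames a [BalancedFrameSet-class] of training frames.
#' @param cfg a [networkConfig()] (its `seed` is replaced per member).
#' @param seeds integer vector of member seeds; an odd count is required so
#'   the vote cannot tie in the binary case.
#' @return list of [TrainedNetwork-class] members.
#' @export
trainEnsemble <- function(frames, cfg, seeds) {
  if (length(seeds) %% 2L == 0L)
    stop("an odd number of ensemble members is required")
  lapply(seeds, function(s) {
    cfg$seed <- as.integer(s)
    trainNetwork(buildNetwork(cfg), frames)
  })
}

#' Fuse, remap and sieve ensemble predictions
#'
#' Runs every member on the frames, fuses the votes by [majorityVote()],
#' folds class 2 into class 0 with [remapClass2()], and smooths the binary
#' track with [sieveFilter()]. With `remapStage = "before"` the member
#' tracks are remapped before voting instead of after (the default remaps
#' the fused track).
#'
#' @param nets list of [TrainedNetwork-class] members (odd count).
#' @param frames a [FrameSet-class] to classify.
#' @param openLen,closeLen sieve parameters, in frames (default 2 each,
#'   about 2.4 s of novel signal per frame step).
#' @param tieRule passed to [majorityVote()].
#' @param remapStage `"after"` (default) or `"before"`.
#' @return an [EnsemblePrediction-class].
#' @export
predictEnsemble <- function(nets, frames, openLen = 2L, closeLen = 2L,
                            tieRule = "class0",
                            remapStage = c("after", "before")) {
  remapStage <- match.arg(remapStage)
  member <- do.call(rbind, lapply(nets, predictFrames, frames = frames))
  voted <- if (remapStage == "before")
    t(apply(member, 1L, remapClass2)) else member
  if (nFrames(frames) == 1L) voted <- matrix(voted, ncol = 1L)
  fused <- as.integer(majorityVote(voted, tieRule = tieRule))
  bin <- remapClass2(fused)
  new("EnsemblePrediction",
      memberTracks = member, fusedTrack = fused, binaryTrack = bin,
      sievedTrack = as.integer(sieveFilter(bin, openLen, closeLen)))
}
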