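#' SMOTE class balancing of training frames
#'
#' Equalises the three training classes by Synthetic Minority Over-sampling:
#' frames are flattened to feature vectors (rows * window values, 2000 for
#' the standard 5 x 400 layout), and for each minority class synthetic
#' vectors `x_i + u * (x_nn - x_i)` are drawn, with `u` uniform on \[0, 1\]
#' and `x_nn` one of the `k` same-class Euclidean nearest neighbours of a
#' randomly chosen class member `x_i`, until every class matches the largest
#' class count. Original frames pass through unmodified; synthetic rows are
#' not re-normalised (interpolants of unit rows are near-unit already, and
#' renormalising would depart from the technique as published). Balancing is
#' applied to training data only — never to test frames.
#'
#' A class absent from the input is skipped; a class with a single member
#' cannot be interpolated and raises an error. `k` larger than class size
#' minus one is truncated with a warning.
#'
#' @param frames a [FrameSet-class] of training frames.
#' @param k number of same-class nearest neighbours considered.
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [BalancedFrameSet-class]; `syntheticMask()` flags generated
#'   frames (all appended after the originals, with start offset -1).
#' @export
smoteBalance <- function(frames, k = 5L, seed = 1L) {
  d <- dim(frames@features)
  n <- d[3]
  lab <- frames@trainLabels
  counts <- tabulate(lab + 1L, 3L)
  present <- which(counts > 0L) - 1L
  target <- max(counts)
  X <- t(matrix(frames@features, nrow = d[1] * d[2], ncol = n))

  set.seed(seed)
  synth <- list()
  synthLab <- integer(0)
  for (cl in present) {
    idx <- which(lab == cl)
    need <- target - length(idx)
    if (need == 0L) next
    if (length(idx) < 2L)
      stop(sprintf("class %d has fewer than 2 members; cannot oversample",
                   cl))
    kEff <- min(k, length(idx) - 1L)
    if (kEff < k)
      warning(sprintf("k reduced from %d to %d for class %d (class size %d)",
                      k, kEff, cl, length(idx)))
    Xc <- X[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(Xc))
    nn <- apply(D, 1L, function(r) order(r)[2:(kEff + 1L)])
    nn <- matrix(nn, nrow = kEff)  # kEff x |class|
    pick <- sample.int(length(idx), need, replace = TRUE)
    nbr <- nn[cbind(sample.int(kEff, need, replace = TRUE), pick)]
    u <- stats::runif(need)
    S <- Xc[pick, , drop = FALSE] +
      u * (Xc[nbr, , drop = FALSE] - Xc[pick, , drop = FALSE])
    synth[[length(synth) + 1L]] <- S
    synthLab <- c(synthLab, rep.int(cl, need))
  }

  nS <- length(synthLab)
  if (nS == 0L) {
    return(new("BalancedFrameSet",
               features = frames@features,
               trainLabels = frames@trainLabels,
               testLabels = frames@testLabels,
               startSamples = frames@startSamples,
               window = frames@window, hop = frames@hop,
               fileId = frames@fileId,
               syntheticMask = logical(n)))
  }
  S <- do.call(rbind, synth)
  feats <- array(0, dim = c(d[1], d[2], n + nS))
  feats[, , seq_len(n)] <- frames@features
  feats[, , n + seq_len(nS)] <- array(t(S), dim = c(d[1], d[2], nS))
  new("BalancedFrameSet",
      features = feats,
      trainLabels = c(frames@trainLabels, synthLab),
      testLabels = c(frames@testLabels, as.integer(synthLab == 1L)),
      startSamples = c(frames@startSamples, rep.int(-1L, nS)),
      window = frames@window, hop = frames@hop, fileId = frames@fileId,
      syntheticMask = c(logical(n), rep.int(TRUE, nS)))
}
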