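# Construct small FrameSets in code for unit tests.

unitRows <- function(m) {
  n2 <- sqrt(rowSums(m^2))
  n2[n2 == 0] <- 1
  m / n2
}

# Separable three-class toy: class 0 = noise, class 1 = strong sine on the
# EOG rows, class 2 = square-wave pattern on the accelerometer rows.
makeToyFrames <- function(nPerClass = 20L, window = 60L, seed = 7L,
                          noiseSd = 0.1) {
  set.seed(seed)
  n <- 3L * nPerClass
  feats <- array(0, dim = c(5L, window, n))
  lab <- integer(n)
  tt <- seq_len(window)
  for (i in seq_len(n)) {
    cls <- (i - 1L) %/% nPerClass
    m <- matrix(rnorm(5L * window, sd = noiseSd), nrow = 5L)
    if (cls == 1L)
      m[1:2, ] <- m[1:2, ] + sin(2 * pi * 0.15 * tt)
    if (cls == 2L)
      m[3:5, ] <- m[3:5, ] + rep(c(1, -1), length.out = window)
    feats[, , i] <- unitRows(m)
    lab[i] <- cls
  }
  new("FrameSet", features = feats, trainLabels = lab,
      testLabels = as.integer(lab == 1L),
      startSamples = (seq_len(n) - 1L) * 100L,
      window = window, hop = 100L, fileId = "toy")
}

# Random imbalanced FrameSet for SMOTE property tests.
makeImbalancedFrames <- function(counts = c(30L, 5L, 4L), window = 20L,
                                 seed = 1L) {
  set.seed(seed)
  n <- sum(counts)
  lab <- rep.int(0:2, counts)
  feats <- array(rnorm(5L * window * n), dim = c(5L, window, n))
  new("FrameSet", features = feats, trainLabels = lab,
      testLabels = as.integer(lab == 1L),
      startSamples = (seq_len(n) - 1L) * 100L,
      window = window, hop = 100L, fileId = "imb")
}

tinyNetConfig <- function(window = 60L, seed = 1L, epochs = 30L,
                          mode = "2d", inputRows = 5L) {
  networkConfig(
    mode = mode, inputRows = inputRows, inputCols = window,
    convBlocks = list(list(filters = 4L, kh = if (mode == "2d") 3L else 1L,
                           kw = 5L, pool = 2L)),
    denseUnits = 8L, dropout = 0, epochs = epochs, batchSize = 20L,
    seed = seed)
}
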