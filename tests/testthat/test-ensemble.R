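test_that("majority vote matches known patterns", {
  expect_identical(majorityVote(matrix(c(1, 1, 1, 0, 0), ncol = 1)), 1L)
  expect_identical(majorityVote(matrix(c(1, 0, 0, 0, 2), ncol = 1)), 0L)
  # three-class plurality tie resolves to class 0 by default
  expect_identical(majorityVote(matrix(c(1, 1, 2, 2, 0), ncol = 1)), 0L)
  expect_identical(majorityVote(matrix(c(1, 1, 2, 2, 0), ncol = 1),
                                tieRule = "lowest"), 1L)
  expect_error(majorityVote(matrix(0L, nrow = 4, ncol = 2)), "odd")
  expect_error(majorityVote(list(c(0L, 1L), c(0L, 1L, 1L))),
               "equal length")
})

test_that("vote fusion equals brute-force counting on all 5-member patterns", {
  patterns <- as.matrix(expand.grid(rep(list(0:2), 5)))
  got <- majorityVote(t(patterns))
  want <- apply(patterns, 1L, bruteVote)
  expect_identical(as.integer(got), as.integer(want))
})

test_that("vote fusion is permutation-invariant across members", {
  set.seed(13)
  tracks <- matrix(sample(0:2, 5 * 40, replace = TRUE), nrow = 5)
  base <- majorityVote(tracks)
  for (i in 1:5)
    expect_identical(majorityVote(tracks[sample(5), , drop = FALSE]), base)
})

test_that("class-2 remapping folds supine into negative and is idempotent", {
  expect_identical(remapClass2(c(0L, 1L, 2L, 2L, 1L)),
                   c(0L, 1L, 0L, 0L, 1L))
  expect_identical(remapClass2(rep(2L, 4)), rep(0L, 4))
  x <- c(0L, 1L, 2L)
  expect_identical(remapClass2(remapClass2(x)), remapClass2(x))
})

test_that("sieve filtering matches its definition on simple cases", {
  expect_identical(sieveFilter(c(0, 1, 0, 0, 1, 1, 0), 2L, 0L),
                   c(0L, 0L, 0L, 0L, 1L, 1L, 0L))
  expect_identical(sieveFilter(c(1, 1, 0, 1, 1), 0L, 2L),
                   c(1L, 1L, 1L, 1L, 1L))
  expect_identical(sieveFilter(integer(0), 2L, 2L), integer(0))
})

test_that("sieve equals the brute-force run-length rewriter exhaustively", {
  for (len in c(1L, 5L, 9L, 12L)) {
    seqs <- allBinarySequences(len)
    for (ps in list(c(2L, 2L), c(3L, 2L), c(0L, 3L), c(2L, 0L))) {
      got <- apply(seqs, 1L, function(b)
        sieveFilter(as.integer(b), ps[1], ps[2]))
      want <- apply(seqs, 1L, function(b)
        bruteSieve(as.integer(b), ps[1], ps[2]))
      expect_identical(got, want)
    }
  }
})

test_that("sieve filtering is idempotent", {
  seqs <- allBinarySequences(10L)
  once <- apply(seqs, 1L, function(b) sieveFilter(as.integer(b), 2L, 2L))
  twice <- apply(once, 2L, function(b) sieveFilter(b, 2L, 2L))
  expect_identical(twice, once)
})

test_that("a single isolated positive frame is sieved away", {
  # the phenomenon reported for the fold whose only true detection was
  # removed by post-processing: one lone positive frame, default opening
  track <- integer(50)
  track[23] <- 1L
  expect_identical(sieveFilter(track, 2L, 2L), integer(50))
})

test_that("predictEnsemble wires voting, remapping and sieving together", {
  fr <- makeToyFrames(6L)
  cfg <- tinyNetConfig(seed = 1L, epochs = 5L)
  nets <- trainEnsemble(smoteBalance(fr, seed = 1), cfg, seeds = c(1L, 2L, 3L))
  expect_error(trainEnsemble(fr, cfg, seeds = c(1L, 2L)), "odd")
  ep <- predictEnsemble(nets, fr)
  expect_identical(dim(memberTracks(ep)), c(3L, nFrames(fr)))
  expect_true(all(binaryTrack(ep) %in% 0:1))
  expect_identical(binaryTrack(ep), remapClass2(fusedTrack(ep)))
  expect_identical(sievedTrack(ep),
                   sieveFilter(binaryTrack(ep), 2L, 2L))
})
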