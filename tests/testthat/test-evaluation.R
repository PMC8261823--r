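test_that("confusion counts tally the 2x2 table", {
  expect_identical(confusionCounts(c(1L, 0L, 1L), c(1L, 0L, 1L)),
                   c(tp = 2L, tn = 1L, fp = 0L, fn = 0L))
  expect_identical(confusionCounts(c(0L, 0L, 0L), c(1L, 1L, 0L)),
                   c(tp = 0L, tn = 1L, fp = 0L, fn = 2L))
  expect_error(confusionCounts(c(0L, 1L), c(0L)), "length")
})

test_that("confusion matches a brute-force tally exhaustively", {
  seqs <- allBinarySequences(4L)
  for (i in seq_len(nrow(seqs))) for (j in seq_len(nrow(seqs))) {
    p <- as.integer(seqs[i, ]); t <- as.integer(seqs[j, ])
    expect_identical(confusionCounts(p, t), bruteConfusion(p, t))
  }
})

test_that("metrics implement the stated formulas", {
  for (seed in 1:10) {
    set.seed(seed)
    cc <- c(tp = sample(0:50, 1), tn = sample(0:5000, 1),
            fp = sample(0:50, 1), fn = sample(0:50, 1))
    m <- frameMetrics(cc)
    if (cc["tp"] + cc["fn"] > 0)
      expect_equal(m[["sensitivity"]],
                   100 * cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]))
    if (2 * cc["tp"] + cc["fp"] + cc["fn"] > 0)
      expect_equal(m[["f1"]],
                   2 * cc[["tp"]] /
                     (2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]]))
  }
})

test_that("degenerate counts follow the reporting convention", {
  m <- frameMetrics(c(tp = 0L, tn = 10L, fp = 0L, fn = 0L))
  expect_equal(m[["sensitivity"]], 100)
  expect_equal(m[["specificity"]], 100)
  expect_equal(m[["f1"]], 1)
  # zero tp with errors present scores 0
  expect_equal(frameMetrics(c(tp = 0L, tn = 5L, fp = 2L, fn = 1L))[["f1"]],
               0)
})

test_that("specificity rounds to 100% whenever fp is relatively rare", {
  for (cc in list(c(tp = 73L, tn = 222515L, fp = 18L, fn = 68L),
                  c(tp = 56L, tn = 221963L, fp = 570L, fn = 85L))) {
    expect_lt(cc[["fp"]] / (cc[["tn"]] + cc[["fp"]]), 0.005)
    expect_equal(unname(roundedMetrics(cc)["specificity"]), 100)
  }
})

test_that("fold aggregation applies the positive-free fold convention", {
  f1 <- aggregateF1(list(c(tp = 1L, tn = 1L, fp = 0L, fn = 1L)))
  expect_equal(unname(f1), c(2 / 3, 0))  # single fold: SE reported as 0

  folds <- list(c(tp = 5L, tn = 10L, fp = 0L, fn = 0L),   # F1 = 1
                c(tp = 1L, tn = 10L, fp = 1L, fn = 1L))   # F1 = 0.5
  expect_equal(aggregateF1(folds)[["mean_f1"]], 0.75)

  # positive-free folds: 1.00 without fp, 0.00 with any fp
  clean <- c(tp = 0L, tn = 20L, fp = 0L, fn = 0L)
  dirty <- c(tp = 0L, tn = 17L, fp = 3L, fn = 0L)
  expect_equal(aggregateF1(list(clean, clean))[["mean_f1"]], 1)
  expect_equal(aggregateF1(list(dirty, clean))[["mean_f1"]], 0.5)
  expect_error(aggregateF1(list()), "no folds")
})

test_that("published confusion counts reproduce the printed metrics", {
  bm <- clinicalBenchmark()
  for (tab in list(bm$experiments, bm$networks)) {
    for (r in seq_len(nrow(tab))) {
      cc <- c(tp = tab$tp[r], tn = tab$tn[r], fp = tab$fp[r],
              fn = tab$fn[r])
      m <- roundedMetrics(cc)
      expect_equal(unname(m["sensitivity"]), tab$sensitivity[r])
      expect_equal(unname(m["specificity"]), tab$specificity[r])
      expect_equal(unname(m["f1"]), tab$f1[r])
    }
  }
})

test_that("the clinical durations give the reported 0.03% imbalance", {
  bm <- clinicalBenchmark()
  expect_equal(sum(bm$durations$nystagmus_s), 179)        # 00:02:59
  expect_equal(sum(bm$durations$non_nystagmus_s), 617678) # 171:34:38
  expect_equal(round(nystagmusPrevalence(bm$durations), 2), 0.03)
})

test_that("the cross-fold harness runs leave-one-out on tiny data", {
  dir <- withr::local_tempdir()
  cfgs <- lapply(1:3, function(i)
    simConfig(duration_s = 70, seed = 50 + i, n_nystagmus_episodes = 1L,
              episode_duration_s = c(10, 12), nystagmus_amp = 8,
              n_negative_supine_events = 0L, n_confuser_episodes = 0L,
              file_id = paste0("f", i)))
  man <- simulateDataset(cfgs, dir)
  folds <- leaveOneOutFolds(man)
  cfg <- pipelineConfig(
    convBlocks = list(list(filters = 3L, kh = 3L, kw = 7L, pool = 2L)),
    denseUnits = 8L, dropout = 0, epochs = 2L, ensembleSize = 1L,
    baseSeed = 5L)
  res <- runCrossfold(man, folds, cfg)
  expect_length(res$folds, 3L)
  # counts cover every test frame and metrics are consistent
  nTest <- (as.integer(round(70 * 41.67)) - 400L) %/% 100L + 1L
  for (f in res$folds) {
    expect_identical(sum(f$counts), nTest)
    expect_true(all(f$counts >= 0))
    expect_equal(unname(f$metrics),
                 unname(frameMetrics(f$counts)))
  }
  expect_true(all(c("mean_f1", "se_f1", "tp", "f1") %in%
                    names(res$aggregate)))
  expect_length(res$memberPooled, 1L)

  # identical seeds give identical results on rerun
  res2 <- runCrossfold(man, folds, cfg)
  expect_identical(res$folds, res2$folds)

  badFolds <- list(list(fold_id = 1, training_file_ids = c("f1", "nope"),
                        testing_file_ids = "f2"))
  expect_error(runCrossfold(man, badFolds, cfg), "unknown file_ids")
})
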