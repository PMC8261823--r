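#' Frame-level confusion counts
#'
#' @param pred binary predicted track.
#' @param truth binary test-label track of equal length.
#' @return named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusionCounts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("prediction and truth tracks differ in length")
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  c(tp = sum(pred == 1L & truth == 1L),
    tn = sum(pred == 0L & truth == 0L),
    fp = sum(pred == 1L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L))
}

#' Sensitivity, specificity and F1 from confusion counts
#'
#' sensitivity = 100 tp/(tp+fn), specificity = 100 tn/(tn+fp) (percent),
#' F1 = 2tp/(2tp+fp+fn) (fraction). Degenerate denominators follow the
#' reporting convention for folds without positive examples: with no
#' positive truth frames (tp+fn = 0) sensitivity is reported as 100%, and
#' with no detections or positives at all (2tp+fp+fn = 0) F1 is reported as
#' 1.00; F1 is 0 when tp = 0 but fp+fn > 0.
#'
#' @param counts named vector with elements tp, tn, fp, fn.
#' @return named numeric `c(sensitivity, specificity, f1)`.
#' @export
frameMetrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  sens <- if (tp + fn == 0) 100 else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) 100 else 100 * tn / (tn + fp)
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  c(sensitivity = sens, specificity = spec, f1 = f1)
}

#' Metrics rounded to reporting precision
#'
#' Sensitivity and specificity to the nearest integer percent, F1 to two
#' decimals — the precision used in the published result tables. Raw values
#' come from [frameMetrics()].
#'
#' @inheritParams frameMetrics
#' @export
roundedMetrics <- function(counts) {
  m <- frameMetrics(counts)
  c(sensitivity = round(m[["sensitivity"]]),
    specificity = round(m[["specificity"]]),
    f1 = round(m[["f1"]], 2))
}

# Per-fold F1 under the degenerate-fold convention: a fold without positive
# truth frames scores 1.00 iff it also produced no false positives, else 0.
.foldF1 <- function(counts) {
  if (counts[["tp"]] + counts[["fn"]] == 0)
    return(if (counts[["fp"]] == 0) 1 else 0)
  frameMetrics(counts)[["f1"]]
}

#' Aggregate F1 over cross-validation folds
#'
#' Mean and standard error (sample standard deviation over folds divided by
#' the square root of the fold count; 0 for a single fold) of per-fold F1
#' scores. Folds with no positive truth frames contribute 1.00 if they also
#' have no false positives, else 0.00.
#'
#' @param foldCounts list of per-fold confusion-count vectors.
#' @return named numeric `c(mean_f1, se_f1)`.
#' @export
aggregateF1 <- function(foldCounts) {
  if (!length(foldCounts)) stop("no folds to aggregate")
  f1 <- vapply(foldCounts, .foldF1, numeric(1))
  se <- if (length(f1) < 2L) 0 else stats::sd(f1) / sqrt(length(f1))
  c(mean_f1 = mean(f1), se_f1 = se)
}

#' Leave-one-out fold specifications
#'
#' One fold per manifest entry: that file is the test set, all others train.
#'
#' @param manifest a manifest data.frame (see [readManifest()]).
#' @return list of folds, each `list(fold_id, training_file_ids,
#'   testing_file_ids)`.
#' @export
leaveOneOutFolds <- function(manifest) {
  ids <- manifest$file_id
  lapply(seq_along(ids), function(i)
    list(fold_id = i, training_file_ids = ids[-i],
         testing_file_ids = ids[i]))
}

#' Cross-fold evaluation of the full detection pipeline
#'
#' For each fold: preprocess and frame every file, SMOTE-balance the
#' training frames (training data only), train the seeded ensemble, classify
#' the test files, fuse by majority vote, remap class 2, sieve-filter each
#' test file's track, and score against the frame test labels. Per-file
#' tracks are sieved independently, then their confusion counts are summed
#' within the fold.
#'
#' @param manifest manifest data.frame of recording/label paths.
#' @param folds list of fold specifications (see [leaveOneOutFolds()]).
#' @param config a [pipelineConfig()].
#' @return list with `folds` (per-fold results: counts before and after the
#'   sieve, rounded and raw metrics, member counts), `aggregate` (mean/SE F1
#'   under the degenerate-fold rule plus pooled counts and metrics), and
#'   `memberPooled` (per-member pooled post-processing F1, for
#'   ensemble-benefit comparisons).
#' @export
runCrossfold <- function(manifest, folds, config = pipelineConfig()) {
  stopifnot(nrow(manifest) >= 2L, length(folds) >= 1L)
  allIds <- unique(unlist(lapply(folds, function(f)
    c(f$training_file_ids, f$testing_file_ids))))
  missing <- setdiff(allIds, manifest$file_id)
  if (length(missing))
    stop(sprintf("fold references unknown file_ids: %s",
                 paste(missing, collapse = ", ")))

  frameCache <- new.env(parent = emptyenv())
  getFrames <- function(fid) {
    if (!is.null(frameCache[[fid]])) return(frameCache[[fid]])
    row <- manifest[manifest$file_id == fid, ]
    rec <- readRecording(row$recording)
    lab <- readLabels(row$labels, rec)
    aligned <- alignAccelerometer(rec, cutoff = config$cutoff,
                                  order = config$order,
                                  zeroPhase = config$zeroPhase)
    fr <- makeFrames(aligned, lab, window = config$window,
                     overlapFraction = config$overlapFraction)
    fr <- subsetChannels(fr, config$channels)
    frameCache[[fid]] <- fr
    fr
  }

  nMember <- config$ensembleSize
  foldResults <- list()
  memberCounts <- replicate(nMember,
                            c(tp = 0L, tn = 0L, fp = 0L, fn = 0L),
                            simplify = FALSE)
  for (fold in folds) {
    train <- combineFrameSets(lapply(fold$training_file_ids, getFrames))
    balanced <- smoteBalance(train, k = config$smoteK,
                             seed = config$baseSeed + 7919L * fold$fold_id)
    rows <- dim(balanced@features)[1]
    netCfg <- networkConfig(
      mode = config$mode, inputRows = rows, inputCols = config$window,
      convBlocks = if (is.null(config$convBlocks))
        referenceArchitecture(rows, config$mode, config$architectureSize)
      else config$convBlocks,
      denseUnits = config$denseUnits, dropout = config$dropout,
      learningRate = config$learningRate, batchSize = config$batchSize,
      epochs = config$epochs, seed = config$baseSeed)
    seeds <- config$memberSeeds + 1000L * fold$fold_id
    nets <- trainEnsemble(balanced, netCfg, seeds)

    pre <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    post <- pre
    for (fid in fold$testing_file_ids) {
      te <- getFrames(fid)
      if (!nFrames(te)) stop(sprintf("fold %d: no test frames in file %s",
                                     fold$fold_id, fid))
      ep <- predictEnsemble(nets, te, openLen = config$openLen,
                            closeLen = config$closeLen,
                            tieRule = config$tieRule,
                            remapStage = config$remapStage)
      truth <- testLabels(te)
      pre <- pre + confusionCounts(binaryTrack(ep), truth)
      post <- post + confusionCounts(sievedTrack(ep), truth)
      for (m in seq_len(nMember)) {
        mt <- sieveFilter(remapClass2(memberTracks(ep)[m, ]),
                          config$openLen, config$closeLen)
        memberCounts[[m]] <- memberCounts[[m]] + confusionCounts(mt, truth)
      }
    }
    foldResults[[length(foldResults) + 1L]] <- list(
      fold_id = fold$fold_id, counts = post, preSieveCounts = pre,
      metrics = frameMetrics(post), rounded = roundedMetrics(post),
      f1 = .foldF1(post))
  }
  pooled <- Reduce(`+`, lapply(foldResults, `[[`, "counts"))
  list(
    folds = foldResults,
    aggregate = c(aggregateF1(lapply(foldResults, `[[`, "counts")),
                  pooled, frameMetrics(pooled)),
    memberPooled = vapply(memberCounts,
                          function(cc) frameMetrics(cc)[["f1"]],
                          numeric(1)))
}

#' Read or write fold specifications
#'
#' Text format: CSV with columns `fold_id`, `training` and `testing`, the
#' latter two holding `+`-separated file ids.
#'
#' @param path fold-spec file path.
#' @return a fold list as used by [runCrossfold()].
#' @export
readFoldSpecs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fold_id", "training", "testing")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: fold file must have columns %s", path,
                 paste(need, collapse = ", ")))
  lapply(seq_len(nrow(df)), function(i) {
    tr <- strsplit(as.character(df$training[i]), "+", fixed = TRUE)[[1]]
    te <- strsplit(as.character(df$testing[i]), "+", fixed = TRUE)[[1]]
    if (length(intersect(tr, te)))
      stop(sprintf("%s: fold %s has overlapping train/test ids",
                   path, df$fold_id[i]))
    list(fold_id = as.integer(df$fold_id[i]), training_file_ids = tr,
         testing_file_ids = te)
  })
}

#' @rdname readFoldSpecs
#' @param folds fold list.
#' @export
writeFoldSpecs <- function(folds, path) {
  df <- do.call(rbind, lapply(folds, function(f)
    data.frame(fold_id = f$fold_id,
               training = paste(f$training_file_ids, collapse = "+"),
               testing = paste(f$testing_file_ids, collapse = "+"))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
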