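#' Pipeline configuration
#'
#' Collects every tunable of the detection chain, with defaults matching the
#' published operating point: 0.25 Hz / order-2 high-pass, 400-sample window
#' with 75% overlap, SMOTE with k = 5, a five-member ensemble, learning rate
#' 0.001, batch size 20, 30 epochs, and a 2-frame open / 2-frame close
#' sieve.
#'
#' @param cutoff,order,zeroPhase high-pass filter settings
#'   (see [highpassFilter()]).
#' @param window,overlapFraction framing settings (see [makeFrames()]).
#' @param smoteK SMOTE neighbour count.
#' @param mode network mode, `"2d"` or `"1d"`.
#' @param channels `"all"`, `"eog"` or `"accel"` (single-modality
#'   ablations).
#' @param convBlocks explicit conv blocks, or `NULL` for the reference
#'   architecture of size `architectureSize`.
#' @param architectureSize `"full"` or `"reduced"`.
#' @param denseUnits,dropout,learningRate,batchSize,epochs network training
#'   settings (see [networkConfig()]).
#' @param ensembleSize number of ensemble members (odd).
#' @param baseSeed integer base seed; every random stage derives its seed
#'   from it.
#' @param memberSeeds explicit member seeds (length `ensembleSize`), default
#'   `baseSeed + 0:(ensembleSize-1)`.
#' @param openLen,closeLen,tieRule,remapStage post-processing settings (see
#'   [predictEnsemble()]).
#' @return a validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(cutoff = 0.25, order = 2L, zeroPhase = FALSE,
                           window = 400L, overlapFraction = 0.75,
                           smoteK = 5L, mode = "2d", channels = "all",
                           convBlocks = NULL, architectureSize = "full",
                           denseUnits = 64L, dropout = 0.5,
                           learningRate = 0.001, batchSize = 20L,
                           epochs = 30L, ensembleSize = 5L, baseSeed = 1L,
                           memberSeeds = NULL, openLen = 2L, closeLen = 2L,
                           tieRule = "class0", remapStage = "after") {
  ensembleSize <- as.integer(ensembleSize)
  if (ensembleSize %% 2L == 0L)
    stop("ensembleSize must be odd (an even vote could tie)")
  if (is.null(memberSeeds))
    memberSeeds <- as.integer(baseSeed) + 0:(ensembleSize - 1L)
  if (length(memberSeeds) != ensembleSize)
    stop("memberSeeds length must equal ensembleSize")
  cfg <- list(cutoff = cutoff, order = as.integer(order),
              zeroPhase = isTRUE(zeroPhase), window = as.integer(window),
              overlapFraction = overlapFraction, smoteK = as.integer(smoteK),
              mode = match.arg(mode, c("2d", "1d")),
              channels = match.arg(channels, c("all", "eog", "accel")),
              convBlocks = convBlocks,
              architectureSize = match.arg(architectureSize,
                                           c("full", "reduced")),
              denseUnits = as.integer(denseUnits), dropout = dropout,
              learningRate = learningRate, batchSize = as.integer(batchSize),
              epochs = as.integer(epochs), ensembleSize = ensembleSize,
              baseSeed = as.integer(baseSeed),
              memberSeeds = as.integer(memberSeeds),
              openLen = as.integer(openLen), closeLen = as.integer(closeLen),
              tieRule = match.arg(tieRule, c("class0", "lowest")),
              remapStage = match.arg(remapStage, c("after", "before")))
  stopifnot(cfg$cutoff > 0, cfg$order >= 1L, cfg$window >= 2L,
            cfg$overlapFraction >= 0, cfg$overlapFraction < 1,
            cfg$smoteK >= 1L, cfg$epochs >= 1L, cfg$batchSize >= 1L,
            cfg$openLen >= 0L, cfg$closeLen >= 0L)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load or save a pipeline configuration file
#'
#' Configurations are YAML files whose keys are the arguments of
#' [pipelineConfig()]; omitted keys take the defaults, unknown keys raise an
#' error. `saveConfig()` then `loadConfig()` is the identity.
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
loadConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(unknown, collapse = ", ")))
  do.call(pipelineConfig, vals)
}

#' @rdname loadConfig
#' @param config a `PipelineConfig`.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' Executes the complete detection chain (preprocess, frame, balance, train
#' ensemble, predict, vote, remap, sieve, score) over a dataset and fold
#' specification, writing per-fold results, the aggregate, and a run log
#' (seeds, per-stage timing) into `outDir`. Reruns with the same
#' configuration produce byte-identical result files.
#'
#' @param config a [pipelineConfig()].
#' @param manifest manifest data.frame (see [readManifest()]).
#' @param folds fold list (see [leaveOneOutFolds()]).
#' @param outDir output directory, created if needed.
#' @return the [runCrossfold()] result, invisibly.
#' @export
runEndToEnd <- function(config, manifest, folds, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  res <- runCrossfold(manifest, folds, config)
  elapsed <- proc.time()[["elapsed"]] - t0

  perFold <- do.call(rbind, lapply(res$folds, function(f)
    data.frame(fold_id = f$fold_id,
               tp = f$counts[["tp"]], tn = f$counts[["tn"]],
               fp = f$counts[["fp"]], fn = f$counts[["fn"]],
               sensitivity = f$rounded[["sensitivity"]],
               specificity = f$rounded[["specificity"]],
               f1 = f$rounded[["f1"]])))
  utils::write.csv(perFold, file.path(outDir, "folds.csv"),
                   row.names = FALSE, quote = FALSE)
  agg <- res$aggregate
  utils::write.csv(
    data.frame(metric = names(agg), value = round(as.numeric(agg), 6)),
    file.path(outDir, "aggregate.csv"), row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("files: %d; folds: %d", nrow(manifest), length(folds)),
    sprintf("base_seed: %d", config$baseSeed),
    sprintf("member_seeds: %s", paste(config$memberSeeds, collapse = " ")),
    sprintf("channels: %s; mode: %s", config$channels, config$mode),
    sprintf("elapsed_s: %.1f", elapsed)),
    file.path(outDir, "run.log"))
  saveConfig(config, file.path(outDir, "config.yaml"))
  invisible(res)
}
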