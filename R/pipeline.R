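# End-to-end convenience driver: single-cell preprocessing, splits, sampling,
# assembly, standardization, training and evaluation in one call. This is the
# path the synthetic recovery study and the command-line wrapper use.

#' Run the full drug-response pipeline on loaded data
#'
#' Performs, in order: single-cell QC -> log-normalization -> variable-gene
#' selection -> cell-cycle scoring -> scaling; pair splitting (10% held-out
#' lines and drugs, 70-30 train-test); k-cell sampling with median padding
#' (held-out lines sampled separately so their cells never enter training
#' tensors); branch assembly with leakage assertions; train-only
#' zero-variance pruning and standardization; forked-model training with the
#' test partition as the monitored validation set; and the six-metric report
#' per partition.
#'
#' @param pairs pair table (will be deduplicated).
#' @param drugBlocks list of [DrugFeatureTable-class].
#' @param omicsBlocks list of [OmicsBlock-class].
#' @param sc a counts-layer [SingleCellMatrix-class], or `NULL` to run
#'   without the single-cell branch.
#' @param config a [ForkedModelConfig-class].
#' @param k single cells sampled per line (default 10).
#' @param qc a [QcThresholds-class]; scale `minGenesPerCell` to the panel
#'   size when using small synthetic panels.
#' @param nHvg variable genes kept (default 2000, capped at the panel size).
#' @param ccGeneSets optional list(s, g2m) for cell-cycle scoring; scoring is
#'   skipped when `NULL`.
#' @param holdoutFraction,testFraction split settings (defaults 0.10 / 0.30).
#' @param seed master seed for split, sampling and training.
#' @return list with `bundle`, `model`, `history`, `metrics` (named list of
#'   [MetricsReport-class]), `scores` (cell-cycle scores or NULL) and `split`.
#' @export
runPipeline <- function(pairs, drugBlocks, omicsBlocks, sc = NULL,
                        config = forkedModelConfig(),
                        k = 10L, qc = qcThresholds(), nHvg = 2000L,
                        ccGeneSets = NULL,
                        holdoutFraction = 0.10, testFraction = 0.30,
                        seed = 1L) {
  pairs <- dedupPairs(pairs)
  split <- makeSplits(pairs, holdoutFraction, testFraction,
                      seed = deriveSeed(seed, "split"))

  sampled <- sampledHeldOut <- NULL
  scores <- NULL
  if (!is.null(sc) && config@useSingleCell) {
    filtered <- qcFilter(sc, qc)
    ln <- logNormalize(filtered)
    hvg <- selectHvg(ln, min(nHvg, nrow(ln)))
    if (!is.null(ccGeneSets)) {
      scores <- scoreCellCycle(ln, ccGeneSets, seed = deriveSeed(seed, "cc"))
    }
    scaled <- scaleCenter(ln, hvg)
    availableLines <- unique(cellLines(scaled))
    sampled <- sampleSingleCells(
      scaled, k,
      seed = deriveSeed(seed, "cells"),
      excludeLines = union(
        split@heldOutCellLines,
        setdiff(availableLines, pairs$cell_line_id)
      )
    )
    heldAvailable <- intersect(split@heldOutCellLines, availableLines)
    if (length(heldAvailable)) {
      sampledHeldOut <- sampleSingleCells(
        scaled, k,
        seed = deriveSeed(seed, "cells_heldout"),
        excludeLines = setdiff(availableLines, heldAvailable)
      )
    }
  }

  bundle <- assembleBranchInputs(
    pairs, split, drugBlocks, omicsBlocks,
    sampled = sampled, sampledHeldOut = sampledHeldOut
  )
  bundle <- standardizeBundle(bundle)

  cfg <- config
  cfg@seed <- deriveSeed(seed, "model")
  widths <- vapply(bundle$partitions$train$inputs, ncol, 1L)
  model <- buildForkedModel(cfg, widths)
  fit <- trainForkedModel(
    model,
    bundle$partitions$train$inputs, bundle$partitions$train$y,
    bundle$partitions$test$inputs, bundle$partitions$test$y
  )

  metrics <- list()
  for (part in setdiff(names(bundle$partitions), "train")) {
    p <- bundle$partitions[[part]]
    metrics[[part]] <- computeMetrics(p$y, predict(fit$model, p$inputs), part)
  }

  list(
    bundle = bundle, model = fit$model, history = fit$history,
    metrics = metrics, scores = scores, split = split, sampled = sampled
  )
}
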