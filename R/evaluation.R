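# Regression metric suite (MSE, MAE, RMSE, PCC, SCC, R^2) and the
# concatenated-input baselines (gradient boosting, single-branch MLP) used to
# benchmark the forked model.

#' Compute the six-metric regression report
#'
#' MSE = mean squared residual, MAE = mean absolute residual, RMSE =
#' sqrt(MSE), PCC = sample Pearson correlation, SCC = Pearson correlation of
#' mid-ranks (average ranks on ties), R^2 = 1 - SS_res / SS_tot (coefficient
#' of determination; can be negative). Correlation metrics and R^2 are `NA`
#' when `yTrue` is constant.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @param partition partition tag stored in the report.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(yTrue, yPred, partition = "test") {
  if (length(yTrue) != length(yPred)) {
    stopf("length mismatch: %d vs %d", length(yTrue), length(yPred))
  }
  if (length(yTrue) < 2) stopf("need at least 2 samples")
  res <- yTrue - yPred
  mse <- mean(res^2)
  mae <- mean(abs(res))
  ssTot <- sum((yTrue - mean(yTrue))^2)
  constant <- ssTot == 0
  constantPred <- var(yPred) == 0
  pcc <- if (constant || constantPred) NA_real_ else cor(yTrue, yPred)
  scc <- if (constant || constantPred) {
    NA_real_
  } else {
    cor(rank(yTrue, ties.method = "average"), rank(yPred, ties.method = "average"))
  }
  r2 <- if (constant) NA_real_ else 1 - sum(res^2) / ssTot
  new("MetricsReport",
    mse = mse, mae = mae, rmse = sqrt(mse), pcc = pcc, scc = scc, r2 = r2,
    n = length(yTrue), partition = partition
  )
}

#' Concatenate branch matrices column-wise (for single-input baselines)
#'
#' @param blocks named list of row-aligned matrices.
#' @return single matrix; a column-provenance manifest (block of origin per
#'   column) is attached as attribute `"provenance"`.
#' @export
concatenateBlocks <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  rows <- unique(vapply(blocks, nrow, 1L))
  if (length(rows) != 1) stopf("blocks have mismatched row counts")
  m <- do.call(cbind, blocks)
  attr(m, "provenance") <- rep(names(blocks), vapply(blocks, ncol, 1L))
  m
}

.baselineMlpConfig <- function(seed) {
  forkedModelConfig(
    useSingleCell = FALSE, hiddenLayerNumber = 3L,
    hiddenSizeDrugs = 128L, hiddenSizeBulk = 128L, hiddenSizeSingleCells = 128L,
    l1 = 0, l2 = 1e-5, batchSize = 64L, maxEpochs = 150L, seed = seed
  )
}

#' Run a concatenated-input baseline over an assembled bundle
#'
#' `"gradient_boosting"` delegates to a boosted-tree regressor (xgboost);
#' `"single_branch_mlp"` is one deep ReLU stack with a linear head on the
#' concatenated matrix (a generic stand-in for published single-input DNN
#' architectures, not a layer-for-layer reproduction of any of them). Both are
#' evaluated with [computeMetrics()] on every available partition.
#'
#' @param kind `"gradient_boosting"` or `"single_branch_mlp"`.
#' @param bundle standardized bundle from [standardizeBundle()].
#' @param seed integer seed.
#' @param nrounds,maxDepth,etaBoost gradient-boosting settings.
#' @param mlpConfig optional [ForkedModelConfig-class] for the MLP baseline.
#' @return named list of [MetricsReport-class], one per partition other than
#'   train.
#' @export
runBaseline <- function(kind = c("gradient_boosting", "single_branch_mlp"),
                        bundle, seed = 1L, nrounds = 300L, maxDepth = 6L,
                        etaBoost = 0.1, mlpConfig = NULL) {
  kind <- match.arg(kind)
  parts <- bundle$partitions
  X <- lapply(parts, function(p) concatenateBlocks(p$inputs))
  y <- lapply(parts, function(p) p$y)
  evalParts <- setdiff(names(parts), "train")
  if (kind == "gradient_boosting") {
    booster <- withSeed(seed, xgboost::xgboost(
      x = X$train, y = y$train, objective = "reg:squarederror",
      nrounds = nrounds, max_depth = maxDepth, learning_rate = etaBoost,
      subsample = 0.8, nthreads = 1L, verbosity = 0
    ))
    preds <- lapply(X[evalParts], function(m) predict(booster, m))
  } else {
    cfg <- if (is.null(mlpConfig)) .baselineMlpConfig(seed) else mlpConfig
    model <- buildForkedModel(cfg, c(concatenated = ncol(X$train)))
    fit <- trainForkedModel(
      model, list(concatenated = X$train), y$train,
      list(concatenated = X$test), y$test
    )
    preds <- lapply(X[evalParts], function(m) {
      predict(fit$model, list(concatenated = m))
    })
  }
  out <- lapply(evalParts, function(pt) computeMetrics(y[[pt]], preds[[pt]], pt))
  stats::setNames(out, evalParts)
}

#' Collate metric reports into a benchmark table
#'
#' @param metrics named list (model name -> list of [MetricsReport-class]) or
#'   a flat list of reports.
#' @return data.frame with one row per model x partition and the six metric
#'   columns.
#' @export
reportMetrics <- function(metrics) {
  if (length(metrics) == 0) {
    return(data.frame(
      model = character(), partition = character(), n = integer(),
      mse = numeric(), mae = numeric(), rmse = numeric(),
      pcc = numeric(), scc = numeric(), r2 = numeric()
    ))
  }
  if (is(metrics[[1]], "MetricsReport")) metrics <- list(model = metrics)
  rows <- lapply(names(metrics), function(model) {
    sub <- lapply(metrics[[model]], metricsAsRow)
    df <- do.call(rbind, sub)
    cbind(model = model, df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a benchmark table as CSV and aligned text
#'
#' @param table data.frame from [reportMetrics()].
#' @param path output path without extension; `.csv` and `.txt` are written.
#' @return invisibly, the paths written.
#' @export
writeBenchmark <- function(table, path) {
  csv <- paste0(path, ".csv")
  txt <- paste0(path, ".txt")
  write.csv(table, csv, row.names = FALSE)
  writeLines(capture.output(print(table, digits = 4, row.names = FALSE)), txt)
  invisible(c(csv, txt))
}
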