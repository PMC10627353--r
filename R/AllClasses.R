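#' @import methods
NULL

# ---------------------------------------------------------------- drug block

#' DrugFeatureTable: one fixed-width descriptor block for a set of drugs
#'
#' A drugs x features real-valued matrix produced by one featurization
#' backend (general physico-chemical descriptors, or taxonomy / SMILES-token
#' features). Row names are drug identifiers; all entries are finite after
#' column-wise cleaning.
#'
#' @slot blockName character(1), e.g. `"general_descriptors"`.
#' @slot matrix numeric matrix, drugs x features, rownames = drug ids.
#' @slot droppedColumns character, descriptor columns removed because they
#'   contained non-numeric or non-finite values.
#'
#' @exportClass DrugFeatureTable
setClass("DrugFeatureTable",
  representation(
    blockName = "character",
    matrix = "matrix",
    droppedColumns = "character"
  )
)

setValidity("DrugFeatureTable", function(object) {
  m <- object@matrix
  if (is.null(rownames(m))) return("matrix must have drug ids as rownames")
  if (anyDuplicated(rownames(m))) return("duplicated drug ids")
  if (is.null(colnames(m)) && ncol(m) > 0) return("matrix must have feature names")
  if (anyDuplicated(colnames(m))) return("duplicated feature names")
  if (length(m) && !all(is.finite(m))) return("non-finite entries after cleaning")
  TRUE
})

#' @describeIn DrugFeatureTable drug identifiers (row order).
#' @param x,object a `DrugFeatureTable`.
#' @export
drugIds <- function(x) rownames(x@matrix)

#' @describeIn DrugFeatureTable the descriptor matrix.
#' @export
featureMatrix <- function(x) x@matrix

#' @describeIn DrugFeatureTable block label.
#' @export
blockName <- function(x) x@blockName

setMethod("show", "DrugFeatureTable", function(object) {
  cat(sprintf(
    "DrugFeatureTable '%s': %d drugs x %d features (%d columns dropped)\n",
    object@blockName, nrow(object@matrix), ncol(object@matrix),
    length(object@droppedColumns)
  ))
})

# ---------------------------------------------------------------- omics block

#' OmicsBlock: one bulk omics matrix over a cell-line universe
#'
#' Cell lines x features matrix reindexed to a caller-supplied cell-line
#' universe. Cell lines absent from the source file get all-zero rows and are
#' recorded in `missingCellIds`; scalar missing entries are zero-filled
#' (absence of the measured entity, per the assembly protocol).
#'
#' @slot blockName character(1) label, e.g. `"methylation"`.
#' @slot matrix numeric matrix, cell lines x features.
#' @slot missingCellIds character, lines absent from the source file.
#'
#' @exportClass OmicsBlock
setClass("OmicsBlock",
  representation(
    blockName = "character",
    matrix = "matrix",
    missingCellIds = "character"
  )
)

setValidity("OmicsBlock", function(object) {
  m <- object@matrix
  if (is.null(rownames(m))) return("matrix must have cell-line ids as rownames")
  if (anyDuplicated(rownames(m))) return("duplicated cell-line rows")
  if (length(m) && !all(is.finite(m))) return("non-finite entries")
  miss <- object@missingCellIds
  if (length(miss)) {
    bad <- setdiff(miss, rownames(m))
    if (length(bad)) return("missingCellIds not in matrix rownames")
    if (any(m[miss, , drop = FALSE] != 0)) {
      return("rows for missing cell lines must be all-zero")
    }
  }
  TRUE
})

#' @describeIn OmicsBlock cell-line identifiers (row order).
#' @param x,object an `OmicsBlock`.
#' @export
cellLineIds <- function(x) rownames(x@matrix)

#' @describeIn OmicsBlock cell lines that were absent from the source file.
#' @export
missingCellIds <- function(x) x@missingCellIds

setMethod("show", "OmicsBlock", function(object) {
  cat(sprintf(
    "OmicsBlock '%s': %d cell lines x %d features (%d lines zero-filled)\n",
    object@blockName, nrow(object@matrix), ncol(object@matrix),
    length(object@missingCellIds)
  ))
})

# ------------------------------------------------------------- single cells

#' SingleCellMatrix: labelled single-cell expression with a pipeline layer tag
#'
#' Extends [SingleCellExperiment::SingleCellExperiment] (genes as rows, cells
#' as columns). `colData` must carry `cell_line_id` and `dataset_id` per cell.
#' The `layer` tag records the preprocessing stage (`counts`, `lognorm`,
#' `scaled`) and is checked by every pipeline step so that stages cannot be
#' applied out of order.
#'
#' @slot layer character(1): `"counts"`, `"lognorm"` or `"scaled"`.
#'
#' @exportClass SingleCellMatrix
setClass("SingleCellMatrix",
  contains = "SingleCellExperiment",
  representation(layer = "character")
)

setValidity("SingleCellMatrix", function(object) {
  if (length(object@layer) != 1L ||
      !object@layer %in% c("counts", "lognorm", "scaled")) {
    return("layer must be one of counts/lognorm/scaled")
  }
  if (is.null(rownames(object))) return("gene symbols (rownames) required")
  if (anyDuplicated(rownames(object))) return("gene symbols must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"cell_line_id" %in% colnames(cd)) return("colData$cell_line_id required")
  if (any(is.na(cd$cell_line_id) | cd$cell_line_id == "")) {
    return("every cell needs a cell_line_id")
  }
  if (object@layer == "counts") {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (min(cnt) < 0) return("counts layer must be non-negative")
  }
  TRUE
})

#' Construct a SingleCellMatrix from a genes x cells matrix
#'
#' @param counts numeric matrix (genes x cells) with unique gene-symbol
#'   rownames; interpreted according to `layer`.
#' @param cellLine character vector, one cell-line id per cell.
#' @param dataset character vector or scalar dataset id (default "ds1").
#' @param layer layer tag; `"counts"` for raw UMI/read counts.
#' @return a [SingleCellMatrix-class] object.
#' @export
SingleCellMatrix <- function(counts, cellLine, dataset = "ds1", layer = "counts") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%04d", seq_len(ncol(counts)))
  }
  cd <- S4Vectors::DataFrame(
    cell_line_id = as.character(rep_len(cellLine, ncol(counts))),
    dataset_id = as.character(rep_len(dataset, ncol(counts))),
    row.names = colnames(counts)
  )
  assays <- stats::setNames(list(counts), layer)
  sce <- SingleCellExperiment::SingleCellExperiment(assays = assays, colData = cd)
  new("SingleCellMatrix", sce, layer = layer)
}

#' @describeIn SingleCellMatrix the pipeline layer tag.
#' @param x,object a `SingleCellMatrix`.
#' @export
scLayer <- function(x) x@layer

#' @describeIn SingleCellMatrix per-cell cell-line labels.
#' @export
cellLines <- function(x) as.character(SummarizedExperiment::colData(x)$cell_line_id)

#' @describeIn SingleCellMatrix the matrix of the current layer (genes x cells).
#' @export
scValues <- function(x) SummarizedExperiment::assay(x, x@layer)

setMethod("show", "SingleCellMatrix", function(object) {
  cat(sprintf(
    "SingleCellMatrix [%s]: %d genes x %d cells, %d cell lines, %d dataset(s)\n",
    object@layer, nrow(object), ncol(object),
    length(unique(cellLines(object))),
    length(unique(SummarizedExperiment::colData(object)$dataset_id))
  ))
})

# ---------------------------------------------------------------- thresholds

#' QcThresholds: single-cell quality-control thresholds
#'
#' Defaults follow the pipeline convention: keep cells expressing at least
#' 1000 genes and remove cells with strictly more than 15% mitochondrial
#' counts, mitochondrial genes being identified by symbol prefix (default
#' `"MT-"`, case-insensitive).
#'
#' @slot minGenesPerCell integer(1).
#' @slot maxMitoFraction numeric(1) in (0, 1).
#' @slot mitoGeneRule character(1) gene-symbol prefix.
#' @exportClass QcThresholds
setClass("QcThresholds",
  representation(
    minGenesPerCell = "integer",
    maxMitoFraction = "numeric",
    mitoGeneRule = "character"
  )
)

setValidity("QcThresholds", function(object) {
  if (object@minGenesPerCell < 1L) return("minGenesPerCell must be >= 1")
  if (object@maxMitoFraction <= 0 || object@maxMitoFraction >= 1) {
    return("maxMitoFraction must lie in (0, 1)")
  }
  TRUE
})

#' @rdname QcThresholds-class
#' @param minGenesPerCell minimum number of expressed genes per retained cell.
#' @param maxMitoFraction maximum tolerated mitochondrial count fraction.
#' @param mitoGeneRule gene-symbol prefix identifying mitochondrial genes.
#' @export
qcThresholds <- function(minGenesPerCell = 1000L, maxMitoFraction = 0.15,
                         mitoGeneRule = "MT-") {
  new("QcThresholds",
    minGenesPerCell = as.integer(minGenesPerCell),
    maxMitoFraction = maxMitoFraction, mitoGeneRule = mitoGeneRule
  )
}

setMethod("show", "QcThresholds", function(object) {
  cat(sprintf(
    "QcThresholds: >= %d expressed genes, <= %.1f%% '%s*' counts\n",
    object@minGenesPerCell, 100 * object@maxMitoFraction, object@mitoGeneRule
  ))
})

# --------------------------------------------------------------- split bundle

#' SplitBundle: the four-way partition of a drug-cell-line pair table
#'
#' Row-index sets into the pair table: `train` / `test` (70-30 over pairs
#' whose drug and cell line are both retained), `leaveCellOut` (held-out cell
#' line, retained drug), `leaveDrugOut` (held-out drug, retained line).
#' Pairs touching both a held-out drug and a held-out line are discarded and
#' recorded.
#'
#' @slot trainIdx,testIdx,leaveCellOutIdx,leaveDrugOutIdx,discardedIdx integer
#'   row indices, pairwise disjoint.
#' @slot heldOutCellLines,heldOutDrugs character key sets.
#' @slot seed integer(1) seed used for the partition.
#' @exportClass SplitBundle
setClass("SplitBundle",
  representation(
    trainIdx = "integer", testIdx = "integer",
    leaveCellOutIdx = "integer", leaveDrugOutIdx = "integer",
    discardedIdx = "integer",
    heldOutCellLines = "character", heldOutDrugs = "character",
    seed = "integer"
  )
)

setValidity("SplitBundle", function(object) {
  sets <- list(
    object@trainIdx, object@testIdx,
    object@leaveCellOutIdx, object@leaveDrugOutIdx, object@discardedIdx
  )
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx)) return("partitions must be pairwise disjoint")
  TRUE
})

setMethod("show", "SplitBundle", function(object) {
  cat(sprintf(
    paste0(
      "SplitBundle (seed %d): %d train / %d test / %d leave-cell-out / ",
      "%d leave-drug-out / %d discarded\n  held out: %d cell lines, %d drugs\n"
    ),
    object@seed, length(object@trainIdx), length(object@testIdx),
    length(object@leaveCellOutIdx), length(object@leaveDrugOutIdx),
    length(object@discardedIdx),
    length(object@heldOutCellLines), length(object@heldOutDrugs)
  ))
})

# --------------------------------------------------------------- standardizer

#' Standardizer: train-partition feature statistics
#'
#' Per-feature mean and standard deviation estimated on the training rows
#' only; `applyStandardizer()` transforms any partition with these stored
#' statistics (no re-fitting path exists for non-training data).
#'
#' @slot mean,sd named numeric vectors.
#' @slot fitPartition character(1) tag of the partition the stats came from.
#' @exportClass Standardizer
setClass("Standardizer",
  representation(mean = "numeric", sd = "numeric", fitPartition = "character")
)

setValidity("Standardizer", function(object) {
  if (length(object@mean) != length(object@sd)) return("mean/sd length mismatch")
  if (any(object@sd <= 0)) {
    return("sd must be > 0 for all features (prune zero-variance features first)")
  }
  TRUE
})

setMethod("show", "Standardizer", function(object) {
  cat(sprintf(
    "Standardizer: %d features, fitted on '%s'\n",
    length(object@mean), object@fitPartition
  ))
})

# --------------------------------------------------------- sampled cell block

#' SampledCellBlock: fixed-size single-cell samples per cell line
#'
#' For every cell line, exactly `k` rows of scaled expression: a seeded
#' without-replacement sample when at least `k` cells are available, otherwise
#' all available cells plus median pseudo-cells (per-gene median over that
#' line's available cells).
#'
#' @slot cells named list of k x genes matrices, one per cell line.
#' @slot paddedCount named integer, pseudo-cells added per line.
#' @slot k integer(1).
#' @slot genes character, gene order shared by all matrices.
#' @slot seed integer(1).
#' @exportClass SampledCellBlock
setClass("SampledCellBlock",
  representation(
    cells = "list", paddedCount = "integer", k = "integer",
    genes = "character", seed = "integer"
  )
)

setValidity("SampledCellBlock", function(object) {
  if (!all(vapply(object@cells, nrow, 1L) == object@k)) {
    return("every cell line must have exactly k rows")
  }
  if (!identical(names(object@cells), names(object@paddedCount))) {
    return("cells / paddedCount name mismatch")
  }
  TRUE
})

#' @describeIn SampledCellBlock number of median pseudo-cells per line.
#' @param x,object a `SampledCellBlock`.
#' @export
paddedCount <- function(x) x@paddedCount

setMethod("show", "SampledCellBlock", function(object) {
  cat(sprintf(
    "SampledCellBlock: %d cell lines x %d cells x %d genes (%d lines padded)\n",
    length(object@cells), object@k, length(object@genes),
    sum(object@paddedCount > 0)
  ))
})

# ------------------------------------------------------------------- model

#' ForkedModelConfig: architecture and training hyperparameters
#'
#' Defaults are the tuned optimum of the reference configuration: 11 hidden
#' layers per branch, branch widths 86 (drugs) / 100 (bulk) / 76 (single
#' cells), no dropout, Adam at learning rate 0.001, batch size 256, single-cell
#' branch enabled. L1/L2 coefficients (1e-5 each), early-stopping patience 10
#' and plateau schedule (factor 0.5, patience 5) are package defaults, all
#' configurable.
#'
#' @slot useSingleCell logical(1).
#' @slot hiddenLayerNumber integer(1) hidden depth per branch.
#' @slot hiddenSizeDrugs,hiddenSizeBulk,hiddenSizeSingleCells integer(1).
#' @slot trunkHidden integer(1) optional hidden layers after fusion (default 0).
#' @slot useDropout logical(1); @slot dropoutRate numeric(1) in [0, 1).
#' @slot l1,l2 numeric(1) >= 0 penalties on weights, biases and activations of
#'   all hidden layers (output layers are unpenalized).
#' @slot learningRate numeric(1) > 0; @slot batchSize integer(1).
#' @slot maxEpochs,earlyStopPatience,plateauPatience integer(1).
#' @slot plateauFactor numeric(1) in (0, 1).
#' @slot seed integer(1).
#' @exportClass ForkedModelConfig
setClass("ForkedModelConfig",
  representation(
    useSingleCell = "logical",
    hiddenLayerNumber = "integer",
    hiddenSizeDrugs = "integer",
    hiddenSizeBulk = "integer",
    hiddenSizeSingleCells = "integer",
    trunkHidden = "integer",
    useDropout = "logical",
    dropoutRate = "numeric",
    l1 = "numeric",
    l2 = "numeric",
    learningRate = "numeric",
    batchSize = "integer",
    maxEpochs = "integer",
    earlyStopPatience = "integer",
    plateauFactor = "numeric",
    plateauPatience = "integer",
    seed = "integer"
  )
)

setValidity("ForkedModelConfig", function(object) {
  if (object@hiddenLayerNumber < 1L) return("hiddenLayerNumber must be >= 1")
  if (min(object@hiddenSizeDrugs, object@hiddenSizeBulk,
          object@hiddenSizeSingleCells) < 1L) {
    return("hidden sizes must be >= 1")
  }
  if (object@dropoutRate < 0 || object@dropoutRate >= 1) {
    return("dropoutRate must lie in [0, 1)")
  }
  if (object@l1 < 0 || object@l2 < 0) return("l1/l2 must be >= 0")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@plateauFactor <= 0 || object@plateauFactor >= 1) {
    return("plateauFactor must lie in (0, 1)")
  }
  TRUE
})

#' @rdname ForkedModelConfig-class
#' @param useSingleCell include the single-cell branch.
#' @param hiddenLayerNumber hidden layers per branch.
#' @param hiddenSizeDrugs,hiddenSizeBulk,hiddenSizeSingleCells branch widths.
#' @param trunkHidden hidden layers after fusion (0 = linear head only).
#' @param useDropout,dropoutRate dropout after each hidden activation.
#' @param l1,l2 regularization coefficients.
#' @param learningRate,batchSize,maxEpochs Adam settings.
#' @param earlyStopPatience,plateauFactor,plateauPatience callback settings.
#' @param seed integer seed controlling initialization and batch order.
#' @export
forkedModelConfig <- function(useSingleCell = TRUE,
                              hiddenLayerNumber = 11L,
                              hiddenSizeDrugs = 86L,
                              hiddenSizeBulk = 100L,
                              hiddenSizeSingleCells = 76L,
                              trunkHidden = 0L,
                              useDropout = FALSE,
                              dropoutRate = 0,
                              l1 = 1e-5,
                              l2 = 1e-5,
                              learningRate = 0.001,
                              batchSize = 256L,
                              maxEpochs = 200L,
                              earlyStopPatience = 10L,
                              plateauFactor = 0.5,
                              plateauPatience = 5L,
                              seed = 1L) {
  new("ForkedModelConfig",
    useSingleCell = useSingleCell,
    hiddenLayerNumber = as.integer(hiddenLayerNumber),
    hiddenSizeDrugs = as.integer(hiddenSizeDrugs),
    hiddenSizeBulk = as.integer(hiddenSizeBulk),
    hiddenSizeSingleCells = as.integer(hiddenSizeSingleCells),
    trunkHidden = as.integer(trunkHidden),
    useDropout = useDropout, dropoutRate = dropoutRate,
    l1 = l1, l2 = l2,
    learningRate = learningRate, batchSize = as.integer(batchSize),
    maxEpochs = as.integer(maxEpochs),
    earlyStopPatience = as.integer(earlyStopPatience),
    plateauFactor = plateauFactor,
    plateauPatience = as.integer(plateauPatience),
    seed = as.integer(seed)
  )
}

setMethod("show", "ForkedModelConfig", function(object) {
  cat(sprintf(
    paste0(
      "ForkedModelConfig: depth %d, widths drugs=%d bulk=%d sc=%d%s, ",
      "dropout=%s(%.2f), l1=%g l2=%g, lr=%g, batch=%d, sc branch=%s\n"
    ),
    object@hiddenLayerNumber, object@hiddenSizeDrugs, object@hiddenSizeBulk,
    object@hiddenSizeSingleCells,
    if (object@trunkHidden > 0) sprintf(", trunk=%d", object@trunkHidden) else "",
    object@useDropout, object@dropoutRate, object@l1, object@l2,
    object@learningRate, object@batchSize, object@useSingleCell
  ))
})

#' ForkedModel: a built (possibly trained) forked multi-branch regressor
#'
#' One fully connected subnetwork per input branch (ReLU hidden layers, linear
#' branch output of the branch's hidden width, no regularization on output
#' layers), branch outputs concatenated into a linear fusion head emitting one
#' real value per sample.
#'
#' @slot config the [ForkedModelConfig-class] used to build it.
#' @slot branchNames,branchWidths input branch labels and widths.
#' @slot params nested list of weight matrices / bias vectors.
#' @slot trained logical(1).
#' @exportClass ForkedModel
setClass("ForkedModel",
  representation(
    config = "ForkedModelConfig",
    branchNames = "character",
    branchWidths = "integer",
    params = "list",
    trained = "logical"
  )
)

setMethod("show", "ForkedModel", function(object) {
  cat(sprintf(
    "ForkedModel: %d branches (%s), %d trainable layers, %s\n",
    length(object@branchWidths),
    paste(sprintf("%s:%d", object@branchNames, object@branchWidths),
      collapse = ", "
    ),
    layerCount(object),
    if (object@trained) "trained" else "untrained"
  ))
})

#' TrainingHistory: per-epoch record of a training run
#'
#' @slot trainLoss,valLoss numeric per-epoch MSE (+ penalties for trainLoss).
#' @slot learningRate numeric per-epoch learning-rate trace.
#' @slot stoppedEpoch,bestEpoch integer(1).
#' @exportClass TrainingHistory
setClass("TrainingHistory",
  representation(
    trainLoss = "numeric", valLoss = "numeric", learningRate = "numeric",
    stoppedEpoch = "integer", bestEpoch = "integer"
  )
)

setValidity("TrainingHistory", function(object) {
  if (length(object@valLoss) &&
      abs(object@valLoss[object@bestEpoch] - min(object@valLoss)) > 1e-12) {
    return("valLoss at bestEpoch must be the minimum")
  }
  TRUE
})

setMethod("show", "TrainingHistory", function(object) {
  cat(sprintf(
    "TrainingHistory: stopped at epoch %d, best epoch %d (val MSE %.4g)\n",
    object@stoppedEpoch, object@bestEpoch, object@valLoss[object@bestEpoch]
  ))
})

# ------------------------------------------------------------------- metrics

#' MetricsReport: the six-metric regression report for one partition
#'
#' MSE, MAE, RMSE on the ln(IC50) scale, Pearson and Spearman correlations,
#' and the coefficient of determination R-squared = 1 - SS_res / SS_tot (may
#' be negative). Correlation metrics are NA when the truth is constant.
#'
#' @slot mse,mae,rmse,pcc,scc,r2 numeric(1).
#' @slot n integer(1) sample count.
#' @slot partition character(1) tag.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    mse = "numeric", mae = "numeric", rmse = "numeric",
    pcc = "numeric", scc = "numeric", r2 = "numeric",
    n = "integer", partition = "character"
  )
)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport [%s, n=%d]: MSE %.4f  MAE %.4f  RMSE %.4f  PCC %.4f  SCC %.4f  R2 %.4f\n",
    object@partition, object@n, object@mse, object@mae, object@rmse,
    object@pcc, object@scc, object@r2
  ))
})

#' @describeIn MetricsReport metrics as a one-row data.frame.
#' @param x,object a `MetricsReport`.
#' @export
metricsAsRow <- function(x) {
  data.frame(
    partition = x@partition, n = x@n, mse = x@mse, mae = x@mae,
    rmse = x@rmse, pcc = x@pcc, scc = x@scc, r2 = x@r2,
    stringsAsFactors = FALSE
  )
}
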