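# Single-cell preprocessing pipeline: gene intersection across datasets, QC
# filtering, log-normalization, variable-gene selection (vst-style), cell-cycle
# module scoring and scaling/centering. The fixed order is
#   intersectGenes -> qcFilter (per dataset) -> mergeSingleCell ->
#   logNormalize -> selectHvg -> scoreCellCycle -> scaleCenter
# and each step checks the layer tag of its input so stages cannot be applied
# out of order.

#' Intersect gene symbols across single-cell datasets
#'
#' @param datasets list of [SingleCellMatrix-class] objects.
#' @return sorted character vector of shared gene symbols.
#' @export
intersectGenes <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  genes <- Reduce(intersect, lapply(datasets, rownames))
  if (length(genes) == 0) stopf("no genes are shared between all datasets")
  sort(genes)
}

#' Merge single-cell datasets on their shared genes
#'
#' Each dataset is subset to the sorted gene intersection, then cells are
#' concatenated.
#'
#' @param datasets list of [SingleCellMatrix-class] objects, all on the same
#'   layer.
#' @return a single [SingleCellMatrix-class].
#' @export
mergeSingleCell <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  layer <- unique(vapply(datasets, scLayer, ""))
  if (length(layer) != 1) stopf("datasets are on different layers: %s",
                                paste(layer, collapse = ", "))
  genes <- intersectGenes(datasets)
  mats <- lapply(datasets, function(d) scValues(d)[genes, , drop = FALSE])
  m <- do.call(cbind, mats)
  colnames(m) <- make.unique(unlist(lapply(mats, colnames)))
  SingleCellMatrix(
    m,
    cellLine = unlist(lapply(datasets, cellLines)),
    dataset = unlist(lapply(datasets, function(d) {
      as.character(SummarizedExperiment::colData(d)$dataset_id)
    })),
    layer = layer
  )
}

.requireLayer <- function(x, layer, op) {
  if (!is(x, "SingleCellMatrix")) stopf("%s expects a SingleCellMatrix", op)
  if (!scLayer(x) %in% layer) {
    stopf(
      "%s requires layer %s but got '%s' (pipeline order: counts -> lognorm -> scaled)",
      op, paste(sQuote(layer), collapse = "/"), scLayer(x)
    )
  }
}

.mitoGenes <- function(genes, rule) {
  startsWith(toupper(genes), toupper(rule))
}

#' Quality-control filter on a counts-layer SingleCellMatrix
#'
#' Keeps cells expressing at least `minGenesPerCell` genes AND with a
#' mitochondrial count fraction of at most `maxMitoFraction` (strictly greater
#' fractions are removed). The mitochondrial fraction is the count sum over
#' genes whose symbol starts with `mitoGeneRule` (case-insensitive) divided by
#' the cell's total counts. Cells with zero total counts are removed with a
#' warning.
#'
#' @param x a counts-layer [SingleCellMatrix-class].
#' @param thresholds a [QcThresholds-class] (default: 1000 genes, 15%, "MT-").
#' @return the filtered [SingleCellMatrix-class]; the per-cell statistics and
#'   keep decision are attached as attribute `"qc"` (a data.frame).
#' @export
qcFilter <- function(x, thresholds = qcThresholds()) {
  .requireLayer(x, "counts", "qcFilter")
  m <- SummarizedExperiment::assay(x, "counts")
  expressed <- colSums(m > 0)
  total <- colSums(m)
  mito <- .mitoGenes(rownames(m), thresholds@mitoGeneRule)
  mitoSum <- if (any(mito)) colSums(m[mito, , drop = FALSE]) else rep(0, ncol(m))
  zero <- total == 0
  if (any(zero)) warnf("removing %d cells with zero total counts", sum(zero))
  mitoFrac <- ifelse(zero, 1, mitoSum / pmax(total, 1))
  keep <- !zero &
    expressed >= thresholds@minGenesPerCell &
    mitoFrac <= thresholds@maxMitoFraction
  out <- x[, keep]
  attr(out, "qc") <- data.frame(
    cell = colnames(m), expressed_genes = expressed,
    mito_fraction = mitoFrac, kept = keep, stringsAsFactors = FALSE
  )
  out
}

#' Log-normalize a counts-layer SingleCellMatrix
#'
#' Per cell: `ln(1 + count * scaleFactor / cell_total)`. All-zero cells stay
#' all-zero. The counts assay is retained (variable-gene selection operates on
#' counts); the layer tag advances to `"lognorm"`.
#'
#' @param x a counts-layer [SingleCellMatrix-class].
#' @param scaleFactor library-size scale factor (default 1e4).
#' @return a lognorm-layer [SingleCellMatrix-class] with assays `counts` and
#'   `lognorm`.
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
  .requireLayer(x, "counts", "logNormalize")
  m <- SummarizedExperiment::assay(x, "counts")
  if (min(m) < 0) stopf("negative counts")
  total <- colSums(m)
  scale <- ifelse(total > 0, scaleFactor / total, 0)
  ln <- log1p(sweep(m, 2, scale, `*`))
  SummarizedExperiment::assay(x, "lognorm", withDimnames = FALSE) <- ln
  x@layer <- "lognorm"
  validObject(x)
  x
}

# vst-style standardized variance: per-gene variance of counts after
# standardizing with the gene mean and a trend-expected sd, clipping
# standardized values at sqrt(#cells). The mean-variance trend is a local
# polynomial fit of log10(variance) on log10(mean) (span 0.3, degree 2).
.standardizedVariance <- function(counts) {
  n <- ncol(counts)
  mu <- rowMeans(counts)
  v <- apply(counts, 1, var)
  sv <- rep(0, nrow(counts))
  use <- v > 0 & mu > 0
  if (sum(use) < 3) return(sv)
  fit <- suppressWarnings(loess(
    log10(v[use]) ~ log10(mu[use]),
    span = 0.3, degree = 2
  ))
  expSd <- sqrt(10^fit$fitted)
  clip <- sqrt(n)
  idx <- which(use)
  for (j in seq_along(idx)) {
    g <- idx[j]
    z <- (counts[g, ] - mu[g]) / expSd[j]
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    sv[g] <- sum((z - mean(z))^2) / (n - 1)
  }
  sv
}

#' Select the most highly variable genes (vst-style)
#'
#' Genes are ranked by standardized variance of their counts against a local
#' polynomial mean-variance trend (clipped at sqrt(#cells)); ties are broken
#' by gene-symbol order.
#'
#' @param x a counts- or lognorm-layer [SingleCellMatrix-class] (counts assay
#'   must be present; the ranking is computed on counts).
#' @param n number of genes to return (default 2000).
#' @return character vector of `n` gene symbols, highest variability first.
#' @export
selectHvg <- function(x, n = 2000L) {
  .requireLayer(x, c("counts", "lognorm"), "selectHvg")
  if (n > nrow(x)) stopf("n (%d) exceeds the number of genes (%d)", n, nrow(x))
  if (n == 0) return(character())
  counts <- SummarizedExperiment::assay(x, "counts")
  sv <- .standardizedVariance(counts)
  ord <- order(-sv, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

#' Read S-phase / G2M gene sets from a two-column text fixture
#'
#' @param path tab-separated file with columns `gene` and `phase`
#'   (`S` or `G2M`). Defaults to the packaged Tirosh-derived list.
#' @return list with character vectors `s` and `g2m` (upper-cased, disjoint).
#' @export
readCellCycleGeneSets <- function(path = system.file("extdata",
                                                     "cell_cycle_genes.tsv",
                                                     package = "forkDR")) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "phase") %in% names(df)))
  s <- toupper(df$gene[df$phase == "S"])
  g2m <- toupper(df$gene[df$phase == "G2M"])
  if (!length(s) || !length(g2m)) stopf("gene sets must be non-empty")
  if (length(intersect(s, g2m))) stopf("S and G2M gene sets must be disjoint")
  list(s = s, g2m = g2m)
}

# module score for one gene set: mean expression over the set minus mean over
# a control set drawn per expression bin (nctrl genes per set gene, sampled
# from the set gene's bin, excluding the set itself so the control reflects
# background expression at matched abundance).
.moduleScore <- function(expr, setGenes, bins, nctrl) {
  setIdx <- which(rownames(expr) %in% setGenes)
  ctrlIdx <- unlist(lapply(setIdx, function(g) {
    pool <- setdiff(which(bins == bins[g]), setIdx)
    if (!length(pool)) pool <- which(bins == bins[g])
    pool[sample.int(length(pool), min(nctrl, length(pool)))]
  }))
  colMeans(expr[setIdx, , drop = FALSE]) -
    colMeans(expr[ctrlIdx, , drop = FALSE])
}

#' Score cell-cycle activity (S and G2M module scores)
#'
#' Module score per cell: mean log-normalized expression over the phase gene
#' set minus the mean over a seeded control set, with `nctrl` control genes
#' drawn from the expression bin of each set gene (genes are binned into
#' `nbins` equal-frequency bins by average expression).
#'
#' @param x a lognorm-layer [SingleCellMatrix-class].
#' @param sets list with elements `s` and `g2m` (gene symbol vectors), e.g.
#'   from [readCellCycleGeneSets()].
#' @param nbins number of average-expression bins (default 24).
#' @param nctrl control genes per set gene (default 100).
#' @param seed integer seed for the control draw.
#' @return data.frame with columns `cell`, `s_score`, `g2m_score`.
#' @export
scoreCellCycle <- function(x, sets, nbins = 24L, nctrl = 100L, seed = 1L) {
  .requireLayer(x, "lognorm", "scoreCellCycle")
  expr <- SummarizedExperiment::assay(x, "lognorm")
  genes <- rownames(expr)
  for (nm in c("s", "g2m")) {
    if (!any(toupper(genes) %in% toupper(sets[[nm]]))) {
      stopf("no '%s' set gene is present in the matrix", nm)
    }
  }
  sets <- lapply(sets, function(g) genes[toupper(genes) %in% toupper(g)])
  avg <- rowMeans(expr)
  nbins <- min(nbins, length(unique(avg)))
  # equal-frequency binning by rank of average expression
  bins <- ceiling(rank(avg, ties.method = "first") / (length(avg) / nbins))
  withSeed(seed, {
    s <- .moduleScore(expr, sets$s, bins, nctrl)
    g2m <- .moduleScore(expr, sets$g2m, bins, nctrl)
  })
  if (!all(is.finite(s)) || !all(is.finite(g2m))) {
    stopf("non-finite cell-cycle scores")
  }
  data.frame(
    cell = colnames(expr), s_score = s, g2m_score = g2m,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Regress cell-cycle scores out of log-normalized expression
#'
#' Optional per-gene linear residualization on the S and G2M scores, applied
#' before scaling for users who want cycle effects removed rather than merely
#' scored.
#'
#' @param x a lognorm-layer [SingleCellMatrix-class].
#' @param scores data.frame from [scoreCellCycle()].
#' @return a lognorm-layer [SingleCellMatrix-class] with residualized values.
#' @export
regressCellCycle <- function(x, scores) {
  .requireLayer(x, "lognorm", "regressCellCycle")
  expr <- SummarizedExperiment::assay(x, "lognorm")
  stopifnot(identical(scores$cell, colnames(expr)))
  design <- cbind(1, scores$s_score, scores$g2m_score)
  # one least-squares solve for all genes at once
  beta <- solve(crossprod(design), crossprod(design, t(expr)))
  resid <- t(expr) - design %*% beta
  SummarizedExperiment::assay(x, "lognorm", withDimnames = FALSE) <- t(resid)
  x
}

#' Scale and center expression (per-gene z-score, clipped)
#'
#' Per-gene z-score across cells, clipped above at `clipMax`; zero-variance
#' genes become all-zero. Output keeps only the requested genes and advances
#' the layer tag to `"scaled"`.
#'
#' @param x a lognorm-layer [SingleCellMatrix-class].
#' @param genes genes to keep (default: all); must be present in `x`.
#' @param clipMax upper clip for scaled values (default 10).
#' @return a scaled-layer [SingleCellMatrix-class] (single `scaled` assay).
#' @export
scaleCenter <- function(x, genes = rownames(x), clipMax = 10) {
  .requireLayer(x, "lognorm", "scaleCenter")
  missing <- setdiff(genes, rownames(x))
  if (length(missing)) stopf("genes not in matrix: %s",
                             paste(head(missing, 5), collapse = ", "))
  expr <- SummarizedExperiment::assay(x, "lognorm")[genes, , drop = FALSE]
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, sd)
  z <- (expr - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z[z > clipMax] <- clipMax
  SingleCellMatrix(
    z,
    cellLine = cellLines(x),
    dataset = as.character(SummarizedExperiment::colData(x)$dataset_id),
    layer = "scaled"
  )
}

# ------------------------------------------------------------------ readers

#' Read a dense cells x genes CSV/TSV into a SingleCellMatrix
#'
#' @param path delimited file, one row per cell; all non-label columns are
#'   gene counts.
#' @param cellLineCol,datasetCol,cellIdCol label column names (`datasetCol`
#'   and `cellIdCol` optional).
#' @param sep field separator (default `,`).
#' @param datasetId dataset label used when `datasetCol` is absent.
#' @return a counts-layer [SingleCellMatrix-class].
#' @export
readSingleCellCsv <- function(path, cellLineCol = "cell_line_id",
                              datasetCol = "dataset_id", cellIdCol = "cell_id",
                              sep = ",", datasetId = basename(path)) {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (!cellLineCol %in% names(df)) {
    stopf("single-cell table is missing required column '%s'", cellLineCol)
  }
  lines <- as.character(df[[cellLineCol]])
  ds <- if (datasetCol %in% names(df)) as.character(df[[datasetCol]]) else datasetId
  ids <- if (cellIdCol %in% names(df)) as.character(df[[cellIdCol]]) else {
    sprintf("%s_cell%05d", datasetId, seq_len(nrow(df)))
  }
  drop <- intersect(c(cellLineCol, datasetCol, cellIdCol), names(df))
  m <- t(as.matrix(df[, setdiff(names(df), drop), drop = FALSE]))
  colnames(m) <- ids
  SingleCellMatrix(m, cellLine = lines, dataset = ds, layer = "counts")
}

#' Read a 10x-style matrix/barcodes/features triplet into a SingleCellMatrix
#'
#' @param matrixPath MatrixMarket file (genes x cells).
#' @param barcodesPath one barcode per line.
#' @param featuresPath gene ids/symbols, first column used (TSV).
#' @param cellLineMap data.frame or CSV path with columns `barcode` and
#'   `cell_line_id`; barcodes without a mapping are dropped.
#' @param datasetId dataset label.
#' @return a counts-layer [SingleCellMatrix-class].
#' @export
readTenx <- function(matrixPath, barcodesPath, featuresPath, cellLineMap,
                     datasetId = "tenx") {
  m <- as.matrix(Matrix::readMM(matrixPath))
  barcodes <- readLines(barcodesPath)
  features <- read.csv(featuresPath, sep = "\t", header = FALSE,
                       stringsAsFactors = FALSE)
  sym <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  rownames(m) <- make.unique(sym)
  colnames(m) <- barcodes
  if (is.character(cellLineMap)) {
    cellLineMap <- read.csv(cellLineMap, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("barcode", "cell_line_id") %in% names(cellLineMap)))
  idx <- match(barcodes, cellLineMap$barcode)
  keep <- !is.na(idx)
  if (!all(keep)) warnf("dropping %d barcodes without a cell-line mapping", sum(!keep))
  SingleCellMatrix(
    m[, keep, drop = FALSE],
    cellLine = cellLineMap$cell_line_id[idx[keep]],
    dataset = datasetId, layer = "counts"
  )
}
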