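# Supervised dataset assembly: bulk omics / screen-table loading, the
# missing-value and deduplication rules, the 10% leave-cell-out /
# leave-drug-out + 70-30 train-test split, train-only zero-variance pruning
# and standardization, k-cell sampling with median padding, and per-branch
# matrix assembly with leakage guards.

#' Load one bulk omics block, reindexed to a cell-line universe
#'
#' Cell lines absent from the file get all-zero rows (recorded in
#' `missingCellIds`); scalar missing entries become zero. Zeros encode absence
#' of the measured entity, which is the convention the assembly protocol uses
#' for the minority of missing bulk values.
#'
#' @param path CSV/TSV whose first column is the cell-line id.
#' @param blockName label for the block.
#' @param universe character vector of cell-line ids defining row order.
#' @param sep field separator (default `,`).
#' @return an [OmicsBlock-class].
#' @export
loadOmicsBlock <- function(path, blockName, universe, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stopf(
      "duplicate cell-line rows in %s: %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m[!is.finite(m)] <- 0
  missing <- setdiff(universe, ids)
  full <- matrix(0, length(universe), ncol(m),
    dimnames = list(universe, colnames(m))
  )
  common <- intersect(universe, ids)
  full[common, ] <- m[common, , drop = FALSE]
  new("OmicsBlock", blockName = blockName, matrix = full, missingCellIds = missing)
}

#' Build an OmicsBlock from an in-memory matrix
#'
#' @param m cell lines x features numeric matrix with rownames.
#' @param blockName block label.
#' @param universe optional cell-line universe to reindex to (default: the
#'   matrix's own rows).
#' @return an [OmicsBlock-class].
#' @export
omicsBlock <- function(m, blockName, universe = rownames(m)) {
  stopifnot(!is.null(rownames(m)))
  m[!is.finite(m)] <- 0
  missing <- setdiff(universe, rownames(m))
  full <- matrix(0, length(universe), ncol(m),
    dimnames = list(universe, colnames(m))
  )
  common <- intersect(universe, rownames(m))
  full[common, ] <- m[common, , drop = FALSE]
  new("OmicsBlock", blockName = blockName, matrix = full, missingCellIds = missing)
}

#' Load the drug-screen pair table, averaging duplicate pairs
#'
#' Repeated (drug, cell line) pairs are collapsed to the arithmetic mean of
#' their ln(IC50) values.
#'
#' @param path CSV with columns for drug, cell line and ln(IC50).
#' @param drugCol,cellLineCol,valueCol column names (defaults `drug_id`,
#'   `cell_line_id`, `ln_ic50`).
#' @return data.frame (the pair table) with columns `drug_id`, `cell_line_id`,
#'   `ln_ic50`; one row per unique pair.
#' @export
loadPairs <- function(path, drugCol = "drug_id", cellLineCol = "cell_line_id",
                      valueCol = "ln_ic50") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c(drugCol, cellLineCol, valueCol)) {
    if (!col %in% names(df)) stopf("pair table is missing column '%s'", col)
  }
  val <- suppressWarnings(as.numeric(df[[valueCol]]))
  bad <- which(!is.finite(val))
  if (length(bad)) {
    stopf("non-numeric ln_ic50 at row(s) %s", paste(head(bad, 5), collapse = ", "))
  }
  dedupPairs(data.frame(
    drug_id = as.character(df[[drugCol]]),
    cell_line_id = as.character(df[[cellLineCol]]),
    ln_ic50 = val, stringsAsFactors = FALSE
  ))
}

#' Collapse duplicated (drug, cell line) pairs to their mean ln(IC50)
#'
#' @param pairs pair table data.frame.
#' @return deduplicated pair table.
#' @export
dedupPairs <- function(pairs) {
  key <- paste(pairs$drug_id, pairs$cell_line_id, sep = "\r")
  if (!anyDuplicated(key)) return(pairs)
  agg <- tapply(pairs$ln_ic50, key, mean)
  first <- !duplicated(key)
  out <- pairs[first, , drop = FALSE]
  out$ln_ic50 <- as.numeric(agg[key[first]])
  rownames(out) <- NULL
  out
}

#' Partition a pair table into train / test / leave-cell-out / leave-drug-out
#'
#' A seeded 10% of unique cell lines and, independently, 10% of unique drugs
#' (round half away from zero) are held out. Pairs touching a held-out cell
#' line only form the leave-cell-out set; a held-out drug only, the
#' leave-drug-out set; both, they are discarded (recorded). Remaining pairs
#' are split 70-30 by a seeded shuffle (test size = floor of the fraction).
#'
#' @param pairs pair table (deduplicated).
#' @param holdoutFraction fraction of unique entities held out (default 0.10).
#' @param testFraction test share of the remaining pairs (default 0.30).
#' @param seed integer seed.
#' @return a [SplitBundle-class].
#' @export
makeSplits <- function(pairs, holdoutFraction = 0.10, testFraction = 0.30,
                       seed = 1L) {
  lines <- sort(unique(pairs$cell_line_id))
  drugs <- sort(unique(pairs$drug_id))
  if (length(lines) < 2 || length(drugs) < 2) {
    stopf("need at least 2 unique cell lines and drugs")
  }
  nLines <- roundHalfAway(holdoutFraction * length(lines))
  nDrugs <- roundHalfAway(holdoutFraction * length(drugs))
  if (nLines == 0 || nDrugs == 0) {
    stopf(
      "holdout fraction %.2f rounds to zero held-out entities; supply more data",
      holdoutFraction
    )
  }
  withSeed(seed, {
    heldLines <- sort(sample(lines, nLines))
    heldDrugs <- sort(sample(drugs, nDrugs))
    lineOut <- pairs$cell_line_id %in% heldLines
    drugOut <- pairs$drug_id %in% heldDrugs
    lco <- which(lineOut & !drugOut)
    ldo <- which(drugOut & !lineOut)
    discarded <- which(lineOut & drugOut)
    remaining <- which(!lineOut & !drugOut)
    nTest <- floor(testFraction * length(remaining))
    shuffled <- sample(remaining)
    testIdx <- sort(shuffled[seq_len(nTest)])
    trainIdx <- sort(shuffled[-seq_len(nTest)])
  })
  new("SplitBundle",
    trainIdx = as.integer(trainIdx), testIdx = as.integer(testIdx),
    leaveCellOutIdx = as.integer(lco), leaveDrugOutIdx = as.integer(ldo),
    discardedIdx = as.integer(discarded),
    heldOutCellLines = heldLines, heldOutDrugs = heldDrugs,
    seed = as.integer(seed)
  )
}

#' Remove features with zero variance over the training rows
#'
#' Variance is computed on the training rows only; a feature that is constant
#' in training is removed from every partition consistently.
#'
#' @param blocks named list of row-aligned matrices (rows = pairs).
#' @param trainRows integer row indices of the training partition.
#' @return the list of matrices with zero-variance columns removed; removed
#'   names are attached as attribute `"removed"` per block.
#' @export
dropZeroVariance <- function(blocks, trainRows) {
  stopifnot(length(trainRows) > 0)
  lapply(blocks, function(m) {
    tr <- m[trainRows, , drop = FALSE]
    v <- apply(tr, 2, function(col) max(col) - min(col))
    keep <- v > 0
    if (!any(keep)) stopf("a block lost all features to zero-variance pruning")
    out <- m[, keep, drop = FALSE]
    attr(out, "removed") <- colnames(m)[!keep]
    out
  })
}

#' Fit a feature standardizer on the training rows of a matrix
#'
#' Uses the population (1/n) standard deviation, the convention of the usual
#' machine-learning scalers, so a two-value column `[1, 3]` gets mean 2 and
#' sd 1.
#'
#' @param block pairs x features matrix.
#' @param trainRows integer row indices defining the fit partition.
#' @param tag partition tag stored on the standardizer.
#' @return a [Standardizer-class].
#' @export
fitStandardizer <- function(block, trainRows, tag = "train") {
  tr <- block[trainRows, , drop = FALSE]
  mu <- colMeans(tr)
  sdv <- sqrt(colMeans(sweep(tr, 2, mu, `-`)^2))
  if (any(sdv == 0)) {
    stopf(
      "zero-variance features must be pruned before standardization: %s",
      paste(head(colnames(tr)[sdv == 0], 5), collapse = ", ")
    )
  }
  new("Standardizer", mean = mu, sd = sdv, fitPartition = tag)
}

#' Transform a matrix with stored train statistics
#'
#' @param std a [Standardizer-class].
#' @param block matrix whose columns match the standardizer's features.
#' @return the standardized matrix.
#' @export
applyStandardizer <- function(std, block) {
  if (!identical(colnames(block), names(std@mean))) {
    stopf("feature names do not match the standardizer's features")
  }
  sweep(sweep(block, 2, std@mean, `-`), 2, std@sd, `/`)
}

#' Sample (and median-pad) k single cells per cell line
#'
#' For each cell line not excluded: if at least `k` cells are available, draw
#' `k` without replacement (seeded); otherwise take all `m` available cells
#' and append `k - m` pseudo-cells, each equal to the per-gene median over the
#' `m` cells (median of an even count = mean of the two central order
#' statistics).
#'
#' @param x a scaled-layer [SingleCellMatrix-class].
#' @param k cells per line (the protocol uses 10, 25 or 50).
#' @param seed integer seed.
#' @param excludeLines cell lines to leave out entirely (e.g. held-out lines,
#'   whose cells must not enter training data).
#' @return a [SampledCellBlock-class].
#' @export
sampleSingleCells <- function(x, k, seed = 1L, excludeLines = character()) {
  .requireLayer(x, "scaled", "sampleSingleCells")
  k <- as.integer(k)
  stopifnot(k >= 1)
  m <- scValues(x)
  lineOf <- cellLines(x)
  lines <- setdiff(sort(unique(lineOf)), excludeLines)
  if (!length(lines)) stopf("no cell lines left after exclusion")
  cells <- vector("list", length(lines))
  names(cells) <- lines
  padded <- stats::setNames(integer(length(lines)), lines)
  withSeed(seed, {
    for (ln in lines) {
      idx <- which(lineOf == ln)
      if (!length(idx)) stopf("cell line '%s' has zero cells", ln)
      avail <- length(idx)
      if (avail >= k) {
        take <- idx[sample.int(avail, k)]
        block <- t(m[, take, drop = FALSE])
      } else {
        block <- t(m[, idx, drop = FALSE])
        med <- apply(block, 2, median)
        pad <- matrix(med, k - avail, ncol(block), byrow = TRUE)
        block <- rbind(block, pad)
        padded[ln] <- as.integer(k - avail)
      }
      rownames(block) <- NULL
      cells[[ln]] <- block
    }
  })
  new("SampledCellBlock",
    cells = cells, paddedCount = padded, k = as.integer(k),
    genes = rownames(m), seed = as.integer(seed)
  )
}

.flattenLine <- function(block) as.numeric(t(block))

# column names for the flattened single-cell branch: cell01_geneA, ...
.scFeatureNames <- function(k, genes) {
  as.vector(t(outer(
    sprintf("cell%02d", seq_len(k)), genes,
    function(a, b) paste(a, b, sep = "_")
  )))
}

#' Assemble per-partition, per-branch input matrices and targets
#'
#' Row i of every branch matrix corresponds to pair i of the partition; the
#' single-cell branch is the pair's k sampled cells flattened to one vector of
#' length k x genes. Pairs whose drug is missing from any drug block, or (for
#' the leave-cell-out partition) whose line is missing from the held-out
#' sample block, are dropped with a logged count. Leakage invariants are
#' asserted on the result.
#'
#' @param pairs deduplicated pair table.
#' @param split a [SplitBundle-class] over `pairs`.
#' @param drugBlocks list of [DrugFeatureTable-class] objects.
#' @param omicsBlocks list of [OmicsBlock-class] objects (zero-filled rows for
#'   missing lines, so every line resolves).
#' @param sampled [SampledCellBlock-class] for retained lines (must exclude
#'   the held-out lines), or `NULL` to omit the single-cell branch.
#' @param sampledHeldOut optional [SampledCellBlock-class] covering the
#'   held-out lines, used only for the leave-cell-out partition.
#' @return list with `partitions` (named list of `list(inputs, y, pairs)`),
#'   `branchNames`, and `dropped` (pair counts removed per partition).
#' @export
assembleBranchInputs <- function(pairs, split, drugBlocks, omicsBlocks,
                                 sampled = NULL, sampledHeldOut = NULL) {
  stopifnot(length(drugBlocks) + length(omicsBlocks) > 0)
  if (!is.null(sampled)) {
    leak <- intersect(names(sampled@cells), split@heldOutCellLines)
    if (length(leak)) {
      stopf(
        "sampled cell block contains held-out cell lines (%s); training-time \
single-cell data must exclude them",
        paste(head(leak, 3), collapse = ", ")
      )
    }
  }
  branchNames <- c(
    vapply(drugBlocks, blockName, ""),
    vapply(omicsBlocks, blockName, ""),
    if (!is.null(sampled)) "single_cells"
  )
  partIdx <- list(
    train = split@trainIdx, test = split@testIdx,
    leave_cell_out = split@leaveCellOutIdx,
    leave_drug_out = split@leaveDrugOutIdx
  )
  dropped <- stats::setNames(integer(length(partIdx)), names(partIdx))
  partitions <- list()
  for (part in names(partIdx)) {
    idx <- partIdx[[part]]
    sub <- pairs[idx, , drop = FALSE]
    ok <- rep(TRUE, nrow(sub))
    for (db in drugBlocks) ok <- ok & sub$drug_id %in% drugIds(db)
    for (ob in omicsBlocks) ok <- ok & sub$cell_line_id %in% cellLineIds(ob)
    scBlock <- NULL
    if (!is.null(sampled)) {
      scBlock <- if (part == "leave_cell_out") sampledHeldOut else sampled
      ok <- if (is.null(scBlock)) {
        ok & FALSE
      } else {
        ok & sub$cell_line_id %in% names(scBlock@cells)
      }
    }
    dropped[part] <- sum(!ok)
    sub <- sub[ok, , drop = FALSE]
    if (!nrow(sub)) {
      if (part %in% c("train", "test")) {
        stopf("partition '%s' is empty after resolving pairs", part)
      }
      partitions[[part]] <- NULL
      next
    }
    inputs <- list()
    for (db in drugBlocks) {
      inputs[[blockName(db)]] <- featureMatrix(db)[sub$drug_id, , drop = FALSE]
    }
    for (ob in omicsBlocks) {
      inputs[[ob@blockName]] <- ob@matrix[sub$cell_line_id, , drop = FALSE]
    }
    if (!is.null(scBlock)) {
      sc <- t(vapply(
        sub$cell_line_id,
        function(ln) .flattenLine(scBlock@cells[[ln]]),
        numeric(scBlock@k * length(scBlock@genes))
      ))
      colnames(sc) <- .scFeatureNames(scBlock@k, scBlock@genes)
      inputs[["single_cells"]] <- sc
    }
    inputs <- lapply(inputs, function(m) {
      rownames(m) <- NULL
      m
    })
    partitions[[part]] <- list(inputs = inputs, y = sub$ln_ic50, pairs = sub)
  }
  if (sum(dropped) > 0) {
    message(sprintf(
      "dropped %d unresolvable pairs (%s)", sum(dropped),
      paste(sprintf("%s: %d", names(dropped), dropped), collapse = ", ")
    ))
  }
  bundle <- list(
    partitions = partitions, branchNames = branchNames, dropped = dropped,
    split = split
  )
  assertLeakageFree(bundle, split)
  bundle
}

#' Assert that an assembled bundle is free of holdout leakage
#'
#' Checks that no held-out cell line or drug appears in the train or test
#' partitions, that the leave-cell-out (leave-drug-out) partition references
#' only held-out lines (drugs), and that partitions reference disjoint
#' row sets.
#'
#' @param bundle output of [assembleBranchInputs()].
#' @param split the [SplitBundle-class] used.
#' @return invisibly `TRUE`; errors on violation.
#' @export
assertLeakageFree <- function(bundle, split) {
  p <- bundle$partitions
  for (part in intersect(c("train", "test"), names(p))) {
    if (length(intersect(p[[part]]$pairs$cell_line_id, split@heldOutCellLines))) {
      stopf("held-out cell line leaked into '%s'", part)
    }
    if (length(intersect(p[[part]]$pairs$drug_id, split@heldOutDrugs))) {
      stopf("held-out drug leaked into '%s'", part)
    }
  }
  if (!is.null(p$leave_cell_out)) {
    if (!all(p$leave_cell_out$pairs$cell_line_id %in% split@heldOutCellLines)) {
      stopf("leave-cell-out partition contains retained cell lines")
    }
    if (any(p$leave_cell_out$pairs$drug_id %in% split@heldOutDrugs)) {
      stopf("leave-cell-out partition contains held-out drugs")
    }
  }
  if (!is.null(p$leave_drug_out)) {
    if (!all(p$leave_drug_out$pairs$drug_id %in% split@heldOutDrugs)) {
      stopf("leave-drug-out partition contains retained drugs")
    }
    if (any(p$leave_drug_out$pairs$cell_line_id %in% split@heldOutCellLines)) {
      stopf("leave-drug-out partition contains held-out cell lines")
    }
  }
  invisible(TRUE)
}

#' Prune zero-variance features and standardize all partitions (train-fit)
#'
#' Applies [dropZeroVariance()] using the training rows, fits one
#' [Standardizer-class] per branch on the training partition, and transforms
#' every partition with the training statistics. The ln(IC50) target is left
#' on its natural scale.
#'
#' @param bundle output of [assembleBranchInputs()].
#' @return the bundle with standardized inputs and a `standardizers` element.
#' @export
standardizeBundle <- function(bundle) {
  parts <- names(bundle$partitions)
  stopifnot("train" %in% parts)
  branches <- names(bundle$partitions$train$inputs)
  rowsPer <- vapply(bundle$partitions[parts], function(p) nrow(p$pairs), 1L)
  offsets <- cumsum(c(0, rowsPer[-length(rowsPer)]))
  names(offsets) <- parts
  standardizers <- list()
  for (br in branches) {
    stacked <- do.call(rbind, lapply(parts, function(pt) {
      bundle$partitions[[pt]]$inputs[[br]]
    }))
    trainRows <- offsets["train"] + seq_len(rowsPer["train"])
    pruned <- dropZeroVariance(list(stacked), trainRows)[[1]]
    std <- fitStandardizer(pruned, trainRows)
    z <- applyStandardizer(std, pruned)
    for (pt in parts) {
      rows <- offsets[pt] + seq_len(rowsPer[pt])
      bundle$partitions[[pt]]$inputs[[br]] <- z[rows, , drop = FALSE]
    }
    standardizers[[br]] <- std
  }
  bundle$standardizers <- standardizers
  bundle
}

#' Write a split manifest (seed, held-out keys, partition sizes) as JSON
#'
#' @param bundle assembled (optionally standardized) bundle.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeSplitManifest <- function(bundle, path) {
  split <- bundle$split
  manifest <- list(
    seed = split@seed,
    held_out_cell_lines = split@heldOutCellLines,
    held_out_drugs = split@heldOutDrugs,
    discarded_pairs = length(split@discardedIdx),
    dropped_pairs = as.list(bundle$dropped),
    partition_sizes = lapply(bundle$partitions, function(p) nrow(p$pairs)),
    branches = bundle$branchNames
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
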