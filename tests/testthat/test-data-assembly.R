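test_that("loadOmicsBlock zero-fills absent lines and scalar gaps", {
  df <- data.frame(
    cell_line_id = c("A", "B"), f1 = c(1, 2), f2 = c(NA, 4)
  )
  block <- loadOmicsBlock(tmpCsv(df), "expr", universe = c("A", "B", "C"))
  expect_equal(cellLineIds(block), c("A", "B", "C"))
  expect_equal(missingCellIds(block), "C")
  expect_equal(unname(block@matrix["C", ]), c(0, 0))
  expect_equal(unname(block@matrix["A", "f2"]), 0) # NaN cell -> 0

  full <- loadOmicsBlock(tmpCsv(df), "expr", universe = c("A", "B"))
  expect_length(missingCellIds(full), 0)

  dup <- data.frame(cell_line_id = c("A", "A"), f1 = c(1, 2))
  expect_error(loadOmicsBlock(tmpCsv(dup), "expr", "A"), "duplicate")
})

test_that("loadPairs averages duplicated pairs and flags bad values", {
  df <- data.frame(
    drug_id = c("d1", "d1", "d2", "d3", "d3", "d3"),
    cell_line_id = c("c1", "c1", "c1", "c2", "c2", "c2"),
    ln_ic50 = c(2, 4, 5, 1, 2, 6)
  )
  pairs <- loadPairs(tmpCsv(df))
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$ln_ic50[pairs$drug_id == "d1"], 3) # mean(2, 4)
  expect_equal(pairs$ln_ic50[pairs$drug_id == "d3"], 3) # mean(1, 2, 6)
  expect_equal(pairs$ln_ic50[pairs$drug_id == "d2"], 5) # untouched

  clean <- df[c(3, 4), ]
  expect_equal(loadPairs(tmpCsv(clean))$ln_ic50, clean$ln_ic50)

  bad <- data.frame(drug_id = "d", cell_line_id = "c", ln_ic50 = "oops")
  expect_error(loadPairs(tmpCsv(bad)), "row")
})

test_that("makeSplits holds out 10% of entities and splits pairs 70-30", {
  grid <- expand.grid(
    drug_id = sprintf("d%03d", 1:100),
    cell_line_id = sprintf("c%03d", 1:100),
    stringsAsFactors = FALSE
  )
  grid$ln_ic50 <- rnorm(nrow(grid))
  split <- makeSplits(grid, seed = 11)
  expect_length(split@heldOutCellLines, 10)
  expect_length(split@heldOutDrugs, 10)
  # 90 x 90 pairs remain; exact 70-30
  expect_length(split@testIdx, 2430)
  expect_length(split@trainIdx, 5670)
  expect_length(split@leaveCellOutIdx, 10 * 90)
  expect_length(split@leaveDrugOutIdx, 10 * 90)
  expect_length(split@discardedIdx, 100)
  # partition sizes sum to the table size
  total <- length(split@trainIdx) + length(split@testIdx) +
    length(split@leaveCellOutIdx) + length(split@leaveDrugOutIdx) +
    length(split@discardedIdx)
  expect_equal(total, nrow(grid))

  # determinism
  split2 <- makeSplits(grid, seed = 11)
  expect_equal(split@trainIdx, split2@trainIdx)
  expect_equal(split@heldOutDrugs, split2@heldOutDrugs)

  tiny <- data.frame(
    drug_id = c("a", "b"), cell_line_id = c("x", "y"), ln_ic50 = 1:2
  )
  expect_error(makeSplits(tiny, holdoutFraction = 0.1), "rounds to zero")
})

test_that("zero-variance pruning is train-defined and consistent", {
  m <- cbind(
    const = rep(1, 6),
    trainConst = c(2, 2, 2, 5, 6, 7), # constant on train rows only
    varies = 1:6
  )
  out <- dropZeroVariance(list(b = m), trainRows = 1:3)$b
  expect_equal(colnames(out), "varies")
  expect_setequal(attr(out, "removed"), c("const", "trainConst"))

  noConst <- dropZeroVariance(list(b = m[, "varies", drop = FALSE]), 1:3)$b
  expect_equal(colnames(noConst), "varies")
  expect_error(
    dropZeroVariance(list(b = m[, "const", drop = FALSE]), 1:3),
    "all features"
  )
})

test_that("standardizer matches the closed form and is train-pure", {
  m <- matrix(c(1, 3, 2, 10, 20, 30), ncol = 2,
    dimnames = list(NULL, c("a", "b"))
  )
  std <- fitStandardizer(m, trainRows = 1:2)
  expect_equal(unname(std@mean["a"]), 2)
  expect_equal(unname(std@sd["a"]), 1) # population sd of [1, 3]
  z <- applyStandardizer(std, m)
  expect_equal(unname(z[3, "a"]), 0) # test value 2 -> 0

  # refit on the transformed training rows is the identity transform
  std2 <- fitStandardizer(z, trainRows = 1:2)
  expect_equal(unname(std2@mean), c(0, 0))
  expect_equal(unname(std2@sd), c(1, 1))

  wrong <- m
  colnames(wrong) <- c("a", "zz")
  expect_error(applyStandardizer(std, wrong), "feature names")
  const <- matrix(1, 3, 1, dimnames = list(NULL, "c"))
  expect_error(fitStandardizer(const, 1:3), "pruned")
})

test_that("sampleSingleCells pads short lines with per-gene medians", {
  genes <- paste0("g", 1:4)
  vals <- matrix(rnorm(4 * 9), 4, 9, dimnames = list(genes, NULL))
  x <- SingleCellMatrix(abs(vals), cellLine = c(rep("L1", 6), rep("L2", 3)))
  x <- logNormalize(x)
  SummarizedExperiment::assay(x, "lognorm", withDimnames = FALSE) <- vals
  scaled <- scaleCenter(x)

  blk <- sampleSingleCells(scaled, k = 10, seed = 2)
  expect_equal(unname(paddedCount(blk)), c(4L, 7L))
  l1 <- blk@cells[["L1"]]
  expect_equal(nrow(l1), 10)
  med <- apply(t(scValues(scaled))[cellLines(scaled) == "L1", ], 2, median)
  for (r in 7:10) expect_equal(unname(l1[r, ]), unname(med))

  # k <= available: rows are a subset of the line's cells, no padding
  blk1 <- sampleSingleCells(scaled, k = 3, seed = 5)
  expect_equal(unname(paddedCount(blk1)), c(0L, 0L))
  lineCells <- t(scValues(scaled))[cellLines(scaled) == "L1", ]
  for (r in 1:3) {
    hits <- apply(lineCells, 1, function(cell) all(cell == blk1@cells$L1[r, ]))
    expect_true(any(hits))
  }

  # reproducible under the same seed; exclusion respected
  expect_identical(
    sampleSingleCells(scaled, k = 3, seed = 5)@cells,
    blk1@cells
  )
  excl <- sampleSingleCells(scaled, k = 3, seed = 5, excludeLines = "L1")
  expect_equal(names(excl@cells), "L2")

  # k = 1 with a single available cell: that cell, no padding
  one <- SingleCellMatrix(matrix(1, 4, 1, dimnames = list(genes, "c1")),
    cellLine = "Solo"
  )
  one <- logNormalize(one)
  oneScaled <- scaleCenter(one)
  b1 <- sampleSingleCells(oneScaled, k = 1, seed = 1)
  expect_equal(unname(paddedCount(b1)), 0L)
  expect_equal(unname(b1@cells$Solo[1, ]), unname(scValues(oneScaled)[, 1]))
})

test_that("median padding with an even cell count uses the central mean", {
  genes <- paste0("g", 1:2)
  m <- matrix(c(1, 10, 2, 20, 4, 40, 8, 80), 2,
    dimnames = list(genes, NULL)
  ) # per-gene values 1,2,4,8 and 10,20,40,80
  x <- SingleCellMatrix(m, cellLine = rep("L", 4), layer = "scaled")
  blk <- sampleSingleCells(x, k = 6, seed = 1)
  pad <- blk@cells$L[5, ]
  expect_equal(unname(pad), c(mean(c(2, 4)), mean(c(20, 40))))
})

test_that("assembled branches stay row-aligned and leakage-free", {
  spec <- syntheticSpec(
    nCellLines = 12L, nDrugs = 10L, drugGeneralDim = 8L, drugTaxonomyDim = 6L,
    omicsDims = c(expression = 10L), nGenes = 40L, mitoGeneCount = 4L,
    ccGeneCount = 4L, nCellsPerLine = c(6L, 15L), seed = 2L
  )
  co <- generateCohort(spec)
  split <- makeSplits(co$pairs, seed = 4)
  bundle <- assembleBranchInputs(
    co$pairs, split, co$drugBlocks, co$omicsBlocks
  )
  for (part in names(bundle$partitions)) {
    p <- bundle$partitions[[part]]
    widths <- vapply(p$inputs, nrow, 1L)
    expect_true(all(widths == length(p$y)))
  }
  expect_true(assertLeakageFree(bundle, split))
  # row alignment: branch rows correspond to the same pair
  p <- bundle$partitions$train
  i <- 5
  drug <- p$pairs$drug_id[i]
  expect_equal(
    unname(p$inputs$general_descriptors[i, ]),
    unname(featureMatrix(co$drugBlocks[[1]])[drug, ])
  )

  # a pair with an unfeaturized drug is dropped with a message
  blocks2 <- co$drugBlocks
  keep <- setdiff(drugIds(blocks2[[1]]), "DRUG001")
  blocks2[[1]]@matrix <- blocks2[[1]]@matrix[keep, ]
  expect_message(
    b2 <- assembleBranchInputs(co$pairs, split, blocks2, co$omicsBlocks),
    "dropped"
  )
  expect_false("DRUG001" %in% b2$partitions$train$pairs$drug_id)
  nAll <- sum(vapply(bundle$partitions, function(p) nrow(p$pairs), 1L))
  nDropped <- sum(vapply(b2$partitions, function(p) nrow(p$pairs), 1L))
  expect_equal(nAll - nDropped, sum(b2$dropped))
})

test_that("the single-cell branch flattens k sampled cells per pair", {
  spec <- syntheticSpec(
    nCellLines = 8L, nDrugs = 6L, drugGeneralDim = 6L, drugTaxonomyDim = 4L,
    omicsDims = c(expression = 6L), nGenes = 40L, mitoGeneCount = 4L,
    ccGeneCount = 4L, nCellsPerLine = c(6L, 12L), seed = 3L
  )
  co <- generateCohort(spec)
  split <- makeSplits(co$pairs, seed = 1)
  filtered <- qcFilter(co$sc, qcThresholds(10L, 0.15))
  scaled <- scaleCenter(logNormalize(filtered))
  sampled <- sampleSingleCells(scaled, 4,
    seed = 1, excludeLines = split@heldOutCellLines
  )
  heldSample <- sampleSingleCells(scaled, 4,
    seed = 2,
    excludeLines = setdiff(unique(cellLines(scaled)), split@heldOutCellLines)
  )
  bundle <- assembleBranchInputs(
    co$pairs, split, co$drugBlocks, co$omicsBlocks,
    sampled = sampled, sampledHeldOut = heldSample
  )
  expect_true("single_cells" %in% bundle$branchNames)
  p <- bundle$partitions$train
  expect_equal(ncol(p$inputs$single_cells), 4 * nrow(scaled))
  line <- p$pairs$cell_line_id[2]
  expect_equal(
    unname(p$inputs$single_cells[2, ]),
    as.numeric(t(sampled@cells[[line]]))
  )
  # held-out lines' cells never enter the training-time sample block
  expect_length(intersect(names(sampled@cells), split@heldOutCellLines), 0)
  # the sc branch is omitted when no sample block is given
  b0 <- assembleBranchInputs(co$pairs, split, co$drugBlocks, co$omicsBlocks)
  expect_false("single_cells" %in% b0$branchNames)
  expect_length(b0$partitions$train$inputs, 3)

  # leakage guard: a sample block containing held-out lines is rejected
  full <- sampleSingleCells(scaled, 4, seed = 1)
  expect_error(
    assembleBranchInputs(co$pairs, split, co$drugBlocks, co$omicsBlocks,
      sampled = full
    ),
    "held-out"
  )
})

test_that("standardizeBundle gives train mean 0 / sd 1 and reuses train stats", {
  bundle <- miniBundle()
  for (br in names(bundle$partitions$train$inputs)) {
    tr <- bundle$partitions$train$inputs[[br]]
    expect_lt(max(abs(colMeans(tr))), 1e-8)
    popSd <- sqrt(colMeans(sweep(tr, 2, colMeans(tr))^2))
    expect_lt(max(abs(popSd - 1)), 1e-8)
    # non-train partitions use the training statistics (not their own)
    te <- bundle$partitions$test$inputs[[br]]
    expect_gt(max(abs(colMeans(te))), 1e-10)
  }
  std <- bundle$standardizers[[1]]
  expect_equal(std@fitPartition, "train")
})
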