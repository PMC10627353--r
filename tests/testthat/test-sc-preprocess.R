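test_that("intersectGenes returns the sorted common gene set", {
  a <- tinySc(genes = c("A", "B", "C"))
  b <- tinySc(genes = c("B", "C", "D"))
  expect_equal(intersectGenes(list(a, b)), c("B", "C"))
  expect_equal(intersectGenes(list(a)), c("A", "B", "C"))
  c3 <- tinySc(genes = c("C", "X", "Y"))
  expect_equal(intersectGenes(list(a, b, c3)), "C")
  d <- tinySc(genes = c("Z1", "Z2", "Z3"))
  expect_error(intersectGenes(list(a, d)), "shared")
})

test_that("mergeSingleCell subsets to shared genes and concatenates cells", {
  a <- tinySc(genes = c("A", "B", "C"), nCells = 3, cellLine = rep("L1", 3))
  b <- tinySc(genes = c("C", "B", "D"), nCells = 2, cellLine = rep("L2", 2))
  m <- mergeSingleCell(list(a, b))
  expect_equal(rownames(m), c("B", "C"))
  expect_equal(ncol(m), 5)
  expect_equal(unique(cellLines(m)), c("L1", "L2"))
})

test_that("qcFilter applies both boundary rules exactly as stated", {
  # 1200-gene panel incl. mitochondrial genes; the default thresholds apply
  genes <- c(sprintf("MT-%d", 1:200), sprintf("G%04d", 1:1000))
  mkCell <- function(nMito, nOther) {
    v <- numeric(1200)
    if (nMito > 0) v[seq_len(nMito)] <- 1
    if (nOther > 0) v[200 + seq_len(nOther)] <- 1
    v
  }
  counts <- cbind(
    exact = mkCell(150, 850), # 1000 genes, mito 150/1000 = 15.0%  -> kept
    few = mkCell(100, 899), # 999 genes, mito ~10%              -> removed
    hot = mkCell(151, 849) # 1000 genes, mito 15.1%            -> removed
  )
  rownames(counts) <- genes
  x <- SingleCellMatrix(counts, cellLine = rep("L", 3))
  out <- qcFilter(x)
  expect_equal(colnames(out), "exact")
  qc <- attr(out, "qc")
  expect_equal(qc$kept, c(TRUE, FALSE, FALSE))
  expect_equal(qc$mito_fraction[1], 0.15)
})

test_that("qcFilter counts survivors on a mixed fixture and is idempotent", {
  # 5 cells: two violate one rule each, three pass (thresholds scaled to the
  # 10-gene panel: >= 4 expressed genes, <= 15% mito)
  genes <- c("MT-1", paste0("G", 1:9))
  counts <- matrix(0, 10, 5, dimnames = list(genes, paste0("c", 1:5)))
  counts[2:6, 1] <- 1 # 5 genes, no mito          -> kept
  counts[c(1, 2:5), 2] <- c(1, 5, 5, 5, 5) # mito 1/21 ~ 4.8%  -> kept
  counts[2:4, 3] <- 1 # only 3 genes              -> removed
  counts[1, 4] <- 1
  counts[2:5, 4] <- 1 # mito 1/5 = 20%            -> removed
  counts[2:7, 5] <- 2 # 6 genes, no mito          -> kept
  x <- SingleCellMatrix(counts, cellLine = rep("L", 5))
  t <- qcThresholds(minGenesPerCell = 4, maxMitoFraction = 0.15)
  out <- qcFilter(x, t)
  expect_equal(colnames(out), c("c1", "c2", "c5"))
  again <- qcFilter(out, t)
  expect_equal(ncol(again), ncol(out))

  # zero-total cell removed with a warning, not an error
  counts0 <- counts
  counts0[, 1] <- 0
  x0 <- SingleCellMatrix(counts0, cellLine = rep("L", 5))
  expect_warning(out0 <- qcFilter(x0, t), "zero total")
  expect_false("c1" %in% colnames(out0))
})

test_that("logNormalize matches the formula and is library-size invariant", {
  counts <- matrix(c(10, 0, 0, 0), 2, 2,
    dimnames = list(c("A", "B"), c("c1", "c2"))
  )
  x <- SingleCellMatrix(counts, cellLine = c("L", "L"))
  ln <- logNormalize(x)
  expect_equal(scLayer(ln), "lognorm")
  m <- SummarizedExperiment::assay(ln, "lognorm")
  expect_equal(unname(m[, "c1"]), c(log(1 + 1e4), 0))
  expect_equal(unname(m[, "c2"]), c(0, 0)) # all-zero cell stays zero

  # doubling all counts of a cell leaves its normalized values unchanged
  y <- tinySc(nCells = 3)
  y2 <- SingleCellMatrix(scValues(y) * 2, cellLine = cellLines(y))
  expect_equal(
    SummarizedExperiment::assay(logNormalize(y), "lognorm"),
    SummarizedExperiment::assay(logNormalize(y2), "lognorm")
  )
})

test_that("selectHvg recovers planted high-variance genes", {
  set.seed(42)
  nCells <- 120
  flat <- matrix(rpois(500 * nCells, lambda = 5), 500,
    dimnames = list(sprintf("FLAT%03d", 1:500), NULL)
  )
  # planted genes are mean-matched to the flat genes (mean 5) but strongly
  # overdispersed, so they stand above the mean-variance trend
  planted <- t(vapply(1:10, function(i) {
    v <- numeric(nCells)
    v[seq_len(nCells / 2)] <- 10
    sample(v)
  }, numeric(nCells)))
  rownames(planted) <- sprintf("HV%02d", 1:10)
  x <- SingleCellMatrix(rbind(flat, planted), cellLine = rep("L", nCells))
  hvg <- selectHvg(x, 10)
  expect_setequal(hvg, rownames(planted))

  expect_setequal(selectHvg(x, nrow(x)), rownames(x)) # n = all genes
  expect_equal(selectHvg(x, 0), character())
  expect_error(selectHvg(x, nrow(x) + 1), "exceeds")
})

test_that("selectHvg is stable under cell and gene permutation", {
  set.seed(9)
  x <- SingleCellMatrix(
    matrix(rnbinom(80 * 40, mu = 4, size = 2), 80,
      dimnames = list(sprintf("g%02d", 1:80), NULL)
    ),
    cellLine = rep("L", 40)
  )
  ref <- selectHvg(x, 15)
  permCells <- x[, sample(ncol(x))]
  expect_equal(selectHvg(permCells, 15), ref)
  permGenes <- x[sample(nrow(x)), ]
  expect_equal(selectHvg(permGenes, 15), ref)
})

test_that("cell-cycle module scores behave as constructed", {
  nCells <- 30
  bg <- matrix(1, 200, nCells, dimnames = list(sprintf("BG%03d", 1:200), NULL))
  sets <- list(s = sprintf("S%d", 1:5), g2m = sprintf("M%d", 1:5))
  # uniform expression: every score is exactly 0
  uni <- rbind(bg, matrix(1, 10, nCells,
    dimnames = list(c(sets$s, sets$g2m), NULL)
  ))
  xu <- SingleCellMatrix(uni, cellLine = rep("L", nCells))
  xu <- logNormalize(xu)
  SummarizedExperiment::assay(xu, "lognorm", withDimnames = FALSE) <- uni
  su <- scoreCellCycle(xu, sets, seed = 1)
  expect_lt(max(abs(su$s_score)), 1e-6)
  expect_lt(max(abs(su$g2m_score)), 1e-6)

  # S genes uniformly +1 above background (G2M at background) -> s score +1,
  # g2m score 0
  shifted <- rbind(
    bg,
    matrix(2, 5, nCells, dimnames = list(sets$s, NULL)),
    matrix(1, 5, nCells, dimnames = list(sets$g2m, NULL))
  )
  xs <- SingleCellMatrix(shifted, cellLine = rep("L", nCells))
  xs <- logNormalize(xs)
  SummarizedExperiment::assay(xs, "lognorm", withDimnames = FALSE) <- shifted
  ss <- scoreCellCycle(xs, sets, seed = 1)
  expect_equal(ss$s_score, rep(1, nCells))
  # the G2M control pool may include a few shifted S genes in this tiny
  # 2-bin fixture, so its null score is only near zero
  expect_lt(max(abs(ss$g2m_score)), 0.1)

  # determinism and the missing-set error
  expect_identical(ss, scoreCellCycle(xs, sets, seed = 1))
  expect_error(
    scoreCellCycle(xs, list(s = "ABSENT", g2m = sets$g2m)),
    "'s' set"
  )
})

test_that("scaleCenter z-scores, zeroes constant genes and clips", {
  set.seed(5)
  nCells <- 150 # enough cells that one outlier can exceed 10 sd
  m <- matrix(rnorm(5 * nCells, sd = 3), 5, nCells,
    dimnames = list(paste0("g", 1:5), NULL)
  )
  m[3, ] <- 7 # constant gene
  m[1, 1] <- 1000 # extreme outlier to trigger the clip
  x <- SingleCellMatrix(pmax(round(abs(m)), 0), cellLine = rep("L", nCells))
  x <- logNormalize(x)
  SummarizedExperiment::assay(x, "lognorm", withDimnames = FALSE) <- m
  sc <- scaleCenter(x)
  z <- scValues(sc)
  expect_equal(scLayer(sc), "scaled")
  expect_equal(unname(z[3, ]), rep(0, nCells))
  for (g in c(2, 4, 5)) {
    expect_lt(abs(mean(z[g, ])), 1e-8)
    expect_equal(sd(z[g, ]), 1, tolerance = 1e-8)
  }
  expect_equal(max(z), 10) # clipped above at 10
  expect_error(scaleCenter(x, genes = "nope"), "not in matrix")
})

test_that("pipeline steps refuse inputs on the wrong layer", {
  x <- tinySc()
  expect_error(scaleCenter(x), "layer")
  expect_error(scoreCellCycle(x, list(s = "G1", g2m = "G2")), "layer")
  ln <- logNormalize(x)
  expect_error(logNormalize(ln), "layer")
  expect_error(qcFilter(ln), "layer")
  sc <- scaleCenter(ln)
  expect_error(selectHvg(sc, 2), "layer")
})

test_that("regressCellCycle removes the score-correlated component", {
  set.seed(11)
  nCells <- 40
  scores <- data.frame(
    cell = sprintf("cell%04d", 1:nCells),
    s_score = rnorm(nCells), g2m_score = rnorm(nCells)
  )
  base <- matrix(rnorm(6 * nCells), 6, nCells,
    dimnames = list(paste0("g", 1:6), scores$cell)
  )
  contaminated <- base + outer(rep(2, 6), scores$s_score)
  x <- SingleCellMatrix(matrix(1, 6, nCells,
    dimnames = dimnames(base)
  ), cellLine = rep("L", nCells))
  x <- logNormalize(x)
  SummarizedExperiment::assay(x, "lognorm", withDimnames = FALSE) <- contaminated
  out <- regressCellCycle(x, scores)
  resid <- SummarizedExperiment::assay(out, "lognorm")
  for (g in 1:6) {
    expect_lt(abs(cor(resid[g, ], scores$s_score)), 1e-8)
  }
})

test_that("the packaged cell-cycle gene sets load and are disjoint", {
  sets <- readCellCycleGeneSets()
  expect_gt(length(sets$s), 30)
  expect_gt(length(sets$g2m), 40)
  expect_length(intersect(sets$s, sets$g2m), 0)
})

test_that("dense CSV and 10x-triplet readers reconstruct the same matrix", {
  counts <- matrix(c(0, 2, 1, 0, 5, 3), 3, 2,
    dimnames = list(c("GA", "GB", "GC"), c("bc1", "bc2"))
  )
  # dense cells x genes layout
  df <- data.frame(
    cell_id = colnames(counts), cell_line_id = c("L1", "L2"), t(counts),
    check.names = FALSE
  )
  x1 <- readSingleCellCsv(tmpCsv(df))
  expect_equal(unname(scValues(x1)), unname(counts))
  expect_equal(cellLines(x1), c("L1", "L2"))

  # 10x triplet
  dir <- tempfile()
  dir.create(dir)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
    file.path(dir, "matrix.mtx")
  )
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = rownames(counts), sym = rownames(counts)),
    file.path(dir, "features.tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  map <- data.frame(barcode = c("bc1", "bc2"), cell_line_id = c("L1", "L2"))
  x2 <- readTenx(
    file.path(dir, "matrix.mtx"), file.path(dir, "barcodes.tsv"),
    file.path(dir, "features.tsv"), map
  )
  expect_equal(unname(scValues(x2)), unname(counts))
  expect_equal(cellLines(x2), cellLines(x1))
})
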