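# Shared fixtures, built in code at test time.

# tiny counts-layer SingleCellMatrix; counts filled deterministically unless
# a matrix is supplied
tinySc <- function(genes = paste0("G", 1:6), nCells = 4,
                   cellLine = rep("CL1", nCells), counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(seq_len(length(genes) * nCells) %% 7,
      nrow = length(genes), dimnames = list(genes, NULL)
    )
  }
  SingleCellMatrix(counts, cellLine = cellLine)
}

# planted linear regression data split into two aligned branch matrices
plantedLinear <- function(n = 400, p = 12, noiseSd = 0.1, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = noiseSd)
  list(X = X, y = y, beta = beta)
}

# a small two-branch standardized bundle around a planted linear signal,
# for model/tuning tests
miniBundle <- function(nLines = 25, nDrugs = 20, seed = 3) {
  spec <- syntheticSpec(
    nCellLines = nLines, nDrugs = nDrugs,
    drugGeneralDim = 16L, drugTaxonomyDim = 8L,
    omicsDims = c(expression = 16L),
    nGenes = 60L, mitoGeneCount = 4L, ccGeneCount = 4L,
    nCellsPerLine = c(6L, 20L), seed = seed
  )
  co <- generateCohort(spec)
  split <- makeSplits(co$pairs, seed = seed)
  bundle <- assembleBranchInputs(co$pairs, split, co$drugBlocks, co$omicsBlocks)
  standardizeBundle(bundle)
}

# naive-definition metric oracle: explicit loops, mid-ranks by sorting
bruteMetrics <- function(y, p) {
  n <- length(y)
  se <- ae <- 0
  for (i in seq_len(n)) {
    se <- se + (y[i] - p[i])^2
    ae <- ae + abs(y[i] - p[i])
  }
  mse <- se / n
  mae <- ae / n
  pearson <- function(a, b) {
    ma <- sum(a) / n
    mb <- sum(b) / n
    num <- den1 <- den2 <- 0
    for (i in seq_len(n)) {
      num <- num + (a[i] - ma) * (b[i] - mb)
      den1 <- den1 + (a[i] - ma)^2
      den2 <- den2 + (b[i] - mb)^2
    }
    num / sqrt(den1 * den2)
  }
  midRank <- function(a) {
    r <- numeric(n)
    for (i in seq_len(n)) {
      less <- ties <- 0
      for (j in seq_len(n)) {
        if (a[j] < a[i]) less <- less + 1
        if (a[j] == a[i]) ties <- ties + 1
      }
      r[i] <- less + (ties + 1) / 2
    }
    r
  }
  ssTot <- 0
  my <- sum(y) / n
  for (i in seq_len(n)) ssTot <- ssTot + (y[i] - my)^2
  list(
    mse = mse, mae = mae, rmse = sqrt(mse),
    pcc = pearson(y, p),
    scc = pearson(midRank(y), midRank(p)),
    r2 = 1 - se / ssTot
  )
}

# write a data.frame to a temp csv, returning the path
tmpCsv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}
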