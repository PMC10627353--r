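# Download-free synthetic cohorts with the statistical structure the pipeline
# assumes: latent-factor drug descriptor blocks and bulk omics blocks,
# negative-binomial single-cell counts with line-specific programs plus
# designated mitochondrial and cell-cycle genes, and a planted
# ln(IC50) surface  y = u.a_d + v.b_c + a_d' M b_c + noise
# (drug main effect + cell-line main effect + bilinear interaction), stored as
# ground truth for recovery tests.

#' Specification for a synthetic drug-response cohort
#'
#' Defaults describe the package's reference study conditions: 40 cell lines x
#' 60 drugs, latent dimension 4, observation noise sd 0.3 on the ln(IC50)
#' scale, unit-variance drug and cell-line main effects with a bilinear
#' interaction of sd 0.4, two bulk omics blocks, a 150-gene single-cell panel
#' (10 mitochondrial, 8 + 8 planted cell-cycle genes) with 6-60 cells per line
#' (deliberately spanning below and above the usual sampling size k = 10 so
#' median padding is exercised), and negative-binomial dispersion 0.5.
#'
#' @param nCellLines,nDrugs cohort dimensions.
#' @param latentDim latent-factor dimension.
#' @param noiseSd Gaussian noise sd added to the ln(IC50) surface.
#' @param interactionSd sd of the bilinear drug x cell-line term.
#' @param drugGeneralDim,drugTaxonomyDim drug descriptor block widths.
#' @param omicsDims named integer vector of bulk block widths.
#' @param nGenes single-cell panel size (includes special genes).
#' @param mitoGeneCount designated mitochondrial genes (`MT-*` symbols).
#' @param ccGeneCount planted cell-cycle genes per phase.
#' @param nCellsPerLine integer range `c(min, max)` of cells per line.
#' @param qcLowQualityRate fraction of cells made to violate QC rules
#'   (half high-mitochondrial, half shallow).
#' @param nbDispersion negative-binomial dispersion (size = 1/dispersion).
#' @param featureNoiseSd sd of independent noise added to descriptor/omics
#'   features.
#' @param missingSmilesRate fraction of drugs with absent SMILES in the drug
#'   table (descriptor blocks still cover all drugs).
#' @param seed integer seed.
#' @return a `SyntheticSpec` (named list, class `"SyntheticSpec"`).
#' @export
syntheticSpec <- function(nCellLines = 40L, nDrugs = 60L, latentDim = 4L,
                          noiseSd = 0.3, interactionSd = 0.4,
                          drugGeneralDim = 64L, drugTaxonomyDim = 32L,
                          omicsDims = c(expression = 80L, copy_number = 40L),
                          nGenes = 150L, mitoGeneCount = 10L, ccGeneCount = 8L,
                          nCellsPerLine = c(6L, 60L),
                          qcLowQualityRate = 0.10,
                          nbDispersion = 0.5, featureNoiseSd = 0.3,
                          missingSmilesRate = 0.05, seed = 1L) {
  stopifnot(
    nCellLines >= 1, nDrugs >= 1, latentDim >= 1, noiseSd >= 0,
    nGenes > mitoGeneCount + 2 * ccGeneCount,
    length(nCellsPerLine) == 2, nCellsPerLine[1] >= 1,
    nCellsPerLine[1] <= nCellsPerLine[2]
  )
  structure(as.list(environment()), class = "SyntheticSpec")
}

# small pool of valid molecules so featurizer backends accept the synthetic
# SMILES (descriptor engines reject arbitrary strings)
.smilesPool <- function() {
  c(
    "CCO", "CC(=O)O", "c1ccccc1", "c1ccncc1", "C1CCCCC1", "CC(C)O",
    "CCN(CC)CC", "CC(=O)Nc1ccc(O)cc1", "c1ccc2ccccc2c1", "CCOC(=O)C",
    "CC(N)C(=O)O", "CSCCC(N)C(=O)O", "OCC(O)CO", "Clc1ccccc1",
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "O=C(O)c1ccccc1OC(C)=O"
  )
}

.geneNames <- function(spec) {
  nOther <- spec$nGenes - spec$mitoGeneCount - 2L * spec$ccGeneCount
  c(
    sprintf("GENE%03d", seq_len(nOther)),
    sprintf("MT-%d", seq_len(spec$mitoGeneCount)),
    sprintf("CCS%d", seq_len(spec$ccGeneCount)),
    sprintf("CCG2M%d", seq_len(spec$ccGeneCount))
  )
}

.latentBlock <- function(latents, dim, noiseSd, featPrefix) {
  p <- ncol(latents)
  loadings <- matrix(rnorm(p * dim), p, dim)
  m <- latents %*% loadings + matrix(rnorm(nrow(latents) * dim, sd = noiseSd),
                                     nrow(latents), dim)
  colnames(m) <- sprintf("%s%03d", featPrefix, seq_len(dim))
  m
}

#' Generate a synthetic cohort with planted signal and full ground truth
#'
#' See [syntheticSpec()] for the generative model. Everything the real loaders
#' consume is produced: a drug table with SMILES, two drug descriptor blocks,
#' bulk omics blocks, a counts-layer single-cell matrix with labelled
#' mitochondrial / cell-cycle genes and planted QC-violating cells, and the
#' pair table. The `truth` element stores latents, loadings, the noise-free
#' ln(IC50) surface and per-cell QC bookkeeping for recovery tests.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `drugTable`, `drugBlocks`, `omicsBlocks`, `sc`,
#'   `pairs`, `ccGeneSets` and `truth`.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    lines <- sprintf("CL%03d", seq_len(spec$nCellLines))
    drugs <- sprintf("DRUG%03d", seq_len(spec$nDrugs))
    A <- matrix(rnorm(spec$nDrugs * spec$latentDim), spec$nDrugs,
                dimnames = list(drugs, NULL))
    B <- matrix(rnorm(spec$nCellLines * spec$latentDim), spec$nCellLines,
                dimnames = list(lines, NULL))

    general <- .latentBlock(A, spec$drugGeneralDim, spec$featureNoiseSd, "gd")
    taxonomy <- .latentBlock(A, spec$drugTaxonomyDim, spec$featureNoiseSd, "tx")
    drugBlocks <- list(
      new("DrugFeatureTable", blockName = "general_descriptors",
          matrix = general, droppedColumns = character()),
      new("DrugFeatureTable", blockName = "taxonomy_features",
          matrix = taxonomy, droppedColumns = character())
    )

    omicsBlocks <- lapply(names(spec$omicsDims), function(nm) {
      m <- .latentBlock(B, spec$omicsDims[[nm]], spec$featureNoiseSd,
                        substr(nm, 1, 2))
      omicsBlock(m, nm)
    })
    names(omicsBlocks) <- names(spec$omicsDims)

    smiles <- sample(.smilesPool(), spec$nDrugs, replace = TRUE)
    absent <- runif(spec$nDrugs) < spec$missingSmilesRate
    smiles[absent] <- NA_character_
    drugTable <- data.frame(drug_id = drugs, smiles = smiles,
                            stringsAsFactors = FALSE)

    # --- single-cell counts -------------------------------------------------
    genes <- .geneNames(spec)
    mito <- startsWith(genes, "MT-")
    sGenes <- genes[startsWith(genes, "CCS")]
    g2mGenes <- genes[startsWith(genes, "CCG2M")]
    baseMu <- exp(rnorm(spec$nGenes, mean = log(2), sd = 1))
    names(baseMu) <- genes
    gamma <- matrix(rnorm(spec$latentDim * spec$nGenes, sd = 0.5),
                    spec$latentDim, spec$nGenes)
    lineLog <- B %*% gamma # line-specific expression program
    nCells <- sample(seq.int(spec$nCellsPerLine[1], spec$nCellsPerLine[2]),
                     spec$nCellLines, replace = TRUE)
    size <- 1 / spec$nbDispersion
    counts <- matrix(0, spec$nGenes, sum(nCells),
                     dimnames = list(genes, NULL))
    cellLine <- character(sum(nCells))
    lowQuality <- character(sum(nCells))
    phase <- character(sum(nCells))
    col <- 0L
    for (li in seq_len(spec$nCellLines)) {
      mu <- baseMu * exp(0.6 * lineLog[li, ])
      for (ci in seq_len(nCells[li])) {
        col <- col + 1L
        cellLine[col] <- lines[li]
        cellMu <- mu
        phase[col] <- sample(c("G1", "S", "G2M"), 1, prob = c(0.6, 0.2, 0.2))
        if (phase[col] == "S") cellMu[sGenes] <- cellMu[sGenes] * 6
        if (phase[col] == "G2M") cellMu[g2mGenes] <- cellMu[g2mGenes] * 6
        bad <- runif(1) < spec$qcLowQualityRate
        lowQuality[col] <- if (!bad) {
          "none"
        } else if (runif(1) < 0.5) {
          cellMu[mito] <- cellMu[mito] * 40
          "high_mito"
        } else {
          cellMu <- cellMu * 0.02
          "shallow"
        }
        counts[, col] <- rnbinom(spec$nGenes, mu = cellMu, size = size)
      }
    }
    colnames(counts) <- sprintf("syn_cell%05d", seq_len(ncol(counts)))
    sc <- SingleCellMatrix(counts, cellLine = cellLine, dataset = "synthetic",
                           layer = "counts")

    # --- pair table ---------------------------------------------------------
    u <- rnorm(spec$latentDim)
    u <- u / sqrt(sum(u^2))
    v <- rnorm(spec$latentDim)
    v <- v / sqrt(sum(v^2))
    M <- matrix(rnorm(spec$latentDim^2), spec$latentDim)
    M <- M * spec$interactionSd / sqrt(sum(M^2))
    surface <- outer(drop(A %*% u), drop(B %*% v), `+`) + A %*% M %*% t(B)
    dimnames(surface) <- list(drugs, lines)
    noise <- matrix(rnorm(length(surface), sd = spec$noiseSd), nrow(surface))
    pairs <- data.frame(
      drug_id = rep(drugs, times = spec$nCellLines),
      cell_line_id = rep(lines, each = spec$nDrugs),
      ln_ic50 = as.numeric(surface + noise),
      stringsAsFactors = FALSE
    )

    truth <- list(
      drugLatents = A, cellLatents = B, u = u, v = v, M = M,
      surface = surface,
      qc = data.frame(
        cell = colnames(counts), cell_line_id = cellLine,
        low_quality = lowQuality, phase = phase,
        expressed_genes = colSums(counts > 0),
        mito_fraction = colSums(counts[mito, , drop = FALSE]) /
          pmax(colSums(counts), 1),
        stringsAsFactors = FALSE
      )
    )
    list(
      drugTable = drugTable, drugBlocks = drugBlocks,
      omicsBlocks = omicsBlocks, sc = sc, pairs = pairs,
      ccGeneSets = list(s = sGenes, g2m = g2mGenes), truth = truth
    )
  })
}

#' Corrupt a cohort to exercise the missing-value and deduplication rules
#'
#' Blanks whole cell-line rows in the first omics block and scalar entries in
#' the others (both recorded), and duplicates a fraction of pairs with
#' jittered ln(IC50) values so pair averaging is exercised.
#'
#' @param cohort output of [generateCohort()].
#' @param rowRate fraction of cell lines blanked from the first block.
#' @param cellRate fraction of scalar entries blanked in the other blocks.
#' @param dupRate fraction of pairs duplicated with jitter.
#' @param jitterSd sd of the jitter applied to duplicated pairs.
#' @param seed integer seed.
#' @return the cohort with corrupted `omicsBlocks` / `pairs` and a
#'   `corruption` record.
#' @export
injectMissingness <- function(cohort, rowRate = 0.1, cellRate = 0.05,
                              dupRate = 0.1, jitterSd = 0.1, seed = 1L) {
  stopifnot(rowRate >= 0, rowRate < 1, cellRate >= 0, cellRate < 1,
            dupRate >= 0, dupRate < 1)
  withSeed(seed, {
    blocks <- cohort$omicsBlocks
    blanked <- character()
    if (length(blocks) && rowRate > 0) {
      ids <- cellLineIds(blocks[[1]])
      nBlank <- floor(rowRate * length(ids))
      if (nBlank > 0) {
        blanked <- sort(sample(ids, nBlank))
        m <- blocks[[1]]@matrix
        m[blanked, ] <- 0
        blocks[[1]] <- new("OmicsBlock",
          blockName = blocks[[1]]@blockName, matrix = m,
          missingCellIds = sort(union(blocks[[1]]@missingCellIds, blanked))
        )
      }
    }
    nScalar <- 0L
    if (length(blocks) > 1 && cellRate > 0) {
      for (bi in 2:length(blocks)) {
        m <- blocks[[bi]]@matrix
        hit <- runif(length(m)) < cellRate
        m[hit] <- 0
        nScalar <- nScalar + sum(hit)
        blocks[[bi]] <- new("OmicsBlock",
          blockName = blocks[[bi]]@blockName, matrix = m,
          missingCellIds = blocks[[bi]]@missingCellIds
        )
      }
    }
    pairs <- cohort$pairs
    nDup <- floor(dupRate * nrow(pairs))
    if (nDup > 0) {
      dupIdx <- sample(nrow(pairs), nDup)
      dup <- pairs[dupIdx, , drop = FALSE]
      dup$ln_ic50 <- dup$ln_ic50 + rnorm(nDup, sd = jitterSd)
      pairs <- rbind(pairs, dup)
    }
    cohort$omicsBlocks <- blocks
    cohort$pairs <- pairs
    cohort$corruption <- list(
      blanked_lines = blanked, scalar_blanks = nScalar,
      duplicated_pairs = nDup
    )
    cohort
  })
}

#' Write a cohort to disk in the layouts the loaders consume
#'
#' @param cohort output of [generateCohort()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$drugTable, file.path(dir, "drugs.csv"), row.names = FALSE)
  for (ob in cohort$omicsBlocks) {
    df <- data.frame(cell_line_id = cellLineIds(ob), ob@matrix,
                     check.names = FALSE)
    write.csv(df, file.path(dir, sprintf("omics_%s.csv", ob@blockName)),
              row.names = FALSE)
  }
  counts <- scValues(cohort$sc)
  scDf <- data.frame(
    cell_id = colnames(counts),
    cell_line_id = cellLines(cohort$sc),
    dataset_id = as.character(
      SummarizedExperiment::colData(cohort$sc)$dataset_id
    ),
    t(counts), check.names = FALSE
  )
  write.csv(scDf, file.path(dir, "sc_counts.csv"), row.names = FALSE)
  write.csv(cohort$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  invisible(dir)
}
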