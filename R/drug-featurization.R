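# SMILES -> fixed-width descriptor blocks for the model's drug branch.
#
# Two blocks are produced: "general_descriptors" (1D/2D physico-chemical
# descriptors; reference backend = ChemmineR/OpenBabel, default backend = a
# documented lightweight SMILES-token schema so the package runs with no
# cheminformatics toolkit) and "taxonomy_features" (element / ring / branch /
# charge token counts plus a character histogram over the SMILES alphabet).

#' Parse a drug table (drug_id, smiles) from CSV
#'
#' Empty or whitespace-only SMILES are normalized to `NA` (the drug is kept in
#' the table but excluded from featurization output, mirroring the attrition
#' between screened compounds and compounds with available structures).
#'
#' @param path CSV file with at least columns `drug_id` and `smiles`.
#' @return data.frame with columns `drug_id` (character, unique) and `smiles`
#'   (character, `NA` when absent).
#' @export
parseDrugTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("drug_id", "smiles")) {
    if (!col %in% names(df)) stopf("drug table is missing required column '%s'", col)
  }
  smiles <- trimws(df$smiles)
  smiles[is.na(smiles) | smiles == ""] <- NA_character_
  out <- data.frame(
    drug_id = df$drug_id, smiles = smiles,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$drug_id)) {
    stopf(
      "duplicated drug_id: %s",
      paste(unique(out$drug_id[duplicated(out$drug_id)]), collapse = ", ")
    )
  }
  out
}

# SMILES alphabet used by the lightweight featurizers (fixed schema; the
# character histogram is computed over exactly these symbols).
.smilesAlphabet <- function() {
  c(
    "C", "c", "N", "n", "O", "o", "S", "s", "P", "p", "F", "I",
    "B", "H", "K", "L", "R", "r", "l", "a", "e", "i", "g", "u", "t", "d",
    "0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
    "(", ")", "[", "]", "=", "#", ":", "+", "-", "@", "/", "\\", ".", "%"
  )
}

# Organic-subset + halogen element tokens, matched longest-first so "Cl" and
# "Br" are not double-counted as C/B.
.elementTokens <- c("Cl", "Br", "Si", "Se", "C", "N", "O", "S", "P", "F", "I", "B")

# Tokenize a SMILES into element symbols (aromatic lowercase forms counted as
# their element). Returns NULL for strings with no recognizable atom.
.countElements <- function(smiles) {
  counts <- stats::setNames(integer(length(.elementTokens)), .elementTokens)
  s <- smiles
  # two-letter tokens first (case-sensitive), then one-letter incl. aromatic
  for (tok in c("Cl", "Br", "Si", "Se")) {
    n <- lengths(regmatches(s, gregexpr(tok, s, fixed = TRUE)))
    counts[tok] <- n
    s <- gsub(tok, "", s, fixed = TRUE)
  }
  for (tok in c("C", "N", "O", "S", "P", "F", "I", "B")) {
    pat <- paste0("[", tok, tolower(tok), "]")
    counts[tok] <- lengths(regmatches(s, gregexpr(pat, s)))
  }
  counts
}

.tokenCounts <- function(smiles) {
  cnt <- function(pat, fixed = FALSE) {
    lengths(regmatches(smiles, gregexpr(pat, smiles, fixed = fixed)))
  }
  c(
    aromatic_atoms = cnt("[cnosp]"),
    ring_closures = cnt("[0-9]"),
    ring_closures_pct = cnt("%[0-9][0-9]"),
    branches = cnt("(", fixed = TRUE),
    bracket_atoms = cnt("[", fixed = TRUE),
    double_bonds = cnt("=", fixed = TRUE),
    triple_bonds = cnt("#", fixed = TRUE),
    pos_charges = cnt("+", fixed = TRUE),
    neg_charge_tokens = cnt("\\]|-"),  # '-' inside brackets approximated below
    stereo_centers = cnt("@", fixed = TRUE),
    cis_trans = cnt("[/\\\\]"),
    dots = cnt(".", fixed = TRUE),
    length = nchar(smiles)
  )
}

# crude monoisotopic-free average atomic masses for the lightweight MW proxy
.atomMass <- c(
  C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974, F = 18.998,
  Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81, Si = 28.085, Se = 78.971
)

# Lightweight general descriptors: one numeric row per SMILES. Schema is
# fixed (names and width independent of input). Counts ignore implicit
# hydrogens; MW proxy is the heavy-atom mass sum.
.lightweightGeneral <- function(smiles) {
  el <- .countElements(smiles)
  tok <- .tokenCounts(smiles)
  heavy <- sum(el)
  halogens <- sum(el[c("F", "Cl", "Br", "I")])
  hetero <- heavy - el[["C"]]
  c(
    heavy_atom_count = heavy,
    mw_heavy = sum(el * .atomMass[names(el)]),
    carbon_count = el[["C"]],
    nitrogen_count = el[["N"]],
    oxygen_count = el[["O"]],
    sulfur_count = el[["S"]],
    phosphorus_count = el[["P"]],
    halogen_count = halogens,
    heteroatom_count = hetero,
    heteroatom_fraction = if (heavy > 0) hetero / heavy else 0,
    aromatic_atom_count = tok[["aromatic_atoms"]],
    aromatic_fraction = if (heavy > 0) tok[["aromatic_atoms"]] / heavy else 0,
    ring_closure_count = tok[["ring_closures"]] / 2,
    branch_count = tok[["branches"]],
    double_bond_count = tok[["double_bonds"]],
    triple_bond_count = tok[["triple_bonds"]],
    hbond_donor_proxy = el[["N"]] + el[["O"]],
    charge_token_count = tok[["pos_charges"]],
    stereo_center_count = tok[["stereo_centers"]],
    smiles_length = tok[["length"]]
  )
}

# Lightweight taxonomy-style features: element counts, ring/branch/charge
# token counts, and a character histogram over the SMILES alphabet.
.lightweightTaxonomy <- function(smiles) {
  el <- .countElements(smiles)
  names(el) <- paste0("n_", names(el))
  tok <- .tokenCounts(smiles)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  alpha <- .smilesAlphabet()
  hist <- vapply(alpha, function(a) sum(chars == a), 0)
  names(hist) <- paste0("chr_", alpha)
  c(
    el,
    ring_tokens = tok[["ring_closures"]],
    branch_tokens = tok[["branches"]],
    pos_charge_tokens = tok[["pos_charges"]],
    stereo_tokens = tok[["stereo_centers"]],
    bracket_tokens = tok[["bracket_atoms"]],
    hist
  )
}

# ChemmineR/OpenBabel backend: physico-chemical properties + element counts.
.chemminerGeneral <- function(smilesVec) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stopf("backend 'chemminer' requires the ChemmineR package")
  }
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smilesVec, names(smilesVec)))
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) warnf("%d SMILES could not be converted by OpenBabel", sum(!ok))
  sdf <- sdf[ok]
  if (length(sdf) == 0) return(NULL)
  pr <- ChemmineR::propOB(sdf)
  num <- pr[vapply(pr, is.numeric, TRUE)]
  ac <- ChemmineR::atomcountMA(sdf, addH = FALSE)
  m <- cbind(as.matrix(num), as.matrix(ac))
  rownames(m) <- names(smilesVec)[ok]
  m
}

.dropBadColumns <- function(m) {
  if (ncol(m) == 0) return(list(matrix = m, dropped = character()))
  ok <- apply(m, 2, function(col) all(is.finite(col)))
  list(matrix = m[, ok, drop = FALSE], dropped = colnames(m)[!ok])
}

.validSmilesRecords <- function(records) {
  stopifnot(is.data.frame(records), all(c("drug_id", "smiles") %in% names(records)))
  records[!is.na(records$smiles), , drop = FALSE]
}

#' Compute the general (1D/2D) descriptor block from SMILES
#'
#' @param records data.frame from [parseDrugTable()] (columns `drug_id`,
#'   `smiles`).
#' @param backend `"lightweight"` (default; documented SMILES-token schema,
#'   no toolkit needed), `"chemminer"` (ChemmineR/OpenBabel physico-chemical
#'   properties), or a function `smiles -> named numeric vector` implementing
#'   a custom engine.
#' @return a [DrugFeatureTable-class] named `"general_descriptors"`; rows are
#'   the drugs with valid, parsable SMILES; columns containing any non-finite
#'   value are dropped and recorded.
#' @export
computeGeneralDescriptors <- function(records, backend = "lightweight") {
  recs <- .validSmilesRecords(records)
  if (nrow(recs) == 0) stopf("no records with valid SMILES")
  if (is.function(backend)) {
    rows <- lapply(recs$smiles, function(s) {
      tryCatch(backend(s), error = function(e) NULL)
    })
  } else if (identical(backend, "lightweight")) {
    rows <- lapply(recs$smiles, function(s) {
      tryCatch(.lightweightGeneral(s), error = function(e) NULL)
    })
  } else if (identical(backend, "chemminer")) {
    sm <- stats::setNames(recs$smiles, recs$drug_id)
    m <- .chemminerGeneral(sm)
    if (is.null(m) || nrow(m) == 0) stopf("no records with valid SMILES")
    cleaned <- .dropBadColumns(m)
    if (length(cleaned$dropped)) {
      message(sprintf("dropped %d non-finite descriptor columns", length(cleaned$dropped)))
    }
    return(new("DrugFeatureTable",
      blockName = "general_descriptors",
      matrix = cleaned$matrix, droppedColumns = cleaned$dropped
    ))
  } else {
    stopf("unknown descriptor backend '%s'", backend)
  }
  keep <- !vapply(rows, is.null, TRUE)
  if (!all(keep)) {
    warnf(
      "skipped %d unparsable SMILES (%s)", sum(!keep),
      paste(head(recs$drug_id[!keep], 5), collapse = ", ")
    )
  }
  if (!any(keep)) stopf("no records with valid SMILES")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- recs$drug_id[keep]
  cleaned <- .dropBadColumns(m)
  if (length(cleaned$dropped)) {
    message(sprintf("dropped %d non-finite descriptor columns", length(cleaned$dropped)))
  }
  new("DrugFeatureTable",
    blockName = "general_descriptors",
    matrix = cleaned$matrix, droppedColumns = cleaned$dropped
  )
}

#' Compute the taxonomy / SMILES-character descriptor block
#'
#' @inheritParams computeGeneralDescriptors
#' @param backend `"lightweight"` (default, built-in schema: element counts,
#'   ring/branch/charge token counts, character histogram over the SMILES
#'   alphabet), `"reference_taxonomy"` (requires a user-registered engine via
#'   `engine=`), or a function `smiles -> named numeric vector`.
#' @param engine optional function implementing the reference taxonomy schema.
#' @return a [DrugFeatureTable-class] named `"taxonomy_features"`.
#' @export
computeTaxonomyFeatures <- function(records, backend = "lightweight",
                                    engine = NULL) {
  recs <- .validSmilesRecords(records)
  if (nrow(recs) == 0) stopf("no records with valid SMILES")
  fn <- if (is.function(backend)) {
    backend
  } else if (identical(backend, "lightweight")) {
    .lightweightTaxonomy
  } else if (identical(backend, "reference_taxonomy")) {
    if (is.null(engine)) {
      stopf(paste0(
        "backend 'reference_taxonomy' needs an engine function (the published ",
        "163-descriptor taxonomy schema is not bundled); pass engine= or use ",
        "backend='lightweight'"
      ))
    }
    engine
  } else {
    stopf("unknown taxonomy backend '%s'", backend)
  }
  rows <- lapply(recs$smiles, function(s) tryCatch(fn(s), error = function(e) NULL))
  keep <- !vapply(rows, is.null, TRUE)
  if (!all(keep)) {
    warnf("skipped %d unparsable SMILES", sum(!keep))
  }
  if (!any(keep)) stopf("no records with valid SMILES")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- recs$drug_id[keep]
  cleaned <- .dropBadColumns(m)
  new("DrugFeatureTable",
    blockName = "taxonomy_features",
    matrix = cleaned$matrix, droppedColumns = cleaned$dropped
  )
}

#' Write a DrugFeatureTable as wide CSV plus a dropped-column sidecar JSON
#'
#' @param x a [DrugFeatureTable-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDrugFeatureTable <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(x@blockName, ".csv"))
  df <- data.frame(drug_id = drugIds(x), x@matrix, check.names = FALSE)
  write.csv(df, csv, row.names = FALSE)
  sidecar <- file.path(dir, paste0(x@blockName, "_dropped.json"))
  jsonlite::write_json(
    list(block = x@blockName, dropped_columns = x@droppedColumns),
    sidecar
  )
  invisible(c(csv, sidecar))
}
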