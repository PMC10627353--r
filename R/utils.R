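#' @importFrom methods new is validObject slot show
#' @importFrom stats cor loess median predict quantile rbinom rnbinom rnorm
#'   runif sd var rpois
#' @importFrom utils read.csv write.csv head capture.output
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assay<- colData
#' @importFrom S4Vectors DataFrame
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' All stochastic operations in the package route their randomness through this
#' helper so that a single integer seed makes a whole run reproducible without
#' clobbering the user's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific child seed from a master seed; keeps every
# consumer of randomness on an independent, reproducible stream while
# staying inside 32-bit integer range.
deriveSeed <- function(seed, salt) {
  s <- (as.double(seed) %% 2147483647) * 48271 + sum(utf8ToInt(as.character(salt)))
  as.integer(s %% 2147483629) + 1L
}

# round half away from zero (used for the 10% entity holdout count)
roundHalfAway <- function(x) floor(x + 0.5)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

asFiniteMatrix <- function(m, what) {
  if (!all(is.finite(m))) stopf("%s contains non-finite values", what)
  m
}
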