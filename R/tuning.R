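# Hyperband hyperparameter search over ForkedModelConfig. Brackets of
# successive halving: bracket s (from s_max = floor(log_eta(R)) down to 0)
# starts n = ceil((s_max+1)/(s+1) * eta^s) sampled configurations at
# r = R * eta^(-s) epochs; each rung keeps the top floor(n_i / eta) by
# validation loss and multiplies the epoch budget by eta.

#' Define a hyperparameter search space
#'
#' Each domain is either a vector of choices (sampled uniformly) or a
#' `list(min, max)` integer range (sampled uniformly inclusive). Defaults
#' bracket the tuned reference configuration.
#'
#' @param useSingleCell,useDropout logical choice vectors.
#' @param hiddenLayerNumber integer range `list(min, max)`.
#' @param hiddenSizeDrugs,hiddenSizeBulk,hiddenSizeSingleCells integer ranges.
#' @param dropoutRate,batchSize,learningRate choice vectors.
#' @return a `SearchSpace` (named list, class `"SearchSpace"`).
#' @export
searchSpace <- function(useSingleCell = c(TRUE, FALSE),
                        hiddenLayerNumber = list(2L, 12L),
                        hiddenSizeDrugs = list(32L, 128L),
                        hiddenSizeBulk = list(32L, 128L),
                        hiddenSizeSingleCells = list(32L, 128L),
                        useDropout = c(TRUE, FALSE),
                        dropoutRate = c(0.1, 0.2, 0.3),
                        batchSize = c(64L, 128L, 256L),
                        learningRate = 0.001) {
  space <- list(
    useSingleCell = useSingleCell,
    hiddenLayerNumber = hiddenLayerNumber,
    hiddenSizeDrugs = hiddenSizeDrugs,
    hiddenSizeBulk = hiddenSizeBulk,
    hiddenSizeSingleCells = hiddenSizeSingleCells,
    useDropout = useDropout,
    dropoutRate = dropoutRate,
    batchSize = batchSize,
    learningRate = learningRate
  )
  if (any(lengths(space) == 0)) stopf("every search-space domain must be non-empty")
  structure(space, class = "SearchSpace")
}

.drawDomain <- function(dom) {
  if (is.list(dom)) {
    choices <- seq.int(dom[[1]], dom[[2]])
    return(choices[sample.int(length(choices), 1L)])
  }
  if (length(dom) == 1L) return(dom)
  dom[sample.int(length(dom), 1L)]
}

#' Sample one configuration uniformly from a search space
#'
#' @param space a [searchSpace()].
#' @param seed integer seed for this draw.
#' @return a [ForkedModelConfig-class].
#' @export
sampleConfig <- function(space, seed = 1L) {
  draw <- withSeed(seed, lapply(unclass(space), .drawDomain))
  forkedModelConfig(
    useSingleCell = draw$useSingleCell,
    hiddenLayerNumber = draw$hiddenLayerNumber,
    hiddenSizeDrugs = draw$hiddenSizeDrugs,
    hiddenSizeBulk = draw$hiddenSizeBulk,
    hiddenSizeSingleCells = draw$hiddenSizeSingleCells,
    useDropout = draw$useDropout,
    dropoutRate = if (draw$useDropout) draw$dropoutRate else 0,
    batchSize = draw$batchSize,
    learningRate = draw$learningRate,
    seed = seed
  )
}

#' The closed-form Hyperband bracket/rung schedule
#'
#' @param R maximum epoch budget per configuration.
#' @param eta halving rate (default 3).
#' @return data.frame with one row per rung: `bracket`, `rung`, `n_configs`,
#'   `epochs`.
#' @export
hyperbandSchedule <- function(R, eta = 3L) {
  if (R < eta) stopf("R must be >= eta")
  sMax <- floor(log(R) / log(eta))
  rows <- list()
  for (s in sMax:0) {
    n <- ceiling((sMax + 1) / (s + 1) * eta^s)
    r <- R * eta^(-s)
    for (i in 0:s) {
      rows[[length(rows) + 1L]] <- data.frame(
        bracket = s, rung = i,
        n_configs = floor(n / eta^i),
        epochs = as.integer(round(r * eta^i))
      )
    }
  }
  do.call(rbind, rows)
}

.configId <- function(cfg) {
  vals <- lapply(
    c(
      "useSingleCell", "hiddenLayerNumber", "hiddenSizeDrugs",
      "hiddenSizeBulk", "hiddenSizeSingleCells", "useDropout", "dropoutRate",
      "l1", "l2", "learningRate", "batchSize", "seed"
    ),
    function(s) format(slot(cfg, s), digits = 15)
  )
  paste(unlist(vals), collapse = "|")
}

# Train one configuration on the bundle for a given epoch budget and return
# its validation MSE. The bundle's test partition is the tuning validation
# set unless an inner validation fold is requested.
.evaluateTrial <- function(cfg, bundle, epochs, innerValFraction = 0) {
  parts <- bundle$partitions
  trainIn <- parts$train$inputs
  trainY <- parts$train$y
  if (!cfg@useSingleCell && "single_cells" %in% names(trainIn)) {
    drop1 <- function(x) x[setdiff(names(x), "single_cells")]
    parts <- lapply(parts, function(p) {
      p$inputs <- drop1(p$inputs)
      p
    })
    trainIn <- parts$train$inputs
  }
  if (innerValFraction > 0) {
    n <- length(trainY)
    nVal <- max(1L, floor(innerValFraction * n))
    valIdx <- withSeed(deriveSeed(cfg@seed, "innerval"), sample.int(n, nVal))
    valIn <- lapply(trainIn, function(m) m[valIdx, , drop = FALSE])
    valY <- trainY[valIdx]
    trainIn <- lapply(trainIn, function(m) m[-valIdx, , drop = FALSE])
    trainY <- trainY[-valIdx]
  } else {
    valIn <- parts$test$inputs
    valY <- parts$test$y
  }
  widths <- vapply(trainIn, ncol, 1L)
  model <- buildForkedModel(cfg, widths)
  fit <- trainForkedModel(model, trainIn, trainY, valIn, valY,
                          maxEpochs = epochs)
  min(fit$history@valLoss)
}

#' Hyperband search over forked-model configurations
#'
#' Runs the standard bracket schedule, recording every (configuration, rung)
#' evaluation; diverged trials are recorded with infinite loss rather than
#' aborting. Re-running with the same seed and a partial trial log skips
#' completed evaluations and reproduces the same result.
#'
#' @param space a [searchSpace()].
#' @param bundle standardized bundle from [standardizeBundle()].
#' @param maxEpochsR maximum epochs per configuration (Hyperband's R).
#' @param eta halving rate (default 3).
#' @param seed master seed; every sampled configuration gets a derived seed.
#' @param innerValFraction if > 0, carve this fraction of the training
#'   partition as the tuning validation fold instead of using the test split.
#' @param trialLog optional data.frame of previous [hyperbandSearch()] trials
#'   to resume from.
#' @return list with `best` (a [ForkedModelConfig-class]), `bestLoss`, and
#'   `trials` (data.frame: config_id, bracket, rung, epochs, val_loss).
#' @export
hyperbandSearch <- function(space, bundle, maxEpochsR, eta = 3L, seed = 1L,
                            innerValFraction = 0, trialLog = NULL) {
  if (!inherits(space, "SearchSpace")) stopf("space must be a searchSpace()")
  sched <- hyperbandSchedule(maxEpochsR, eta)
  brackets <- unique(sched$bracket)
  trials <- list()
  configs <- list()
  lookup <- function(id, bracket, rung) {
    if (is.null(trialLog)) return(NULL)
    hit <- trialLog$config_id == id & trialLog$bracket == bracket &
      trialLog$rung == rung
    if (any(hit)) trialLog$val_loss[which(hit)[1]] else NULL
  }
  drawCounter <- 0L
  for (s in sort(brackets, decreasing = TRUE)) {
    rungs <- sched[sched$bracket == s, , drop = FALSE]
    n0 <- rungs$n_configs[rungs$rung == 0]
    cfgs <- lapply(seq_len(n0), function(i) {
      sampleConfig(space, seed = deriveSeed(seed, sprintf("s%d_c%d", s, i)))
    })
    for (i in seq_len(nrow(rungs))) {
      rung <- rungs$rung[i]
      nKeep <- rungs$n_configs[i]
      epochs <- rungs$epochs[i]
      if (rung > 0) {
        prev <- trials[vapply(trials, function(t) {
          t$bracket == s && t$rung == rung - 1L
        }, TRUE)]
        losses <- vapply(prev, function(t) t$val_loss, 1)
        ord <- order(losses)
        keepIds <- vapply(prev, function(t) t$config_id, "")[ord][seq_len(nKeep)]
        cfgs <- configs[keepIds]
      }
      for (cfg in cfgs) {
        id <- .configId(cfg)
        configs[[id]] <- cfg
        cached <- lookup(id, s, rung)
        loss <- if (!is.null(cached)) {
          cached
        } else {
          tryCatch(
            .evaluateTrial(cfg, bundle, epochs, innerValFraction),
            error = function(e) Inf
          )
        }
        trials[[length(trials) + 1L]] <- list(
          config_id = id, bracket = s, rung = rung,
          epochs = epochs, val_loss = loss
        )
      }
    }
  }
  df <- do.call(rbind, lapply(trials, as.data.frame))
  if (all(!is.finite(df$val_loss))) stopf("all Hyperband trials diverged")
  bestRow <- which.min(df$val_loss)
  list(
    best = configs[[df$config_id[bestRow]]],
    bestLoss = df$val_loss[bestRow],
    trials = df
  )
}
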