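# The forked multi-branch regressor. Each input branch is processed by its own
# fully connected subnetwork (ReLU hidden layers of the branch's width,
# optional dropout after each activation, then an unregularized linear branch
# output of the same width); branch outputs are concatenated and fused by a
# single linear unit (optionally preceded by trunk hidden layers). L1+L2
# penalties apply to the weights, biases and activations of every hidden
# layer; output layers are unpenalized. Training is Adam on MSE with
# early stopping (best-weight restore) and reduce-LR-on-plateau.

.branchWidthFor <- function(cfg, name) {
  switch(name,
    single_cells = cfg@hiddenSizeSingleCells,
    general_descriptors = ,
    taxonomy_features = cfg@hiddenSizeDrugs,
    cfg@hiddenSizeBulk
  )
}

.initLayer <- function(fanIn, fanOut, scale = sqrt(2 / fanIn)) {
  list(
    W = matrix(rnorm(fanIn * fanOut, sd = scale), fanIn, fanOut),
    b = rep(0, fanOut)
  )
}

#' Build an (untrained) forked multi-branch model
#'
#' @param cfg a [ForkedModelConfig-class].
#' @param branchWidths named integer vector of input widths, one per branch.
#'   Branch hidden width follows the name: `general_descriptors` /
#'   `taxonomy_features` use the drug width, `single_cells` the single-cell
#'   width, anything else the bulk width.
#' @return an untrained [ForkedModel-class] with seeded He-initialized
#'   weights.
#' @export
buildForkedModel <- function(cfg, branchWidths) {
  if (length(branchWidths) == 0) stopf("at least one input branch is required")
  if (any(branchWidths < 1)) stopf("branch widths must be >= 1")
  if (is.null(names(branchWidths))) {
    names(branchWidths) <- sprintf("branch%d", seq_along(branchWidths))
  }
  H <- cfg@hiddenLayerNumber
  params <- withSeed(cfg@seed, {
    branches <- lapply(names(branchWidths), function(nm) {
      w <- .branchWidthFor(cfg, nm)
      sizes <- c(branchWidths[[nm]], rep(w, H))
      layers <- lapply(seq_len(H), function(l) .initLayer(sizes[l], sizes[l + 1]))
      out <- .initLayer(w, w, scale = sqrt(1 / w))
      list(hidden = layers, out = out)
    })
    names(branches) <- names(branchWidths)
    concatWidth <- sum(vapply(
      names(branchWidths),
      function(nm) .branchWidthFor(cfg, nm), 1L
    ))
    trunk <- list()
    if (cfg@trunkHidden > 0) {
      trunk <- lapply(seq_len(cfg@trunkHidden), function(l) {
        .initLayer(concatWidth, concatWidth)
      })
    }
    head <- .initLayer(concatWidth, 1L, scale = sqrt(1 / concatWidth))
    list(branches = branches, trunk = trunk, head = head)
  })
  new("ForkedModel",
    config = cfg, branchNames = names(branchWidths),
    branchWidths = as.integer(branchWidths), params = params, trained = FALSE
  )
}

#' Number of trainable (weighted) layers of a forked model
#'
#' Per branch: hidden layers plus the linear branch-output layer; plus any
#' trunk hidden layers and the final linear unit.
#'
#' @param model a [ForkedModel-class].
#' @return integer layer count.
#' @export
layerCount <- function(model) {
  H <- model@config@hiddenLayerNumber
  length(model@branchWidths) * (H + 1L) + length(model@params$trunk) + 1L
}

.checkInputs <- function(model, inputs) {
  if (!identical(names(inputs), model@branchNames)) {
    if (is.null(names(inputs)) &&
        length(inputs) == length(model@branchNames)) {
      names(inputs) <- model@branchNames
    } else {
      stopf(
        "branch names do not match the model (expected %s)",
        paste(model@branchNames, collapse = ", ")
      )
    }
  }
  for (i in seq_along(inputs)) {
    if (ncol(inputs[[i]]) != model@branchWidths[i]) {
      stopf(
        "branch '%s' width mismatch: model expects %d, input has %d",
        model@branchNames[i], model@branchWidths[i], ncol(inputs[[i]])
      )
    }
  }
  inputs
}

# Forward pass. Returns prediction vector plus (optionally) all activations
# needed for backprop, and the dropout masks used (training mode only).
.forward <- function(params, inputs, cfg, training = FALSE) {
  dropout <- training && cfg@useDropout && cfg@dropoutRate > 0
  keep <- 1 - cfg@dropoutRate
  cache <- list(branches = list())
  outs <- vector("list", length(inputs))
  for (bi in seq_along(inputs)) {
    br <- params$branches[[bi]]
    A <- as.matrix(inputs[[bi]])
    acts <- list()
    masks <- list()
    for (l in seq_along(br$hidden)) {
      Z <- A %*% br$hidden[[l]]$W
      Z <- sweep(Z, 2, br$hidden[[l]]$b, `+`)
      A <- relu(Z)
      if (dropout) {
        mask <- matrix(
          rbinom(length(A), 1, keep) / keep,
          nrow(A), ncol(A)
        )
        A <- A * mask
        masks[[l]] <- mask
      }
      acts[[l]] <- A
    }
    O <- sweep(A %*% br$out$W, 2, br$out$b, `+`)
    outs[[bi]] <- O
    cache$branches[[bi]] <- list(input = as.matrix(inputs[[bi]]), acts = acts,
                                 masks = masks, out = O)
  }
  C <- do.call(cbind, outs)
  cache$concat <- C
  A <- C
  cache$trunkActs <- list()
  for (l in seq_along(params$trunk)) {
    Z <- sweep(A %*% params$trunk[[l]]$W, 2, params$trunk[[l]]$b, `+`)
    A <- relu(Z)
    cache$trunkActs[[l]] <- A
  }
  yhat <- drop(sweep(A %*% params$head$W, 2, params$head$b, `+`))
  cache$headIn <- A
  list(yhat = yhat, cache = cache)
}

# Gradient of MSE + regularization wrt all parameters. Activity penalties are
# averaged over the batch so the effective loss is batch-size independent.
.backward <- function(params, cache, yhat, y, cfg) {
  n <- length(y)
  l1 <- cfg@l1
  l2 <- cfg@l2
  grads <- list(branches = vector("list", length(params$branches)),
                trunk = list(), head = NULL)
  dyhat <- matrix(2 * (yhat - y) / n, ncol = 1)
  # head
  A <- cache$headIn
  grads$head <- list(W = crossprod(A, dyhat), b = sum(dyhat))
  dA <- dyhat %*% t(params$head$W)
  # trunk (hidden, regularized)
  for (l in rev(seq_along(params$trunk))) {
    act <- cache$trunkActs[[l]]
    dA <- dA + (l1 * sign(act) + 2 * l2 * act) / n
    dZ <- dA * (act > 0)
    Aprev <- if (l > 1) cache$trunkActs[[l - 1]] else cache$concat
    grads$trunk[[l]] <- list(
      W = crossprod(Aprev, dZ) + l1 * sign(params$trunk[[l]]$W) +
        2 * l2 * params$trunk[[l]]$W,
      b = colSums(dZ) + l1 * sign(params$trunk[[l]]$b) +
        2 * l2 * params$trunk[[l]]$b
    )
    dA <- dZ %*% t(params$trunk[[l]]$W)
  }
  # split concat gradient over branches
  offset <- 0L
  for (bi in seq_along(params$branches)) {
    br <- params$branches[[bi]]
    bc <- cache$branches[[bi]]
    w <- ncol(bc$out)
    dO <- dA[, offset + seq_len(w), drop = FALSE]
    offset <- offset + w
    lastAct <- bc$acts[[length(bc$acts)]]
    gb <- list(hidden = vector("list", length(br$hidden)),
               out = list(W = crossprod(lastAct, dO), b = colSums(dO)))
    dAct <- dO %*% t(br$out$W)
    for (l in rev(seq_along(br$hidden))) {
      act <- bc$acts[[l]]
      dAct <- dAct + (l1 * sign(act) + 2 * l2 * act) / n
      if (length(bc$masks) >= l && !is.null(bc$masks[[l]])) {
        dAct <- dAct * bc$masks[[l]]
      }
      dZ <- dAct * (act > 0)
      Aprev <- if (l > 1) bc$acts[[l - 1]] else bc$input
      gb$hidden[[l]] <- list(
        W = crossprod(Aprev, dZ) + l1 * sign(br$hidden[[l]]$W) +
          2 * l2 * br$hidden[[l]]$W,
        b = colSums(dZ) + l1 * sign(br$hidden[[l]]$b) +
          2 * l2 * br$hidden[[l]]$b
      )
      dAct <- dZ %*% t(br$hidden[[l]]$W)
    }
    grads$branches[[bi]] <- gb
  }
  grads
}

# flatten params/grads into a single list of tensors for the Adam loop
.tensorList <- function(params) {
  out <- list()
  for (bi in seq_along(params$branches)) {
    br <- params$branches[[bi]]
    for (l in seq_along(br$hidden)) {
      out[[sprintf("b%d.h%d.W", bi, l)]] <- br$hidden[[l]]$W
      out[[sprintf("b%d.h%d.b", bi, l)]] <- br$hidden[[l]]$b
    }
    out[[sprintf("b%d.out.W", bi)]] <- br$out$W
    out[[sprintf("b%d.out.b", bi)]] <- br$out$b
  }
  for (l in seq_along(params$trunk)) {
    out[[sprintf("t%d.W", l)]] <- params$trunk[[l]]$W
    out[[sprintf("t%d.b", l)]] <- params$trunk[[l]]$b
  }
  out[["head.W"]] <- params$head$W
  out[["head.b"]] <- params$head$b
  out
}

.fromTensorList <- function(tl, template) {
  params <- template
  for (bi in seq_along(params$branches)) {
    for (l in seq_along(params$branches[[bi]]$hidden)) {
      params$branches[[bi]]$hidden[[l]]$W <- tl[[sprintf("b%d.h%d.W", bi, l)]]
      params$branches[[bi]]$hidden[[l]]$b <- tl[[sprintf("b%d.h%d.b", bi, l)]]
    }
    params$branches[[bi]]$out$W <- tl[[sprintf("b%d.out.W", bi)]]
    params$branches[[bi]]$out$b <- tl[[sprintf("b%d.out.b", bi)]]
  }
  for (l in seq_along(params$trunk)) {
    params$trunk[[l]]$W <- tl[[sprintf("t%d.W", l)]]
    params$trunk[[l]]$b <- tl[[sprintf("t%d.b", l)]]
  }
  params$head$W <- tl[["head.W"]]
  params$head$b <- tl[["head.b"]]
  params
}

.regLoss <- function(params, cfg, nBatch) {
  pen <- 0
  for (br in params$branches) {
    for (l in br$hidden) {
      pen <- pen + cfg@l1 * (sum(abs(l$W)) + sum(abs(l$b))) +
        cfg@l2 * (sum(l$W^2) + sum(l$b^2))
    }
  }
  for (l in params$trunk) {
    pen <- pen + cfg@l1 * (sum(abs(l$W)) + sum(abs(l$b))) +
      cfg@l2 * (sum(l$W^2) + sum(l$b^2))
  }
  pen
}

#' Train a forked model with Adam, early stopping and LR-on-plateau
#'
#' Minimizes MSE (plus L1/L2 penalties) in minibatches. Training halts when
#' validation MSE fails to improve for `earlyStopPatience` epochs; the weights
#' of the best epoch are restored. The learning rate is multiplied by
#' `plateauFactor` after `plateauPatience` non-improving epochs (floored at
#' 1e-6).
#'
#' @param model an untrained (or trained) [ForkedModel-class].
#' @param trainInputs named list of branch matrices (rows = samples).
#' @param trainTargets numeric target vector.
#' @param valInputs,valTargets validation data monitored by the callbacks.
#' @param maxEpochs optional override of the config's epoch budget.
#' @return list with `model` (trained) and `history`
#'   ([TrainingHistory-class]).
#' @export
trainForkedModel <- function(model, trainInputs, trainTargets,
                             valInputs, valTargets, maxEpochs = NULL) {
  cfg <- model@config
  trainInputs <- .checkInputs(model, trainInputs)
  valInputs <- .checkInputs(model, valInputs)
  n <- length(trainTargets)
  stopifnot(all(vapply(trainInputs, nrow, 1L) == n))
  stopifnot(all(vapply(valInputs, nrow, 1L) == length(valTargets)))
  epochs <- if (is.null(maxEpochs)) cfg@maxEpochs else as.integer(maxEpochs)

  params <- model@params
  mState <- lapply(.tensorList(params), function(t) t * 0)
  vState <- mState
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr <- cfg@learningRate

  trainLoss <- valLoss <- lrTrace <- numeric(0)
  best <- Inf
  bestParams <- params
  bestEpoch <- 0L
  sinceBest <- 0L
  sincePlateau <- 0L

  withSeed(deriveSeed(cfg@seed, "train"), {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg@batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg@batchSize - 1L, n)]
        xb <- lapply(trainInputs, function(m) m[idx, , drop = FALSE])
        yb <- trainTargets[idx]
        fw <- .forward(params, xb, cfg, training = TRUE)
        mseb <- mean((fw$yhat - yb)^2)
        if (!is.finite(mseb)) {
          stopf("training diverged (non-finite loss at epoch %d)", epoch)
        }
        epochLoss <- epochLoss + mseb * length(idx)
        grads <- .backward(params, fw$cache, fw$yhat, yb, cfg)
        step <- step + 1L
        tl <- .tensorList(params)
        gl <- .tensorList(grads)
        for (k in names(tl)) {
          mState[[k]] <- beta1 * mState[[k]] + (1 - beta1) * gl[[k]]
          vState[[k]] <- beta2 * vState[[k]] + (1 - beta2) * gl[[k]]^2
          mhat <- mState[[k]] / (1 - beta1^step)
          vhat <- vState[[k]] / (1 - beta2^step)
          tl[[k]] <- tl[[k]] - lr * mhat / (sqrt(vhat) + eps)
        }
        params <- .fromTensorList(tl, params)
      }
      trainLoss[epoch] <- epochLoss / n + .regLoss(params, cfg, n)
      vw <- .forward(params, valInputs, cfg, training = FALSE)
      valLoss[epoch] <- mean((vw$yhat - valTargets)^2)
      lrTrace[epoch] <- lr
      if (!is.finite(valLoss[epoch])) {
        stopf("training diverged (non-finite validation loss at epoch %d)", epoch)
      }
      if (valLoss[epoch] < best) {
        best <- valLoss[epoch]
        bestParams <- params
        bestEpoch <- epoch
        sinceBest <- 0L
        sincePlateau <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        sincePlateau <- sincePlateau + 1L
        if (sincePlateau >= cfg@plateauPatience) {
          lr <- max(lr * cfg@plateauFactor, 1e-6)
          sincePlateau <- 0L
        }
        if (sinceBest >= cfg@earlyStopPatience) break
      }
    }
  })

  model@params <- bestParams
  model@trained <- TRUE
  history <- new("TrainingHistory",
    trainLoss = trainLoss, valLoss = valLoss, learningRate = lrTrace,
    stoppedEpoch = length(valLoss), bestEpoch = bestEpoch
  )
  list(model = model, history = history)
}

#' Predict ln(IC50) for assembled branch inputs
#'
#' Deterministic forward pass (dropout inactive).
#'
#' @param object a trained [ForkedModel-class].
#' @param inputs named list of branch matrices.
#' @return numeric prediction vector, one value per row.
#' @export
setMethod("predict", "ForkedModel", function(object, inputs) {
  inputs <- .checkInputs(object, inputs)
  .forward(object@params, inputs, object@config, training = FALSE)$yhat
})

#' Concatenated per-branch output vectors (pre-fusion inspection)
#'
#' Exposes the linear branch outputs before the fusion head; column ranges per
#' branch are attached as attribute `"branch_columns"`. Useful for verifying
#' branch isolation: perturbing features of one branch can only change that
#' branch's slots.
#'
#' @param model a [ForkedModel-class].
#' @param inputs named list of branch matrices.
#' @return samples x (sum of branch widths) matrix.
#' @export
branchOutputs <- function(model, inputs) {
  inputs <- .checkInputs(model, inputs)
  fw <- .forward(model@params, inputs, model@config, training = FALSE)
  C <- fw$cache$concat
  widths <- vapply(fw$cache$branches, function(b) ncol(b$out), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  attr(C, "branch_columns") <- stats::setNames(
    lapply(seq_along(widths), function(i) starts[i]:ends[i]),
    model@branchNames
  )
  C
}

#' Save / load a forked model directory
#'
#' The directory holds the weights (RDS), the config and branch manifest
#' (JSON) and an integrity manifest with an MD5 of the weights blob; loading
#' verifies the format version and the checksum, and a round trip preserves
#' predictions bit-for-bit.
#'
#' @param model a [ForkedModel-class].
#' @param path directory to create/overwrite.
#' @return invisibly, `path`.
#' @export
saveForkedModel <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  weightsPath <- file.path(path, "weights.rds")
  saveRDS(model@params, weightsPath, version = 2)
  cfg <- model@config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  jsonlite::write_json(
    cfgList, file.path(path, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest <- list(
    format_version = 1L,
    weights_md5 = unname(tools::md5sum(weightsPath)),
    branch_names = model@branchNames,
    branch_widths = model@branchWidths,
    trained = model@trained
  )
  jsonlite::write_json(
    manifest, file.path(path, "manifest.json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname saveForkedModel
#' @export
loadForkedModel <- function(path) {
  manifestPath <- file.path(path, "manifest.json")
  if (!file.exists(manifestPath)) stopf("no model manifest at %s", path)
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$format_version), 1L)) {
    stopf("unsupported model format version: %s", manifest$format_version)
  }
  weightsPath <- file.path(path, "weights.rds")
  md5 <- unname(tools::md5sum(weightsPath))
  if (!identical(md5, manifest$weights_md5)) {
    stopf("model integrity check failed: weights do not match the manifest")
  }
  cfgList <- jsonlite::read_json(file.path(path, "config.json"),
                                 simplifyVector = TRUE)
  cfg <- forkedModelConfig(
    useSingleCell = cfgList$useSingleCell,
    hiddenLayerNumber = cfgList$hiddenLayerNumber,
    hiddenSizeDrugs = cfgList$hiddenSizeDrugs,
    hiddenSizeBulk = cfgList$hiddenSizeBulk,
    hiddenSizeSingleCells = cfgList$hiddenSizeSingleCells,
    trunkHidden = cfgList$trunkHidden,
    useDropout = cfgList$useDropout, dropoutRate = cfgList$dropoutRate,
    l1 = cfgList$l1, l2 = cfgList$l2,
    learningRate = cfgList$learningRate, batchSize = cfgList$batchSize,
    maxEpochs = cfgList$maxEpochs,
    earlyStopPatience = cfgList$earlyStopPatience,
    plateauFactor = cfgList$plateauFactor,
    plateauPatience = cfgList$plateauPatience,
    seed = cfgList$seed
  )
  params <- readRDS(weightsPath)
  new("ForkedModel",
    config = cfg, branchNames = manifest$branch_names,
    branchWidths = as.integer(manifest$branch_widths),
    params = params, trained = isTRUE(manifest$trained)
  )
}
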