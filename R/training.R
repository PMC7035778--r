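# Training: feed-forward regression head on the molecule latent, masked MSE
# for multi-target data with per-row missingness, Adam with a warm-up /
# exponential-decay learning rate schedule, z-score target normalisation on
# training statistics, and best-checkpoint selection by validation RMSE.

#' Training configuration
#'
#' @param epochs number of passes over the training partition.
#' @param batchSize molecules per gradient step.
#' @param warmupEpochs epochs of linear learning rate warm-up.
#' @param initLR,maxLR,finalLR learning rate at step 0, at the end of
#'   warm-up, and at the last step (exponential decay in between).
#' @param normalize z-score targets on training statistics (metrics are
#'   always reported on the original scale).
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 30L, batchSize = 50L, warmupEpochs = 2,
                        initLR = 5e-4, maxLR = 5e-3, finalLR = 5e-4,
                        normalize = TRUE) {
  stopifnot(epochs >= 1, batchSize >= 1, initLR > 0, maxLR > 0, finalLR > 0)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 warmupEpochs = warmupEpochs, initLR = initLR, maxLR = maxLR,
                 finalLR = finalLR, normalize = isTRUE(normalize)),
            class = "TrainConfig")
}

#' Learning rate schedule
#'
#' Linear warm-up from `initLR` to `maxLR` over the warm-up span, then
#' exponential decay reaching `finalLR` at the last step.
#'
#' @param step 0-based global step.
#' @param config a [trainConfig()].
#' @param stepsPerEpoch gradient steps per epoch (sets the warm-up span and
#'   total step count).
#' @return learning rate (a positive real).
#' @export
lrSchedule <- function(step, config, stepsPerEpoch = 1L) {
  total <- config$epochs * stepsPerEpoch
  warm <- config$warmupEpochs * stepsPerEpoch
  if (step <= warm && warm > 0)
    return(config$initLR + (config$maxLR - config$initLR) * step / warm)
  if (warm >= total) return(config$maxLR)
  config$maxLR * (config$finalLR / config$maxLR)^((step - warm) / (total - warm))
}

#' Masked mean squared error
#'
#' MSE over unmasked entries only; returns 0 when everything is masked (no
#' signal, no contribution).
#'
#' @param pred,target numeric vectors or matrices of equal shape.
#' @param mask logical, TRUE where the target is observed.
#' @return nonnegative scalar.
#' @examples
#' maskedMseLoss(c(1, 2), c(1.5, 9.9), c(TRUE, FALSE))  # 0.25
#' @export
maskedMseLoss <- function(pred, target, mask) {
  stopifnot(length(pred) == length(target), length(pred) == length(mask))
  k <- sum(mask)
  if (k == 0) return(0)
  sum(((pred - target)[mask])^2) / k
}

#' Regression metrics
#'
#' MAE, MSE, RMSE, coefficient of determination (R2, computed against the
#' mean of the observed values) and Pearson correlation (PC).
#'
#' @param pred predicted values.
#' @param obs observed values (same length; pairs with `NA` are dropped).
#' @return a [MetricsReport-class].
#' @examples
#' computeMetrics(c(2, 3, 4), c(1, 2, 3))  # MAE 1, RMSE 1, R2 -0.5, PC 1
#' @export
computeMetrics <- function(pred, obs) {
  keep <- !(is.na(pred) | is.na(obs))
  pred <- pred[keep]; obs <- obs[keep]
  n <- length(pred)
  stopifnot(n >= 1)
  err <- pred - obs
  mse <- mean(err^2)
  ssTot <- sum((obs - mean(obs))^2)
  r2 <- if (n >= 2 && ssTot > 0) 1 - sum(err^2) / ssTot else NA_real_
  pc <- NA_real_
  if (n >= 2) {
    if (sd(pred) == 0 || sd(obs) == 0) {
      warning("zero variance: Pearson correlation undefined")
    } else {
      pc <- cor(pred, obs)
    }
  }
  new("MetricsReport", MAE = mean(abs(err)), MSE = mse, RMSE = sqrt(mse),
      R2 = r2, PC = pc, n = as.integer(n))
}

# --- head ----------------------------------------------------------------

# Feed-forward head: ffnLayers - 1 hidden layers of width `hiddenSize`, then
# a linear K-output layer. Output-layer rows are initialised per unit
# (fan-out 1, filled row-by-row) so that a K-target head nests the K = 1
# head: the first output starts from identical weights regardless of K.
.headInit <- function(inputSize, hiddenSize, K, ffnLayers) {
  layers <- list()
  nin <- inputSize
  if (ffnLayers > 1) {
    for (l in seq_len(ffnLayers - 1)) {
      layers[[l]] <- list(W = .xavier(hiddenSize, nin, byrow = TRUE),
                          b = numeric(hiddenSize))
      nin <- hiddenSize
    }
  }
  bound <- sqrt(6 / (nin + 1))
  Wout <- matrix(runif(K * nin, -bound, bound), K, nin, byrow = TRUE)
  layers[[ffnLayers]] <- list(W = Wout, b = numeric(K))
  layers
}

.headForward <- function(latents, head, activation, dropout = 0,
                         training = FALSE, keepCache = FALSE) {
  act <- .activation(activation)
  L <- length(head)
  A <- latents
  As <- list(A); Zs <- list(); masks <- list()
  if (L > 1) {
    for (l in seq_len(L - 1)) {
      Z <- tcrossprod(A, head[[l]]$W)
      Z <- sweep(Z, 2, head[[l]]$b, "+")
      A <- act$f(Z)
      if (training && dropout > 0) {
        masks[[l]] <- .dropoutMask(nrow(A), ncol(A), dropout)
        A <- A * masks[[l]]
      }
      Zs[[l]] <- Z; As[[l + 1]] <- A
    }
  }
  pred <- sweep(tcrossprod(A, head[[L]]$W), 2, head[[L]]$b, "+")
  if (!keepCache) return(list(pred = pred))
  list(pred = pred, As = As, Zs = Zs, masks = masks)
}

.headBackward <- function(cache, dPred, head, activation) {
  act <- .activation(activation)
  L <- length(head)
  grads <- vector("list", L)
  A <- cache$As[[L]]
  grads[[L]] <- list(W = crossprod(dPred, A), b = colSums(dPred))
  dA <- dPred %*% head[[L]]$W
  if (L > 1) {
    for (l in rev(seq_len(L - 1))) {
      if (length(cache$masks) >= l && !is.null(cache$masks[[l]]))
        dA <- dA * cache$masks[[l]]
      dZ <- dA * act$df(cache$Zs[[l]])
      grads[[l]] <- list(W = crossprod(dZ, cache$As[[l]]), b = colSums(dZ))
      dA <- dZ %*% head[[l]]$W
    }
  }
  list(grads = grads, dLatents = dA)
}

# --- normalisation -------------------------------------------------------

.normStats <- function(targets) {
  mean <- apply(targets, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else 0
  })
  sd <- apply(targets, 2, function(v) {
    v <- v[!is.na(v)]
    s <- if (length(v) >= 2) sd(v) else 0
    if (is.na(s) || s == 0) 1 else s
  })
  list(mean = mean, sd = sd)
}

.normalizeTargets <- function(targets, norm) {
  sweep(sweep(targets, 2, norm$mean, "-"), 2, norm$sd, "/")
}

.denormalize <- function(pred, norm) {
  sweep(sweep(pred, 2, norm$sd, "*"), 2, norm$mean, "+")
}

# --- batching helpers ----------------------------------------------------

# Lightweight batch assembly (same layout as BatchedMolGraph, no S4 cost).
.batchPieces <- function(graphs) {
  nA <- vapply(graphs, nAtoms, integer(1))
  nE <- vapply(graphs, nEdges, integer(1))
  offA <- cumsum(c(0L, nA[-length(nA)]))
  offE <- cumsum(c(0L, nE[-length(nE)]))
  src <- integer(sum(nE)); tgt <- integer(sum(nE)); rev <- integer(sum(nE))
  for (m in seq_along(graphs)) {
    idx <- seq_len(nE[m]) + offE[m]
    src[idx] <- graphs[[m]]@edgeSource + offA[m]
    tgt[idx] <- graphs[[m]]@edgeTarget + offA[m]
    rev[idx] <- graphs[[m]]@edge2rev + offE[m]
  }
  list(af = do.call(rbind, lapply(graphs, atomFeatures)),
       ef = do.call(rbind, lapply(graphs, edgeFeatures)),
       src = src, tgt = tgt, rev = rev,
       mol = rep(seq_along(graphs), nA))
}

.flattenParams <- function(encoder, head) {
  out <- encoder[c("Winp", "Wh", "Wo", "Wah")]
  for (l in seq_along(head)) {
    out[[paste0("headW", l)]] <- head[[l]]$W
    out[[paste0("headb", l)]] <- head[[l]]$b
  }
  out
}

.unflattenHead <- function(flat, L) {
  lapply(seq_len(L), function(l)
    list(W = flat[[paste0("headW", l)]], b = flat[[paste0("headb", l)]]))
}

# Full model forward on a list of graphs (evaluation mode).
.modelForward <- function(graphs, encoder, head, hyper) {
  pieces <- .batchPieces(graphs)
  params <- encoderParams(hyper$hiddenSize, hyper$depth, hyper$activation,
                          Winp = encoder$Winp, Wh = encoder$Wh,
                          Wo = encoder$Wo, Wah = encoder$Wah)
  G <- .encoderForward(pieces, params)$G
  att <- .attentionForward(G, pieces$mol, attention = hyper$attention)
  .headForward(att$latents, head, hyper$activation)$pred
}

# --- fit -----------------------------------------------------------------

#' Fit a (self-attention) message passing regression model
#'
#' Trains the directed-edge message passing encoder, the self-attention
#' readout (or plain average pooling for the MPN ablation) and the
#' feed-forward head end to end with Adam, a masked MSE loss on z-scored
#' targets, and a warm-up/decay learning rate schedule. The checkpoint with
#' the best validation RMSE is retained.
#'
#' @param data data.frame with a `smiles` column and numeric target
#'   column(s); `NA` marks an unobserved target (masked out of the loss).
#' @param targetColumns names of the target columns; default: all
#'   non-`smiles` columns. Length K > 1 trains a multi-target model that
#'   predicts all properties in one forward pass.
#' @param trainIdx,valIdx row indices of the training and validation
#'   partitions (both nonempty).
#' @param hiddenSize,depth,activation encoder hyperparameters (graph
#'   embedding size, message passing steps, nonlinearity).
#' @param ffnLayers layers of the fully connected head (1-3).
#' @param dropout dropout rate applied to messages and head activations
#'   during training.
#' @param attention `TRUE` for the self-attention readout (SAMPN);
#'   `FALSE` for plain average pooling of G (the MPN ablation).
#' @param config a [trainConfig()].
#' @param seed integer seed; fixes initialisation, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return a [SampnModel-class] with the best-validation weights and a
#'   per-epoch history.
#' @export
sampnFit <- function(data, targetColumns = NULL, trainIdx, valIdx,
                     hiddenSize = 64L, depth = 3L, activation = "ReLU",
                     ffnLayers = 2L, dropout = 0, attention = TRUE,
                     config = trainConfig(), seed = 1L, verbose = FALSE) {
  stopifnot(is.data.frame(data), "smiles" %in% names(data))
  if (is.null(targetColumns)) targetColumns <- setdiff(names(data), "smiles")
  stopifnot(length(targetColumns) >= 1)
  if (length(trainIdx) == 0 || length(valIdx) == 0)
    stop("training and validation partitions must both be nonempty")
  K <- length(targetColumns)
  targets <- as.matrix(data[, targetColumns, drop = FALSE])
  graphs <- lapply(data$smiles, molToGraph)

  norm <- if (config$normalize) .normStats(targets[trainIdx, , drop = FALSE])
          else list(mean = rep(0, K), sd = rep(1, K))
  tN <- .normalizeTargets(targets, norm)

  hyper <- list(hiddenSize = as.integer(hiddenSize), depth = as.integer(depth),
                activation = activation, ffnLayers = as.integer(ffnLayers),
                dropout = dropout, attention = isTRUE(attention),
                batchSize = config$batchSize, epochs = config$epochs)

  set.seed(seed)
  encParams <- encoderParams(hiddenSize, depth, activation)
  head <- .headInit(hiddenSize, hiddenSize, K, ffnLayers)
  flat <- .flattenParams(encParams, head)
  adam <- .adamInit(flat)

  stepsPerEpoch <- max(1L, ceiling(length(trainIdx) / config$batchSize))
  globalStep <- 0L
  best <- list(rmse = Inf, flat = flat)
  history <- data.frame()

  for (epoch in seq_len(config$epochs)) {
    set.seed((seed + 7919L * epoch) %% .Machine$integer.max)
    order <- sample(trainIdx)
    sqSum <- 0; nObs <- 0
    for (b in seq_len(stepsPerEpoch)) {
      idx <- order[seq((b - 1L) * config$batchSize + 1L,
                       min(b * config$batchSize, length(order)))]
      idx <- idx[!is.na(idx)]
      if (!length(idx)) next
      pieces <- .batchPieces(graphs[idx])
      encP <- encoderParams(hiddenSize, depth, activation,
                            Winp = flat$Winp, Wh = flat$Wh,
                            Wo = flat$Wo, Wah = flat$Wah)
      encCache <- .encoderForward(pieces, encP, keepCache = TRUE,
                                  dropout = dropout, training = TRUE)
      att <- .attentionForward(encCache$G, pieces$mol,
                               attention = hyper$attention, keepCache = TRUE)
      headL <- .unflattenHead(flat, ffnLayers)
      hc <- .headForward(att$latents, headL, activation, dropout,
                         training = TRUE, keepCache = TRUE)
      tb <- tN[idx, , drop = FALSE]
      mask <- !is.na(tb)
      kUnmasked <- sum(mask)
      if (kUnmasked == 0) next
      resid <- hc$pred - tb
      resid[!mask] <- 0
      sqSum <- sqSum + sum(resid^2); nObs <- nObs + kUnmasked
      dPred <- 2 * resid / kUnmasked
      hb <- .headBackward(hc, dPred, headL, activation)
      dG <- .attentionBackward(encCache$G, att, hb$dLatents,
                               attention = hyper$attention)
      encGrads <- .encoderBackward(encCache, dG, encP)
      grads <- encGrads
      for (l in seq_len(ffnLayers)) {
        grads[[paste0("headW", l)]] <- hb$grads[[l]]$W
        grads[[paste0("headb", l)]] <- hb$grads[[l]]$b
      }
      lr <- lrSchedule(globalStep, config, stepsPerEpoch)
      upd <- .adamStep(flat, grads, adam, lr, globalStep + 1L)
      flat <- upd$params; adam <- upd$state
      globalStep <- globalStep + 1L
    }
    trainLoss <- if (nObs > 0) sqSum / nObs else NA_real_

    valPred <- .denormalize(
      .modelForward(graphs[valIdx], flat, .unflattenHead(flat, ffnLayers), hyper),
      norm)
    valObs <- targets[valIdx, , drop = FALSE]
    keep <- !is.na(valObs)
    valRmse <- sqrt(mean((valPred[keep] - valObs[keep])^2))
    if (valRmse < best$rmse) best <- list(rmse = valRmse, flat = flat)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = trainLoss, val_rmse = valRmse,
      lr = lrSchedule(globalStep, config, stepsPerEpoch)))
    if (verbose)
      message(sprintf("epoch %d: train loss %.5f, val RMSE %.4f",
                      epoch, trainLoss, valRmse))
  }

  new("SampnModel",
      encoder = best$flat[c("Winp", "Wh", "Wo", "Wah")],
      head = .unflattenHead(best$flat, ffnLayers),
      hyper = hyper, norm = norm, targets = targetColumns,
      history = history)
}

#' Predict molecular properties with a fitted model
#'
#' @param object a [SampnModel-class].
#' @param newdata SMILES character vector, a data.frame with a `smiles`
#'   column, or a list of [MolGraph-class] objects.
#' @param ... unused.
#' @return numeric matrix, one row per molecule and one column per target,
#'   on the original property scale.
#' @export
setMethod("predict", "SampnModel", function(object, newdata, ...) {
  graphs <-
    if (is.character(newdata)) lapply(newdata, molToGraph)
    else if (is.data.frame(newdata)) lapply(newdata$smiles, molToGraph)
    else if (is.list(newdata)) newdata
    else stop("newdata must be SMILES, a data.frame, or a list of MolGraphs")
  pred <- .denormalize(
    .modelForward(graphs, object@encoder, object@head, object@hyper),
    object@norm)
  colnames(pred) <- object@targets
  pred
})

#' Per-atom attention coefficients under a fitted model
#'
#' Encodes the molecule with the model's weights and returns the attention
#' coefficients (atom weight score minus molecular mean), ready for heatmap
#' rendering or CSV export.
#'
#' @param model a [SampnModel-class] trained with `attention = TRUE`.
#' @param smiles a single SMILES string.
#' @param aggregate `"column"` (attention received, default) or `"row"`.
#' @return data.frame with `atom` (index), `element`, `coefficient`.
#' @export
atomAttention <- function(model, smiles, aggregate = c("column", "row")) {
  stopifnot(is(model, "SampnModel"))
  if (!isTRUE(model@hyper$attention))
    warning("model was trained without self-attention; ",
            "coefficients reflect an untrained attention readout")
  aggregate <- match.arg(aggregate)
  graph <- molToGraph(smiles)
  params <- encoderParams(model@hyper$hiddenSize, model@hyper$depth,
                          model@hyper$activation,
                          Winp = model@encoder$Winp, Wh = model@encoder$Wh,
                          Wo = model@encoder$Wo, Wah = model@encoder$Wah)
  res <- attendGraph(graph, params, aggregate)
  data.frame(atom = seq_len(nAtoms(graph)), element = graph@elements,
             coefficient = res$coefficients, stringsAsFactors = FALSE)
}

#' Save / load a fitted model
#'
#' The checkpoint holds the weights, hyperparameters, normalisation
#' constants and training history.
#'
#' @param model a [SampnModel-class].
#' @param path file path for the checkpoint.
#' @return `readSampnModel` returns the restored [SampnModel-class].
#' @export
saveSampnModel <- function(model, path) {
  stopifnot(is(model, "SampnModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveSampnModel
#' @export
readSampnModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "SampnModel"))
  model
}
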