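# Model evaluation protocol: stratified k-fold cross-validation for a
# continuous target (quantile-binned), repeated with independent seeds; grid
# search over the hyperparameter lattice ranked by validation RMSE; and an
# ECFP-1024 / 500-tree random forest as the classical baseline.

#' Stratified k-fold train/validation/test split
#'
#' Records are binned into `bins` quantile bins of the (first observed)
#' target; each bin is shuffled and divided into `k` near-equal chunks. In
#' fold `f`, chunk `f` is the test partition, the cyclically next chunk is
#' the validation partition, and the rest train — giving ~80/10/10 for
#' `k = 10` with every record appearing in the test partition of exactly one
#' fold. Deterministic given the seed.
#'
#' @param data data.frame with `smiles` and target column(s).
#' @param targetColumn column used for stratification (default: first
#'   non-`smiles` column; rows missing it are binned by their available
#'   targets' mean).
#' @param k number of folds (>= 2).
#' @param seed RNG seed for the per-bin shuffles.
#' @param bins number of quantile strata.
#' @return a [SplitPlan-class].
#' @export
stratifiedSplit <- function(data, targetColumn = NULL, k = 10L, seed = 1L,
                            bins = 10L) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  k <- as.integer(k)
  if (k < 2L || n < k) stop("need k >= 2 and at least k records")
  if (is.null(targetColumn))
    targetColumn <- setdiff(names(data), "smiles")[1]
  y <- data[[targetColumn]]
  if (anyNA(y)) {
    other <- as.matrix(data[, setdiff(names(data), "smiles"), drop = FALSE])
    y[is.na(y)] <- rowMeans(other, na.rm = TRUE)[is.na(y)]
  }
  bins <- max(1L, min(as.integer(bins), n %/% k))
  edges <- unique(quantile(y, probs = seq(0, 1, length.out = bins + 1L),
                           na.rm = TRUE))
  strata <- if (length(edges) > 2)
    cut(y, breaks = edges, include.lowest = TRUE, labels = FALSE)
  else rep(1L, n)
  strata[is.na(strata)] <- 1L

  set.seed(as.integer(seed))
  assignments <- matrix("train", n, k)
  for (s in unique(strata)) {
    rows <- sample(which(strata == s))
    b <- length(rows)
    # k near-equal chunks (sizes differ by at most 1)
    sizes <- rep(b %/% k, k)
    if (b %% k) sizes[seq_len(b %% k)] <- sizes[seq_len(b %% k)] + 1L
    chunk <- rep(seq_len(k), sizes)
    for (f in seq_len(k)) {
      testRows <- rows[chunk == f]
      valRows <- rows[chunk == (f %% k) + 1L]
      assignments[testRows, f] <- "test"
      assignments[valRows, f] <- "validation"
    }
  }
  new("SplitPlan", assignments = assignments, k = k,
      seed = as.integer(seed), bins = as.integer(bins))
}

#' Partition indices of one fold
#'
#' @param plan a [SplitPlan-class].
#' @param fold fold number in `1..k`.
#' @return list with integer vectors `train`, `validation`, `test`.
#' @export
foldIndices <- function(plan, fold) {
  stopifnot(is(plan, "SplitPlan"), fold >= 1, fold <= plan@k)
  a <- plan@assignments[, fold]
  list(train = which(a == "train"),
       validation = which(a == "validation"),
       test = which(a == "test"))
}

#' Hyperparameter grid
#'
#' The search lattice: activation in \{Tanh, ELU, LeakyReLU, ReLU, PReLU,
#' SELU\}, message passing depth 2-6 (step 1), hidden size 32-512 (step 32),
#' dropout 0.0-0.4 (step 0.05), fully connected layers 1-3 (step 1).
#'
#' @param activation,depth,hiddenSize,dropout,ffnLayers optional overrides
#'   of each axis.
#' @return list of class `GridSpace`.
#' @export
gridSpace <- function(activation = .ACTIVATIONS,
                      depth = 2:6,
                      hiddenSize = seq(32L, 512L, by = 32L),
                      dropout = seq(0, 0.4, by = 0.05),
                      ffnLayers = 1:3) {
  structure(list(activation = activation, depth = depth,
                 hiddenSize = hiddenSize, dropout = dropout,
                 ffnLayers = ffnLayers),
            class = "GridSpace")
}

#' Grid search over the hyperparameter lattice
#'
#' Samples `budget` distinct points from the grid (or enumerates all of them
#' when `budget` covers the lattice), evaluates each with `evaluator`, and
#' returns the point with the lowest validation RMSE together with the full
#' trial table.
#'
#' @param data data.frame passed to the evaluator.
#' @param space a [gridSpace()].
#' @param budget number of points to evaluate.
#' @param seed RNG seed for sampling the lattice.
#' @param evaluator `function(data, point)` returning a validation RMSE;
#'   the default trains a SAMPN model on an internal 80/10/10 split with
#'   `...` passed to [sampnFit()]'s [trainConfig()].
#' @param ... extra arguments for the default evaluator (`epochs`,
#'   `batchSize`, `targetColumn`).
#' @return list with `best` (named list of hyperparameters + `rmse`) and
#'   `trials` (data.frame, one row per evaluated point).
#' @export
gridSearch <- function(data, space = gridSpace(), budget = 10L, seed = 1L,
                       evaluator = NULL, ...) {
  stopifnot(inherits(space, "GridSpace"), budget >= 1)
  lattice <- expand.grid(activation = space$activation,
                         depth = space$depth,
                         hiddenSize = space$hiddenSize,
                         dropout = space$dropout,
                         ffnLayers = space$ffnLayers,
                         stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  take <- min(as.integer(budget), nrow(lattice))
  pts <- lattice[sample(nrow(lattice), take), , drop = FALSE]
  if (is.null(evaluator)) evaluator <- .defaultEvaluator(seed, ...)
  rmse <- numeric(take)
  for (i in seq_len(take)) {
    point <- as.list(pts[i, ])
    rmse[i] <- evaluator(data, point)
  }
  trials <- cbind(pts, rmse = rmse)
  rownames(trials) <- NULL
  bestRow <- which.min(rmse)
  best <- c(as.list(pts[bestRow, ]), list(rmse = rmse[bestRow]))
  list(best = best, trials = trials)
}

.defaultEvaluator <- function(seed, epochs = 10L, batchSize = 50L,
                              targetColumn = NULL) {
  function(data, point) {
    tc <- if (is.null(targetColumn)) setdiff(names(data), "smiles")[1]
          else targetColumn
    plan <- stratifiedSplit(data, tc, k = 10L, seed = seed)
    f <- foldIndices(plan, 1L)
    model <- sampnFit(data, tc, f$train, f$validation,
                      hiddenSize = point$hiddenSize, depth = point$depth,
                      activation = point$activation,
                      ffnLayers = point$ffnLayers, dropout = point$dropout,
                      config = trainConfig(epochs = epochs,
                                           batchSize = batchSize),
                      seed = seed)
    min(model@history$val_rmse)
  }
}

# --- ECFP / random forest baseline --------------------------------------

# Deterministic 31-bit integer hash of an integer vector.
.hashInts <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Circular (Morgan-style) hashed fingerprint
#'
#' Extended-connectivity fingerprint over the heavy-atom graph: initial atom
#' identifiers hash the atom invariants (atomic number, degree, formal
#' charge, aromaticity, ring membership), then `radius` rounds of
#' neighbourhood hashing (sorted (bond type, neighbour id) pairs); every
#' identifier from every round folds into a fixed-length bit vector.
#'
#' @param smiles character vector of SMILES.
#' @param nbits fingerprint length (default 1024).
#' @param radius number of neighbourhood expansion rounds (default 2,
#'   the ECFP4-equivalent).
#' @return 0/1 integer matrix, one row per molecule, `nbits` columns.
#' @export
ecfpFingerprint <- function(smiles, nbits = 1024L, radius = 2L) {
  nbits <- as.integer(nbits)
  fps <- matrix(0L, length(smiles), nbits)
  for (m in seq_along(smiles)) {
    p <- .parseSmiles(smiles[m])
    if (is.null(p)) stop("unparseable SMILES: ", smiles[m])
    n <- length(p$elements)
    ringAtoms <- rep(FALSE, n)
    ra <- unique(c(p$bonds$from[p$bonds$ring], p$bonds$to[p$bonds$ring]))
    ringAtoms[ra] <- TRUE
    ids <- vapply(seq_len(n), function(i) .hashInts(c(
      .atomicNumber(p$elements[i]), p$degree[i], p$charge[i],
      as.integer(p$aromatic[i]), as.integer(ringAtoms[i]))), integer(1))
    bondOrder <- match(p$bonds$order, .BOND_ORDER)
    nb <- vector("list", n)
    for (b in seq_along(p$bonds$from)) {
      i <- p$bonds$from[b]; j <- p$bonds$to[b]
      nb[[i]] <- rbind(nb[[i]], c(bondOrder[b], j))
      nb[[j]] <- rbind(nb[[j]], c(bondOrder[b], i))
    }
    all <- ids
    r <- 1L
    while (r <= radius) {
      ids <- vapply(seq_len(n), function(i) {
        if (is.null(nb[[i]])) return(.hashInts(c(r, ids[i])))
        pairs <- cbind(nb[[i]][, 1], ids[nb[[i]][, 2]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        .hashInts(c(r, ids[i], as.integer(t(pairs))))
      }, integer(1))
      all <- c(all, ids)
      r <- r + 1L
    }
    fps[m, (all %% nbits) + 1L] <- 1L
  }
  fps
}

#' ECFP / random forest baseline over a split plan
#'
#' For each fold, fits a 500-tree random forest on ECFP-1024 fingerprints of
#' the training+validation molecules and evaluates on the test partition
#' with the same metrics as the network models.
#'
#' @param data data.frame with `smiles` and the target column.
#' @param plan a [SplitPlan-class] for `data`.
#' @param targetColumn target to model (default: first non-`smiles` column).
#' @param seed RNG seed (forest growth).
#' @param ntree number of trees (default 500).
#' @param folds fold subset to run (default: all).
#' @return named list of [MetricsReport-class], one per fold.
#' @export
rfBaseline <- function(data, plan, targetColumn = NULL, seed = 1L,
                       ntree = 500L, folds = seq_len(plan@k)) {
  stopifnot(is(plan, "SplitPlan"), nrow(plan@assignments) == nrow(data))
  if (is.null(targetColumn))
    targetColumn <- setdiff(names(data), "smiles")[1]
  y <- data[[targetColumn]]
  fp <- ecfpFingerprint(data$smiles)
  out <- list()
  for (f in folds) {
    idx <- foldIndices(plan, f)
    fit <- c(idx$train, idx$validation)
    fit <- fit[!is.na(y[fit])]
    test <- idx$test[!is.na(y[idx$test])]
    set.seed(as.integer(seed) + f)
    forest <- randomForest::randomForest(fp[fit, , drop = FALSE], y[fit],
                                         ntree = as.integer(ntree))
    pred <- predict(forest, fp[test, , drop = FALSE])
    out[[paste0("fold", f)]] <- computeMetrics(pred, y[test])
  }
  out
}

# --- benchmark -----------------------------------------------------------

.MODEL_KINDS <- c("rf", "mpn", "sampn", "multi_mpn", "multi_sampn")

#' Cross-validated model benchmark
#'
#' Runs the requested models over `repeats` independent stratified
#' cross-validation plans (one seed each) and aggregates per-model test
#' metrics as mean +/- standard deviation. The `mpn` variants are the
#' ablation: identical configuration with the self-attention readout
#' replaced by plain average pooling of G; the `multi_*` variants predict
#' all target columns in one forward pass.
#'
#' @param data data.frame with `smiles` and target column(s).
#' @param models subset of `c("rf", "mpn", "sampn", "multi_mpn",
#'   "multi_sampn")`.
#' @param targetColumn the single-target/stratification column (default:
#'   first non-`smiles` column); multi-target models use all columns.
#' @param k folds per plan.
#' @param repeats number of re-splits.
#' @param seeds one seed per repeat (default `1:repeats`).
#' @param folds fold subset within each plan (default: all `k`).
#' @param hiddenSize,depth,activation,ffnLayers,dropout,config network
#'   hyperparameters shared by all network models.
#' @param verbose print progress.
#' @return list with `summary` (data.frame: model, metric means and sds,
#'   number of evaluations) and `details` (per-evaluation data.frame).
#' @export
runBenchmark <- function(data, models = c("rf", "mpn", "sampn"),
                         targetColumn = NULL, k = 10L, repeats = 3L,
                         seeds = seq_len(repeats), folds = seq_len(k),
                         hiddenSize = 64L, depth = 3L, activation = "ReLU",
                         ffnLayers = 2L, dropout = 0,
                         config = trainConfig(epochs = 20L), verbose = FALSE) {
  models <- match.arg(models, .MODEL_KINDS, several.ok = TRUE)
  stopifnot(length(seeds) == repeats)
  if (is.null(targetColumn))
    targetColumn <- setdiff(names(data), "smiles")[1]
  allTargets <- setdiff(names(data), "smiles")
  details <- data.frame()
  for (r in seq_len(repeats)) {
    plan <- stratifiedSplit(data, targetColumn, k = k, seed = seeds[r])
    for (f in folds) {
      idx <- foldIndices(plan, f)
      for (model in models) {
        met <- if (model == "rf") {
          rfBaseline(data, plan, targetColumn, seed = seeds[r],
                     folds = f)[[1]]
        } else {
          multi <- startsWith(model, "multi")
          tcols <- if (multi) allTargets else targetColumn
          fitted <- sampnFit(data, tcols, idx$train, idx$validation,
                             hiddenSize = hiddenSize, depth = depth,
                             activation = activation, ffnLayers = ffnLayers,
                             dropout = dropout,
                             attention = model %in% c("sampn", "multi_sampn"),
                             config = config, seed = seeds[r])
          test <- idx$test[!is.na(data[[targetColumn]][idx$test])]
          pred <- predict(fitted, data$smiles[test])[, targetColumn]
          computeMetrics(pred, data[[targetColumn]][test])
        }
        details <- rbind(details, data.frame(
          model = model, repeatIdx = r, fold = f, seed = seeds[r],
          MAE = met@MAE, MSE = met@MSE, RMSE = met@RMSE,
          R2 = met@R2, PC = met@PC))
        if (verbose)
          message(sprintf("repeat %d fold %d %s: RMSE %.4f",
                          r, f, model, met@RMSE))
      }
    }
  }
  summary <- do.call(rbind, lapply(unique(details$model), function(m) {
    sub <- details[details$model == m, ]
    data.frame(model = m, n = nrow(sub),
               RMSE = mean(sub$RMSE), RMSE_sd = sd(sub$RMSE),
               MAE = mean(sub$MAE), MAE_sd = sd(sub$MAE),
               R2 = mean(sub$R2), R2_sd = sd(sub$R2),
               PC = mean(sub$PC), PC_sd = sd(sub$PC))
  }))
  rownames(summary) <- NULL
  list(summary = summary, details = details)
}

#' Write a benchmark summary as CSV and a Markdown table
#'
#' @param benchmark result of [runBenchmark()].
#' @param csvPath,mdPath output paths (`NULL` to skip either).
#' @return invisibly, the Markdown lines.
#' @export
writeBenchmark <- function(benchmark, csvPath = NULL, mdPath = NULL) {
  s <- benchmark$summary
  if (!is.null(csvPath)) write.csv(s, csvPath, row.names = FALSE)
  fmt <- function(m, sdv) sprintf("%.3f ± %.3f", m, sdv)
  md <- c("| Model | RMSE | MAE | R2 | PC |",
          "|---|---|---|---|---|",
          vapply(seq_len(nrow(s)), function(i) sprintf(
            "| %s | %s | %s | %s | %s |", s$model[i],
            fmt(s$RMSE[i], s$RMSE_sd[i]), fmt(s$MAE[i], s$MAE_sd[i]),
            fmt(s$R2[i], s$R2_sd[i]), fmt(s$PC[i], s$PC_sd[i])),
            character(1)))
  if (!is.null(mdPath)) writeLines(md, mdPath)
  invisible(md)
}
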