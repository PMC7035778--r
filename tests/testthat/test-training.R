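test_that("masked loss averages over unmasked entries only", {
  expect_equal(maskedMseLoss(c(1, 2), c(1, 2), c(TRUE, TRUE)), 0)
  expect_equal(maskedMseLoss(c(1.0, 2.0), c(1.5, 9.9), c(TRUE, FALSE)), 0.25)
  expect_equal(maskedMseLoss(c(1, 2), c(9, 9), c(FALSE, FALSE)), 0)
  expect_error(maskedMseLoss(1, c(1, 2), TRUE))
})

test_that("learning rate warms up linearly then decays to the final rate", {
  cfg <- trainConfig(epochs = 10, warmupEpochs = 2,
                     initLR = 1e-4, maxLR = 1e-3, finalLR = 1e-4)
  spe <- 7L
  expect_equal(lrSchedule(0, cfg, spe), 1e-4)
  expect_equal(lrSchedule(2 * spe, cfg, spe), 1e-3)
  expect_equal(lrSchedule(spe, cfg, spe), (1e-4 + 1e-3) / 2)
  final <- lrSchedule(10 * spe, cfg, spe)
  expect_lt(abs(final - 1e-4) / 1e-4, 0.01)
  # monotone decay after warm-up
  lrs <- vapply(seq(2 * spe, 10 * spe), lrSchedule, numeric(1),
                config = cfg, stepsPerEpoch = spe)
  expect_true(all(diff(lrs) < 0))
})

test_that("metrics match their closed-form values", {
  m <- computeMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m@MAE, 0); expect_equal(m@RMSE, 0)
  expect_equal(m@R2, 1); expect_equal(m@PC, 1)

  m2 <- computeMetrics(c(2, 3, 4), c(1, 2, 3))
  expect_equal(m2@MAE, 1); expect_equal(m2@MSE, 1); expect_equal(m2@RMSE, 1)
  expect_equal(m2@R2, -0.5)   # SS_res 3, SS_tot 2
  expect_equal(m2@PC, 1)

  m3 <- computeMetrics(-c(1, 2, 3), c(1, 2, 3))
  expect_equal(m3@PC, -1)

  expect_warning(mz <- computeMetrics(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(mz@PC))
})

test_that("metric identities hold on random evaluations", {
  set.seed(11)
  for (i in 1:10) {
    pred <- rnorm(20); obs <- rnorm(20)
    m <- computeMetrics(pred, obs)
    expect_equal(m@RMSE^2, m@MSE, tolerance = 1e-12)
    expect_lte(m@MAE, m@RMSE + 1e-12)
    expect_gte(m@PC, -1); expect_lte(m@PC, 1)
    expect_lte(m@R2, 1)
  }
})

test_that("target normalisation round-trips to identity", {
  set.seed(12)
  y <- matrix(rnorm(40, mean = 3, sd = 2.5), 20, 2)
  norm <- sampn:::.normStats(y)
  back <- sampn:::.denormalize(sampn:::.normalizeTargets(y, norm), norm)
  expect_equal(back, y, tolerance = 1e-9)
})

test_that("the feed-forward head computes what it says", {
  # zero weights -> zero prediction for every target
  head0 <- list(list(W = matrix(0, 3, 4), b = numeric(3)))
  p <- sampn:::.headForward(matrix(rnorm(8), 2, 4), head0, "ReLU")$pred
  expect_true(all(p == 0))

  # a 1-layer head is an affine map
  W <- matrix(c(1, 2, -1, 0.5), 2, 2)
  head1 <- list(list(W = W, b = c(0.1, -0.2)))
  x <- matrix(c(1, 3), 1, 2)
  p1 <- sampn:::.headForward(x, head1, "ReLU")$pred
  expect_equal(as.numeric(p1), as.numeric(W %*% t(x)) + c(0.1, -0.2))
})

test_that("training is deterministic given the seed and the loss descends", {
  d <- fixture200()[1:80, ]
  plan <- stratifiedSplit(d, "value", k = 10, seed = 1)
  f <- foldIndices(plan, 1)
  cfg <- trainConfig(epochs = 4, batchSize = 40)
  m1 <- sampnFit(d, "value", f$train, f$validation, hiddenSize = 12L,
                 depth = 2L, config = cfg, seed = 9)
  m2 <- sampnFit(d, "value", f$train, f$validation, hiddenSize = 12L,
                 depth = 2L, config = cfg, seed = 9)
  expect_equal(m1@history$train_loss[1], m2@history$train_loss[1],
               tolerance = 1e-6)
  expect_identical(m1@encoder$Winp, m2@encoder$Winp)
  expect_lt(m1@history$train_loss[4], m1@history$train_loss[1])

  m3 <- sampnFit(d, "value", f$train, f$validation, hiddenSize = 12L,
                 depth = 2L, config = cfg, seed = 10)
  expect_false(isTRUE(all.equal(m1@history$train_loss[1],
                                m3@history$train_loss[1])))
})

test_that("a fully masked second target reproduces single-target dynamics", {
  d <- fixture200()[1:80, ]
  d2 <- d
  d2$second <- NA_real_
  plan <- stratifiedSplit(d, "value", k = 10, seed = 3)
  f <- foldIndices(plan, 1)
  cfg <- trainConfig(epochs = 2, batchSize = 40)
  single <- sampnFit(d, "value", f$train, f$validation, hiddenSize = 10L,
                     depth = 2L, config = cfg, seed = 4)
  multi <- sampnFit(d2, c("value", "second"), f$train, f$validation,
                    hiddenSize = 10L, depth = 2L, config = cfg, seed = 4)
  expect_equal(multi@history$train_loss[1], single@history$train_loss[1],
               tolerance = 1e-6)
})

test_that("multi-target models predict all properties in one pass", {
  d <- makeFixtureDataset(60, seed = 15, multiTarget = TRUE)
  d <- suppressMessages(cleanDataset(d))
  n <- nrow(d)
  m <- sampnFit(d, c("value", "ring_fraction"), seq_len(n - 10),
                seq(n - 9, n), hiddenSize = 10L, depth = 2L,
                config = trainConfig(epochs = 2, batchSize = 30), seed = 5)
  pred <- predict(m, c("CCO", "c1ccccc1"))
  expect_equal(dim(pred), c(2, 2))
  expect_equal(colnames(pred), c("value", "ring_fraction"))
  expect_true(all(is.finite(pred)))
})

test_that("model checkpoints restore weights, normalisation and predictions", {
  m <- tinyTrainedModel()
  path <- withr::local_tempfile(fileext = ".rds")
  saveSampnModel(m, path)
  back <- readSampnModel(path)
  expect_identical(back@encoder, m@encoder)
  expect_identical(back@norm, m@norm)
  expect_equal(predict(back, "CCO"), predict(m, "CCO"))
})

test_that("empty partitions are rejected", {
  d <- fixture200()[1:20, ]
  expect_error(sampnFit(d, "value", integer(0), 1:5), "nonempty")
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(20)
  graphs <- lapply(c("CCO", "C=O", "c1ccccc1"), molToGraph)
  pieces <- sampn:::.batchPieces(graphs)
  H <- 4L; depth <- 2L; ffn <- 2L
  enc <- encoderParams(H, depth, "Tanh")
  head <- sampn:::.headInit(H, H, 1L, ffn)
  flat <- sampn:::.flattenParams(enc, head)
  tb <- matrix(c(1.8, 0.9, 3.0), 3, 1)
  for (attention in c(TRUE, FALSE)) {
    lossOf <- function(fl) {
      eP <- encoderParams(H, depth, "Tanh", Winp = fl$Winp, Wh = fl$Wh,
                          Wo = fl$Wo, Wah = fl$Wah)
      G <- sampn:::.encoderForward(pieces, eP)$G
      att <- sampn:::.attentionForward(G, pieces$mol, attention = attention)
      pred <- sampn:::.headForward(att$latents,
                                   sampn:::.unflattenHead(fl, ffn), "Tanh")$pred
      mean((pred - tb)^2)
    }
    eP <- encoderParams(H, depth, "Tanh", Winp = flat$Winp, Wh = flat$Wh,
                        Wo = flat$Wo, Wah = flat$Wah)
    cache <- sampn:::.encoderForward(pieces, eP, keepCache = TRUE)
    att <- sampn:::.attentionForward(cache$G, pieces$mol,
                                     attention = attention, keepCache = TRUE)
    hl <- sampn:::.unflattenHead(flat, ffn)
    hc <- sampn:::.headForward(att$latents, hl, "Tanh", keepCache = TRUE)
    dPred <- 2 * (hc$pred - tb) / length(tb)
    hb <- sampn:::.headBackward(hc, dPred, hl, "Tanh")
    dG <- sampn:::.attentionBackward(cache$G, att, hb$dLatents,
                                     attention = attention)
    grads <- sampn:::.encoderBackward(cache, dG, eP)
    eps <- 1e-6
    for (k in c("Winp", "Wh", "Wo", "Wah")) {
      idx <- sample(length(flat[[k]]), 4)
      for (i in idx) {
        up <- flat; up[[k]][i] <- up[[k]][i] + eps
        dn <- flat; dn[[k]][i] <- dn[[k]][i] - eps
        num <- (lossOf(up) - lossOf(dn)) / (2 * eps)
        expect_equal(grads[[k]][i], num, tolerance = 1e-4)
      }
    }
  }
})
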