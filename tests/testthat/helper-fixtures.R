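# Shared, lazily built fixtures (cached for the test session).

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# The study-scale fixture set: 600 generated molecules, cleaned.
fixture600 <- function() memo("d600", function()
  suppressMessages(cleanDataset(makeFixtureDataset(600, seed = 7))))

# Exactly 200 unique-structure records (for the split-protocol checks).
fixture200 <- function() memo("d200", function() {
  d <- suppressMessages(cleanDataset(makeFixtureDataset(400, seed = 21)))
  stopifnot(nrow(d) >= 200)
  d[seq_len(200), ]
})

# A small untrained-but-initialised model (fixed weights, identity norm),
# enough for prediction-contract tests that do not need a good fit.
initModel <- function(hiddenSize = 12L, depth = 3L, K = 1L, seed = 5L) {
  memo(paste("model", hiddenSize, depth, K, seed, sep = "_"), function() {
    set.seed(seed)
    enc <- encoderParams(hiddenSize, depth)
    head <- sampn:::.headInit(hiddenSize, hiddenSize, K, 2L)
    new("SampnModel",
        encoder = enc[c("Winp", "Wh", "Wo", "Wah")],
        head = head,
        hyper = list(hiddenSize = hiddenSize, depth = depth,
                     activation = "ReLU", ffnLayers = 2L, dropout = 0,
                     attention = TRUE),
        norm = list(mean = rep(0, K), sd = rep(1, K)),
        targets = paste0("y", seq_len(K)),
        history = data.frame())
  })
}

# A quickly trained tiny model for checkpoint/viz/CLI tests.
tinyTrainedModel <- function() memo("tiny_trained", function() {
  d <- fixture200()[seq_len(120), ]
  plan <- stratifiedSplit(d, "value", k = 10, seed = 2)
  f <- foldIndices(plan, 1)
  sampnFit(d, "value", f$train, f$validation, hiddenSize = 16L, depth = 2L,
           config = trainConfig(epochs = 3, batchSize = 40), seed = 2)
})
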