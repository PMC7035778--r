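# Brute-force reference implementation of the directed-edge message passing
# encoder, written as explicit loops over edges and neighbours, independent
# of the vectorized code path. Used to pin the encoder's numerics.

oracleActivation <- function(name) {
  switch(tolower(name),
         relu = function(z) ifelse(z > 0, z, 0),
         tanh = function(z) tanh(z),
         stop("oracle supports relu/tanh only"))
}

oracleEncode <- function(graph, params) {
  act <- oracleActivation(params$activation)
  n <- nAtoms(graph)
  ne <- nEdges(graph)
  H <- params$hiddenSize
  af <- atomFeatures(graph)
  ef <- edgeFeatures(graph)
  src <- graph@edgeSource
  tgt <- graph@edgeTarget
  rev <- graph@edge2rev

  M <- matrix(0, max(ne, 1), H)
  for (e in seq_len(ne)) {
    xe <- c(af[src[e], ], ef[e, ])
    M[e, ] <- act(as.numeric(params$Winp %*% xe))
  }
  d <- 2
  while (d <= params$depth) {
    Mnew <- M
    for (e in seq_len(ne)) {
      x <- src[e]
      s <- rep(0, H)
      for (e2 in seq_len(ne)) {
        # messages into x from every neighbour except the target of e
        if (tgt[e2] == x && e2 != rev[e]) s <- s + M[e2, ]
      }
      xe <- c(af[x, ], ef[e, ])
      Mnew[e, ] <- act(as.numeric(params$Winp %*% xe + params$Wh %*% s))
    }
    M <- Mnew
    d <- d + 1
  }
  G <- matrix(0, n, H)
  for (y in seq_len(n)) {
    s <- rep(0, H)
    for (e in seq_len(ne)) if (tgt[e] == y) s <- s + M[e, ]
    G[y, ] <- act(as.numeric(
      params$Wo %*% (params$Wah %*% af[y, ] + s)))
  }
  G
}
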