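smallParams <- function(H = 4L, depth = 3L, seed = 17L, activation = "ReLU") {
  set.seed(seed)
  encoderParams(H, depth, activation)
}

test_that("merged edge input concatenates source-atom and bond features", {
  g <- molToGraph("CN")
  X <- mergedEdgeInput(g)
  expect_equal(dim(X), c(2, 150))
  expect_equal(X[1, ], c(atomFeatures(g)[1, ], edgeFeatures(g)[1, ]))
  expect_equal(X[2, ], c(atomFeatures(g)[2, ], edgeFeatures(g)[2, ]))
  # reverse edges of an asymmetric bond differ in the atom block only
  expect_false(isTRUE(all.equal(X[1, 1:139], X[2, 1:139])))
  expect_equal(X[1, 140:150], X[2, 140:150])

  caffeine <- molToGraph("CN1C=NC2=C1C(=O)N(C)C(=O)N2C")
  expect_equal(dim(mergedEdgeInput(caffeine)), c(30, 150))
})

test_that("initial messages follow Re(Winp . (fx || fxy))", {
  g <- molToGraph("CC")
  zero <- encoderParams(3L, 2L, Winp = matrix(0, 3, 150),
                        Wh = matrix(0, 3, 3), Wo = matrix(0, 3, 3),
                        Wah = matrix(0, 3, 139))
  expect_true(all(initMessages(g, zero)$messages == 0))

  # H = 1, all-ones input weights: message = number of active feature bits
  ones <- encoderParams(1L, 2L, Winp = matrix(1, 1, 150),
                        Wh = matrix(1, 1, 1), Wo = matrix(1, 1, 1),
                        Wah = matrix(1, 1, 139))
  m <- initMessages(g, ones)$messages
  expect_equal(m[1, 1], sum(c(atomFeatures(g)[1, ], edgeFeatures(g)[1, ])))
  # the two C->C edges have identical (fx, fxy), hence identical messages
  expect_equal(m[1, 1], m[2, 1])
})

test_that("edges from degree-1 atoms keep their initial message at all depths", {
  p <- smallParams()
  # diatomic: both sources are degree 1, messages constant across depth
  g <- molToGraph("CO")
  m1 <- initMessages(g, p)
  m2 <- updateMessages(m1, g, p)
  m3 <- updateMessages(m2, g, p)
  expect_equal(m3$messages, m1$messages)
  expect_equal(m3$depth, 3)

  # in a path, only the edges leaving the middle atom can change
  path <- molToGraph("CCO")
  pm1 <- initMessages(path, p)
  pm2 <- updateMessages(pm1, path, p)
  deg1 <- which(vapply(seq_len(nEdges(path)),
                       function(e) length(path@node2nei[[path@edgeSource[e]]]) == 1,
                       logical(1)))
  expect_equal(pm2$messages[deg1, ], pm1$messages[deg1, ])
})

test_that("3-atom path matches a hand-looped evaluation of the equations", {
  g <- molToGraph("CCO")
  p <- smallParams(H = 2L, depth = 2L, seed = 23L)
  m <- updateMessages(initMessages(g, p), g, p)
  G <- nodeHidden(g, m, p)
  Gref <- oracleEncode(g, p)
  expect_lt(max(abs(G - Gref)), 1e-12)
})

test_that("isolated atoms reduce the readout to the self-feature term", {
  g <- molToGraph("C")
  p <- smallParams()
  m <- structure(list(messages = matrix(0, 0, 4), depth = 3L),
                 class = "MessageTensor")
  G <- nodeHidden(g, m, p)
  act <- function(z) pmax(z, 0)
  expect_equal(as.numeric(G),
               as.numeric(act(p$Wo %*% (p$Wah %*% atomFeatures(g)[1, ]))))

  zero <- encoderParams(4L, 3L, Winp = matrix(0, 4, 150),
                        Wh = matrix(0, 4, 4), Wo = matrix(0, 4, 4),
                        Wah = matrix(0, 4, 139))
  expect_true(all(encodeGraph(molToGraph("CCO"), zero) == 0))
})

test_that("vectorized encoder matches the brute-force oracle", {
  smis <- generateMolecules(120, seed = 13)
  small <- unique(smis[vapply(smis, function(s) nAtoms(molToGraph(s)),
                              numeric(1)) <= 6])
  expect_gte(length(small), 5)
  for (act in c("ReLU", "Tanh")) {
    p <- smallParams(H = 8L, depth = 3L, seed = 29L, activation = act)
    for (s in small) {
      g <- molToGraph(s)
      expect_lt(max(abs(encodeGraph(g, p) - oracleEncode(g, p))), 1e-10)
    }
  }
})

test_that("encoding a batch equals stacking per-molecule encodings", {
  p <- smallParams(H = 6L)
  graphs <- lapply(c("CCO", "c1ccncc1", "CC(=O)O"), molToGraph)
  G <- encodeGraph(batchGraphs(graphs), p)
  expect_equal(attr(G, "mol"), rep(1:3, vapply(graphs, nAtoms, integer(1))))
  stacked <- do.call(rbind, lapply(graphs, encodeGraph, params = p))
  expect_equal(unname(G[, ]), stacked, tolerance = 1e-12)
})

test_that("encoding is permutation-equivariant", {
  p <- smallParams(H = 6L)
  smis <- generateMolecules(12, seed = 41)
  set.seed(4)
  for (s in smis) {
    g <- molToGraph(s)
    if (nAtoms(g) < 2) next
    perm <- sample(nAtoms(g))
    G <- encodeGraph(g, p)
    Gp <- encodeGraph(permuteGraph(g, perm), p)
    expect_lt(max(abs(Gp[perm, ] - G)), 1e-5)
  }
  # the same structure written as two different SMILES encodes to the same
  # multiset of atom hidden vectors
  for (pair in list(c("CCO", "OCC"), c("Cc1ccccc1", "c1ccccc1C"),
                    c("CC(=O)O", "OC(C)=O"))) {
    G1 <- encodeGraph(molToGraph(pair[1]), p)
    G2 <- encodeGraph(molToGraph(pair[2]), p)
    o1 <- G1[do.call(order, as.data.frame(G1)), ]
    o2 <- G2[do.call(order, as.data.frame(G2)), ]
    expect_lt(max(abs(o1 - o2)), 1e-5)
  }
})

test_that("depth-d encoding is local: distant edits leave hidden states unchanged", {
  p <- smallParams(H = 5L, depth = 3L)
  short <- encodeGraph(molToGraph("CCCCCCCC"), p)    # 8-carbon path
  long <- encodeGraph(molToGraph("CCCCCCCCCC"), p)   # extended at the far end
  # atoms 1..4 are at graph distance > 3 from any changed atom
  expect_equal(long[1:4, ], short[1:4, ], tolerance = 1e-12)
  # atoms near the extension must change (sanity that the test can fail)
  expect_gt(max(abs(long[8, ] - short[8, ])), 1e-8)
})

test_that("depth mismatches and dimension mismatches are rejected", {
  g <- molToGraph("CCO")
  p <- smallParams(depth = 3L)
  m1 <- initMessages(g, p)
  expect_error(nodeHidden(g, m1, p), "depth")
  expect_error(encoderParams(4L, 2L, Winp = matrix(0, 3, 150)))
  g2 <- molToGraph("CCCC")
  expect_error(updateMessages(m1, g2, p), "match")
})
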