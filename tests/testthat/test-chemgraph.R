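test_that("reading preserves rows and encodes blank cells as missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,logP", "CCO,1.2", "c1ccccc1,2.1"), path)
  d <- readDataset(path)
  expect_equal(nrow(d), 2)
  expect_equal(d$logP, c(1.2, 2.1))
  expect_false(anyNA(d$logP))

  writeLines(c("smiles,logP,logS", "CCO,1.2,", "CCN,,0.5"), path)
  d <- readDataset(path)
  expect_true(is.na(d$logS[1]))
  expect_true(is.na(d$logP[2]))
  expect_false(is.na(d$logP[1]))

  expect_error(readDataset(path, "nope"), "not found")
})

test_that("round trip through write/read preserves the table", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- makeFixtureDataset(25, seed = 4, multiTarget = TRUE)
  writeDataset(d, path)
  back <- readDataset(path)
  expect_equal(back$smiles, d$smiles)
  expect_equal(back$value, d$value, tolerance = 1e-12)
  expect_equal(is.na(back$ring_fraction), is.na(d$ring_fraction))
})

test_that("cleaning collapses duplicate structures keeping the maximum", {
  d <- data.frame(smiles = c("CCO", "OCC"), logP = c(1.0, 2.0))
  out <- cleanDataset(d)
  expect_equal(nrow(out), 1)
  expect_equal(out$logP, 2.0)
  expect_equal(out$smiles, canonicalizeSmiles("CCO"))

  # per-property maximum over a multi-target duplicate pair
  d2 <- data.frame(smiles = c("CCO", "OCC"), a = c(3, 1), b = c(NA, 5))
  out2 <- cleanDataset(d2)
  expect_equal(out2$a, 3)
  expect_equal(out2$b, 5)
})

test_that("cleaning drops unparseable rows, empty input and is idempotent", {
  expect_equal(nrow(cleanDataset(data.frame(smiles = character(0),
                                            y = numeric(0)))), 0)
  d <- data.frame(smiles = c("CCO", "not_a_smiles"), y = c(1, 3))
  expect_message(out <- cleanDataset(d), "unparseable")
  expect_equal(nrow(out), 1)
  expect_equal(out$y, 1)

  big <- makeFixtureDataset(80, seed = 9, multiTarget = TRUE)
  once <- suppressMessages(cleanDataset(big))
  twice <- suppressMessages(cleanDataset(once))
  expect_identical(once, twice)
})

test_that("cleaning drops records with no observed target", {
  d <- data.frame(smiles = c("CCO", "CCN"), a = c(NA, 1), b = c(NA, NA))
  out <- suppressMessages(cleanDataset(d))
  expect_equal(nrow(out), 1)
  expect_equal(out$a, 1)
})

test_that("atom featurization matches the one-hot block layout", {
  # ethane carbon: 1 heavy neighbour, neutral, sp3, non-aromatic
  v <- featurizeAtom("C", degree = 1)
  expect_length(v, 139)
  expect_equal(which(v[1:118] == 1), 6)          # atomic number block
  expect_equal(which(v[119:124] == 1), 2)        # degree bucket "1"
  expect_equal(which(v[125:129] == 1), 3)        # charge bucket 0
  expect_equal(which(v[130:133] == 1), 3)        # chirality unspecified
  expect_equal(which(v[134:138] == 1), 3)        # sp3
  expect_equal(v[139], 0)

  # benzene carbon carries the aromatic flag
  b <- molToGraph("c1ccccc1")
  expect_true(all(atomFeatures(b)[, 139] == 1))

  # charged atom and block-exclusivity invariants
  w <- featurizeAtom("O", degree = 1, formalCharge = -1)
  expect_equal(which(w[125:129] == 1), 2)
  for (blk in list(1:118, 119:124, 125:129, 130:133, 134:138))
    expect_lte(sum(w[blk]), 1)
  expect_warning(featurizeAtom("C", degree = 7), "clamped")
  expect_warning(featurizeAtom("N", degree = 1, formalCharge = 3), "clamped")
  expect_error(featurizeAtom("Xx", degree = 0), "unknown element")
})

test_that("bond featurization matches the one-hot block layout", {
  v <- featurizeBond("single")
  expect_length(v, 11)
  expect_equal(which(v[1:4] == 1), 1)
  expect_equal(v[5], 0)
  expect_equal(which(v[6:11] == 1), 1)           # stereo none

  # benzene ring bond: aromatic + in ring
  b <- molToGraph("c1ccccc1")
  ef <- edgeFeatures(b)[1, ]
  expect_equal(which(ef[1:4] == 1), 4)
  expect_equal(ef[5], 1)

  expect_message(v2 <- featurizeBond("double", stereo = "weird"), "none")
  expect_equal(which(v2[6:11] == 1), 1)
  expect_error(featurizeBond("quadruple"), "unknown bond order")
})

test_that("directed graphs have two opposed edges per bond", {
  g <- molToGraph("CN")                           # one bond
  expect_equal(nEdges(g), 2)
  expect_equal(g@edgeSource, c(1L, 2L))
  expect_equal(g@edgeTarget, c(2L, 1L))

  m <- molToGraph("C")                            # single heavy atom
  expect_equal(nAtoms(m), 1)
  expect_equal(nEdges(m), 0)

  caffeine <- molToGraph("CN1C=NC2=C1C(=O)N(C)C(=O)N2C")
  expect_equal(nAtoms(caffeine), 14)
  expect_equal(nEdges(caffeine), 30)

  expect_error(molToGraph("not_a_smiles"), "unparseable")
})

test_that("graph index lists are mutually consistent on generated molecules", {
  smis <- generateMolecules(25, seed = 31)
  for (s in smis) {
    g <- molToGraph(s)
    ne <- nEdges(g)
    expect_equal(ne, 2 * nBonds(g))
    if (ne == 0) next
    expect_false(any(g@edge2rev == seq_len(ne)))
    expect_identical(g@edge2rev[g@edge2rev], seq_len(ne))
    expect_identical(g@edgeSource[g@edge2rev], g@edgeTarget)
    expect_identical(g@edgeTarget[g@edge2rev], g@edgeSource)
    for (v in seq_len(nAtoms(g))) {
      expect_setequal(g@node2edge[[v]], which(g@edgeTarget == v))
      expect_setequal(g@node2nei[[v]], g@edgeSource[g@edgeTarget == v])
    }
  }
})

test_that("featurization is permutation-covariant", {
  g <- molToGraph("CC(=O)Nc1ccccc1")
  set.seed(8)
  perm <- sample(nAtoms(g))
  pg <- permuteGraph(g, perm)
  expect_equal(pg@atomFeatures[perm, ], g@atomFeatures)
  expect_true(validObject(pg))
})

test_that("batching preserves identity and unbatching recovers inputs", {
  graphs <- lapply(generateMolecules(10, seed = 12), molToGraph)
  b1 <- batchGraphs(graphs[1])
  expect_equal(length(unbatchGraphs(b1)), 1)
  expect_identical(unbatchGraphs(b1)[[1]]@edgeSource, graphs[[1]]@edgeSource)

  b <- batchGraphs(graphs)
  expect_equal(nAtoms(b), sum(vapply(graphs, nAtoms, integer(1))))
  back <- unbatchGraphs(b)
  for (i in seq_along(graphs)) {
    expect_identical(back[[i]]@edgeSource, graphs[[i]]@edgeSource)
    expect_identical(back[[i]]@atomFeatures, graphs[[i]]@atomFeatures)
  }
  expect_error(batchGraphs(list()), "nonempty")
})

test_that("graph JSON dump round-trips the index lists", {
  g <- molToGraph("CCO")
  js <- jsonlite::fromJSON(graphToJSON(g))
  expect_equal(js$n_atoms, 3)
  expect_equal(js$n_bonds, 2)
  expect_equal(js$edge2revedge, c(2, 1, 4, 3))
})
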