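# Deterministic synthetic-molecule generator. Molecules are assembled from a
# fixed fragment grammar (alkyl chains, benzene, pyridine, cyclohexane and a
# phenyl-alkyl combination, decorated with hydroxyl/amine/halide/carbonyl/
# methoxy/acid/nitrile substituents), kept under 30 heavy atoms. Properties
# are simple graph-derived functions (linear in element counts, heavy atom
# count, or ring fraction) plus optional Gaussian noise, so a message passing
# model of depth >= 1 can recover them; the noise stream is seeded
# independently of molecule generation.

.SUBSTITUENTS <- c("O", "N", "F", "Cl", "Br", "OC", "C#N", "C=O", "C(=O)O")
.RING_SUBSTITUENTS <- c("O", "N", "F", "Cl", "Br", "OC", "C#N", "C(=O)O")

.DEFAULT_COEFFICIENTS <- c(C = 0.5, N = -0.4, O = 0.8,
                           F = -0.25, Cl = 0.3, Br = 0.9)

.chainSmiles <- function(k, subs, positions, carbonylPos = 0L) {
  out <- character(k)
  for (i in seq_len(k)) {
    out[i] <- "C"
    if (i == carbonylPos) out[i] <- paste0(out[i], "(=O)")
    j <- which(positions == i)
    if (length(j)) out[i] <- paste0(out[i], "(", subs[j[1]], ")")
  }
  paste(out, collapse = "")
}

.sampleChain <- function(maxLen = 10L) {
  k <- sample(2:maxLen, 1)
  nsub <- min(sample(0:3, 1, prob = c(0.15, 0.4, 0.3, 0.15)), k - 1L)
  subs <- if (nsub) sample(.SUBSTITUENTS, nsub, replace = TRUE) else character(0)
  positions <- if (nsub) sample(seq_len(k), nsub) else integer(0)
  carbonyl <- 0L
  if ("C=O" %in% subs) {
    # keep the ketone/aldehyde inline instead of as a branch
    carbonyl <- positions[match("C=O", subs)]
    positions <- positions[subs != "C=O"]
    subs <- subs[subs != "C=O"]
  }
  .chainSmiles(k, subs, positions, carbonyl)
}

.sampleRing <- function(core = c("benzene", "pyridine", "cyclohexane")) {
  core <- match.arg(core)
  nsub <- sample(0:2, 1, prob = c(0.15, 0.5, 0.35))
  subs <- if (nsub) sample(.RING_SUBSTITUENTS, nsub, replace = TRUE)
          else character(0)
  tpl <- switch(core,
    benzene = c("c1ccccc1", "c1ccc(%s)cc1", "c1cc(%s)cc(%s)c1"),
    pyridine = c("c1ccncc1", "c1cc(%s)ncc1", "c1c(%s)cnc(%s)c1"),
    cyclohexane = c("C1CCCCC1", "C1CCC(%s)CC1", "C1CC(%s)CC(%s)C1"))
  do.call(sprintf, c(list(tpl[nsub + 1]), as.list(subs)))
}

.samplePhenylChain <- function() {
  k <- sample(1:6, 1)
  nsub <- sample(0:1, 1, prob = c(0.4, 0.6))
  subs <- if (nsub) sample(setdiff(.SUBSTITUENTS, "C=O"), nsub) else character(0)
  positions <- if (nsub) sample(seq_len(k), nsub) else integer(0)
  paste0("c1ccc(", .chainSmiles(k, subs, positions), ")cc1")
}

#' Generate synthetic molecules
#'
#' Draws `n` SMILES from the fixed fragment grammar. Deterministic given the
#' seed; duplicates are allowed (they exercise the structure-level
#' deduplication of [cleanDataset()]).
#'
#' @param n number of molecules.
#' @param seed integer RNG seed.
#' @return character vector of `n` valid SMILES strings.
#' @examples
#' generateMolecules(3, seed = 7)
#' @export
generateMolecules <- function(n, seed = 7L) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  vapply(seq_len(n), function(i) {
    kind <- sample(c("chain", "benzene", "pyridine", "cyclohexane", "phenyl"),
                   1, prob = c(0.40, 0.20, 0.15, 0.10, 0.15))
    switch(kind,
           chain = .sampleChain(),
           benzene = .sampleRing("benzene"),
           pyridine = .sampleRing("pyridine"),
           cyclohexane = .sampleRing("cyclohexane"),
           phenyl = .samplePhenylChain())
  }, character(1))
}

# Element counts and ring-atom fraction from the toolkit parse.
.moleculeComposition <- function(smiles) {
  p <- .parseSmiles(smiles)
  if (is.null(p)) stop("unparseable SMILES: ", smiles)
  ringAtoms <- unique(c(p$bonds$from[p$bonds$ring], p$bonds$to[p$bonds$ring]))
  list(counts = table(p$elements), n = length(p$elements),
       ringFraction = length(ringAtoms) / length(p$elements))
}

#' Synthetic target property of a molecule
#'
#' `atom_count_linear`: weighted sum of per-element heavy atom counts,
#' `y = sum_e c_e * n_e + eps`; `heavy_atom_count`: number of heavy atoms;
#' `ring_fraction`: fraction of heavy atoms in rings. Gaussian noise (sd
#' `noiseSd`) is drawn from a stream seeded by `noiseSeed`, independent of
#' molecule generation.
#'
#' @param smiles character vector of SMILES.
#' @param kind property kind (see above).
#' @param coefficients named per-element weights for `atom_count_linear`;
#'   elements not named get weight 0.
#' @param noiseSd standard deviation of the additive noise (default 0).
#' @param noiseSeed seed for the noise stream.
#' @return numeric vector of property values.
#' @examples
#' syntheticProperty("CCO", coefficients = c(C = 0.5, O = 0.8))  # 1.8
#' @export
syntheticProperty <- function(smiles, kind = c("atom_count_linear",
                                               "heavy_atom_count",
                                               "ring_fraction"),
                              coefficients = .DEFAULT_COEFFICIENTS,
                              noiseSd = 0, noiseSeed = 1L) {
  kind <- match.arg(kind)
  y <- vapply(smiles, function(s) {
    comp <- .moleculeComposition(s)
    switch(kind,
           atom_count_linear = {
             cs <- coefficients[names(comp$counts)]
             cs[is.na(cs)] <- 0
             sum(cs * as.numeric(comp$counts))
           },
           heavy_atom_count = comp$n,
           ring_fraction = comp$ringFraction)
  }, numeric(1), USE.NAMES = FALSE)
  if (noiseSd > 0) {
    set.seed(as.integer(noiseSeed))
    y <- y + rnorm(length(y), 0, noiseSd)
  }
  y
}

#' Build a synthetic fixture dataset
#'
#' Generates molecules and properties in the package's input schema
#' (`smiles` + value columns). In multi-target mode a second property
#' (`ring_fraction`) is added with partial, disjoint missingness to exercise
#' the masked multi-target loss: each record observes at least one property.
#'
#' @param n number of records.
#' @param seed seed for molecule generation; the noise and missingness
#'   streams are derived from it but independent.
#' @param path optional CSV path; when given, the table is also written
#'   (blank cell = missing value).
#' @param multiTarget add the second, partially missing property.
#' @param coefficients,noiseSd passed to [syntheticProperty()] for the
#'   primary (linear atom-count) property.
#' @return data.frame with `smiles` and `value` (+ `ring_fraction`).
#' @export
makeFixtureDataset <- function(n = 600L, seed = 7L, path = NULL,
                               multiTarget = FALSE,
                               coefficients = .DEFAULT_COEFFICIENTS,
                               noiseSd = 0.1) {
  smiles <- generateMolecules(n, seed)
  noiseSeed <- (as.integer(seed) + 1000003L) %% .Machine$integer.max
  value <- syntheticProperty(smiles, "atom_count_linear",
                             coefficients = coefficients,
                             noiseSd = noiseSd, noiseSeed = noiseSeed)
  df <- data.frame(smiles = smiles, value = value, stringsAsFactors = FALSE)
  if (multiTarget) {
    df$ring_fraction <- syntheticProperty(smiles, "ring_fraction")
    set.seed((as.integer(seed) + 2000003L) %% .Machine$integer.max)
    u <- runif(n)
    # ~25% observe only the ring fraction, ~35% only the linear property
    df$value[u < 0.25] <- NA
    df$ring_fraction[u >= 0.25 & u < 0.60] <- NA
  }
  if (!is.null(path)) writeDataset(df, path)
  df
}
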