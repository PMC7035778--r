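# Feature block layout. Atom vectors are 118 + 6 + 5 + 4 + 5 + 1 = 139 long:
# atom type (one-hot over atomic number 1..118), heavy-neighbour degree
# (buckets 0..5), formal charge (-2..+2), chirality (R, S, unspecified,
# unrecognized), hybridization (sp, sp2, sp3, sp3d, sp3d2), aromaticity flag.
# Bond vectors are 4 + 1 + 6 = 11: bond type (single/double/triple/aromatic),
# ring membership, stereo (none/any/Z/E/cis/trans).

.ATOM_FEATURE_LENGTH <- 139L
.BOND_FEATURE_LENGTH <- 11L
.CHIRALITY <- c("R", "S", "unspecified", "unrecognized")
.HYBRID <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
.BOND_ORDER <- c("single", "double", "triple", "aromatic")
.BOND_STEREO <- c("none", "any", "Z", "E", "cis", "trans")

#' One-hot atom feature vector
#'
#' Encodes an atom descriptor into the fixed 139-long binary feature vector
#' used by the message passing encoder: atomic-number one-hot (118), heavy
#' neighbour count bucket (0..5), formal charge bucket (-2..+2), chirality
#' tag, hybridization, and an aromaticity flag, in that order.
#'
#' @param element element symbol (e.g. `"C"`) or atomic number 1..118.
#' @param degree number of heavy-atom neighbours; values above 5 are clamped
#'   to the last bucket with a warning.
#' @param formalCharge integer formal charge; clamped to \[-2, 2\] with a
#'   warning outside that range.
#' @param chirality one of `"R"`, `"S"`, `"unspecified"`, `"unrecognized"`.
#' @param hybridization one of `"sp"`, `"sp2"`, `"sp3"`, `"sp3d"`, `"sp3d2"`,
#'   or any other string for "no bucket".
#' @param aromatic logical aromaticity flag.
#' @return numeric 0/1 vector of length 139.
#' @examples
#' v <- featurizeAtom("C", degree = 1)
#' length(v)  # 139
#' @export
featurizeAtom <- function(element, degree, formalCharge = 0L,
                          chirality = "unspecified",
                          hybridization = "sp3", aromatic = FALSE) {
  z <- if (is.numeric(element)) as.integer(element) else .atomicNumber(element)
  if (is.na(z) || z < 1L || z > 118L)
    stop("unknown element: ", element)
  v <- numeric(.ATOM_FEATURE_LENGTH)
  v[z] <- 1
  if (degree > 5L) {
    warning("heavy-neighbour count ", degree, " clamped to bucket 5")
    degree <- 5L
  }
  v[118L + 1L + as.integer(degree)] <- 1
  fc <- as.integer(formalCharge)
  if (fc < -2L || fc > 2L) {
    warning("formal charge ", fc, " clamped to [-2, 2]")
    fc <- max(-2L, min(2L, fc))
  }
  v[124L + 3L + fc] <- 1                       # offset 125..129 for -2..2
  ci <- match(chirality, .CHIRALITY)
  if (!is.na(ci)) v[129L + ci] <- 1
  hi <- match(hybridization, .HYBRID)
  if (!is.na(hi)) v[133L + hi] <- 1
  v[139L] <- as.numeric(isTRUE(aromatic))
  v
}

#' One-hot bond feature vector
#'
#' @param order bond order: `"single"`, `"double"`, `"triple"` or
#'   `"aromatic"`.
#' @param ring logical: is the bond part of a ring.
#' @param stereo one of `"none"`, `"any"`, `"Z"`, `"E"`, `"cis"`, `"trans"`;
#'   unknown tags map to `"none"` with a message.
#' @return numeric 0/1 vector of length 11.
#' @examples
#' featurizeBond("single")
#' @export
featurizeBond <- function(order, ring = FALSE, stereo = "none") {
  oi <- match(order, .BOND_ORDER)
  if (is.na(oi)) stop("unknown bond order: ", order)
  v <- numeric(.BOND_FEATURE_LENGTH)
  v[oi] <- 1
  v[5L] <- as.numeric(isTRUE(ring))
  si <- match(stereo, .BOND_STEREO)
  if (is.na(si)) {
    message("unknown bond stereo tag '", stereo, "' mapped to 'none'")
    si <- 1L
  }
  v[5L + si] <- 1
  v
}

#' Convert a SMILES string into a directed-edge molecular graph
#'
#' Parses the SMILES (heavy atoms only, hydrogens implicit), featurizes atoms
#' and bonds, and builds the four index lists of the directed-graph data
#' model: Edge2Node (source/target atom per directed edge), Node2Edge
#' (incoming directed edges per atom), Edge2Revedge (the opposed edge), and
#' Node2NeiNode (neighbour atoms). Every chemical bond contributes two
#' opposed directed edges, so the directed-edge count is always twice the
#' bond count.
#'
#' @param smiles a single SMILES string.
#' @return a [MolGraph-class] object.
#' @examples
#' g <- molToGraph("CCO")
#' nAtoms(g)  # 3
#' nEdges(g)  # 4
#' @export
molToGraph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  p <- .parseSmiles(smiles)
  if (is.null(p)) stop("unparseable SMILES: ", smiles)
  n <- length(p$elements)
  af <- matrix(0, n, .ATOM_FEATURE_LENGTH)
  for (i in seq_len(n))
    af[i, ] <- featurizeAtom(p$elements[i], p$degree[i], p$charge[i],
                             p$chirality[i], p$hybrid[i], p$aromatic[i])
  nb <- nrow(p$bonds)
  ne <- 2L * nb
  ef <- matrix(0, ne, .BOND_FEATURE_LENGTH)
  src <- integer(ne); tgt <- integer(ne); rev <- integer(ne)
  for (b in seq_len(nb)) {
    bv <- featurizeBond(p$bonds$order[b], p$bonds$ring[b], p$bonds$stereo[b])
    e1 <- 2L * b - 1L; e2 <- 2L * b
    ef[e1, ] <- bv; ef[e2, ] <- bv
    src[e1] <- p$bonds$from[b]; tgt[e1] <- p$bonds$to[b]
    src[e2] <- p$bonds$to[b];   tgt[e2] <- p$bonds$from[b]
    rev[e1] <- e2; rev[e2] <- e1
  }
  node2edge <- lapply(seq_len(n), function(v) which(tgt == v))
  node2nei <- lapply(seq_len(n), function(v) src[tgt == v])
  new("MolGraph", smiles = smiles, canonical = p$canonical,
      elements = p$elements, atomFeatures = af, edgeFeatures = ef,
      edgeSource = src, edgeTarget = tgt, node2edge = node2edge,
      edge2rev = rev, node2nei = node2nei, coords = p$coords)
}

#' Renumber the atoms of a MolGraph
#'
#' Applies an atom permutation, producing the graph that a differently
#' ordered SMILES of the same structure would yield. Used to check
#' permutation equivariance of featurization and encoding.
#'
#' @param graph a [MolGraph-class].
#' @param perm integer permutation of `seq_len(nAtoms(graph))`; atom `i` of
#'   the input becomes atom `perm[i]` of the output.
#' @return a [MolGraph-class] with rows/indices permuted.
#' @export
permuteGraph <- function(graph, perm) {
  n <- nAtoms(graph)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  src <- perm[graph@edgeSource]
  tgt <- perm[graph@edgeTarget]
  inv <- order(perm)
  new("MolGraph", smiles = graph@smiles, canonical = graph@canonical,
      elements = graph@elements[inv],
      atomFeatures = graph@atomFeatures[inv, , drop = FALSE],
      edgeFeatures = graph@edgeFeatures,
      edgeSource = src, edgeTarget = tgt,
      node2edge = lapply(seq_len(n), function(v) which(tgt == v)),
      edge2rev = graph@edge2rev,
      node2nei = lapply(seq_len(n), function(v) src[tgt == v]),
      coords = graph@coords[inv, , drop = FALSE])
}

#' Concatenate MolGraphs into a single batched graph
#'
#' Atom and edge indices are offset per molecule; membership vectors keep
#' molecules separable, so unbatching recovers the inputs exactly and the
#' encoder/attention stages never mix molecules.
#'
#' @param graphs nonempty list of [MolGraph-class] objects.
#' @return a [BatchedMolGraph-class].
#' @seealso [unbatchGraphs()]
#' @export
batchGraphs <- function(graphs) {
  if (!is.list(graphs) || length(graphs) == 0L)
    stop("batchGraphs() needs a nonempty list of MolGraph objects")
  stopifnot(all(vapply(graphs, is, logical(1), "MolGraph")))
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
  new("BatchedMolGraph",
      graphs = graphs,
      atomFeatures = do.call(rbind, lapply(graphs, atomFeatures)),
      edgeFeatures = do.call(rbind, lapply(graphs, edgeFeatures)),
      edgeSource = src, edgeTarget = tgt, edge2rev = rev,
      molOfAtom = rep(seq_along(graphs), nA),
      molOfEdge = rep(seq_along(graphs), nE))
}

#' @rdname batchGraphs
#' @param batch a [BatchedMolGraph-class].
#' @export
unbatchGraphs <- function(batch) {
  stopifnot(is(batch, "BatchedMolGraph"))
  batch@graphs
}

#' Read a (smiles, value) table
#'
#' Reads a CSV with a `smiles` column plus one or more numeric property
#' columns; a blank cell means the property is unobserved for that molecule
#' (multi-target masking).
#'
#' @param path CSV file path (UTF-8, header row).
#' @param valueColumns character vector of value column names; default: all
#'   columns except `smiles`.
#' @return data.frame with `smiles` plus numeric value columns (`NA` =
#'   missing/masked).
#' @export
readDataset <- function(path, valueColumns = NULL) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L)
    return(data.frame(smiles = character(0)))
  if (!"smiles" %in% names(df))
    stop("input table must have a 'smiles' column")
  if (is.null(valueColumns)) valueColumns <- setdiff(names(df), "smiles")
  missing <- setdiff(valueColumns, names(df))
  if (length(missing))
    stop("value column(s) not found: ", paste(missing, collapse = ", "))
  out <- df[, c("smiles", valueColumns), drop = FALSE]
  for (vc in valueColumns)
    out[[vc]] <- suppressWarnings(as.numeric(out[[vc]]))
  out
}

#' Write a (smiles, value) table
#'
#' @param data data.frame as returned by [readDataset()]/[cleanDataset()].
#' @param path output CSV path; missing targets are written as blank cells.
#' @export
writeDataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Clean a molecular property table
#'
#' Drops rows whose SMILES the toolkit cannot parse (with a message),
#' collapses duplicate *structures* (canonical-SMILES identity, not raw
#' string identity) keeping, per property, the maximum observed value, and
#' drops records with no observed property left. Output rows are in first
#' occurrence order and carry canonical SMILES. Idempotent.
#'
#' @param data data.frame with `smiles` plus numeric value columns.
#' @return cleaned data.frame of the same schema.
#' @examples
#' \dontrun{
#' cleanDataset(data.frame(smiles = c("CCO", "OCC"), logP = c(1, 2)))
#' # -> one ethanol record with logP 2
#' }
#' @export
cleanDataset <- function(data) {
  stopifnot(is.data.frame(data), "smiles" %in% names(data))
  valueColumns <- setdiff(names(data), "smiles")
  if (nrow(data) == 0L) return(data)
  canon <- canonicalizeSmiles(data$smiles)
  bad <- is.na(canon)
  if (any(bad))
    message("dropped ", sum(bad), " unparseable SMILES: ",
            paste(utils::head(data$smiles[bad], 5), collapse = ", "))
  data <- data[!bad, , drop = FALSE]
  canon <- canon[!bad]
  keys <- unique(canon)
  rows <- lapply(keys, function(k) {
    sub <- data[canon == k, valueColumns, drop = FALSE]
    vals <- vapply(valueColumns, function(vc) {
      v <- sub[[vc]]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, numeric(1))
    c(list(smiles = k), as.list(vals))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(out) <- c("smiles", valueColumns)
  if (length(valueColumns)) {
    observed <- rowSums(!is.na(out[, valueColumns, drop = FALSE])) > 0
    if (any(!observed))
      message("dropped ", sum(!observed), " record(s) with no observed target")
    out <- out[observed, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Serialize a MolGraph to JSON (debugging aid)
#'
#' @param graph a [MolGraph-class].
#' @param path optional file to write to; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly, if written to file).
#' @export
graphToJSON <- function(graph, path = NULL) {
  stopifnot(is(graph, "MolGraph"))
  obj <- list(
    smiles = graph@smiles, canonical = graph@canonical,
    n_atoms = nAtoms(graph), n_bonds = nBonds(graph),
    elements = graph@elements,
    edge_source = graph@edgeSource, edge_target = graph@edgeTarget,
    edge2revedge = graph@edge2rev,
    node2edge = graph@node2edge, node2neinode = graph@node2nei,
    atom_features = graph@atomFeatures, edge_features = graph@edgeFeatures)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
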