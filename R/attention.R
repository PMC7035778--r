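# Dot-product self-attention readout over atom hidden vectors.
#
#   W_att = softmax(G . G^T)      (row-wise, unscaled)
#   E_G   = W_att . G
#
# The molecule latent vector is the global average pooling of G + E_G, and
# the per-atom attention coefficient is the atom's attention weight score
# minus the molecular average, so coefficients always sum to zero: positive
# values mark atoms that receive more attention than average.

.rowSoftmax <- function(A) {
  A <- A - apply(A, 1, max)        # shift for numerical stability
  E <- exp(A)
  E / rowSums(E)
}

#' Self-attention weight matrix
#'
#' Row-wise softmax of `G %*% t(G)`, with no scaling factor. Row `i` holds
#' the attention that atom `i` pays to every atom of the molecule; each row
#' sums to 1.
#'
#' @param G numeric matrix `n x H` of atom hidden vectors (one molecule).
#' @return row-stochastic `n x n` matrix.
#' @examples
#' attentionWeights(matrix(c(1, 0), 2, 1))  # rows softmax([1,0]) and [.5,.5]
#' @export
attentionWeights <- function(G) {
  G <- as.matrix(G)
  stopifnot(nrow(G) >= 1)
  .rowSoftmax(tcrossprod(G))
}

#' Attention-weighted atom embeddings
#'
#' `E_G = W_att %*% G`: each row is the attention-weighted combination of all
#' atom hidden vectors.
#'
#' @param Watt row-stochastic attention matrix from [attentionWeights()].
#' @param G matching atom hidden matrix.
#' @return numeric matrix of the same shape as `G`.
#' @export
attentiveEmbedding <- function(Watt, G) {
  G <- as.matrix(G)
  if (ncol(Watt) != nrow(G)) stop("W_att and G shapes do not agree")
  Watt %*% G
}

#' Molecule latent vector
#'
#' Global average pooling over atoms of `G + E_G`.
#'
#' @param G atom hidden matrix `n x H`.
#' @param EG attentive embedding matrix `n x H`.
#' @return numeric vector of length `H`.
#' @export
moleculeLatent <- function(G, EG) {
  G <- as.matrix(G); EG <- as.matrix(EG)
  stopifnot(identical(dim(G), dim(EG)))
  colMeans(G + EG)
}

#' Per-atom attention coefficients
#'
#' An atom's weight score is, by default, the mean of its *column* of
#' `W_att` (the attention it receives from all atoms); the coefficient is
#' that score minus the molecular mean score, so the coefficients sum to 0.
#' `aggregate = "row"` uses the row mean (attention paid) instead.
#'
#' @param Watt attention matrix from [attentionWeights()].
#' @param aggregate `"column"` (default) or `"row"`.
#' @return numeric vector of length `n`, summing to 0.
#' @export
attentionCoefficients <- function(Watt, aggregate = c("column", "row")) {
  aggregate <- match.arg(aggregate)
  s <- if (aggregate == "column") colMeans(Watt) else rowMeans(Watt)
  s - mean(s)
}

# Attention stage over a batch: per-molecule blocks, never across molecules.
# Returns per-molecule latents (nMols x H) plus caches for backprop.
.attentionForward <- function(G, mol, attention = TRUE, keepCache = FALSE) {
  ids <- sort(unique(mol))
  H <- ncol(G)
  latents <- matrix(0, length(ids), H)
  caches <- if (keepCache) vector("list", length(ids)) else NULL
  for (k in seq_along(ids)) {
    rows <- which(mol == ids[k])
    Gm <- G[rows, , drop = FALSE]
    if (attention) {
      W <- .rowSoftmax(tcrossprod(Gm))
      E <- W %*% Gm
      latents[k, ] <- colMeans(Gm + E)
      if (keepCache) caches[[k]] <- list(rows = rows, W = W)
    } else {
      latents[k, ] <- colMeans(Gm)
      if (keepCache) caches[[k]] <- list(rows = rows)
    }
  }
  list(latents = latents, caches = caches, ids = ids)
}

# Adjoint of the attention stage: dLatents (nMols x H) -> dG (nAtoms x H).
.attentionBackward <- function(G, fwd, dLatents, attention = TRUE) {
  dG <- matrix(0, nrow(G), ncol(G))
  for (k in seq_along(fwd$ids)) {
    cache <- fwd$caches[[k]]
    rows <- cache$rows
    n <- length(rows)
    dlat <- dLatents[k, ]
    dSum <- matrix(dlat / n, n, length(dlat), byrow = TRUE)
    if (!attention) {
      dG[rows, ] <- dG[rows, ] + dSum
      next
    }
    Gm <- G[rows, , drop = FALSE]
    W <- cache$W
    dE <- dSum
    dGm <- dSum + crossprod(W, dE)
    dW <- tcrossprod(dE, Gm)
    # softmax rows: dA_i = W_i * (dW_i - <dW_i, W_i>)
    dA <- W * (dW - rowSums(dW * W))
    dGm <- dGm + (dA + t(dA)) %*% Gm
    dG[rows, ] <- dG[rows, ] + dGm
  }
  dG
}

#' Attention analysis of one molecule under a fitted encoder
#'
#' Convenience wrapper: encodes the molecule and returns the attention
#' matrix, attentive embedding, latent vector and per-atom coefficients.
#'
#' @param graph a [MolGraph-class] (or SMILES string).
#' @param params an [encoderParams()] list.
#' @param aggregate passed to [attentionCoefficients()].
#' @return list with `Watt`, `EG`, `latent`, `coefficients`.
#' @export
attendGraph <- function(graph, params, aggregate = c("column", "row")) {
  if (is.character(graph)) graph <- molToGraph(graph)
  G <- encodeGraph(graph, params)
  W <- attentionWeights(G)
  EG <- attentiveEmbedding(W, G)
  list(Watt = W, EG = EG, latent = moleculeLatent(G, EG),
       coefficients = attentionCoefficients(W, match.arg(aggregate)))
}
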