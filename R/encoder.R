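# Directed-edge message passing encoder.
#
# Messages live on directed edges. The initial message that atom x sends to
# its neighbour y is a learned transform of the merged node-edge feature
# f_x || f_xy:
#
#   M_xy^1 = Re(W_inp . (f_x || f_xy))
#
# and subsequent passes re-inject that input term (the skip connection) while
# aggregating the previous messages flowing into x from everywhere but y:
#
#   M_xy^d = Re(W_inp . (f_x || f_xy) + W_h . sum_{z in N(x)\y} M_zx^{d-1})
#
# After the final pass each atom aggregates its incoming messages into a
# hidden vector:
#
#   h_y = Re(W_o . (W_ah . f_y + sum_{z in N(y)} M_zy^d))
#
# yielding the graph representation G = {h_1 ... h_n}. Updates are
# synchronous (Jacobi-style): M^d is computed for all edges from the complete
# M^{d-1}, which realises the "all neighbours except y first" gating.

#' Encoder parameter set
#'
#' Creates (or wraps) the four weight matrices of the directed-edge message
#' passing encoder. When a weight is not supplied it is drawn from a
#' Glorot-uniform distribution using the current RNG state.
#'
#' @param hiddenSize hidden width H of messages and atom hidden vectors.
#' @param depth number of message passing iterations (>= 1).
#' @param activation one of `"ReLU"` (default), `"Tanh"`, `"ELU"`,
#'   `"LeakyReLU"`, `"PReLU"`, `"SELU"`.
#' @param Winp `H x 150` input transform of the merged node-edge feature.
#' @param Wh `H x H` message update transform.
#' @param Wo `H x H` output transform of the readout.
#' @param Wah `H x 139` atom self-feature transform of the readout.
#' @return a list of class `EncoderParams`.
#' @export
encoderParams <- function(hiddenSize = 64L, depth = 3L, activation = "ReLU",
                          Winp = NULL, Wh = NULL, Wo = NULL, Wah = NULL) {
  H <- as.integer(hiddenSize)
  stopifnot(H >= 1L, depth >= 1L)
  .activation(activation)  # validates the name
  nin <- .ATOM_FEATURE_LENGTH + .BOND_FEATURE_LENGTH
  if (is.null(Winp)) Winp <- .xavier(H, nin)
  if (is.null(Wh)) Wh <- .xavier(H, H)
  if (is.null(Wo)) Wo <- .xavier(H, H)
  if (is.null(Wah)) Wah <- .xavier(H, .ATOM_FEATURE_LENGTH)
  stopifnot(identical(dim(Winp), c(H, as.integer(nin))),
            identical(dim(Wh), c(H, H)), identical(dim(Wo), c(H, H)),
            identical(dim(Wah), c(H, .ATOM_FEATURE_LENGTH)))
  structure(list(Winp = Winp, Wh = Wh, Wo = Wo, Wah = Wah,
                 hiddenSize = H, depth = as.integer(depth),
                 activation = activation),
            class = "EncoderParams")
}

# Pull the raw pieces an encoder pass needs out of either graph class.
.graphPieces <- function(x) {
  if (is(x, "MolGraph"))
    list(af = x@atomFeatures, ef = x@edgeFeatures,
         src = x@edgeSource, tgt = x@edgeTarget, rev = x@edge2rev,
         mol = rep(1L, nAtoms(x)))
  else if (is(x, "BatchedMolGraph"))
    list(af = x@atomFeatures, ef = x@edgeFeatures,
         src = x@edgeSource, tgt = x@edgeTarget, rev = x@edge2rev,
         mol = x@molOfAtom)
  else stop("expected a MolGraph or BatchedMolGraph")
}

# Sparse incidence matrix: (n_atoms x n_edges), 1 where the edge's `idx`
# endpoint is the atom. Used for incoming-message sums and their adjoints.
.incidence <- function(nAtoms, idx) {
  Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                       dims = c(nAtoms, length(idx)))
}

#' Merged node-edge input matrix
#'
#' Row `e` is the concatenation `f_x || f_xy` of the source-atom features and
#' the bond features of directed edge `e`.
#'
#' @param graph a [MolGraph-class] or [BatchedMolGraph-class].
#' @return numeric matrix `(2 * nBonds) x 150`.
#' @export
mergedEdgeInput <- function(graph) {
  p <- .graphPieces(graph)
  cbind(p$af[p$src, , drop = FALSE], p$ef)
}

#' Initial edge messages (depth 1)
#'
#' `M^1 = Re(W_inp . (f_x || f_xy))`, one row per directed edge.
#'
#' @inheritParams mergedEdgeInput
#' @param params an [encoderParams()] list.
#' @return a `MessageTensor`: list with `messages` (`(2 nBonds) x H`) and
#'   `depth = 1`.
#' @export
initMessages <- function(graph, params) {
  act <- .activation(params$activation)
  P <- tcrossprod(mergedEdgeInput(graph), params$Winp)
  structure(list(messages = act$f(P), depth = 1L), class = "MessageTensor")
}

#' One synchronous message passing update
#'
#' Advances the messages from depth `d - 1` to depth `d`:
#' `M_xy^d = Re(W_inp (f_x || f_xy) + W_h sum_{z in N(x)\y} M_zx^{d-1})`.
#' The excluded-neighbour sum is computed as (all messages into x) minus the
#' reverse message `M_yx^{d-1}`.
#'
#' @param prev the previous `MessageTensor`.
#' @inheritParams initMessages
#' @return a `MessageTensor` at `depth = prev$depth + 1`.
#' @export
updateMessages <- function(prev, graph, params) {
  stopifnot(inherits(prev, "MessageTensor"), prev$depth >= 1L)
  p <- .graphPieces(graph)
  act <- .activation(params$activation)
  M <- prev$messages
  if (nrow(M) != length(p$src)) stop("message tensor does not match graph")
  P <- tcrossprod(mergedEdgeInput(graph), params$Winp)
  Ain <- .incidence(nrow(p$af), p$tgt)
  S <- as.matrix(Ain %*% M)
  B <- S[p$src, , drop = FALSE] - M[p$rev, , drop = FALSE]
  structure(list(messages = act$f(P + tcrossprod(B, params$Wh)),
                 depth = prev$depth + 1L),
            class = "MessageTensor")
}

#' Atom hidden vectors from final messages
#'
#' Readout `h_y = Re(W_o (W_ah f_y + sum_{z in N(y)} M_zy^d))`, giving the
#' graph representation `G` (one row per atom).
#'
#' @param final the `MessageTensor` at the encoder's final depth.
#' @inheritParams initMessages
#' @return numeric matrix `nAtoms x H`.
#' @export
nodeHidden <- function(graph, final, params) {
  stopifnot(inherits(final, "MessageTensor"))
  if (final$depth != params$depth)
    stop("message depth ", final$depth, " != encoder depth ", params$depth)
  p <- .graphPieces(graph)
  act <- .activation(params$activation)
  M <- final$messages
  SN <- if (length(p$tgt)) as.matrix(.incidence(nrow(p$af), p$tgt) %*% M)
        else matrix(0, nrow(p$af), params$hiddenSize)
  inner <- tcrossprod(p$af, params$Wah) + SN
  act$f(tcrossprod(inner, params$Wo))
}

# Vectorized full forward pass shared by encodeGraph() and training; caches
# every pre-activation needed for backprop when keepCache = TRUE. Message
# dropout masks (training only) are applied after each activation.
.encoderForward <- function(pieces, params, keepCache = FALSE,
                            dropout = 0, training = FALSE) {
  act <- .activation(params$activation)
  H <- params$hiddenSize
  nA <- nrow(pieces$af)
  nE <- length(pieces$src)
  Xe <- cbind(pieces$af[pieces$src, , drop = FALSE], pieces$ef)
  P <- tcrossprod(Xe, params$Winp)
  Ain <- if (nE) .incidence(nA, pieces$tgt) else NULL
  Zs <- vector("list", params$depth)
  Ms <- vector("list", params$depth)
  masks <- vector("list", params$depth)
  Z <- P
  M <- act$f(Z)
  if (training && dropout > 0 && nE) {
    masks[[1]] <- .dropoutMask(nE, H, dropout)
    M <- M * masks[[1]]
  }
  Zs[[1]] <- Z; Ms[[1]] <- M
  d <- 2L
  while (d <= params$depth) {
    S <- as.matrix(Ain %*% M)
    B <- S[pieces$src, , drop = FALSE] - M[pieces$rev, , drop = FALSE]
    Z <- P + tcrossprod(B, params$Wh)
    M <- act$f(Z)
    if (training && dropout > 0 && nE) {
      masks[[d]] <- .dropoutMask(nE, H, dropout)
      M <- M * masks[[d]]
    }
    Zs[[d]] <- Z; Ms[[d]] <- M
    d <- d + 1L
  }
  SN <- if (nE) as.matrix(Ain %*% M) else matrix(0, nA, H)
  inner <- tcrossprod(pieces$af, params$Wah) + SN
  preG <- tcrossprod(inner, params$Wo)
  G <- act$f(preG)
  if (!keepCache) return(list(G = G))
  list(G = G, Xe = Xe, P = P, Zs = Zs, Ms = Ms, masks = masks,
       SN = SN, inner = inner, preG = preG, Ain = Ain, pieces = pieces)
}

# Adjoint of the encoder forward pass: given dL/dG, accumulate gradients for
# the four weight matrices. The excluded-neighbour sum B[e] = S_src(e) -
# M[rev(e)] has adjoint dM[e'] = (sum of dB over edges leaving tgt(e')) -
# dB[rev(e')].
.encoderBackward <- function(cache, dG, params) {
  act <- .activation(params$activation)
  pieces <- cache$pieces
  nA <- nrow(pieces$af)
  nE <- length(pieces$src)
  dPre <- dG * act$df(cache$preG)
  dInner <- dPre %*% params$Wo
  gWo <- crossprod(dPre, cache$inner)
  gWah <- crossprod(dInner, pieces$af)
  gWinp <- matrix(0, nrow(params$Winp), ncol(params$Winp))
  gWh <- matrix(0, params$hiddenSize, params$hiddenSize)
  if (nE) {
    Aout <- .incidence(nA, pieces$src)
    dM <- as.matrix(Matrix::crossprod(cache$Ain, dInner))  # dSN -> edges
    dP <- matrix(0, nE, params$hiddenSize)
    d <- params$depth
    while (d >= 2L) {
      if (!is.null(cache$masks[[d]])) dM <- dM * cache$masks[[d]]
      dZ <- dM * act$df(cache$Zs[[d]])
      dP <- dP + dZ
      # recompute B for the weight gradient (cheap relative to storing it)
      Mprev <- cache$Ms[[d - 1L]]
      S <- as.matrix(cache$Ain %*% Mprev)
      B <- S[pieces$src, , drop = FALSE] - Mprev[pieces$rev, , drop = FALSE]
      gWh <- gWh + crossprod(dZ, B)
      dB <- dZ %*% params$Wh
      Tm <- as.matrix(Aout %*% dB)
      dM <- Tm[pieces$tgt, , drop = FALSE] - dB[pieces$rev, , drop = FALSE]
      d <- d - 1L
    }
    if (!is.null(cache$masks[[1L]])) dM <- dM * cache$masks[[1L]]
    dZ1 <- dM * act$df(cache$Zs[[1L]])
    dP <- dP + dZ1
    gWinp <- crossprod(dP, cache$Xe)
  }
  list(Winp = gWinp, Wh = gWh, Wo = gWo, Wah = gWah)
}

#' Encode a molecule (or batch) into per-atom hidden vectors
#'
#' Runs the full message passing encoder: initial messages, `depth - 1`
#' synchronous updates, then the per-atom readout. For a batch, molecules
#' are encoded independently (their rows are simply stacked).
#'
#' @param graph a [MolGraph-class] or [BatchedMolGraph-class].
#' @param params an [encoderParams()] list.
#' @return numeric matrix `nAtoms x H`; for a batch, the attribute
#'   `"mol"` holds the molecule id of each row.
#' @examples
#' set.seed(1)
#' G <- encodeGraph(molToGraph("CCO"), encoderParams(hiddenSize = 8))
#' dim(G)  # 3 x 8
#' @export
encodeGraph <- function(graph, params) {
  pieces <- .graphPieces(graph)
  G <- .encoderForward(pieces, params)$G
  if (is(graph, "BatchedMolGraph")) attr(G, "mol") <- pieces$mol
  G
}
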