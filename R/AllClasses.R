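#' @import methods
#' @importFrom stats predict rnorm runif sd cor quantile setNames
#' @importFrom utils read.csv write.csv head
NULL

#' MolGraph: a directed-edge chemical graph
#'
#' Heavy-atom molecular graph in the index-list form used by directed-edge
#' message passing: every chemical bond between atoms \eqn{x} and \eqn{y}
#' contributes two opposed directed edges \eqn{x \to y} and \eqn{y \to x}.
#' Atom and bond feature matrices hold the one-hot encodings produced by
#' [featurizeAtom()] and [featurizeBond()].
#'
#' @slot smiles input SMILES string.
#' @slot canonical canonical SMILES emitted by the parsing toolkit.
#' @slot elements character vector of element symbols, one per heavy atom.
#' @slot atomFeatures numeric matrix, `nAtoms x 139`.
#' @slot edgeFeatures numeric matrix, `(2 * nBonds) x 11`; row `e` holds the
#'   bond features of the bond underlying directed edge `e`.
#' @slot edgeSource,edgeTarget integer vectors (Edge2Node): source/target atom
#'   index of each directed edge.
#' @slot node2edge list of integer vectors (Node2Edge): for each atom, the
#'   indices of its *incoming* directed edges (the direction needed by the
#'   neighbour aggregation of the readout).
#' @slot edge2rev integer vector (Edge2Revedge): index of the opposed edge;
#'   a fixed-point-free involution.
#' @slot node2nei list of integer vectors (Node2NeiNode): neighbour atom
#'   indices per atom.
#' @slot coords numeric matrix `nAtoms x 2` of 2D depiction coordinates.
#' @export
setClass("MolGraph", representation(
  smiles = "character",
  canonical = "character",
  elements = "character",
  atomFeatures = "matrix",
  edgeFeatures = "matrix",
  edgeSource = "integer",
  edgeTarget = "integer",
  node2edge = "list",
  edge2rev = "integer",
  node2nei = "list",
  coords = "matrix"
))

setValidity("MolGraph", function(object) {
  n <- length(object@elements)
  ne <- length(object@edgeSource)
  msg <- character(0)
  if (nrow(object@atomFeatures) != n) msg <- c(msg, "atomFeatures rows != n atoms")
  if (ncol(object@atomFeatures) != 139) msg <- c(msg, "atomFeatures must have 139 columns")
  if (ne > 0 && ncol(object@edgeFeatures) != 11) msg <- c(msg, "edgeFeatures must have 11 columns")
  if (nrow(object@edgeFeatures) != ne) msg <- c(msg, "edgeFeatures rows != n directed edges")
  if (ne %% 2 != 0) msg <- c(msg, "directed edge count must be even (2 per bond)")
  if (length(object@edgeTarget) != ne) msg <- c(msg, "edgeSource/edgeTarget length mismatch")
  if (length(object@edge2rev) != ne) msg <- c(msg, "edge2rev length mismatch")
  if (ne > 0) {
    if (any(object@edge2rev == seq_len(ne))) msg <- c(msg, "edge2rev has fixed points")
    if (!identical(object@edge2rev[object@edge2rev], seq_len(ne)))
      msg <- c(msg, "edge2rev is not an involution")
    if (!identical(object@edgeSource[object@edge2rev], object@edgeTarget))
      msg <- c(msg, "reverse edge endpoints inconsistent")
  }
  if (length(object@node2edge) != n || length(object@node2nei) != n)
    msg <- c(msg, "node2edge/node2nei length != n atoms")
  if (length(msg)) msg else TRUE
})

#' BatchedMolGraph: several MolGraphs concatenated for one forward pass
#'
#' Atom and edge matrices of the member molecules stacked with global
#' indices; `molOfAtom`/`molOfEdge` record molecule membership so that no
#' message or attention weight ever crosses a molecule boundary.
#'
#' @slot graphs the member [MolGraph-class] objects, in order.
#' @slot atomFeatures,edgeFeatures stacked feature matrices.
#' @slot edgeSource,edgeTarget,edge2rev global (offset) index vectors.
#' @slot molOfAtom,molOfEdge molecule id per atom / per directed edge.
#' @export
setClass("BatchedMolGraph", representation(
  graphs = "list",
  atomFeatures = "matrix",
  edgeFeatures = "matrix",
  edgeSource = "integer",
  edgeTarget = "integer",
  edge2rev = "integer",
  molOfAtom = "integer",
  molOfEdge = "integer"
))

setValidity("BatchedMolGraph", function(object) {
  msg <- character(0)
  if (length(object@graphs) < 1) msg <- c(msg, "empty batch")
  if (nrow(object@atomFeatures) != length(object@molOfAtom))
    msg <- c(msg, "molOfAtom length mismatch")
  if (length(object@edgeSource) != length(object@molOfEdge))
    msg <- c(msg, "molOfEdge length mismatch")
  if (length(object@edgeSource) &&
      any(object@molOfAtom[object@edgeSource] != object@molOfEdge))
    msg <- c(msg, "an edge crosses a molecule boundary")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: regression evaluation metrics
#'
#' @slot MAE,MSE,RMSE mean absolute / squared / root-mean-squared error.
#' @slot R2 coefficient of determination against the mean of the observed
#'   values (can be negative).
#' @slot PC Pearson correlation coefficient.
#' @slot n number of evaluated pairs.
#' @export
setClass("MetricsReport", representation(
  MAE = "numeric", MSE = "numeric", RMSE = "numeric",
  R2 = "numeric", PC = "numeric", n = "integer"
))

setValidity("MetricsReport", function(object) {
  msg <- character(0)
  if (object@MSE < 0 || object@MAE < 0) msg <- c(msg, "errors must be nonnegative")
  if (abs(object@RMSE - sqrt(object@MSE)) > 1e-9) msg <- c(msg, "RMSE != sqrt(MSE)")
  if (length(msg)) msg else TRUE
})

#' SplitPlan: stratified k-fold train/validation/test assignments
#'
#' @slot assignments character matrix `n x k` with entries
#'   `"train"`, `"validation"` or `"test"`.
#' @slot k number of folds.
#' @slot seed RNG seed the plan was drawn with.
#' @slot bins number of quantile bins used to stratify the continuous target.
#' @export
setClass("SplitPlan", representation(
  assignments = "matrix", k = "integer", seed = "integer", bins = "integer"
))

setValidity("SplitPlan", function(object) {
  ok <- all(object@assignments %in% c("train", "validation", "test"))
  if (!ok) "assignments must be train/validation/test" else TRUE
})

#' SampnModel: a trained (self-attention) message passing regressor
#'
#' Holds the encoder weight matrices of the directed-edge message passing
#' network, the feed-forward head, the target normalisation constants and
#' the hyperparameter record.
#'
#' @slot encoder list with `Winp` (H x 150), `Wh` (H x H), `Wo` (H x H),
#'   `Wah` (H x 139), and optional bias vectors.
#' @slot head list of layers, each `list(W, b)`.
#' @slot hyper hyperparameter record (hidden size, depth, activation,
#'   dropout, ffn layers, attention flag, ...).
#' @slot norm list with per-target `mean` and `sd` used to z-score targets.
#' @slot targets names of the predicted properties (length K).
#' @slot history per-epoch training/validation metrics (data.frame).
#' @export
setClass("SampnModel", representation(
  encoder = "list", head = "list", hyper = "list",
  norm = "list", targets = "character", history = "data.frame"
))

setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph: %s\n  %d atoms, %d bonds, %d directed edges\n",
              object@smiles, length(object@elements),
              length(object@edgeSource) %/% 2L, length(object@edgeSource)))
})

setMethod("show", "BatchedMolGraph", function(object) {
  cat(sprintf("BatchedMolGraph: %d molecules, %d atoms, %d directed edges\n",
              length(object@graphs), nrow(object@atomFeatures),
              length(object@edgeSource)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (n = %d)\n  MAE %.4f  MSE %.4f  RMSE %.4f  R2 %.4f  PC %.4f\n",
              object@n, object@MAE, object@MSE, object@RMSE, object@R2, object@PC))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d records, %d folds, %d strata (seed %d)\n",
              nrow(object@assignments), object@k, object@bins, object@seed))
})

setMethod("show", "SampnModel", function(object) {
  h <- object@hyper
  cat(sprintf("SampnModel (%s): hidden %d, depth %d, %s, %d FFN layer(s), K = %d\n",
              if (isTRUE(h$attention)) "SAMPN" else "MPN",
              h$hiddenSize, h$depth, h$activation, h$ffnLayers,
              length(object@targets)))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs; best validation RMSE %.4f\n",
                max(object@history$epoch),
                min(object@history$val_rmse, na.rm = TRUE)))
})

#' @rdname MolGraph-class
#' @param x a MolGraph or BatchedMolGraph
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname MolGraph-class
#' @export
setGeneric("nBonds", function(x) standardGeneric("nBonds"))
#' @rdname MolGraph-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname MolGraph-class
#' @export
setGeneric("atomFeatures", function(x) standardGeneric("atomFeatures"))
#' @rdname MolGraph-class
#' @export
setGeneric("edgeFeatures", function(x) standardGeneric("edgeFeatures"))
#' @rdname MolGraph-class
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))

#' @rdname MolGraph-class
#' @export
setMethod("nAtoms", "MolGraph", function(x) length(x@elements))
#' @rdname MolGraph-class
#' @export
setMethod("nBonds", "MolGraph", function(x) length(x@edgeSource) %/% 2L)
#' @rdname MolGraph-class
#' @export
setMethod("nEdges", "MolGraph", function(x) length(x@edgeSource))
#' @rdname MolGraph-class
#' @export
setMethod("atomFeatures", "MolGraph", function(x) x@atomFeatures)
#' @rdname MolGraph-class
#' @export
setMethod("edgeFeatures", "MolGraph", function(x) x@edgeFeatures)
#' @rdname MolGraph-class
#' @export
setMethod("canonicalSmiles", "MolGraph", function(x) x@canonical)
#' @rdname MolGraph-class
#' @export
setMethod("nAtoms", "BatchedMolGraph", function(x) nrow(x@atomFeatures))
#' @rdname MolGraph-class
#' @export
setMethod("nEdges", "BatchedMolGraph", function(x) length(x@edgeSource))
#' @rdname MolGraph-class
#' @export
setMethod("nBonds", "BatchedMolGraph", function(x) length(x@edgeSource) %/% 2L)
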