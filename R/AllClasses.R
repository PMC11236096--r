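#' @import methods
#' @importFrom stats sd rnorm runif
#' @importFrom utils read.delim write.table head
NULL

.SYM_TOL <- 1e-8
.ROWSUM_TOL <- 1e-10
.NEG_TOL <- 1e-12

.checkSquareNumeric <- function(v) {
  if (!is.matrix(v) || !is.numeric(v))
    return("'values' must be a numeric matrix")
  if (nrow(v) != ncol(v))
    return("'values' must be square")
  if (anyNA(v) || any(!is.finite(v)))
    return("'values' must be finite and free of NA")
  NULL
}

#' WeightMatrix: a weighted undirected graph
#'
#' Square, symmetric, non-negative adjacency matrix of an undirected graph
#' \eqn{G=(V,E,W)} with at least two nodes. The diagonal is usually zero (no
#' self loops) but a positive diagonal is permitted because the preprocessing
#' step of the denoiser deliberately adds one.
#'
#' @slot values numeric matrix of edge weights.
#' @slot nodeIds character vector of node labels, one per row/column.
#' @export
setClass("WeightMatrix",
  slots = c(values = "matrix", nodeIds = "character"),
  validity = function(object) {
    v <- object@values
    msg <- .checkSquareNumeric(v)
    if (!is.null(msg)) return(msg)
    if (nrow(v) < 2) return("a network needs at least 2 nodes")
    if (length(object@nodeIds) != nrow(v))
      return("length of 'nodeIds' must equal the matrix dimension")
    if (anyDuplicated(object@nodeIds))
      return("'nodeIds' must be unique")
    if (min(v) < 0) return("edge weights must be non-negative")
    if (max(abs(v - t(v))) > .SYM_TOL)
      return("'values' must be symmetric (undirected graph)")
    TRUE
  })

#' QuasiTransition: a relaxed random-walk matrix
#'
#' Holds the raw output of inverse diffusion: a square matrix whose rows sum
#' to one in exact arithmetic but whose entries may be negative when the input
#' network violates the forward-diffusion generative assumption, and whose
#' rows no longer sum to one after the per-row negative-value shift.
#'
#' @slot values numeric matrix.
#' @slot nodeIds character node labels.
#' @export
setClass("QuasiTransition",
  slots = c(values = "matrix", nodeIds = "character"),
  validity = function(object) {
    msg <- .checkSquareNumeric(object@values)
    if (!is.null(msg)) return(msg)
    if (length(object@nodeIds) != nrow(object@values))
      return("length of 'nodeIds' must equal the matrix dimension")
    TRUE
  })

#' TransitionMatrix: a row-stochastic random walk
#'
#' Row-stochastic, non-negative matrix \eqn{P = D^{-1}W} defining a random
#' walk on a weighted graph.
#'
#' @export
setClass("TransitionMatrix",
  contains = "QuasiTransition",
  validity = function(object) {
    v <- object@values
    if (min(v) < -.NEG_TOL)
      return("transition probabilities must be non-negative")
    if (max(abs(rowSums(v) - 1)) > .ROWSUM_TOL)
      return("every row must sum to 1")
    TRUE
  })

#' StationaryDistribution: the long-run occupancy of a random walk
#'
#' Probability vector \eqn{\pi} with \eqn{\pi P = \pi}; for the random walk on
#' a connected undirected graph it is proportional to node degree.
#'
#' @slot values numeric probability vector.
#' @slot nodeIds character node labels.
#' @export
setClass("StationaryDistribution",
  slots = c(values = "numeric", nodeIds = "character"),
  validity = function(object) {
    v <- object@values
    if (anyNA(v) || any(!is.finite(v))) return("'values' must be finite")
    if (min(v) < -.NEG_TOL) return("probabilities must be non-negative")
    if (abs(sum(v) - 1) > .ROWSUM_TOL) return("'values' must sum to 1")
    if (length(object@nodeIds) != length(v))
      return("length of 'nodeIds' must equal length of 'values'")
    TRUE
  })

#' SimilarityMatrix: symmetric similarity or correlation scores
#'
#' Input/output container for the similarity-based comparator denoisers.
#' When flagged as a correlation matrix, the diagonal must be one and entries
#' must lie in \eqn{[-1, 1]}.
#'
#' @slot values numeric symmetric matrix.
#' @slot nodeIds character node labels.
#' @slot correlation logical; whether the matrix is a correlation matrix.
#' @export
setClass("SimilarityMatrix",
  slots = c(values = "matrix", nodeIds = "character", correlation = "logical"),
  validity = function(object) {
    v <- object@values
    msg <- .checkSquareNumeric(v)
    if (!is.null(msg)) return(msg)
    if (length(object@nodeIds) != nrow(v))
      return("length of 'nodeIds' must equal the matrix dimension")
    if (max(abs(v - t(v))) > 1e-10)
      return("'values' must be symmetric")
    if (isTRUE(object@correlation)) {
      if (max(abs(diag(v) - 1)) > 1e-8)
        return("a correlation matrix must have unit diagonal")
      if (max(abs(v)) > 1 + 1e-8)
        return("correlation entries must lie in [-1, 1]")
    }
    TRUE
  })

#' DenoiseConfig: hyper-parameters of the diffusion denoiser
#'
#' @slot m numeric diffusion intensity, strictly greater than 1 (the
#'   path-length decay base; larger m means gentler denoising; default 4).
#' @slot eps1 numeric off-diagonal preprocessing offset, or NA for the
#'   automatic rule (1 for unweighted input, minimum non-zero weight
#'   otherwise).
#' @slot eps2 numeric diagonal preprocessing offset, or NA for automatic.
#' @slot alpha numeric output weight scale of the walk-to-graph mapping, or
#'   NA meaning "match the preprocessed input's total weight".
#' @slot renormalizeRows logical; renormalize rows after the negative-value
#'   shift so the walk-to-graph mapping acts on a true transition matrix
#'   (default TRUE). FALSE reproduces the literal pseudocode, which applies
#'   the mapping to the shifted, non-stochastic matrix.
#' @export
setClass("DenoiseConfig",
  slots = c(m = "numeric", eps1 = "numeric", eps2 = "numeric",
            alpha = "numeric", renormalizeRows = "logical"),
  validity = function(object) {
    if (length(object@m) != 1 || is.na(object@m) || object@m <= 1)
      return("'m' must be a single value strictly greater than 1 (series convergence)")
    for (s in c("eps1", "eps2")) {
      x <- slot(object, s)
      if (length(x) != 1) return(sprintf("'%s' must be a single value", s))
      if (!is.na(x) && x < 0) return(sprintf("'%s' must be non-negative", s))
    }
    if (length(object@alpha) != 1)
      return("'alpha' must be a single value")
    if (!is.na(object@alpha) && object@alpha <= 0)
      return("'alpha' must be positive")
    TRUE
  })

#' NEConfig: network-enhancement settings
#'
#' @slot k integer neighbourhood size (NA: min(20, n - 1) at run time).
#' @slot alpha numeric retention weight in (0, 1) of the diffusion update.
#' @slot iterations positive integer count of diffusion updates.
#' @export
setClass("NEConfig",
  slots = c(k = "numeric", alpha = "numeric", iterations = "numeric"),
  validity = function(object) {
    if (!is.na(object@k) && (object@k < 1 || object@k != round(object@k)))
      return("'k' must be a positive integer")
    if (object@alpha < 0 || object@alpha >= 1)
      return("'alpha' must lie in [0, 1)")
    if (object@iterations < 1 || object@iterations != round(object@iterations))
      return("'iterations' must be a positive integer")
    TRUE
  })

#' NoisySimSpec: recipe for one synthetic noisy network
#'
#' @slot topology one of "circular", "er", "ba".
#' @slot n integer node count.
#' @slot p numeric edge-formation probability (ER only).
#' @slot e integer edges added per step (BA only).
#' @slot noiseProportion numeric in (0, 1): fraction of the noisy network's
#'   edges that are injected indirect-noise edges.
#' @slot decay numeric > 1 path-length decay base of the noise score.
#' @slot maxPathLen integer longest path length scored (default 4).
#' @slot seed integer RNG seed.
#' @export
setClass("NoisySimSpec",
  slots = c(topology = "character", n = "numeric", p = "numeric",
            e = "numeric", noiseProportion = "numeric", decay = "numeric",
            maxPathLen = "numeric", seed = "numeric"),
  validity = function(object) {
    if (!object@topology %in% c("circular", "er", "ba"))
      return("'topology' must be one of 'circular', 'er', 'ba'")
    if (object@n < 3 || object@n != round(object@n))
      return("'n' must be an integer >= 3")
    if (object@topology == "er" && (object@p <= 0 || object@p >= 1))
      return("'p' must lie in (0, 1) for an ER graph")
    if (object@topology == "ba" &&
        (object@e < 1 || object@e >= object@n || object@e != round(object@e)))
      return("'e' must be an integer in [1, n) for a BA graph")
    if (object@noiseProportion < 0 || object@noiseProportion >= 1)
      return("'noiseProportion' must lie in [0, 1)")
    if (object@decay <= 1)
      return("'decay' must be greater than 1")
    if (object@maxPathLen < 2)
      return("'maxPathLen' must be at least 2")
    TRUE
  })

#' LabeledNetwork: a noisy network with signal/noise edge labels
#'
#' @slot weights WeightMatrix of the noisy network.
#' @slot labels data.frame with columns nodeA, nodeB, label in
#'   {"signal", "noise"}; one row per positive-weight unordered pair.
#' @slot meta list of generation metadata (topology, noise proportion, seed,
#'   edge counts).
#' @export
setClass("LabeledNetwork",
  slots = c(weights = "WeightMatrix", labels = "data.frame", meta = "list"),
  validity = function(object) {
    lb <- object@labels
    need <- c("nodeA", "nodeB", "label")
    if (!all(need %in% names(lb)))
      return("'labels' needs columns nodeA, nodeB, label")
    if (!all(lb$label %in% c("signal", "noise")))
      return("labels must be 'signal' or 'noise'")
    v <- object@weights@values
    npos <- sum(v[upper.tri(v)] > 0)
    if (nrow(lb) != npos)
      return("every positive-weight pair must carry exactly one label")
    TRUE
  })
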