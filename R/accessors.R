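#' @include AllClasses.R
NULL

.defaultIds <- function(v, nodeIds = NULL) {
  if (!is.null(nodeIds)) return(as.character(nodeIds))
  if (!is.null(rownames(v))) return(rownames(v))
  sprintf("v%d", seq_len(nrow(v)))
}

.withIds <- function(v, ids) {
  dimnames(v) <- list(ids, ids)
  v
}

#' Construct a WeightMatrix
#'
#' @param values square symmetric non-negative numeric matrix.
#' @param nodeIds optional character node labels; defaults to the matrix
#'   dimnames or v1..vn.
#' @return a \linkS4class{WeightMatrix}.
#' @examples
#' weightMatrix(rbind(c(0, 1), c(1, 0)))
#' @export
weightMatrix <- function(values, nodeIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- .defaultIds(values, nodeIds)
  new("WeightMatrix", values = .withIds(values, ids), nodeIds = ids)
}

#' Construct a TransitionMatrix
#'
#' @param values square row-stochastic non-negative matrix.
#' @param nodeIds optional node labels.
#' @return a \linkS4class{TransitionMatrix}.
#' @export
transitionMatrix <- function(values, nodeIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[values < 0 & values > -.NEG_TOL] <- 0
  ids <- .defaultIds(values, nodeIds)
  new("TransitionMatrix", values = .withIds(values, ids), nodeIds = ids)
}

#' Construct a QuasiTransition
#'
#' @param values square numeric matrix (negative entries permitted).
#' @param nodeIds optional node labels.
#' @return a \linkS4class{QuasiTransition}.
#' @export
quasiTransition <- function(values, nodeIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- .defaultIds(values, nodeIds)
  new("QuasiTransition", values = .withIds(values, ids), nodeIds = ids)
}

#' Construct a SimilarityMatrix
#'
#' @param values square symmetric numeric matrix.
#' @param nodeIds optional node labels.
#' @param correlation logical; declare the matrix a correlation matrix
#'   (unit diagonal, entries in [-1, 1]).
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
similarityMatrix <- function(values, nodeIds = NULL, correlation = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values <- (values + t(values)) / 2
  ids <- .defaultIds(values, nodeIds)
  new("SimilarityMatrix", values = .withIds(values, ids), nodeIds = ids,
      correlation = isTRUE(correlation))
}

.sentinelNum <- function(x, sentinels) {
  if (is.character(x)) {
    if (x %in% sentinels) return(NA_real_)
    stop("unknown sentinel '", x, "'")
  }
  as.numeric(x)
}

#' Denoiser hyper-parameters
#'
#' @param m diffusion intensity, strictly > 1. Default 4.
#' @param eps1 off-diagonal preprocessing offset; "auto" (the default) picks 1
#'   for unweighted input and the minimum non-zero weight otherwise.
#' @param eps2 diagonal preprocessing offset; "auto" as for \code{eps1}.
#' @param alpha output weight scale; "match-input-sum" (the default) scales
#'   the denoised network to the preprocessed input's total weight.
#' @param renormalizeRows renormalize rows after the negative-value shift
#'   (default TRUE); FALSE follows the literal pseudocode.
#' @return a \linkS4class{DenoiseConfig}.
#' @examples
#' denoiseConfig(m = 4)
#' @export
denoiseConfig <- function(m = 4, eps1 = "auto", eps2 = "auto",
                          alpha = "match-input-sum", renormalizeRows = TRUE) {
  new("DenoiseConfig",
      m = as.numeric(m),
      eps1 = .sentinelNum(eps1, "auto"),
      eps2 = .sentinelNum(eps2, "auto"),
      alpha = .sentinelNum(alpha, "match-input-sum"),
      renormalizeRows = isTRUE(renormalizeRows))
}

#' Network-enhancement settings
#'
#' @param k neighbourhood size; NA picks min(20, n - 1) at run time.
#' @param alpha retention weight in (0, 1) of the diffusion update.
#' @param iterations number of diffusion updates.
#' @return a \linkS4class{NEConfig}.
#' @export
neConfig <- function(k = NA, alpha = 0.9, iterations = 2) {
  new("NEConfig", k = as.numeric(k), alpha = as.numeric(alpha),
      iterations = as.numeric(iterations))
}

#' Recipe for a synthetic noisy network
#'
#' @param topology "circular", "er" or "ba".
#' @param n node count.
#' @param p ER edge-formation probability.
#' @param e BA edges added per step.
#' @param noiseProportion fraction of the noisy network's edges that are
#'   injected indirect-noise edges; the study sweep uses 0.1-0.5.
#' @param decay path-length decay base of the noise score (> 1).
#' @param maxPathLen longest path length contributing to the noise score.
#' @param seed integer RNG seed.
#' @return a \linkS4class{NoisySimSpec}.
#' @examples
#' simSpec("er", n = 50, p = 0.3, noiseProportion = 0.3, seed = 1)
#' @export
simSpec <- function(topology = c("circular", "er", "ba"), n, p = 0.3, e = 3,
                    noiseProportion = 0.3, decay = 4, maxPathLen = 4,
                    seed = 1) {
  topology <- match.arg(topology)
  new("NoisySimSpec", topology = topology, n = as.numeric(n),
      p = as.numeric(p), e = as.numeric(e),
      noiseProportion = as.numeric(noiseProportion),
      decay = as.numeric(decay), maxPathLen = as.numeric(maxPathLen),
      seed = as.numeric(seed))
}

#' Node labels of a network object
#'
#' @param x a network container from this package.
#' @return character vector of node labels.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "WeightMatrix", function(x) x@nodeIds)
#' @rdname nodeIds
#' @export
setMethod("nodeIds", "QuasiTransition", function(x) x@nodeIds)
#' @rdname nodeIds
#' @export
setMethod("nodeIds", "StationaryDistribution", function(x) x@nodeIds)
#' @rdname nodeIds
#' @export
setMethod("nodeIds", "SimilarityMatrix", function(x) x@nodeIds)
#' @rdname nodeIds
#' @export
setMethod("nodeIds", "LabeledNetwork", function(x) x@weights@nodeIds)

#' Noisy weights of a labelled network
#'
#' @param x a \linkS4class{LabeledNetwork}.
#' @return the \linkS4class{WeightMatrix} of the noisy network.
#' @export
noisyWeights <- function(x) {
  stopifnot(is(x, "LabeledNetwork"))
  x@weights
}

#' Edge labels of a labelled network
#'
#' @param x a \linkS4class{LabeledNetwork}.
#' @return data.frame with columns nodeA, nodeB, label.
#' @export
edgeLabels <- function(x) {
  stopifnot(is(x, "LabeledNetwork"))
  x@labels
}

#' @export
#' @rdname coercion-matrix
#' @param x object to coerce.
#' @param ... unused.
#' @title Extract the underlying numeric matrix
setMethod("as.matrix", "WeightMatrix", function(x, ...) x@values)
#' @rdname coercion-matrix
#' @export
setMethod("as.matrix", "QuasiTransition", function(x, ...) x@values)
#' @rdname coercion-matrix
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)

#' @export
#' @describeIn StationaryDistribution-class numeric vector of probabilities.
#' @param x a StationaryDistribution.
setMethod("as.vector", "StationaryDistribution", function(x) {
  stats::setNames(x@values, x@nodeIds)
})

.showMat <- function(object, what) {
  v <- object@values
  cat(sprintf("%s of %d nodes\n", what, nrow(v)))
  k <- min(5L, nrow(v))
  print(round(v[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (nrow(v) > k) cat(sprintf("... (%d more rows/columns)\n", nrow(v) - k))
  invisible(NULL)
}

setMethod("show", "WeightMatrix", function(object) {
  .showMat(object, "WeightMatrix (undirected weighted graph)")
})
setMethod("show", "TransitionMatrix", function(object) {
  .showMat(object, "TransitionMatrix (row-stochastic random walk)")
})
setMethod("show", "QuasiTransition", function(object) {
  .showMat(object, "QuasiTransition (relaxed random walk)")
})
setMethod("show", "SimilarityMatrix", function(object) {
  .showMat(object, if (object@correlation) "SimilarityMatrix (correlation)"
           else "SimilarityMatrix")
})
setMethod("show", "StationaryDistribution", function(object) {
  cat(sprintf("StationaryDistribution over %d nodes\n", length(object@values)))
  print(round(head(stats::setNames(object@values, object@nodeIds), 8), 4))
  invisible(NULL)
})
setMethod("show", "LabeledNetwork", function(object) {
  tb <- table(object@labels$label)
  cat(sprintf("LabeledNetwork: %d nodes, %d signal + %d noise edges (%s)\n",
              nrow(object@weights@values),
              sum(object@labels$label == "signal"),
              sum(object@labels$label == "noise"),
              paste0(object@meta$topology %||% "?")))
  invisible(tb)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
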