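#' @include diffusion.R
NULL

# shared tail of both composite operators: map a (possibly shifted) walk back
# to an undirected graph and fix the output scale.
.walkToGraph <- function(Pv, ids, alpha, targetSum, renormalize) {
  if (renormalize) {
    P <- transitionMatrix(Pv / rowSums(Pv), ids)
    pi <- stationaryDistribution(P)@values
    M <- pi * P@values
  } else {
    # literal pseudocode: dominant left eigenvector of the shifted matrix
    e <- eigen(t(Pv))
    i <- which.max(Re(e$values))
    pi <- Re(e$vectors[, i])
    if (sum(pi) < 0) pi <- -pi
    pi <- pi / sum(pi)
    M <- pi * Pv
  }
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M[M < 0 & M > -.NEG_TOL] <- 0
  if (is.na(alpha)) {
    s <- sum(M)
    if (s <= 0) stop("denoised network has no weight left", call. = FALSE)
    M <- M * (targetSum / s)
  } else {
    M <- M * alpha
  }
  weightMatrix(M, ids)
}

#' Denoise a network by reverse diffusion (RENDOR)
#'
#' Treats the observed network as the outcome of length-decayed random-walk
#' diffusion on an unknown direct network and inverts that diffusion,
#' stripping transitive (indirect) contributions of all path lengths.
#' Pipeline: preprocess (\eqn{\tilde W = W + \epsilon_1 J + \epsilon_2 I}),
#' row-normalize to a walk, apply \code{\link{inverseDiffusion}} with
#' intensity m, shift negative rows (\code{\link{clipNegativeRows}}),
#' renormalize, and map back to a graph through the stationary distribution.
#' The output is a dense weighted complete graph: pairs absent from the input
#' may acquire a small weight.
#'
#' @param W a \linkS4class{WeightMatrix}.
#' @param cfg a \linkS4class{DenoiseConfig}; see \code{\link{denoiseConfig}}.
#' @return a symmetric, zero-diagonal \linkS4class{WeightMatrix}.
#' @examples
#' W <- weightMatrix(rbind(c(0, 1, 1, 0), c(1, 0, 1, 0),
#'                         c(1, 1, 0, 1), c(0, 0, 1, 0)))
#' rendorDenoise(W, denoiseConfig(m = 4))
#' @seealso \code{\link{nrDiffuse}} for the forward (noise-adding) operator.
#' @export
rendorDenoise <- function(W, cfg = denoiseConfig()) {
  stopifnot(is(W, "WeightMatrix"), is(cfg, "DenoiseConfig"))
  Wp <- preprocessNetwork(W, cfg@eps1, cfg@eps2)
  P <- toTransition(Wp)
  Q <- inverseDiffusion(P, cfg@m)
  Qc <- clipNegativeRows(Q)
  .walkToGraph(Qc@values, W@nodeIds, cfg@alpha, sum(Wp@values),
               cfg@renormalizeRows)
}

#' Forward graph diffusion (noise-raising operator)
#'
#' The composite forward operator: graph to walk, forward diffusion
#' \eqn{f_m}, walk back to graph. It spreads weight along paths of all
#' lengths and is the generative model that \code{\link{rendorDenoise}}
#' inverts; useful for synthesizing diffusion-noised networks and for
#' round-trip testing.
#'
#' @param W a connected \linkS4class{WeightMatrix}.
#' @param cfg a \linkS4class{DenoiseConfig}; preprocessing defaults to none
#'   (eps1 = eps2 = 0) because the forward operator needs no irreducibility
#'   repair beyond connectivity.
#' @return a symmetric, zero-diagonal \linkS4class{WeightMatrix}, complete on
#'   a connected input.
#' @export
nrDiffuse <- function(W, cfg = denoiseConfig(eps1 = 0, eps2 = 0)) {
  stopifnot(is(W, "WeightMatrix"), is(cfg, "DenoiseConfig"))
  e1 <- if (is.na(cfg@eps1)) 0 else cfg@eps1
  e2 <- if (is.na(cfg@eps2)) 0 else cfg@eps2
  Wp <- preprocessNetwork(W, e1, e2)
  P <- toTransition(Wp)
  F <- forwardDiffusion(P, cfg@m)
  .walkToGraph(F@values, W@nodeIds, cfg@alpha, sum(Wp@values),
               renormalize = TRUE)
}
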