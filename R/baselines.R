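#' @include accessors.R
NULL

.simInput <- function(G) {
  if (is(G, "SimilarityMatrix") || is(G, "WeightMatrix")) return(G@values)
  if (is.matrix(G)) return(G)
  stop("expected a SimilarityMatrix, WeightMatrix or matrix", call. = FALSE)
}

.ndEigenMap <- function(lambda) lambda / (1 + lambda)

#' Network deconvolution (ND)
#'
#' Eigenvalue-reweighting deconvolution: the observed similarity matrix is
#' linearly rescaled so that the spectral radius of the direct matrix stays
#' below one, eigendecomposed \eqn{G = U \Sigma U^\top}, each eigenvalue
#' mapped \eqn{\lambda \to \lambda / (1 + \lambda)}, and reassembled. This
#' inverts the transitive-closure series \eqn{G_{obs} = G_{dir}(I -
#' G_{dir})^{-1}}.
#'
#' @param G symmetric \linkS4class{SimilarityMatrix} (or WeightMatrix/matrix).
#' @param scale spectral radius of the direct output in (0, 1); NULL skips
#'   the rescaling and applies the eigenvalue map to G as given.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
ndDenoise <- function(G, scale = 0.9) {
  v <- .simInput(G)
  if (max(abs(v - t(v))) > 1e-8)
    stop("network deconvolution requires a symmetric input", call. = FALSE)
  v <- (v + t(v)) / 2
  e <- eigen(v, symmetric = TRUE)
  lam <- e$values
  if (!is.null(scale)) {
    if (scale <= 0 || scale >= 1)
      stop("'scale' must lie strictly in (0, 1)", call. = FALSE)
    lmax <- max(lam); lmin <- min(lam)
    cand <- c(if (lmax > 0) scale / ((1 - scale) * lmax),
              if (lmin < 0) scale / ((1 + scale) * abs(lmin)))
    delta <- if (length(cand)) min(cand) else 1
    lam <- delta * lam
  }
  if (any(abs(1 + lam) < 1e-12))
    stop("an eigenvalue hit -1 after scaling; choose a smaller 'scale'",
         call. = FALSE)
  out <- e$vectors %*% (.ndEigenMap(lam) * t(e$vectors))
  ids <- .defaultIds(v, if (is.matrix(G)) NULL else nodeIds(G))
  similarityMatrix(out, ids)
}

#' Network enhancement (NE)
#'
#' KNN-localized diffusion denoiser. Local kernel:
#' \eqn{P_{ij} = W_{ij} / \sum_{k \in N_i} W_{ik}} restricted to the k
#' nearest (heaviest) neighbours \eqn{N_i} of node i, then
#' \eqn{T_{ij} = \sum_k P_{ik} P_{jk} / \sum_v P_{vk}}, iterating
#' \eqn{W_{t+1} = \alpha T W_t T + (1 - \alpha) T} from \eqn{W_0 = W}.
#'
#' @param W a \linkS4class{WeightMatrix}.
#' @param cfg an \linkS4class{NEConfig}; see \code{\link{neConfig}}.
#' @return a symmetric \linkS4class{WeightMatrix}.
#' @export
neDenoise <- function(W, cfg = neConfig()) {
  stopifnot(is(W, "WeightMatrix"), is(cfg, "NEConfig"))
  v <- W@values
  n <- nrow(v)
  k <- if (is.na(cfg@k)) min(20, n - 1) else cfg@k
  if (k >= n)
    stop("'k' must be smaller than the node count", call. = FALSE)
  P <- .neKernelP(v, k)
  colP <- colSums(P)
  inv <- ifelse(colP > 0, 1 / colP, 0)
  T <- P %*% (inv * t(P))
  Wt <- v
  for (it in seq_len(cfg@iterations))
    Wt <- cfg@alpha * T %*% Wt %*% T + (1 - cfg@alpha) * T
  Wt <- (Wt + t(Wt)) / 2
  Wt[Wt < 0 & Wt > -.NEG_TOL] <- 0
  weightMatrix(Wt, W@nodeIds)
}

.neKernelP <- function(v, k) {
  n <- nrow(v)
  P <- matrix(0, n, n)
  short <- 0L
  for (i in seq_len(n)) {
    w <- v[i, ]
    w[i] <- 0
    pos <- which(w > 0)
    if (!length(pos))
      stop("node ", i, " has no positive-weight neighbour", call. = FALSE)
    if (length(pos) < k) short <- short + 1L
    nb <- pos[order(w[pos], decreasing = TRUE)][seq_len(min(k, length(pos)))]
    P[i, nb] <- w[nb] / sum(w[nb])
  }
  if (short > 0)
    message(short, " node(s) had fewer than k positive-weight neighbours; ",
            "all available neighbours were used")
  P
}

#' Silencing of indirect effects
#'
#' Treats the input correlation matrix C as the global response matrix and
#' solves for the local (direct) response matrix
#' \deqn{S = (C - I + D((C - I) C)) C^{-1},}
#' where D(X) zeroes the off-diagonal of X.
#'
#' @param C a \linkS4class{SimilarityMatrix} with unit diagonal (or matrix).
#' @param ridge apply ridge repair \eqn{C + \delta I} when C is numerically
#'   singular (default FALSE: singularity is a hard error).
#' @param delta ridge magnitude used when \code{ridge = TRUE}.
#' @param symmetrize average S with its transpose (default TRUE; the raw
#'   solution of the silencing equation is not exactly symmetric because the
#'   diagonal-restoring term breaks the symmetry of \eqn{(C-I)C^{-1}}).
#'   FALSE returns the literal solution, which satisfies
#'   \eqn{S C = C - I + D((C-I)C)} to machine precision.
#' @return a \linkS4class{SimilarityMatrix} of direct effects, or a bare
#'   numeric matrix when \code{symmetrize = FALSE}.
#' @export
silencerDenoise <- function(C, ridge = FALSE, delta = 1e-6,
                            symmetrize = TRUE) {
  v <- .simInput(C)
  n <- nrow(v)
  if (max(abs(diag(v) - 1)) > 1e-8)
    stop("the silencer expects a unit-diagonal (correlation-like) matrix",
         call. = FALSE)
  v <- .ensureInvertible(v, ridge, delta)
  I <- diag(n)
  num <- v - I + diag(diag((v - I) %*% v))
  S <- num %*% solve(v)
  ids <- .defaultIds(v, if (is.matrix(C)) NULL else nodeIds(C))
  if (!symmetrize) {
    dimnames(S) <- list(ids, ids)
    return(S)
  }
  similarityMatrix((S + t(S)) / 2, ids)
}

#' Partial correlation / inverse correlation matrix (ICM)
#'
#' Inverts the correlation matrix to the precision matrix \eqn{S = C^{-1}}
#' and rescales to partial correlations
#' \eqn{P_{ij} = -S_{ij} / \sqrt{S_{ii} S_{jj}}} (diagonal 1), removing
#' linear indirect effects mediated by the remaining variables.
#'
#' @inheritParams silencerDenoise
#' @return a symmetric \linkS4class{SimilarityMatrix} with unit diagonal.
#' @export
icmDenoise <- function(C, ridge = FALSE, delta = 1e-6) {
  v <- .simInput(C)
  v <- .ensureInvertible(v, ridge, delta)
  S <- solve(v)
  d <- diag(S)
  if (any(d <= 0))
    stop("precision matrix has non-positive diagonal; input is not a valid ",
         "covariance/correlation structure", call. = FALSE)
  P <- -S / sqrt(outer(d, d))
  diag(P) <- 1
  P <- (P + t(P)) / 2
  ids <- .defaultIds(v, if (is.matrix(C)) NULL else nodeIds(C))
  similarityMatrix(P, ids)
}

.ensureInvertible <- function(v, ridge, delta) {
  if (rcond(v) > 1e-12) return(v)
  if (!ridge)
    stop("input matrix is numerically singular; re-run with ridge = TRUE ",
         "to repair it as C + delta*I", call. = FALSE)
  message("singular input repaired with ridge delta = ", delta)
  v + delta * diag(nrow(v))
}

#' Turn a scored matrix into an edge ranking
#'
#' Emits every unordered node pair (i < j, lexicographic by node index) with
#' its score, the uniform interface feeding the evaluation metrics. Signed
#' scores (silencer / partial correlation) are ranked by absolute value by
#' default, since evaluation concerns edge existence, not sign.
#'
#' @param M a \linkS4class{WeightMatrix}, \linkS4class{SimilarityMatrix} or
#'   symmetric matrix.
#' @param absolute rank by |score| (default TRUE; identity for non-negative
#'   input).
#' @return data.frame with columns nodeA, nodeB, score covering all
#'   \eqn{\binom{n}{2}} pairs.
#' @export
edgeRanking <- function(M, absolute = TRUE) {
  v <- .simInput(M)
  if (max(abs(v - t(v))) > 1e-8)
    stop("edge ranking requires a symmetric matrix", call. = FALSE)
  ids <- .defaultIds(v, if (is.matrix(M)) NULL else nodeIds(M))
  n <- nrow(v)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  score <- v[idx]
  if (absolute) score <- abs(score)
  data.frame(nodeA = ids[idx[, 1]], nodeB = ids[idx[, 2]], score = score,
             stringsAsFactors = FALSE)
}
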