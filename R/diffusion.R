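#' @include accessors.R
NULL

.checkM <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m <= 1)
    stop("'m' must be a single number strictly greater than 1; ",
         "the path-length series diverges otherwise", call. = FALSE)
  as.numeric(m)
}

#' Map a graph to its random walk (operator g)
#'
#' Row-normalizes the adjacency matrix: \eqn{P = D^{-1} W}, where D is the
#' diagonal degree matrix (row sums of W).
#'
#' @param W a \linkS4class{WeightMatrix}.
#' @return the \linkS4class{TransitionMatrix} of the random walk on W.
#' @examples
#' W <- weightMatrix(rbind(c(0, 1, 3), c(1, 0, 0), c(3, 0, 0)))
#' toTransition(W)
#' @export
toTransition <- function(W) {
  stopifnot(is(W, "WeightMatrix"))
  v <- W@values
  d <- rowSums(v)
  bad <- which(d <= 0)
  if (length(bad))
    stop("node(s) with zero degree: ", paste(W@nodeIds[bad], collapse = ", "),
         "; preprocess with eps1, eps2 > 0 first", call. = FALSE)
  transitionMatrix(v / d, W@nodeIds)
}

#' Forward diffusion of a random walk
#'
#' Adds the probability of all paths of length k joining two nodes, each
#' weighted by \eqn{1/m^k}, and renormalizes:
#' \deqn{f_m(P) = (m - 1) P (mI - P)^{-1},}
#' the closed form of the normalized series \eqn{\sum_{k \ge 1} P^k / m^k}.
#' Models how a direct network accumulates transitive (indirect) edge noise.
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param m diffusion intensity, strictly > 1.
#' @return the diffused \linkS4class{TransitionMatrix}.
#' @examples
#' P <- transitionMatrix(rbind(c(0, 1), c(1, 0)))
#' forwardDiffusion(P, m = 4)   # [[0.2, 0.8], [0.8, 0.2]]
#' @export
forwardDiffusion <- function(P, m = 4) {
  stopifnot(is(P, "TransitionMatrix"))
  m <- .checkM(m)
  v <- P@values
  n <- nrow(v)
  out <- tryCatch(
    (m - 1) * v %*% solve(m * diag(n) - v),
    error = function(e) stop("(mI - P) is numerically singular: ",
                             conditionMessage(e), call. = FALSE))
  transitionMatrix(out, P@nodeIds)
}

#' Inverse diffusion of a random walk (the denoising core)
#'
#' Exact functional inverse of \code{\link{forwardDiffusion}}:
#' \deqn{f_m^{-1}(P) = m ((m - 1) I + P)^{-1} P.}
#' Rows sum to one, but entries may be negative when the input walk was not
#' generated by forward diffusion (typically on sparse networks); see
#' \code{\link{clipNegativeRows}}.
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param m diffusion intensity, strictly > 1.
#' @return a \linkS4class{QuasiTransition}.
#' @examples
#' P <- transitionMatrix(rbind(c(0.2, 0.8), c(0.8, 0.2)))
#' inverseDiffusion(P, m = 4)   # recovers [[0, 1], [1, 0]]
#' @export
inverseDiffusion <- function(P, m = 4) {
  stopifnot(is(P, "QuasiTransition"))
  m <- .checkM(m)
  v <- P@values
  n <- nrow(v)
  A <- (m - 1) * diag(n) + v
  out <- tryCatch(
    m * solve(A, v),
    error = function(e) stop("((m - 1)I + P) is numerically singular ",
                             "(reciprocal condition number ",
                             format(rcond(A), digits = 3), "): ",
                             conditionMessage(e), call. = FALSE))
  quasiTransition(out, P@nodeIds)
}

#' Stationary distribution of a random walk
#'
#' Left principal eigenvector of P, normalized to sum one: \eqn{\pi P = \pi}.
#' A dense left eigen-decomposition is used up to \code{denseLimit} nodes and
#' power iteration above.
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param method "eigen", "power", or "auto" (eigen up to denseLimit nodes).
#' @param tol convergence tolerance of the power iteration.
#' @param maxIter iteration cap of the power iteration.
#' @param denseLimit size cutover from dense eigen to power iteration.
#' @return a \linkS4class{StationaryDistribution}.
#' @examples
#' W <- weightMatrix(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
#' stationaryDistribution(toTransition(W))   # uniform 1/3
#' @export
stationaryDistribution <- function(P, method = c("auto", "eigen", "power"),
                                   tol = 1e-12, maxIter = 1e5,
                                   denseLimit = 2000) {
  stopifnot(is(P, "TransitionMatrix"))
  method <- match.arg(method)
  v <- P@values
  n <- nrow(v)
  g <- igraph::graph_from_adjacency_matrix((v > 0) * 1, mode = "directed")
  if (igraph::components(g, mode = "strong")$no > 1)
    stop("the chain is reducible; preprocess the network with eps1 > 0 ",
         "to make it irreducible", call. = FALSE)
  if (method == "auto") method <- if (n <= denseLimit) "eigen" else "power"
  pi <- if (method == "eigen") .statEigen(v) else .statPower(v, tol, maxIter)
  resid <- max(abs(drop(pi %*% v) - pi))
  if (is.null(pi) || resid > 1e-8) {
    pi <- .statPower(v, tol, maxIter)
    resid <- max(abs(drop(pi %*% v) - pi))
    if (resid > 1e-8)
      stop("stationary distribution did not converge (residual ",
           format(resid, digits = 3), ")", call. = FALSE)
  }
  new("StationaryDistribution", values = pi, nodeIds = P@nodeIds)
}

.statEigen <- function(v) {
  e <- eigen(t(v))
  i <- which.max(Re(e$values))
  vec <- Re(e$vectors[, i])
  if (sum(vec) < 0) vec <- -vec
  vec[vec < 0 & vec > -1e-10] <- 0
  if (min(vec) < 0) return(NULL)
  vec / sum(vec)
}

.statPower <- function(v, tol, maxIter) {
  n <- nrow(v)
  pi <- rep(1 / n, n)
  # half-step damping keeps periodic chains from oscillating
  for (it in seq_len(maxIter)) {
    nxt <- 0.5 * drop(pi %*% v) + 0.5 * pi
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi)) < tol) return(nxt)
    pi <- nxt
  }
  stop("power iteration for the stationary distribution did not converge ",
       "within ", maxIter, " iterations", call. = FALSE)
}

#' Map a random walk back to a graph (operator h)
#'
#' Recovers an undirected weighted graph from a transition matrix:
#' \eqn{\alpha \, \mathrm{diag}(\pi(P)) P}, symmetrized as
#' \eqn{(M + M^\top)/2} with the diagonal zeroed. For the reversible walk of
#' a connected graph W with \eqn{\alpha = \sum_{ij} W_{ij}} this inverts
#' \code{\link{toTransition}} exactly.
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param alpha positive constant controlling the total output weight.
#' @param pi optional precomputed \linkS4class{StationaryDistribution}.
#' @return a \linkS4class{WeightMatrix}.
#' @examples
#' W <- weightMatrix(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
#' fromTransition(toTransition(W), alpha = sum(as.matrix(W)))  # recovers W
#' @export
fromTransition <- function(P, alpha, pi = NULL) {
  stopifnot(is(P, "TransitionMatrix"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  if (is.null(pi)) pi <- stationaryDistribution(P)
  M <- alpha * (pi@values * P@values)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M[M < 0 & M > -.NEG_TOL] <- 0
  weightMatrix(M, P@nodeIds)
}

.autoEps <- function(v) {
  nz <- v[v > 0]
  if (!length(nz)) return(1)
  if (max(nz) - min(nz) <= 1e-12 && abs(max(nz) - 1) <= 1e-12) 1 else min(nz)
}

#' Preprocess a network for inverse diffusion
#'
#' Adds a small complete graph and self loops,
#' \eqn{\tilde W = W + \epsilon_1 J + \epsilon_2 I} (J all ones, I identity),
#' making the walk irreducible and taming negative entries of the inverse
#' step. The automatic rule takes \eqn{\epsilon_1 = \epsilon_2 = 1} for an
#' unweighted network and the minimum non-zero weight otherwise.
#'
#' @param W a \linkS4class{WeightMatrix}.
#' @param eps1 off-diagonal offset, or NA/"auto" for the automatic rule.
#' @param eps2 diagonal offset, or NA/"auto" for the automatic rule.
#' @return a \linkS4class{WeightMatrix} (diagonal may be positive), with the
#'   resolved offsets in attributes "eps1" and "eps2" of its values.
#' @export
preprocessNetwork <- function(W, eps1 = NA, eps2 = NA) {
  stopifnot(is(W, "WeightMatrix"))
  eps1 <- .sentinelNum(eps1, "auto")
  eps2 <- .sentinelNum(eps2, "auto")
  v <- W@values
  auto <- .autoEps(v)
  if (is.na(eps1)) eps1 <- auto
  if (is.na(eps2)) eps2 <- auto
  if (eps1 < 0 || eps2 < 0)
    stop("preprocessing offsets must be non-negative", call. = FALSE)
  out <- v + eps1
  diag(out) <- diag(v) + eps1 + eps2
  res <- weightMatrix(out, W@nodeIds)
  attr(res@values, "eps1") <- eps1
  attr(res@values, "eps2") <- eps2
  res
}

#' Remove negative entries of an inverse-diffused walk
#'
#' Per-row correction: rows containing an entry below \code{-tol} are shifted
#' by subtracting their smallest (negative) value from every entry of the
#' row; other rows are untouched. After the shift a corrected row sums to
#' \eqn{1 - n\beta_i} rather than 1.
#'
#' @param P a \linkS4class{QuasiTransition}.
#' @param tol entries above \code{-tol} count as zero (floating-point guard).
#' @return a non-negative \linkS4class{QuasiTransition}.
#' @examples
#' q <- quasiTransition(rbind(c(0.5, -0.2, 0.7), c(0.1, 0.8, 0.1),
#'                            c(0, 0, 1)))
#' as.matrix(clipNegativeRows(q))
#' @export
clipNegativeRows <- function(P, tol = 1e-12) {
  stopifnot(is(P, "QuasiTransition"))
  v <- P@values
  beta <- pmin(apply(v, 1, min), 0)
  beta[beta > -tol] <- 0
  v <- v - beta           # beta recycled column-wise: subtracts per row
  v[v < 0] <- 0           # residual -0-level dust
  quasiTransition(v, P@nodeIds)
}
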