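# shared fixture builders (all generated in code; no stored data)

cycleAdj <- function(n) {
  A <- matrix(0, n, n)
  i <- seq_len(n)
  j <- c(seq_len(n)[-1], 1L)
  A[cbind(i, j)] <- 1
  A[cbind(j, i)] <- 1
  A
}

# random row-stochastic matrix (not necessarily reversible)
randomStochastic <- function(n) {
  v <- matrix(stats::runif(n * n), n, n)
  v / rowSums(v)
}

# random connected weighted undirected graph with positive weights
randomConnectedGraph <- function(n, p = 0.25) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < p]
    A[on] <- stats::runif(length(on), 0.2, 2)
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "undirected")
    if (igraph::is_connected(g)) return(A)
  }
}

# brute-force truncated diffusion series sum_{k=1..K} P^k/m^k, normalized
seriesDiffusion <- function(P, m, K = 60) {
  n <- nrow(P)
  acc <- matrix(0, n, n)
  Pk <- diag(n)
  norm <- 0
  for (k in seq_len(K)) {
    Pk <- Pk %*% P
    acc <- acc + Pk / m^k
    norm <- norm + 1 / m^k
  }
  acc / norm
}
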