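#' @include accessors.R
NULL

.INJECT_SEED_OFFSET <- 1000003L

#' Generate a ground-truth graph
#'
#' Builds the unweighted true network underlying a simulation: an n-cycle
#' ("circular"), an Erdos-Renyi G(n, p) graph ("er"), or a Barabasi-Albert
#' preferential-attachment graph ("ba", complete seed on e + 1 nodes, each
#' subsequent node attaching e distinct edges with probability proportional
#' to degree). ER graphs are regenerated with an incremented seed until
#' connected (a message reports each regeneration).
#'
#' @param spec a \linkS4class{NoisySimSpec}.
#' @return a unit-weight \linkS4class{WeightMatrix}.
#' @examples
#' makeTrueGraph(simSpec("circular", n = 20, seed = 1))
#' @export
makeTrueGraph <- function(spec) {
  stopifnot(is(spec, "NoisySimSpec"))
  n <- spec@n
  A <- switch(spec@topology,
    circular = {
      A <- matrix(0, n, n)
      i <- seq_len(n)
      j <- c(seq_len(n)[-1], 1L)
      A[cbind(i, j)] <- 1
      A[cbind(j, i)] <- 1
      A
    },
    er = .erConnected(n, spec@p, spec@seed),
    ba = .baGraph(n, spec@e, spec@seed))
  weightMatrix(A, sprintf("v%d", seq_len(n)))
}

.erConnected <- function(n, p, seed) {
  s <- seed
  repeat {
    set.seed(s)
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
    s <- s + 1
    message("ER draw disconnected; regenerating with seed ", s)
  }
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

.baGraph <- function(n, e, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  seedN <- e + 1
  A[seq_len(seedN), seq_len(seedN)] <- 1
  diag(A) <- 0
  for (v in seq(seedN + 1, n)) {
    deg <- rowSums(A[seq_len(v - 1), , drop = FALSE])
    tgt <- seq_len(v - 1)[sample.int(v - 1, e, prob = deg)]
    A[v, tgt] <- 1
    A[tgt, v] <- 1
  }
  A
}

#' Inject indirect-noise edges into a true network
#'
#' Adds spurious edges between non-adjacent node pairs with probability
#' proportional to a path-proximity score
#' \eqn{s_{ij} = \sum_{k=2}^{K} (A^k)_{ij} / d^k} (A the binary adjacency,
#' d the decay base, K = maxPathLen): the more and the shorter the paths
#' joining two nodes, the likelier a noise edge between them. The number of
#' added edges is \code{round(q/(1-q) * |E|)} so that noise edges form the
#' requested proportion q of the noisy network. Added edges carry the mean
#' existing edge weight. Pairs with zero score are only used (uniformly, with
#' a message) when the quota cannot otherwise be met.
#'
#' @param Wtrue a connected \linkS4class{WeightMatrix} ground truth.
#' @param spec a \linkS4class{NoisySimSpec} (noiseProportion, decay,
#'   maxPathLen, seed are used).
#' @param kernel "count" (the default) scores candidate pairs by binary
#'   adjacency powers \eqn{A^k}; "walk" uses powers of the degree-normalized
#'   transition matrix instead, weighting paths the way the random-walk
#'   diffusion model does.
#' @return a \linkS4class{LabeledNetwork} whose signal edges reproduce
#'   \code{Wtrue} exactly.
#' @export
injectIndirectNoise <- function(Wtrue, spec, kernel = c("count", "walk")) {
  kernel <- match.arg(kernel)
  stopifnot(is(Wtrue, "WeightMatrix"), is(spec, "NoisySimSpec"))
  v <- Wtrue@values
  n <- nrow(v)
  A <- (v > 0) * 1
  nTrue <- sum(A[upper.tri(A)])
  q <- spec@noiseProportion
  quota <- round(q / (1 - q) * nTrue)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  free <- ut[A[ut] == 0, , drop = FALSE]
  if (quota > nrow(free)) {
    maxProp <- nrow(free) / (nrow(free) + nTrue)
    stop(sprintf(paste0("requested noise proportion %.3f needs %d new edges ",
                        "but only %d non-adjacent pairs exist (maximum ",
                        "achievable proportion %.3f)"),
                 q, quota, nrow(free), maxProp), call. = FALSE)
  }
  chosen <- matrix(integer(0), 0, 2)
  if (quota > 0) {
    B <- if (kernel == "count") A else A / rowSums(A)
    Bk <- B %*% B
    S <- Bk / spec@decay^2
    k <- 2
    while (k < spec@maxPathLen) {
      k <- k + 1
      Bk <- Bk %*% B
      S <- S + Bk / spec@decay^k
    }
    S <- (S + t(S)) / 2
    sc <- S[free]
    set.seed(spec@seed + .INJECT_SEED_OFFSET)
    pos <- which(sc > 0)
    if (quota <= length(pos)) {
      pick <- pos[sample.int(length(pos), quota, prob = sc[pos])]
    } else {
      message("path-proximity scores cover only ", length(pos),
              " candidate pairs; filling the quota uniformly")
      zero <- which(sc == 0)
      pick <- c(pos, zero[sample.int(length(zero), quota - length(pos))])
    }
    chosen <- free[pick, , drop = FALSE]
  }
  wNoise <- mean(v[v > 0])
  out <- v
  out[chosen] <- wNoise
  out[chosen[, c(2, 1), drop = FALSE]] <- wNoise
  sig <- ut[A[ut] == 1, , drop = FALSE]
  ids <- Wtrue@nodeIds
  labels <- rbind(
    data.frame(nodeA = ids[sig[, 1]], nodeB = ids[sig[, 2]],
               label = rep("signal", nrow(sig)), stringsAsFactors = FALSE),
    data.frame(nodeA = ids[chosen[, 1]], nodeB = ids[chosen[, 2]],
               label = rep("noise", nrow(chosen)), stringsAsFactors = FALSE))
  new("LabeledNetwork", weights = weightMatrix(out, ids), labels = labels,
      meta = list(topology = spec@topology, noiseProportion = q,
                  seed = spec@seed, nSignal = nTrue, nNoise = quota))
}

#' Sweep noise proportions with replicates
#'
#' Generates a grid of labelled noisy networks: for proportion index i and
#' replicate index j, the seed is \code{base + 1000 * i + j}, so the whole
#' sweep is reproducible from one base seed. A fresh true graph is drawn for
#' every replicate.
#'
#' @param specBase a \linkS4class{NoisySimSpec} template (its seed is the
#'   base seed).
#' @param proportions numeric vector of noise proportions.
#' @param replicates replicate count per proportion.
#' @return list of \linkS4class{LabeledNetwork}, proportion-major order.
#' @export
noiseSweep <- function(specBase, proportions, replicates = 1) {
  stopifnot(is(specBase, "NoisySimSpec"), length(proportions) >= 1,
            replicates >= 1)
  out <- vector("list", length(proportions) * replicates)
  idx <- 0L
  for (i in seq_along(proportions)) {
    for (j in seq_len(replicates)) {
      sp <- specBase
      sp@noiseProportion <- proportions[i]
      sp@seed <- specBase@seed + 1000 * i + j
      idx <- idx + 1L
      out[[idx]] <- injectIndirectNoise(makeTrueGraph(sp), sp)
    }
  }
  out
}
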