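#' @include baselines.R netsim.R rendor.R
NULL

.checkLabels <- function(scores, labels, needNeg = TRUE) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("'labels' must be 0/1", call. = FALSE)
  if (sum(labels) == 0)
    stop("no positive labels: the metric is undefined", call. = FALSE)
  if (needNeg && sum(labels) == length(labels))
    stop("no negative labels: the metric is undefined", call. = FALSE)
}

#' Area under the ROC curve of an edge ranking
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' pair outranks a uniformly chosen negative pair, ties counted 1/2.
#'
#' @param scores numeric edge confidence scores.
#' @param labels 0/1 truth labels aligned with \code{scores}.
#' @return AUROC in [0, 1].
#' @examples
#' aurocScore(c(0.9, 0.8, 0.3), c(1, 0, 1))   # 0.5
#' @export
aurocScore <- function(scores, labels) {
  .checkLabels(scores, labels)
  r <- rank(scores, ties.method = "average")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve of an edge ranking
#'
#' Step-wise, non-interpolated area over descending unique score thresholds
#' (average-precision style): at each threshold the step in recall is
#' multiplied by the precision reached there.
#'
#' @inheritParams aurocScore
#' @return AUPR in [0, 1].
#' @export
auprScore <- function(scores, labels) {
  .checkLabels(scores, labels, needNeg = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  cumTP <- cumsum(l)
  npred <- seq_along(l)
  # keep only the last index of each tied score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumTP[last]; np <- npred[last]
  prec <- tp / np
  rec <- tp / sum(labels)
  sum(diff(c(0, rec)) * prec)
}

#' Confusion counts at a top-k cutoff
#'
#' Predicts positive for the k highest-scored pairs (ties broken by the
#' stable input order, which is lexicographic node-pair order for rankings
#' produced by \code{\link{edgeRanking}}) and negative otherwise.
#'
#' @inheritParams aurocScore
#' @param k number of pairs predicted positive, between 1 and
#'   \code{length(scores)}.
#' @return named vector (TP, FP, TN, FN, f1).
#' @export
confusionAtK <- function(scores, labels, k) {
  .checkLabels(scores, labels, needNeg = FALSE)
  n <- length(scores)
  if (k < 1 || k > n)
    stop("'k' must lie between 1 and the number of pairs (", n, ")",
         call. = FALSE)
  top <- order(-scores)[seq_len(k)]
  tp <- sum(labels[top] == 1)
  fp <- k - tp
  fn <- sum(labels == 1) - tp
  tn <- n - k - fn
  c(TP = tp, FP = fp, TN = tn, FN = fn,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
}

#' True-positive counts along a cutoff grid
#'
#' @inheritParams confusionAtK
#' @param ks ascending integer cutoffs.
#' @return data.frame with columns k and TP (monotone nondecreasing).
#' @export
tpCurve <- function(scores, labels, ks) {
  if (is.unsorted(ks)) stop("'ks' must be sorted ascending", call. = FALSE)
  tp <- vapply(ks, function(k) unname(confusionAtK(scores, labels, k)["TP"]),
               numeric(1))
  data.frame(k = ks, TP = tp)
}

#' Truth labels of a labelled network over the full pair universe
#'
#' @param net a \linkS4class{LabeledNetwork}.
#' @param ranking a ranking data.frame (nodeA, nodeB, score) as produced by
#'   \code{\link{edgeRanking}}; defaults to the ranking of the noisy weights.
#' @return 0/1 vector aligned with \code{ranking}: 1 for signal (true) edges,
#'   0 for noise and absent pairs.
#' @export
truthVector <- function(net, ranking = edgeRanking(noisyWeights(net))) {
  stopifnot(is(net, "LabeledNetwork"))
  lb <- net@labels
  sig <- lb[lb$label == "signal", , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  as.integer(key(ranking$nodeA, ranking$nodeB) %in% key(sig$nodeA, sig$nodeB))
}

.asCorrelationLike <- function(W, radius = 0.95) {
  # I + lambda*W with lambda shrunk so the result is positive definite:
  # the correlation-like input the silencer/partial-correlation methods
  # expect when handed a bare adjacency matrix
  v <- W@values
  mx <- max(v)
  if (mx > 0) v <- v / mx
  diag(v) <- 0
  rho <- max(abs(eigen(v, symmetric = TRUE, only.values = TRUE)$values))
  if (rho >= radius) v <- v * (radius / rho)
  diag(v) <- 1
  similarityMatrix(v, W@nodeIds, correlation = TRUE)
}

#' Built-in denoiser registry for benchmarking
#'
#' Returns a named list of functions WeightMatrix -> scored symmetric matrix.
#' "input" is the identity pass-through. The silencer and partial-correlation
#' methods receive the weights rescaled to max 1 with unit diagonal (a
#' correlation-like matrix), with ridge repair enabled, since they are
#' defined on correlation inputs.
#'
#' @param m diffusion intensity for the diffusion-based methods.
#' @param neCfg an \linkS4class{NEConfig} for network enhancement.
#' @return named list of denoiser closures.
#' @export
denoiserRegistry <- function(m = 4, neCfg = neConfig()) {
  list(
    input = function(W) W,
    rendor = function(W) rendorDenoise(W, denoiseConfig(m = m)),
    nd = function(W) ndDenoise(W),
    ne = function(W) neDenoise(W, neCfg),
    silencer = function(W) silencerDenoise(.asCorrelationLike(W), ridge = TRUE),
    icm = function(W) icmDenoise(.asCorrelationLike(W), ridge = TRUE)
  )
}

#' Benchmark denoisers on labelled noisy networks
#'
#' Applies each method to each network, ranks all node pairs, scores the
#' ranking against the signal edges, and aggregates by method, topology and
#' noise proportion. Method failures are recorded as NA cells, never fatal.
#'
#' @param networks list of \linkS4class{LabeledNetwork} (e.g. from
#'   \code{\link{noiseSweep}}).
#' @param methods named list of denoiser functions, or a character subset of
#'   the names of \code{\link{denoiserRegistry}}.
#' @param m diffusion intensity passed to the registry when \code{methods}
#'   is a character vector.
#' @param universe "all": score every node pair, absent pairs as negatives
#'   (the default; the denoised matrix is complete). "edges": restrict to
#'   the noisy network's own edges, classifying signal against injected
#'   noise (the undenoised input is uninformative there by construction).
#' @return list with elements \code{perNetwork} (one row per method and
#'   network: auroc, aupr) and \code{summary} (method x topology x
#'   proportion x metric: mean, sd, replicates).
#' @export
benchmarkDenoisers <- function(networks, methods = names(denoiserRegistry()),
                               m = 4, universe = c("all", "edges")) {
  stopifnot(length(networks) >= 1, length(methods) >= 1)
  universe <- match.arg(universe)
  if (is.character(methods)) {
    reg <- denoiserRegistry(m = m)
    bad <- setdiff(methods, names(reg))
    if (length(bad))
      stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
    methods <- reg[methods]
  }
  rows <- list()
  for (ni in seq_along(networks)) {
    net <- networks[[ni]]
    W <- noisyWeights(net)
    baseRank <- edgeRanking(W)
    keep <- if (universe == "edges") baseRank$score > 0
            else rep(TRUE, nrow(baseRank))
    truth <- truthVector(net, baseRank)[keep]
    for (mn in names(methods)) {
      res <- tryCatch({
        out <- methods[[mn]](W)
        r <- edgeRanking(out)
        if (!identical(r$nodeA, baseRank$nodeA))
          stop("method permuted the node universe")
        sc <- r$score[keep]
        c(auroc = aurocScore(sc, truth),
          aupr = auprScore(sc, truth))
      }, error = function(e) {
        message("method '", mn, "' failed on network ", ni, ": ",
                conditionMessage(e))
        c(auroc = NA_real_, aupr = NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        method = mn,
        topology = net@meta$topology %||% NA_character_,
        proportion = net@meta$noiseProportion %||% NA_real_,
        network = ni, auroc = res[["auroc"]], aupr = res[["aupr"]],
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  agg <- list()
  for (metric in c("auroc", "aupr")) {
    sp <- split(per, list(per$method, per$topology, per$proportion),
                drop = TRUE)
    for (cell in sp) {
      agg[[length(agg) + 1L]] <- data.frame(
        method = cell$method[1], topology = cell$topology[1],
        proportion = cell$proportion[1], metric = metric,
        mean = mean(cell[[metric]], na.rm = TRUE),
        sd = stats::sd(cell[[metric]]),
        replicates = sum(!is.na(cell[[metric]])),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, agg)
  summary <- summary[order(summary$metric, summary$topology,
                           summary$proportion, summary$method), ]
  rownames(summary) <- NULL
  list(perNetwork = per, summary = summary)
}
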