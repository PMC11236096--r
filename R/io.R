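#' @include accessors.R
NULL

.atomicWrite <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

.readTsv <- function(path, header) {
  read.delim(path, header = header, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "#")
}

.detectHeader <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
}

#' Read an undirected network from a file
#'
#' Supports three-column edge lists (nodeA, nodeB, weight; the weight column
#' may be omitted, defaulting to 1; a header is auto-detected) and dense
#' adjacency matrices with node ids as the header row and first column.
#' Node order is first appearance for edge lists and header order for
#' adjacency input.
#'
#' @param path file path.
#' @param format "auto", "edge_list" or "adjacency".
#' @param symmetrize average an asymmetric adjacency input instead of
#'   erroring (default FALSE; asymmetry beyond 1e-8 is an error).
#' @param defaultWeight weight for edge lists without a weight column.
#' @return a \linkS4class{WeightMatrix}.
#' @export
readNetwork <- function(path, format = c("auto", "edge_list", "adjacency"),
                        symmetrize = FALSE, defaultWeight = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    format <- if (length(first) > 3) "adjacency" else "edge_list"
  }
  if (format == "adjacency") return(.readAdjacency(path, symmetrize))
  .readEdgeList(path, defaultWeight)
}

.readEdgeList <- function(path, defaultWeight) {
  header <- .detectHeader(path)
  df <- .readTsv(path, header)
  if (ncol(df) < 2) stop("edge list needs at least 2 columns", call. = FALSE)
  a <- as.character(df[[1]])
  b <- as.character(df[[2]])
  w <- if (ncol(df) >= 3) suppressWarnings(as.numeric(df[[3]]))
       else rep(defaultWeight, length(a))
  if (anyNA(w))
    stop("non-numeric weight on line ", which(is.na(w))[1] + header,
         call. = FALSE)
  neg <- which(w < 0)
  if (length(neg))
    stop("negative weight on line ", neg[1] + header, call. = FALSE)
  self <- which(a == b)
  if (length(self))
    stop("self-edge on line ", self[1] + header, call. = FALSE)
  ids <- unique(c(rbind(a, b)))
  n <- length(ids)
  if (n < 2) stop("network needs at least 2 nodes", call. = FALSE)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(a)) {
    if (a[i] == b[i]) stop("self-edge on line ", i + header, call. = FALSE)
    key <- paste(min(a[i], b[i]), max(a[i], b[i]), sep = "\r")
    prev <- seen[[key]]
    if (!is.null(prev)) {
      if (abs(prev - w[i]) > 1e-12)
        stop("duplicate pair ", a[i], "-", b[i],
             " with conflicting weights (", prev, " vs ", w[i], ")",
             call. = FALSE)
      warning("duplicate pair ", a[i], "-", b[i], " with equal weight; ",
              "keeping one copy", call. = FALSE)
    }
    seen[[key]] <- w[i]
    v[a[i], b[i]] <- w[i]
    v[b[i], a[i]] <- w[i]
  }
  weightMatrix(v, ids)
}

.readAdjacency <- function(path, symmetrize) {
  df <- .readTsv(path, header = TRUE)
  ids <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  if (nrow(v) != ncol(v))
    stop("adjacency input is not square", call. = FALSE)
  if (!identical(ids, colnames(v)))
    stop("adjacency row ids do not match column ids", call. = FALSE)
  asym <- max(abs(v - t(v)))
  if (asym > 1e-8) {
    if (!symmetrize)
      stop("adjacency input is asymmetric (max |A - t(A)| = ",
           format(asym, digits = 3),
           "); pass symmetrize = TRUE to average", call. = FALSE)
    v <- (v + t(v)) / 2
  }
  if (min(v) < 0) stop("negative weights in adjacency input", call. = FALSE)
  weightMatrix(v, ids)
}

#' Write a network to a file (atomically)
#'
#' @param W a \linkS4class{WeightMatrix}.
#' @param path output path; written via a temporary file and rename.
#' @param format "edge_list" (upper-triangle positive-weight pairs) or
#'   "adjacency" (dense matrix with id header).
#' @return the path, invisibly.
#' @export
writeNetwork <- function(W, path, format = c("edge_list", "adjacency")) {
  stopifnot(is(W, "WeightMatrix"))
  format <- match.arg(format)
  v <- W@values
  ids <- W@nodeIds
  .atomicWrite(path, function(tmp) {
    if (format == "edge_list") {
      idx <- which(upper.tri(v) & v > 0, arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      df <- data.frame(nodeA = ids[idx[, 1]], nodeB = ids[idx[, 2]],
                       weight = v[idx])
      write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      df <- data.frame(id = ids, v, check.names = FALSE)
      colnames(df) <- c("id", ids)
      write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
}

#' Write a labelled network as an edge-list/label file pair
#'
#' @param net a \linkS4class{LabeledNetwork}.
#' @param edgePath path of the (nodeA, nodeB, weight) TSV.
#' @param labelPath path of the (nodeA, nodeB, label) TSV.
#' @return invisibly, c(edgePath, labelPath).
#' @export
writeLabeledNetwork <- function(net, edgePath, labelPath) {
  stopifnot(is(net, "LabeledNetwork"))
  writeNetwork(noisyWeights(net), edgePath, "edge_list")
  .atomicWrite(labelPath, function(tmp) {
    write.table(edgeLabels(net), tmp, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  invisible(c(edgePath, labelPath))
}

#' Read a DREAM-style gold standard
#'
#' Three columns: regulator, target, 0/1 label. Directed entries are
#' symmetrized (an unordered pair is positive if either direction is),
#' matching the undirected denoiser output.
#'
#' @param path file path.
#' @return data.frame with columns nodeA, nodeB, label (0/1), one row per
#'   unordered pair present in the file.
#' @export
readGoldStandard <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- .detectHeader(path)
  df <- .readTsv(path, header)
  if (ncol(df) < 3) stop("gold standard needs 3 columns", call. = FALSE)
  lab <- suppressWarnings(as.integer(df[[3]]))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("gold-standard labels must be 0/1", call. = FALSE)
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  ka <- pmin(a, b); kb <- pmax(a, b)
  key <- paste(ka, kb, sep = "\r")
  agg <- tapply(lab, key, max)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(nodeA = parts[, 1], nodeB = parts[, 2],
                    label = as.integer(agg), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$nodeA, out$nodeB), ]
}

#' Zero-pad a rectangular weight matrix to square form
#'
#' Regulator-by-target (e.g. TF-by-gene) score matrices are completed over
#' the union of row and column ids, missing entries set to zero, and
#' symmetrized by the elementwise maximum of the two directed entries.
#'
#' @param M numeric matrix (rows: regulators, columns: targets).
#' @param rowIds,colIds id vectors; default to the dimnames of M.
#' @return a square \linkS4class{WeightMatrix} over the id union.
#' @export
padToSquare <- function(M, rowIds = rownames(M), colIds = colnames(M)) {
  M <- as.matrix(M)
  if (is.null(rowIds) || is.null(colIds))
    stop("row and column ids are required", call. = FALSE)
  if (anyDuplicated(rowIds) || anyDuplicated(colIds))
    stop("duplicate ids in rows or columns", call. = FALSE)
  if (length(rowIds) != nrow(M) || length(colIds) != ncol(M))
    stop("id lengths do not match the matrix dimensions", call. = FALSE)
  ids <- unique(c(rowIds, colIds))
  n <- length(ids)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  v[rowIds, colIds] <- M
  v <- pmax(v, t(v))
  if (min(v) < 0) stop("negative weights are not supported", call. = FALSE)
  weightMatrix(v, ids)
}
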