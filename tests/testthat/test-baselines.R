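test_that("deconvolution reweights eigenvalues by lambda/(1+lambda)", {
  set.seed(2)
  v <- rnorm(5)
  vhat <- v / sqrt(sum(v^2))
  G <- similarityMatrix(vhat %*% t(vhat))    # rank one, eigenvalue 1
  out <- as.matrix(ndDenoise(G, scale = NULL))
  expect_equal(out, 0.5 * vhat %*% t(vhat), tolerance = 1e-10,
               ignore_attr = TRUE)           # 1 -> 0.5; null space 0 -> 0
  # with rescaling, the output spectral radius equals `scale`
  set.seed(4)
  M <- crossprod(matrix(rnorm(36), 6, 6)) / 6
  outS <- as.matrix(ndDenoise(similarityMatrix(M), scale = 0.9))
  expect_equal(max(abs(eigen(outS, symmetric = TRUE)$values)), 0.9,
               tolerance = 1e-10)
  expect_error(ndDenoise(similarityMatrix(M), scale = 1.2), "0, 1")
  expect_error(ndDenoise(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("deconvolution commutes with node permutation", {
  set.seed(8)
  M <- crossprod(matrix(rnorm(49), 7, 7)) / 7
  perm <- sample(7)
  Pm <- diag(7)[perm, ]
  lhs <- as.matrix(ndDenoise(similarityMatrix(Pm %*% M %*% t(Pm))))
  rhs <- Pm %*% as.matrix(ndDenoise(similarityMatrix(M))) %*% t(Pm)
  expect_equal(lhs, rhs, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("enhancement kernel is row-normalized over the k nearest neighbours", {
  set.seed(14)
  A <- randomConnectedGraph(12, p = 0.5)
  W <- weightMatrix(A)
  # alpha = 0 and one iteration degenerate the update to T itself
  T1 <- as.matrix(neDenoise(W, neConfig(k = 4, alpha = 0, iterations = 1)))
  # rebuild P and T independently from the definitions
  n <- nrow(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- A[i, ]
    nb <- order(w, decreasing = TRUE)[seq_len(4)]
    nb <- nb[w[nb] > 0]
    P[i, nb] <- w[nb] / sum(w[nb])
  }
  expect_equal(rowSums(P), rep(1, n))        # P rows sum to one by construction
  Tref <- matrix(0, n, n)
  cs <- colSums(P)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    kk <- which(cs > 0)
    Tref[i, j] <- sum(P[i, kk] * P[j, kk] / cs[kk])
  }
  expect_equal(T1, (Tref + t(Tref)) / 2, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(neDenoise(W, neConfig(k = 12)), "smaller")
})

test_that("enhancement concentrates weight within dense blocks", {
  # two 5-cliques bridged by weak edges
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1
  diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 0.1
  A[1, 10] <- A[10, 1] <- 0.1
  W <- weightMatrix(A)
  blockMass <- function(v) {
    within <- sum(v[1:5, 1:5]) + sum(v[6:10, 6:10])
    within / sum(v)
  }
  out <- suppressMessages(as.matrix(neDenoise(W, neConfig(k = 4))))
  expect_gte(blockMass(out), blockMass(A))
})

test_that("silencer matches its closed form on small cases", {
  expect_equal(as.matrix(silencerDenoise(similarityMatrix(diag(4)))),
               matrix(0, 4, 4), tolerance = 1e-12, ignore_attr = TRUE)
  # 2x2 correlation: S has off-diagonal exactly r
  r <- 0.5
  C <- similarityMatrix(rbind(c(1, r), c(r, 1)), correlation = TRUE)
  expect_equal(as.matrix(silencerDenoise(C)), rbind(c(0, r), c(r, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # definitional residual on an AR(1) correlation structure, where the
  # long-range correlations are genuinely transitive
  n <- 10
  Cv <- 0.6^abs(outer(seq_len(n), seq_len(n), "-"))
  S <- silencerDenoise(similarityMatrix(Cv, correlation = TRUE),
                       symmetrize = FALSE)
  target <- Cv - diag(n) + diag(diag((Cv - diag(n)) %*% Cv))
  expect_lt(max(abs(S %*% Cv - target)), 1e-8)
  # silencing strips the indirect chain correlations
  Ssym <- as.matrix(silencerDenoise(similarityMatrix(Cv,
                                                     correlation = TRUE)))
  off <- upper.tri(Cv)
  expect_lte(mean(abs(Ssym[off])), mean(abs(Cv[off])))
})

test_that("partial correlation inverts and rescales the correlation matrix", {
  expect_equal(as.matrix(icmDenoise(similarityMatrix(diag(3)))), diag(3),
               tolerance = 1e-12, ignore_attr = TRUE)
  r <- 0.42
  C <- similarityMatrix(rbind(c(1, r), c(r, 1)), correlation = TRUE)
  out <- as.matrix(icmDenoise(C))
  expect_equal(out[1, 2], r, tolerance = 1e-12)
  expect_identical(unname(diag(out)), c(1, 1))
  # chain X -> Y -> Z: the X-Z partial correlation vanishes
  rxy <- 0.6; ryz <- 0.6
  C3 <- similarityMatrix(rbind(c(1, rxy, rxy * ryz),
                               c(rxy, 1, ryz),
                               c(rxy * ryz, ryz, 1)), correlation = TRUE)
  out3 <- as.matrix(icmDenoise(C3))
  expect_lt(abs(out3[1, 3]), 1e-12)
  expect_identical(out3, t(out3))
})

test_that("singular similarity input is a hard error unless ridge repair is chosen", {
  sing <- similarityMatrix(matrix(1, 3, 3))
  expect_error(icmDenoise(sing), "ridge")
  expect_error(silencerDenoise(sing), "ridge")
  expect_message(icmDenoise(sing, ridge = TRUE), "ridge")
})

test_that("edge ranking emits each unordered pair once, by |score| for signed input", {
  M <- similarityMatrix(rbind(c(0, 0.2, -0.9), c(0.2, 0, 0.4),
                              c(-0.9, 0.4, 0)),
                        nodeIds = c("a", "b", "c"))
  r <- edgeRanking(M)
  expect_equal(nrow(r), 3)
  expect_equal(r$score[r$nodeA == "a" & r$nodeB == "c"], 0.9)
  rRaw <- edgeRanking(M, absolute = FALSE)
  expect_equal(rRaw$score[rRaw$nodeA == "a" & rRaw$nodeB == "c"], -0.9)
  # relabeling-consistent: permuting rows/cols permutes pairs, not scores
  perm <- c(3, 1, 2)
  Mp <- similarityMatrix(as.matrix(M)[perm, perm],
                         nodeIds = c("c", "a", "b"))
  rp <- edgeRanking(Mp)
  key <- function(d) paste(pmin(d$nodeA, d$nodeB), pmax(d$nodeA, d$nodeB))
  expect_equal(rp$score[order(key(rp))], r$score[order(key(r))])
})
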