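test_that("toTransition row-normalizes by degree", {
  P <- toTransition(weightMatrix(cycleAdj(3)))
  expect_equal(as.matrix(P),
               rbind(c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)),
               ignore_attr = TRUE)
  P2 <- toTransition(weightMatrix(rbind(c(0, 1), c(1, 0))))
  expect_equal(as.matrix(P2), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
  # path a-b-c with weights 1 and 3: middle row splits 1/4, 3/4
  W <- weightMatrix(rbind(c(0, 1, 0), c(1, 0, 3), c(0, 3, 0)),
                    nodeIds = c("a", "b", "c"))
  expect_equal(as.matrix(toTransition(W))[2, ], c(a = 0.25, b = 0, c = 0.75))
  # isolated node is an error naming the node
  W0 <- weightMatrix(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)),
                     nodeIds = c("a", "b", "lonely"))
  expect_error(toTransition(W0), "lonely")
})

test_that("forward diffusion matches the closed form and its hand-worked case", {
  P <- transitionMatrix(rbind(c(0, 1), c(1, 0)))
  # (m-1)P(mI-P)^-1 = 1/(m+1) [[1, m], [m, 1]] for the 2-node swap walk
  out <- forwardDiffusion(P, m = 4)
  expect_equal(as.matrix(out), rbind(c(0.2, 0.8), c(0.8, 0.2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identity walk is a fixed point
  I5 <- transitionMatrix(diag(5))
  expect_equal(as.matrix(forwardDiffusion(I5, 4)), diag(5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # huge m: the single-step term dominates
  set.seed(11)
  Pr <- transitionMatrix(randomStochastic(8))
  expect_lt(max(abs(as.matrix(forwardDiffusion(Pr, 1e6)) - as.matrix(Pr))),
            1e-5)
  expect_error(forwardDiffusion(Pr, 1), "greater than 1")
  expect_error(forwardDiffusion(Pr, 0.3), "greater than 1")
})

test_that("closed form equals the truncated path series", {
  set.seed(42)
  for (n in c(5, 20, 50)) {
    P <- randomStochastic(n)
    for (m in c(2, 4, 10)) {
      closed <- as.matrix(forwardDiffusion(transitionMatrix(P), m))
      expect_lt(max(abs(closed - seriesDiffusion(P, m, K = 60))), 1e-10)
    }
  }
})

test_that("inverse diffusion inverts forward diffusion and conserves row sums", {
  P <- transitionMatrix(rbind(c(0.2, 0.8), c(0.8, 0.2)))
  expect_equal(as.matrix(inverseDiffusion(P, 4)), rbind(c(0, 1), c(1, 0)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.matrix(inverseDiffusion(transitionMatrix(diag(4)), 4)),
               diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(7)
  for (m in c(2, 4, 10)) {
    P <- randomStochastic(50)
    fwd <- as.matrix(forwardDiffusion(transitionMatrix(P), m))
    back <- as.matrix(inverseDiffusion(transitionMatrix(fwd), m))
    expect_lt(max(abs(back - P)), 1e-8)
    # other composition order, through a quasi-transition
    q <- inverseDiffusion(transitionMatrix(P), m)
    expect_lt(max(abs(rowSums(as.matrix(q)) - 1)), 1e-10)
    qfwd <- (m - 1) * as.matrix(q) %*% solve(m * diag(50) - as.matrix(q))
    expect_lt(max(abs(qfwd - P)), 1e-8)
  }
  expect_error(inverseDiffusion(transitionMatrix(diag(3)), 1),
               "greater than 1")
})

test_that("stationary distribution is the left fixed point", {
  # doubly stochastic walk on a cycle: uniform
  pc <- stationaryDistribution(toTransition(weightMatrix(cycleAdj(3))))
  expect_equal(unname(as.vector(pc)), rep(1 / 3, 3), tolerance = 1e-12)
  # path graph: proportional to degree (1, 2, 1)
  W <- weightMatrix(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  pp <- stationaryDistribution(toTransition(W))
  expect_equal(unname(as.vector(pp)), c(0.25, 0.5, 0.25), tolerance = 1e-10)
  # random irreducible chain vs an independent power-iteration oracle
  set.seed(5)
  P <- randomStochastic(20)
  pi <- as.vector(stationaryDistribution(transitionMatrix(P)))
  expect_lt(max(abs(drop(pi %*% P) - pi)), 1e-8)
  ref <- rep(1 / 20, 20)
  for (i in seq_len(1e4)) ref <- drop(ref %*% P)
  expect_equal(unname(pi), ref / sum(ref), tolerance = 1e-8)
  # power method agrees with the eigen route
  pw <- as.vector(stationaryDistribution(transitionMatrix(P),
                                         method = "power"))
  expect_equal(unname(pw), unname(pi), tolerance = 1e-8)
  # reducible chain is rejected with advice
  Pred <- transitionMatrix(rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0),
                                 c(0, 0, 1)))
  expect_error(stationaryDistribution(Pred), "reducible")
})

test_that("graph -> walk -> graph round trip recovers the graph (g/h duality)", {
  set.seed(9)
  for (rep in seq_len(20)) {
    n <- sample(5:50, 1)
    A <- randomConnectedGraph(n)
    W <- weightMatrix(A)
    back <- fromTransition(toTransition(W), alpha = sum(A))
    expect_lt(max(abs(as.matrix(back) - A)), 1e-8)
  }
  # uniform walk on the complete 3-graph, alpha = 6: unit off-diagonals
  K3 <- weightMatrix(cycleAdj(3))
  out <- fromTransition(toTransition(K3), alpha = 6)
  expect_equal(as.matrix(out), cycleAdj(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fromTransition(toTransition(K3), alpha = -1), "positive")
})

test_that("preprocessing applies the additive offsets and the auto rule", {
  W <- weightMatrix(cycleAdj(4))
  # unweighted: eps1 = eps2 = 1; edges 2, non-edges 1, diagonal 2
  out <- as.matrix(preprocessNetwork(W))
  expect_equal(attr(out, "eps1"), 1)
  expect_equal(out[1, 2], 2)
  expect_equal(out[1, 3], 1)
  expect_equal(diag(out), rep(2, 4), ignore_attr = TRUE)
  # weighted: both offsets equal the minimum non-zero weight
  Wv <- weightMatrix(rbind(c(0, 0.05, 2), c(0.05, 0, 1), c(2, 1, 0)))
  outv <- as.matrix(preprocessNetwork(Wv))
  expect_equal(attr(outv, "eps1"), 0.05)
  expect_equal(attr(outv, "eps2"), 0.05)
  expect_equal(outv[1, 2], 0.10)
  expect_equal(diag(outv), rep(0.1, 3), ignore_attr = TRUE)
  # zero offsets: identity
  expect_equal(as.matrix(preprocessNetwork(W, 0, 0)), as.matrix(W),
               ignore_attr = TRUE)
  expect_error(preprocessNetwork(W, -0.1, 0), "non-negative")
})

test_that("negative-row clipping shifts only offending rows", {
  q <- quasiTransition(rbind(c(0.5, -0.2, 0.7),
                             c(0.2, 0.6, 0.2),
                             c(0, 0, 0)))
  out <- as.matrix(clipNegativeRows(q))
  expect_equal(out[1, ], c(0.7, 0, 0.9), ignore_attr = TRUE)
  expect_equal(out[2, ], c(0.2, 0.6, 0.2), ignore_attr = TRUE)
  expect_equal(out[3, ], c(0, 0, 0), ignore_attr = TRUE)  # zero row untouched
  # wholly non-negative input is unchanged
  p <- quasiTransition(randomStochastic(6))
  expect_identical(as.matrix(clipNegativeRows(p)), as.matrix(p))
  # tiny float dust is not treated as negative
  tiny <- quasiTransition(rbind(c(1 + 1e-13, -1e-13), c(0.5, 0.5)))
  expect_identical(as.matrix(clipNegativeRows(tiny))[1, 1], 1 + 1e-13)
})
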