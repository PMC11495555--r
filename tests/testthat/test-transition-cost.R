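# Transportation cost matrix, Sinkhorn bridge solver, per-condition cost
# table and the baseline KL divergence.

test_that("cost matrix is -log Q with Inf on zeros and optional smoothing", {
  K <- 4
  Qu <- JointTransitionMatrix(matrix(1 / K^2, K, K))
  expect_equal(transportationCostMatrix(Qu)$C,
               matrix(2 * log(K), K, K))
  Q <- JointTransitionMatrix(matrix(c(.4, .2, .1, .3), 2))
  expect_equal(transportationCostMatrix(Q)$C,
               matrix(c(0.9163, 1.6094, 2.3026, 1.2040), 2),
               tolerance = 1e-4)
  Qz <- JointTransitionMatrix(matrix(c(.5, .5, 0, 0), 2), nPairs = 10L)
  expect_true(is.infinite(transportationCostMatrix(Qz)$C[1, 2]))
  sm <- transportationCostMatrix(Qz, pseudocount = 1)
  expect_true(all(is.finite(sm$C)))
  expect_equal(sum(sm$Q), 1)
  expect_equal(sm$Q[1, 1], 6 / 14)   # (5 + 1) / (10 + 4)
})

test_that("the reference coupling's own marginals give cost zero", {
  set.seed(41)
  for (K in c(2, 5, 7)) {
    Q <- randomJoint(K)
    sol <- sinkhornBridge(transportProblem(JointTransitionMatrix(Q),
                                           rowSums(Q), colSums(Q)))
    expect_lt(abs(transitionCost(sol)), 1e-10)
    expect_equal(transportPlan(sol), Q, tolerance = 1e-8)
  }
})

test_that("K = 2 bridge matches the one-parameter brute-force oracle", {
  set.seed(42)
  for (r in 1:25) {
    Q <- randomJoint(2)
    p0 <- randomSimplex(2); pT <- randomSimplex(2)
    sol <- sinkhornBridge(transportProblem(JointTransitionMatrix(Q), p0, pT))
    expect_lt(abs(transitionCost(sol) - bridgeOracleK2(Q, p0, pT)), 1e-4)
  }
})

test_that("uniform reference gives the additive KL closed form", {
  set.seed(43)
  for (K in 2:4) {
    Qu <- JointTransitionMatrix(matrix(1 / K^2, K, K))
    p0 <- randomSimplex(K); pT <- randomSimplex(K)
    sol <- sinkhornBridge(transportProblem(Qu, p0, pT))
    closed <- sum(p0 * log(p0 * K)) + sum(pT * log(pT * K))
    expect_lt(abs(transitionCost(sol) - closed), 1e-8)
    # optimal plan under independence reference is the product coupling
    expect_equal(transportPlan(sol), outer(p0, pT), tolerance = 1e-8)
  }
})

test_that("objective identity: sum C P - H(P) = KL(P || Q) on every solve", {
  set.seed(44)
  for (r in 1:20) {
    K <- sample(2:7, 1)
    Q <- randomJoint(K)
    p0 <- randomSimplex(K); pT <- randomSimplex(K)
    pr <- transportProblem(JointTransitionMatrix(Q), p0, pT)
    sol <- sinkhornBridge(pr)
    P <- transportPlan(sol)
    pos <- P > 0
    lhs <- sum(costMatrix(pr)[pos] * P[pos]) + sum(P[pos] * log(P[pos]))
    expect_lt(abs(lhs - transitionCost(sol)), 1e-10)
    expect_gte(transitionCost(sol), -1e-12)
    # plan reconstructs from the reported multipliers (scaling form)
    expect_equal(P, Q * outer(sol@u, sol@v), tolerance = 1e-8)
  }
})

test_that("solution is stable across solver tolerance settings", {
  set.seed(45)
  Q <- randomJoint(4)
  p0 <- randomSimplex(4); pT <- randomSimplex(4)
  pr <- transportProblem(JointTransitionMatrix(Q), p0, pT)
  c1 <- transitionCost(sinkhornBridge(pr, tol = 1e-10))
  c2 <- transitionCost(sinkhornBridge(pr, tol = 1e-13))
  expect_lt(abs(c1 - c2), 1e-8)
})

test_that("infeasible marginal support raises; pseudocount repairs it", {
  Q <- JointTransitionMatrix(matrix(c(.5, .5, 0, 0), 2), nPairs = 100L)
  expect_error(
    sinkhornBridge(transportProblem(Q, c(.5, .5), c(.5, .5))),
    class = "msbridgeInfeasibleError")
  sol <- sinkhornBridge(transportProblem(Q, c(.5, .5), c(.5, .5),
                                         pseudocount = 1))
  expect_true(is.finite(transitionCost(sol)))
})

test_that("cost is convex in the target and monotone along a ray", {
  set.seed(46)
  Q <- randomJoint(3)
  jm <- JointTransitionMatrix(Q)
  p0 <- rowSums(Q)
  costTo <- function(pT)
    transitionCost(sinkhornBridge(transportProblem(jm, p0, pT)))
  base <- colSums(Q)                 # the cost-zero target
  dirv <- c(.5, .3, .2) - base
  for (r in 1:5) {
    a <- randomSimplex(3); b <- randomSimplex(3)
    mid <- (a + b) / 2
    expect_lte(costTo(mid), (costTo(a) + costTo(b)) / 2 + 1e-8)
  }
  # farther along a fixed ray from the minimiser never costs less
  cs <- vapply(c(.25, .5, .75, 1), function(s) costTo(base + s * dirv), 0)
  expect_true(all(diff(cs) > -1e-10))
})

test_that("per-condition table solves against the shared resting reference", {
  pStay <- 0.85; K <- 3
  Tm <- metastableChain(rep(1 / K, K), pStay)
  rest <- generateMarkovSequence(6000, Tm, seed = 47)
  task <- generateMarkovSequence(1200, Tm, seed = 48)
  sq <- makeSeq(list(rest, task), c("rest", "taskA"), srate = 250, K = K)
  # a task distribution equal to the reference marginals costs zero
  w <- segmentRest(sq, windowS = 2)
  Q <- jointProbability(w, "rest")
  tab <- transitionCostPerCondition(
    list(Q = Q, pi0 = rowSums(jointMatrix(Q))),
    list(CoverageDistribution(colSums(jointMatrix(Q)), "colmarg"),
         coverage(sq, "taskA", dropBoundaryRuns = FALSE)))
  expect_equal(tab$condition, c("colmarg", "taskA"))  # sorted
  expect_lt(tab$cost[tab$condition == "colmarg"], 1e-10)
  expect_gte(tab$cost[tab$condition == "taskA"], 0)
  # solver failures are tagged with the condition
  bad <- CoverageDistribution(c(1, 0, 0), "badcond")
  Qz <- JointTransitionMatrix(rbind(c(0, .5, 0), c(.25, 0, 0),
                                    c(0, 0, .25)), nPairs = 100L)
  expect_error(
    transitionCostPerCondition(list(Q = Qz, pi0 = c(0, .5, .5)),
                               list(bad)),
    regexp = "badcond")
})

test_that("KL divergence closed forms and support guard", {
  expect_equal(klDivergence(c(.3, .7), c(.3, .7)), 0)
  expect_equal(klDivergence(c(.5, .5), c(.75, .25)), 0.14384,
               tolerance = 1e-4)
  expect_equal(klDivergence(c(1, 0), c(.5, .5)), log(2))
  expect_error(klDivergence(c(.5, .5), c(1, 0)),
               class = "msbridgeInfiniteDivergenceError")
  expect_error(klDivergence(c(.5, .5), c(1, 0, 0)),
               class = "msbridgeInputError")
})
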