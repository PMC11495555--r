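# Discrete Schrodinger bridge between resting and task microstate
# distributions: transportation cost matrix, Sinkhorn solver, per-condition
# cost tables, and the baseline KL divergence.

#' Transportation cost matrix from the resting joint matrix
#'
#' `C = -log Q` elementwise; entries where `Q` is zero get `+Inf`. With
#' `pseudocount > 0`, pair counts are Laplace-smoothed first:
#' `Q <- (counts + pseudocount) / (nPairs + K^2 * pseudocount)`.
#'
#' @param Q a [JointTransitionMatrix-class].
#' @param pseudocount nonnegative smoothing count (default 0).
#' @return list with the (possibly smoothed) matrix `Q` and cost matrix `C`.
#' @export
transportationCostMatrix <- function(Q, pseudocount = 0) {
  if (pseudocount < 0)
    msbStop("msbridgeParameterError", "pseudocount must be >= 0")
  qm <- jointMatrix(Q)
  if (pseudocount > 0) {
    n <- Q@nPairs
    if (is.na(n))
      msbStop("msbridgeInputError",
              "pseudocount smoothing needs the pair count behind Q")
    K <- nrow(qm)
    qm <- (qm * n + pseudocount) / (n + K^2 * pseudocount)
  }
  list(Q = qm, C = -log(qm))
}

#' Assemble a discrete Schrodinger bridge problem
#'
#' @param Q a [JointTransitionMatrix-class] (the resting reference
#'   coupling).
#' @param pi0 source marginal: a [CoverageDistribution-class] or numeric
#'   vector.
#' @param piT target marginal, same forms.
#' @param pseudocount optional Laplace smoothing of `Q`
#'   (see [transportationCostMatrix()]).
#' @return A [TransportProblem-class].
#' @export
transportProblem <- function(Q, pi0, piT, pseudocount = 0) {
  sm <- transportationCostMatrix(Q, pseudocount)
  p0 <- if (is(pi0, "CoverageDistribution")) coverageProbs(pi0) else
    as.numeric(pi0)
  pT <- if (is(piT, "CoverageDistribution")) coverageProbs(piT) else
    as.numeric(piT)
  # new() cannot take a slot literally named C (partial-matches Class)
  obj <- new("TransportProblem")
  obj@Q <- sm$Q; obj@pi0 <- p0; obj@piT <- pT; obj@C <- sm$C
  validObject(obj)
  obj
}

# Log-domain Sinkhorn on the active support; returns list(P, logU, logV,
# iterations, marginalError). K is small, so dense log-sum-exp is cheap.
.sinkhornLog <- function(Qs, p0, pT, tol, maxIter, logU) {
  logQ <- log(Qs)                     # -Inf on zeros
  lp0 <- log(p0); lpT <- log(pT)
  logV <- rep(0, length(pT))
  lse <- function(m) {                # row-wise log-sum-exp
    mx <- apply(m, 1L, max)
    mx + log(rowSums(exp(m - mx)))
  }
  err <- Inf; it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    logU <- lp0 - lse(sweep(logQ, 2L, logV, "+"))
    logV <- lpT - lse(t(logQ + logU))
    if (it %% 10L == 0L || it == maxIter) {
      P <- exp(logQ + outer(logU, logV, "+"))
      err <- max(abs(rowSums(P) - p0), abs(colSums(P) - pT))
      if (err < tol) break
    }
  }
  P <- exp(logQ + outer(logU, logV, "+"))
  err <- max(abs(rowSums(P) - p0), abs(colSums(P) - pT))
  list(P = P, logU = logU, logV = logV, iterations = it,
       marginalError = err)
}

#' Solve the Schrodinger bridge by Sinkhorn iteration
#'
#' Alternating diagonal scaling `u <- pi0 / (Q v)`, `v <- piT / (Q' u)` on
#' the support of the marginals, until the worst absolute marginal
#' violation of `P = diag(u) Q diag(v)` falls below `tol`. Switches to
#' log-domain updates when any scaling exceeds 1e30. The transition cost
#' is `D_KL(P || Q) = sum_ij P_ij log(P_ij / Q_ij)` in nats (terms with
#' `P_ij = 0` contribute 0) — identically `sum_ij C_ij P_ij - H(P)` with
#' `C = -log Q` and `H` the Shannon entropy of the plan.
#'
#' @param prob a [TransportProblem-class].
#' @param tol maximum absolute marginal violation (default 1e-10).
#' @param maxIter iteration cap (default 1e5).
#' @return A [BridgeSolution-class].
#' @examples
#' Q <- JointTransitionMatrix(matrix(c(.4, .2, .1, .3), 2), nPairs = 1000L)
#' pr <- transportProblem(Q, c(.5, .5), c(.7, .3))
#' sol <- sinkhornBridge(pr)
#' transitionCost(sol)
#' @export
sinkhornBridge <- function(prob, tol = 1e-10, maxIter = 1e5L) {
  if (tol <= 0) msbStop("msbridgeParameterError", "tol must be > 0")
  Q <- prob@Q; p0 <- prob@pi0; pT <- prob@piT
  K <- nrow(Q)
  act0 <- p0 > 0; actT <- pT > 0
  Qs <- Q[act0, actT, drop = FALSE]
  badRow <- rowSums(Qs) == 0
  badCol <- colSums(Qs) == 0
  if (any(badRow) || any(badCol))
    msbStop("msbridgeInfeasibleError",
      paste("marginals place mass on states with no reference support",
            "(rows [%s], cols [%s]); consider a pseudocount on Q"),
      paste(which(act0)[badRow], collapse = ","),
      paste(which(actT)[badCol], collapse = ","))
  p0a <- p0[act0]; pTa <- pT[actT]
  u <- rep(1, length(p0a)); v <- rep(1, length(pTa))
  it <- 0L; err <- Inf; logDomain <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    u <- p0a / as.vector(Qs %*% v)
    v <- pTa / as.vector(crossprod(Qs, u))
    if (!all(is.finite(u)) || !all(is.finite(v)) ||
        max(u) > 1e30 || max(v) > 1e30 || min(u) <= 0 || min(v) <= 0) {
      logDomain <- TRUE
      break
    }
    if (it %% 10L == 0L || it == maxIter) {
      P <- Qs * outer(u, v)
      err <- max(abs(rowSums(P) - p0a), abs(colSums(P) - pTa))
      if (err < tol) break
    }
  }
  if (logDomain) {
    res <- .sinkhornLog(Qs, p0a, pTa, tol, maxIter, log(pmax(u, 1e-300)))
    P <- res$P; u <- exp(res$logU); v <- exp(res$logV)
    it <- it + res$iterations; err <- res$marginalError
  } else {
    P <- Qs * outer(u, v)
    err <- max(abs(rowSums(P) - p0a), abs(colSums(P) - pTa))
  }
  if (!(err < tol))
    msbStop("msbridgeConvergenceError",
            "Sinkhorn did not reach tol %g in %d iterations (marginal error %g)",
            tol, as.integer(maxIter), err)
  Pfull <- matrix(0, K, K)
  Pfull[act0, actT] <- P
  pos <- Pfull > 0
  cost <- sum(Pfull[pos] * log(Pfull[pos] / Q[pos]))
  uf <- numeric(K); vf <- numeric(K)
  uf[act0] <- u; vf[actT] <- v
  new("BridgeSolution", P = Pfull, u = uf, v = vf, cost = cost,
      iterations = it, marginalError = err)
}

#' Transition cost from rest to each task condition
#'
#' Estimates the resting reference: the two-step joint matrix `Q` over
#' 2-second resting windows and the resting coverage `pi0`, then solves
#' one Schrodinger bridge per task coverage distribution against the
#' shared `Q`.
#'
#' @param rest either a [MicrostateSequence-class] containing a rest
#'   segment (windowed via [segmentRest()]), or a list with elements `Q`
#'   ([JointTransitionMatrix-class]) and `pi0`.
#' @param taskPis list of task [CoverageDistribution-class] objects.
#' @param windowS resting window length in seconds (default 2).
#' @param dropBoundaryRuns boundary-run exclusion for the coverage
#'   estimates (default TRUE; never applied to `Q`).
#' @param pseudocount Laplace smoothing for `Q` (default 0).
#' @param tol,maxIter Sinkhorn controls.
#' @param restCondition rest segment label (default "rest").
#' @return data.frame `(condition, cost, iterations, marginalError)`
#'   sorted by condition.
#' @export
transitionCostPerCondition <- function(rest, taskPis, windowS = 2,
                                       dropBoundaryRuns = TRUE,
                                       pseudocount = 0, tol = 1e-10,
                                       maxIter = 1e5L,
                                       restCondition = "rest") {
  if (is(rest, "MicrostateSequence")) {
    wseq <- segmentRest(rest, windowS = windowS,
                        restCondition = restCondition)
    Q <- jointProbability(wseq, restCondition)
    pi0 <- coverage(wseq, restCondition,
                    dropBoundaryRuns = dropBoundaryRuns)
  } else {
    Q <- rest$Q; pi0 <- rest$pi0
  }
  if (!length(taskPis))
    msbStop("msbridgeInputError", "need at least one task condition")
  rows <- lapply(taskPis, function(piT) {
    cond <- if (is(piT, "CoverageDistribution")) piT@condition else "task"
    sol <- tryCatch(
      sinkhornBridge(transportProblem(Q, pi0, piT,
                                      pseudocount = pseudocount),
                     tol = tol, maxIter = maxIter),
      error = function(e)
        msbStop("msbridgeConditionError", "condition '%s': %s", cond,
                conditionMessage(e)))
    data.frame(condition = cond, cost = transitionCost(sol),
               iterations = sol@iterations,
               marginalError = sol@marginalError)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kullback-Leibler divergence between two coverage distributions
#'
#' `sum_k piA_k log(piA_k / piB_k)` in nats with the convention
#' `0 log 0 = 0`. A state with `piA_k > 0` but `piB_k = 0` makes the
#' divergence infinite and raises an error.
#'
#' @param piA,piB [CoverageDistribution-class] objects or numeric
#'   probability vectors of equal length.
#' @return Nonnegative scalar divergence (nats).
#' @export
klDivergence <- function(piA, piB) {
  a <- if (is(piA, "CoverageDistribution")) coverageProbs(piA) else
    as.numeric(piA)
  b <- if (is(piB, "CoverageDistribution")) coverageProbs(piB) else
    as.numeric(piB)
  if (length(a) != length(b))
    msbStop("msbridgeInputError", "distributions must have equal length")
  d <- klVec(a, b)
  if (!is.finite(d))
    msbStop("msbridgeInfiniteDivergenceError",
            "piA places mass where piB has none: divergence is infinite")
  d
}
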