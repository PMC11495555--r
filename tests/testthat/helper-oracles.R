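# Independent oracles and small random-problem generators used across
# tests. These deliberately avoid the package's own solver paths.

# KL divergence between two couplings (0 log 0 = 0).
klPlan <- function(P, Q) {
  pos <- P > 0
  if (any(pos & Q <= 0)) return(Inf)
  sum(P[pos] * log(P[pos] / Q[pos]))
}

# Brute-force bridge cost for K = 2: the transportation polytope has a
# single free parameter P[1,1]; golden-section search over its interval.
bridgeOracleK2 <- function(Q, p0, pT) {
  lo <- max(0, p0[1] + pT[1] - 1)
  hi <- min(p0[1], pT[1])
  f <- function(x) {
    P <- matrix(c(x, pT[1] - x, p0[1] - x, 1 - p0[1] - pT[1] + x), 2)
    klPlan(P, Q)
  }
  stats::optimize(f, c(lo, hi), tol = 1e-12)$objective
}

# Brute-force bridge cost for K = 3: the free 2 x 2 block determines the
# rest through the marginal constraints; penalised Nelder-Mead from the
# independent coupling, restarted once for polish.
bridgeOracleK3 <- function(Q, p0, pT) {
  mk <- function(x) {
    P <- matrix(0, 3, 3)
    P[1:2, 1:2] <- matrix(x, 2, 2)
    P[1:2, 3] <- p0[1:2] - rowSums(P[1:2, 1:2, drop = FALSE])
    P[3, ] <- pT - colSums(P[1:2, , drop = FALSE])
    P
  }
  f <- function(x) {
    P <- mk(x)
    if (any(P < -1e-12)) return(1e6 + 1e6 * sum(pmax(-P, 0)))
    klPlan(pmax(P, 0), Q)
  }
  start <- as.vector(outer(p0, pT)[1:2, 1:2])
  o <- stats::optim(start, f, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 50000))
  o <- stats::optim(o$par, f, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 50000))
  o$value
}

randomSimplex <- function(K, shape = 2) {
  w <- stats::rgamma(K, shape)
  w / sum(w)
}

randomJoint <- function(K, shape = 1) {
  m <- matrix(stats::rgamma(K * K, shape), K)
  m / sum(m)
}

# Quick sequence builder: one segment per element of `labelsList`,
# laid out back-to-back, each tagged with the matching condition.
makeSeq <- function(labelsList, conditions, srate = 250, K = NULL) {
  labs <- unlist(labelsList)
  len <- vapply(labelsList, length, 1L)
  start <- cumsum(c(1L, len[-length(len)]))
  seg <- data.frame(start = start, end = start + len,
                    condition = conditions)
  if (is.null(K)) K <- max(labs)
  MicrostateSequence(labs, seg, srate = srate, K = K)
}
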