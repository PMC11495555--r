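# Internal numeric helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never
#' perturbs user-level random streams.
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Average-reference a channels x time matrix (zero mean per column)
#' @noRd
avgReference <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

#' Average-reference maps stored as rows (maps x channels)
#' @noRd
avgReferenceRows <- function(x) {
  x - rowMeans(x)
}

#' Pearson spatial correlation between two zero-mean maps
#'
#' For average-referenced maps this equals the cosine similarity.
#' @noRd
spatialCorr <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Maximal-run encoding of an integer label vector
#' @return data.frame(label, length, start)
#' @noRd
labelRuns <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, length = r$lengths,
             start = ends - r$lengths + 1L)
}

#' Stop with a classed condition (keeps error contracts testable)
#' @noRd
msbStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "msbridgeError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' KL divergence between two discrete distributions (nats)
#'
#' 0 * log 0 = 0; infinite when p puts mass where q has none.
#' @noRd
klVec <- function(p, q) {
  pos <- p > 0
  if (any(pos & q <= 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}
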