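# From labeled microstate sequences to per-condition coverage
# distributions, the resting two-step joint matrix, and the
# transition-asymmetry test.

#' Split resting segments into fixed-length windows
#'
#' Rest is divided into consecutive non-overlapping windows of
#' `windowS` seconds (the duration of a single task trial, 2 s in the
#' reference design); a trailing partial window is discarded. Segments of
#' other conditions are left untouched.
#'
#' @param seq a [MicrostateSequence-class].
#' @param windowS window length in seconds (default 2).
#' @param restCondition label identifying rest segments (default "rest").
#' @return The re-segmented [MicrostateSequence-class].
#' @export
segmentRest <- function(seq, windowS = 2, restCondition = "rest") {
  if (windowS <= 0) msbStop("msbridgeParameterError", "windowS must be > 0")
  seg <- segments(seq)
  isRest <- seg$condition == restCondition
  if (!any(isRest))
    msbStop("msbridgeInputError", "no segment with condition '%s'",
            restCondition)
  w <- as.integer(round(windowS * samplingRate(seq)))
  out <- seg[!isRest, , drop = FALSE]
  for (i in which(isRest)) {
    len <- seg$end[i] - seg$start[i]
    nw <- len %/% w
    if (nw < 1L)
      msbStop("msbridgeInsufficientDataError",
              "rest segment of %d samples shorter than one %g-s window",
              len, windowS)
    starts <- seg$start[i] + (seq_len(nw) - 1L) * w
    out <- rbind(out, data.frame(start = starts, end = starts + w,
                                 condition = restCondition))
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  MicrostateSequence(stateLabels(seq), out, srate = samplingRate(seq),
                     K = nStates(seq))
}

# Per-segment label vectors for one condition.
.segmentLabels <- function(seq, condition) {
  seg <- segments(seq)
  seg <- seg[seg$condition == condition, , drop = FALSE]
  if (!nrow(seg))
    msbStop("msbridgeInputError", "no segment with condition '%s'", condition)
  lapply(seq_len(nrow(seg)), function(i)
    stateLabels(seq)[seg$start[i]:(seg$end[i] - 1L)])
}

# Drop the first and last maximal same-label run of a segment's labels
# (the boundary microstates: runs truncated by the segment edge).
.dropBoundaryRuns <- function(lab) {
  r <- rle(lab)
  if (length(r$lengths) <= 2L) return(integer())
  lo <- r$lengths[1L] + 1L
  hi <- length(lab) - r$lengths[length(r$lengths)]
  lab[lo:hi]
}

#' Microstate coverage distribution for a condition
#'
#' Pools samples across all segments of the condition and returns the
#' empirical state distribution. With `dropBoundaryRuns` (the default),
#' the first and last maximal same-label run of every segment are excluded
#' before counting, since those runs are truncated by the segment edge and
#' their duration (hence presence) is unreliable.
#'
#' @param seq a [MicrostateSequence-class].
#' @param condition condition label to pool.
#' @param dropBoundaryRuns exclude boundary runs per segment (default TRUE).
#' @return A [CoverageDistribution-class] of length `nStates(seq)`.
#' @export
coverage <- function(seq, condition, dropBoundaryRuns = TRUE) {
  labs <- .segmentLabels(seq, condition)
  if (dropBoundaryRuns) labs <- lapply(labs, .dropBoundaryRuns)
  pooled <- unlist(labs)
  if (!length(pooled))
    msbStop("msbridgeDegenerateError",
            "all samples of condition '%s' excluded as boundary runs",
            condition)
  K <- nStates(seq)
  cnt <- tabulate(pooled, nbins = K)
  CoverageDistribution(cnt / sum(cnt), condition = condition,
                       nSamples = length(pooled))
}

#' Joint probability of two consecutive microstates
#'
#' Counts ordered pairs `(k_{t-1}, k_t)` over consecutive samples within
#' segments of the condition (never across a segment boundary) and
#' normalises by the total pair count.
#'
#' @param seq a [MicrostateSequence-class].
#' @param condition condition label (default "rest").
#' @param dropBoundaryRuns also exclude each segment's boundary runs before
#'   pairing (default FALSE; boundary exclusion is a coverage concept).
#' @return A [JointTransitionMatrix-class].
#' @export
jointProbability <- function(seq, condition = "rest",
                             dropBoundaryRuns = FALSE) {
  labs <- .segmentLabels(seq, condition)
  if (dropBoundaryRuns) labs <- lapply(labs, .dropBoundaryRuns)
  K <- nStates(seq)
  cnt <- matrix(0L, K, K)
  for (lab in labs) {
    if (length(lab) < 2L) next
    from <- lab[-length(lab)]
    to <- lab[-1L]
    cnt <- cnt + matrix(tabulate((to - 1L) * K + from, nbins = K * K), K, K)
  }
  n <- sum(cnt)
  if (n == 0L)
    msbStop("msbridgeInsufficientDataError",
            "no consecutive sample pairs in condition '%s'", condition)
  JointTransitionMatrix(cnt / n, nPairs = n)
}

#' Paired test for asymmetric transitions across a cohort
#'
#' For each unordered state pair i < j, a two-tailed paired t-test across
#' subjects of `Q_ij - Q_ji`. When the differences have zero variance, the
#' t statistic is undefined; if their mean is also 0 the pair is reported
#' as non-significant with `undefined = TRUE`, otherwise the statistic is
#' infinite and p is reported as 0.
#'
#' @param cohortQ list of [JointTransitionMatrix-class], one per subject
#'   (>= 3), all with the same K.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `i`, `j`, `meanDiff`, `t`, `p`,
#'   `significant`, `undefined`.
#' @export
asymmetryTest <- function(cohortQ, alpha = 0.05) {
  if (length(cohortQ) < 3L)
    msbStop("msbridgeInputError", "need >= 3 subjects, got %d",
            length(cohortQ))
  K <- nStates(cohortQ[[1L]])
  if (!all(vapply(cohortQ, nStates, 1L) == K))
    msbStop("msbridgeInputError", "all Q matrices must share the same K")
  n <- length(cohortQ)
  rows <- list()
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    d <- vapply(cohortQ, function(q) jointMatrix(q)[i, j] -
                                      jointMatrix(q)[j, i], 0)
    m <- mean(d); s <- stats::sd(d)
    if (s == 0) {
      if (m == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          i = i, j = j, meanDiff = m, t = NA_real_, p = NA_real_,
          significant = FALSE, undefined = TRUE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          i = i, j = j, meanDiff = m, t = sign(m) * Inf, p = 0,
          significant = TRUE, undefined = FALSE)
      }
    } else {
      tt <- m / (s / sqrt(n))
      p <- 2 * stats::pt(-abs(tt), df = n - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j, meanDiff = m, t = tt, p = p,
        significant = p < alpha, undefined = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
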