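# Polarity-invariant modified k-means for microstate topographies,
# two-level (subject -> group) fitting, cross-validation selection of K,
# and template back-fitting to continuous EEG.

# Deterministic sign convention for a map: the component with the largest
# absolute value is made positive (first such index on ties).
.canonicalSign <- function(a) {
  i <- which.max(abs(a))
  if (a[i] < 0) -a else a
}

# Assign maps (rows) to templates A (K x C) by squared projection;
# ties break to the lowest template index.
.assignMaps <- function(maps, A) {
  proj2 <- (maps %*% t(A))^2
  max.col(proj2, ties.method = "first")
}

# GEV of an assignment: polarity-invariant explained variance weighted by
# each map's own power. For zero-mean maps and unit-norm templates this is
# sum (v . a_L)^2 / sum |v|^2.
.gevOf <- function(maps, A, L) {
  proj <- rowSums(maps * A[L, , drop = FALSE])
  tot <- sum(maps^2)
  if (tot == 0) return(0)
  sum(proj^2) / tot
}

# Residual noise variance and the CV criterion for channel count C.
.residualNoise <- function(maps, A, L) {
  C <- ncol(maps)
  proj <- rowSums(maps * A[L, , drop = FALSE])
  sum(rowSums(maps^2) - proj^2) / (nrow(maps) * (C - 1))
}

.cvCriterion <- function(sigma2, C, K) {
  sigma2 * ((C - 1) / (C - 1 - K))^2
}

# First principal direction of a cluster of maps (rows): leading right
# singular vector, re-centred and unit-normalised with canonical sign.
.principalMap <- function(X) {
  sv <- svd(X, nu = 0L, nv = 1L)
  a <- sv$v[, 1L]
  a <- a - mean(a)
  n <- sqrt(sum(a^2))
  if (n == 0) return(NULL)
  .canonicalSign(a / n)
}

#' Polarity-invariant modified k-means over topographic maps
#'
#' Iterates (a) assignment of each map to the template with the largest
#' squared inner product (sign-blind), ties to the lowest index, and
#' (b) template update to the principal eigenvector of the assigned maps'
#' scatter matrix, until the relative change in global explained variance
#' (GEV) falls below `tol` or `maxIter` is reached. The best of `restarts`
#' random initialisations by GEV is returned. An emptied cluster is
#' re-seeded from the currently worst-fit map.
#'
#' @param maps n x channels matrix of average-referenced maps (n > K).
#' @param K number of templates.
#' @param restarts random restarts (default 50).
#' @param seed RNG seed; restart r uses `seed + r - 1`.
#' @param tol relative GEV change convergence threshold (default 1e-6).
#' @param maxIter iteration cap per restart (default 300).
#' @return A [TemplateSet-class] with GEV, residual noise and (unset) CV.
#' @examples
#' A <- generateTemplates(16, 3, seed = 1)
#' maps <- A[rep(1:3, 50), ] * sample(c(-1, 1), 150, replace = TRUE)
#' fit <- modifiedKMeans(maps, K = 3, restarts = 5, seed = 2)
#' gev(fit)  # 1 (noiseless)
#' @export
modifiedKMeans <- function(maps, K, restarts = 50L, seed = 1L,
                           tol = 1e-6, maxIter = 300L) {
  maps <- as.matrix(maps)
  n <- nrow(maps); C <- ncol(maps)
  if (K >= n)
    msbStop("msbridgeParameterError",
            "need more maps (%d) than clusters (K = %d)", n, K)
  if (K < 1L) msbStop("msbridgeParameterError", "K must be >= 1")
  best <- NULL
  for (r in seq_len(restarts)) {
    A <- withSeed(seed + r - 1L, {
      idx <- sample(n, K)
      t(apply(maps[idx, , drop = FALSE], 1L, function(a) {
        a <- a - mean(a)
        nn <- sqrt(sum(a^2))
        if (nn == 0) a <- stats::rnorm(C)
        a <- a - mean(a)
        .canonicalSign(a / sqrt(sum(a^2)))
      }))
    })
    gevPrev <- -Inf
    L <- .assignMaps(maps, A)
    for (it in seq_len(maxIter)) {
      for (k in seq_len(K)) {
        idx <- which(L == k)
        if (!length(idx)) {
          # re-seed from the worst-fit map
          proj <- rowSums(maps * A[L, , drop = FALSE])
          fit <- proj^2 / pmax(rowSums(maps^2), .Machine$double.eps)
          w <- which.min(fit)
          a <- maps[w, ] - mean(maps[w, ])
          nn <- sqrt(sum(a^2))
          if (nn > 0) A[k, ] <- .canonicalSign(a / nn)
          L[w] <- k
          idx <- w
        }
        a <- .principalMap(maps[idx, , drop = FALSE])
        if (!is.null(a)) A[k, ] <- a
      }
      L <- .assignMaps(maps, A)
      g <- .gevOf(maps, A, L)
      if (is.finite(gevPrev) &&
          abs(g - gevPrev) <= tol * max(gevPrev, .Machine$double.eps)) {
        gevPrev <- g
        break
      }
      gevPrev <- g
    }
    g <- .gevOf(maps, A, L)
    if (is.null(best) || g > best$gev)
      best <- list(A = A, L = L, gev = g)
  }
  sigma2 <- .residualNoise(maps, best$A, best$L)
  chn <- colnames(maps)
  if (is.null(chn)) chn <- sprintf("ch%02d", seq_len(C))
  new("TemplateSet", maps = best$A, gev = best$gev,
      residualNoise = sigma2, cv = NA_real_, seed = as.integer(seed),
      restarts = as.integer(restarts), channelNames = chn)
}

#' Two-level (subject then group) microstate fitting
#'
#' Fits the modified k-means separately to each subject's peak maps, pools
#' the resulting subject templates (unit weight each), and fits a
#' group-level modified k-means to the pooled templates.
#'
#' @param subjectPeakMaps list of n_s x channels map matrices, one per
#'   subject.
#' @param K number of templates at both levels.
#' @param restarts,seed,tol,maxIter passed to [modifiedKMeans()]; subject s
#'   uses `seed + s`.
#' @return A [TemplateSet-class] of group templates.
#' @export
twoLevelFit <- function(subjectPeakMaps, K, restarts = 50L, seed = 1L,
                        tol = 1e-6, maxIter = 300L) {
  if (!length(subjectPeakMaps))
    msbStop("msbridgeInputError", "need at least one subject")
  subj <- vector("list", length(subjectPeakMaps))
  for (s in seq_along(subjectPeakMaps)) {
    subj[[s]] <- tryCatch(
      modifiedKMeans(subjectPeakMaps[[s]], K, restarts = restarts,
                     seed = seed + s, tol = tol, maxIter = maxIter),
      error = function(e)
        msbStop("msbridgeSubjectError", "subject %d: %s", s,
                conditionMessage(e)))
  }
  pooled <- do.call(rbind, lapply(subj, templateMaps))
  if (length(subjectPeakMaps) == 1L)
    return(subj[[1L]])
  modifiedKMeans(pooled, K, restarts = restarts, seed = seed, tol = tol,
                 maxIter = maxIter)
}

#' Select the number of microstates by the cross-validation criterion
#'
#' For each K in `kRange`, runs the two-level fit and evaluates the group
#' templates on the pooled subject peak maps: residual noise
#' `sigma2 = sum_i (|v_i|^2 - (a_{L_i} . v_i)^2) / (n (C - 1))` and
#' `CV = sigma2 * ((C - 1) / (C - 1 - K))^2`, with C the channel count.
#' The selected K minimises CV; ties break to the smaller K. K values with
#' `K >= C - 1` leave CV undefined and are skipped with a warning.
#'
#' @param subjectPeakMaps list of per-subject peak-map matrices.
#' @param kRange integer vector of candidate K.
#' @param restarts,seed,tol,maxIter passed to [twoLevelFit()].
#' @return A [ClusterFitResult-class].
#' @export
selectK <- function(subjectPeakMaps, kRange, restarts = 50L, seed = 1L,
                    tol = 1e-6, maxIter = 300L) {
  pooled <- do.call(rbind, lapply(subjectPeakMaps, as.matrix))
  C <- ncol(pooled)
  kRange <- sort(unique(as.integer(kRange)))
  rows <- list(); fits <- list()
  for (K in kRange) {
    if (K >= C - 1L) {
      warning(sprintf("K = %d >= channels - 1 = %d: CV undefined, skipped",
                      K, C - 1L))
      next
    }
    ts <- twoLevelFit(subjectPeakMaps, K, restarts = restarts, seed = seed,
                      tol = tol, maxIter = maxIter)
    A <- templateMaps(ts)
    L <- .assignMaps(pooled, A)
    sigma2 <- .residualNoise(pooled, A, L)
    cv <- .cvCriterion(sigma2, C, K)
    g <- .gevOf(pooled, A, L)
    ts@residualNoise <- sigma2
    ts@cv <- cv
    rows[[length(rows) + 1L]] <-
      data.frame(K = K, gev = g, residualNoise = sigma2, cv = cv)
    fits[[as.character(K)]] <- ts
  }
  if (!length(rows))
    msbStop("msbridgeParameterError",
            "no K in range is admissible for %d channels", C)
  tab <- do.call(rbind, rows)
  # ties within numerical noise break toward the smaller K
  kSel <- min(tab$K[tab$cv <= min(tab$cv) + 1e-15])
  new("ClusterFitResult", table = tab, selectedK = as.integer(kSel),
      templates = fits)
}

#' Back-fit templates to a continuous recording
#'
#' Labels every time point with the template of highest absolute spatial
#' correlation (equivalently, minimum Euclidean distance between the
#' normalised average-referenced map and the template up to polarity);
#' ties break to the lowest template index. No temporal smoothing is
#' applied. Condition segments are taken from the recording's annotations.
#'
#' @param rec a preprocessed [EEGRecording-class].
#' @param templates a [TemplateSet-class] on the same channel set.
#' @return A [MicrostateSequence-class].
#' @export
backfitSequence <- function(rec, templates) {
  miss <- setdiff(channelNames(templates), channelNames(rec))
  extra <- setdiff(channelNames(rec), channelNames(templates))
  if (length(miss) || length(extra))
    msbStop("msbridgeSchemaError",
            "channel mismatch; recording lacks [%s], templates lack [%s]",
            paste(miss, collapse = ","), paste(extra, collapse = ","))
  x <- eegData(rec)[match(channelNames(templates), channelNames(rec)), ,
                    drop = FALSE]
  x <- avgReference(x)
  A <- templateMaps(templates)
  absProj <- abs(A %*% x)            # K x T; |corr| ranking since |v| common
  labels <- max.col(t(absProj), ties.method = "first")
  ann <- annotations(rec)
  seg <- data.frame(start = ann$onset, end = ann$onset + ann$duration,
                    condition = ann$condition)
  MicrostateSequence(labels, seg, srate = samplingRate(rec),
                     K = nStates(templates))
}
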