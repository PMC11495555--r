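# Synthetic ground-truth cohorts: random topographies, metastable Markov
# label dynamics with condition-dependent stationary distributions, and
# rendered EEG. Every pipeline stage is testable against known truth.

#' Synthetic cohort configuration
#'
#' Defaults mirror the reference study design: 44 subjects, 64 channels at
#' 500 Hz, a 4-minute resting session, 2-second trials in six task
#' conditions (congruent/incongruent crossed with PC25/PC50/PC75), and
#' metastable label dynamics (self-transition 0.9, mean dwell ~10 samples).
#'
#' @param nChannels electrodes (default 64).
#' @param KTrue number of generator topographies (default 7).
#' @param nSubjects cohort size (default 44).
#' @param srate rendering sample rate in Hz (default 500).
#' @param restDurationS resting duration in seconds (default 240).
#' @param trialDurationS trial length in seconds (default 2).
#' @param nTrialsPerCondition trials per condition (default 48).
#' @param itiDurationS inter-trial interval, rendered as noise only
#'   (default 0.5).
#' @param pStay self-transition probability of the label chain
#'   (default 0.9).
#' @param conditionEffects named list (condition -> K-vector of logit
#'   shifts applied to the resting stationary distribution), or NULL for
#'   the built-in graded task/congruency/interaction pattern
#'   (see [defaultConditionEffects()]).
#' @param snr amplitude-to-noise ratio of the rendered EEG (default 10).
#' @param seed root RNG seed.
#' @return A validated configuration list (class `SyntheticConfig`).
#' @export
syntheticConfig <- function(nChannels = 64L, KTrue = 7L, nSubjects = 44L,
                            srate = 500, restDurationS = 240,
                            trialDurationS = 2, nTrialsPerCondition = 48L,
                            itiDurationS = 0.5, pStay = 0.9,
                            conditionEffects = NULL, snr = 10, seed = 1L) {
  if (pStay <= 0 || pStay >= 1)
    msbStop("msbridgeParameterError", "pStay must lie in (0, 1)")
  if (trialDurationS <= 0)
    msbStop("msbridgeParameterError", "trialDurationS must be > 0")
  if (snr <= 0) msbStop("msbridgeParameterError", "snr must be > 0")
  if (KTrue >= nChannels)
    msbStop("msbridgeParameterError", "KTrue must be < nChannels")
  if (is.null(conditionEffects))
    conditionEffects <- defaultConditionEffects(KTrue)
  bad <- vapply(conditionEffects, function(v) length(v) != KTrue, TRUE)
  if (any(bad))
    msbStop("msbridgeParameterError",
            "every condition effect must be a K-vector (K = %d)", KTrue)
  structure(list(nChannels = as.integer(nChannels),
                 KTrue = as.integer(KTrue),
                 nSubjects = as.integer(nSubjects), srate = srate,
                 restDurationS = restDurationS,
                 trialDurationS = trialDurationS,
                 nTrialsPerCondition = as.integer(nTrialsPerCondition),
                 itiDurationS = itiDurationS, pStay = pStay,
                 conditionEffects = conditionEffects, snr = snr,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Built-in graded condition effects
#'
#' Logit-shift vectors for the six task conditions, composed from three
#' orthonormal zero-sum contrast patterns over the K states: an overall
#' task shift, a congruency modulation scaled by the -.5/+.5 congruency
#' code, and an interaction modulation scaled by the congruency x PC
#' product. Magnitudes are set so coverage changes land in the few-percent
#' range typical of task modulations of microstate coverage.
#'
#' @param K number of states.
#' @param taskShift,congruencyShift,interactionShift scale of the three
#'   components (defaults 0.15, 0.08, 0.05).
#' @return Named list of K-vectors, one per condition of
#'   [conditionDesign()].
#' @export
defaultConditionEffects <- function(K, taskShift = 0.15,
                                    congruencyShift = 0.08,
                                    interactionShift = 0.05) {
  cp <- stats::contr.poly(K)
  u1 <- cp[, 1L]; u2 <- cp[, 2L]
  u3 <- if (ncol(cp) >= 3L) cp[, 3L] else cp[, 1L]
  des <- conditionDesign()
  eff <- lapply(seq_len(nrow(des)), function(r)
    taskShift * u1 +
    des$congruencyCode[r] * congruencyShift * u2 +
    des$interaction[r] * interactionShift * u3)
  names(eff) <- des$condition
  eff
}

#' Generate random microstate topographies
#'
#' Rejection-samples zero-mean, unit-norm maps with pairwise absolute
#' spatial correlation below `maxAbsCorr`.
#'
#' @param nChannels channels per map.
#' @param KTrue number of maps (< nChannels).
#' @param seed RNG seed.
#' @param maxAbsCorr pairwise |correlation| bound (default 0.6).
#' @param budget rejection attempts per map (default 1000).
#' @return KTrue x nChannels matrix.
#' @export
generateTemplates <- function(nChannels, KTrue, seed = 1L,
                              maxAbsCorr = 0.6, budget = 1000L) {
  if (KTrue >= nChannels)
    msbStop("msbridgeParameterError", "KTrue must be < nChannels")
  withSeed(seed, {
    A <- matrix(0, KTrue, nChannels)
    for (k in seq_len(KTrue)) {
      ok <- FALSE
      for (try in seq_len(budget)) {
        a <- stats::rnorm(nChannels)
        a <- a - mean(a)
        a <- a / sqrt(sum(a^2))
        if (k == 1L ||
            all(abs(A[seq_len(k - 1L), , drop = FALSE] %*% a) < maxAbsCorr)) {
          A[k, ] <- a
          ok <- TRUE
          break
        }
      }
      if (!ok)
        msbStop("msbridgeGenerationError",
                "could not place template %d within %d attempts; try fewer templates",
                k, budget)
    }
    colnames(A) <- sprintf("ch%02d", seq_len(nChannels))
    A
  })
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P row-stochastic transition matrix.
#' @return Probability vector `pi` with `pi P = pi`.
#' @export
stationaryDistribution <- function(P) {
  if (max(abs(rowSums(P) - 1)) > 1e-9)
    msbStop("msbridgeParameterError", "transition matrix rows must sum to 1")
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Metastable chain with a prescribed stationary distribution
#'
#' `T = pStay I + (1 - pStay) 1 pi'` — with probability `pStay` the state
#' persists, otherwise it redraws from `pi`. The stationary distribution
#' is exactly `pi` and the effective self-transition is
#' `pStay + (1 - pStay) pi_i`.
#'
#' @param pi target stationary distribution.
#' @param pStay persistence probability.
#' @return Row-stochastic K x K matrix.
#' @export
metastableChain <- function(pi, pStay) {
  K <- length(pi)
  pStay * diag(K) + (1 - pStay) * matrix(pi, K, K, byrow = TRUE)
}

#' Shift a distribution in logit space
#'
#' `pi' propto exp(log pi + shift)` — moves the stationary distribution
#' while leaving the persistence structure of [metastableChain()] alone.
#'
#' @param pi base probability vector (strictly positive).
#' @param shift additive log-space shift vector.
#' @return Shifted probability vector.
#' @export
logitShift <- function(pi, shift) {
  w <- exp(log(pi) + shift)
  w / sum(w)
}

#' Sample a path from a finite Markov chain
#'
#' The chain starts at its stationary distribution; fixed seeds give
#' bit-identical paths.
#'
#' @param T path length in samples.
#' @param transition row-stochastic transition matrix.
#' @param seed RNG seed.
#' @return Integer label path of length T (values `1..K`).
#' @export
generateMarkovSequence <- function(T, transition, seed = 1L) {
  pi0 <- stationaryDistribution(transition)
  K <- nrow(transition)
  cum <- t(apply(transition, 1L, cumsum))
  withSeed(seed, {
    path <- integer(T)
    u <- stats::runif(T)
    path[1L] <- findInterval(u[1L], cumsum(pi0)) + 1L
    for (t in seq_len(T - 1L))
      path[t + 1L] <- findInterval(u[t + 1L], cum[path[t], ],
                                   left.open = TRUE) + 1L
    pmin(path, K)
  })
}

#' Render EEG from a label path and templates
#'
#' `v_t = sign_t * a_{k_t} * s_t + noise`, with `s_t` a raised rectified
#' sinusoid envelope (`floor + |sin(2 pi f t)|`, positive everywhere so
#' every sample stays identifiable), random per-sample polarity flips on
#' the template term, and iid zero-mean Gaussian channel noise scaled so
#' the mean signal amplitude to noise amplitude ratio equals `snr`.
#' Samples with `NA` labels (inter-trial gaps) are rendered as noise only.
#'
#' @param path integer label path (`1..K`, NA for noise-only samples).
#' @param templates K x channels matrix of unit-norm zero-mean maps.
#' @param snr amplitude-to-noise ratio (Inf for noiseless).
#' @param seed RNG seed.
#' @param srate sample rate in Hz (default 250).
#' @param envelopeFreq envelope frequency in Hz (default 10, alpha-like).
#' @param envelopeFloor additive envelope floor (default 0.25).
#' @return channels x length(path) numeric matrix.
#' @export
renderEEG <- function(path, templates, snr = 10, seed = 1L, srate = 250,
                      envelopeFreq = 10, envelopeFloor = 0.25) {
  templates <- as.matrix(templates)
  K <- nrow(templates); C <- ncol(templates)
  if (any(path > K, na.rm = TRUE))
    msbStop("msbridgeParameterError", "labels exceed the template count")
  T <- length(path)
  tt <- (seq_len(T) - 1L) / srate
  s <- envelopeFloor + abs(sin(2 * pi * envelopeFreq * tt))
  withSeed(seed, {
    flips <- sample(c(-1, 1), T, replace = TRUE)
    x <- matrix(0, C, T)
    ok <- !is.na(path)
    if (any(ok))
      x[, ok] <- t(templates[path[ok], , drop = FALSE]) *
        rep(s[ok] * flips[ok], each = C)
    if (is.finite(snr)) {
      sigma <- mean(s) / (snr * sqrt(C))
      x <- x + matrix(stats::rnorm(C * T, sd = sigma), C, T)
    }
    rownames(x) <- colnames(templates)
    x
  })
}

#' Generate a full synthetic cohort
#'
#' Per subject: a resting label path from the baseline metastable chain,
#' then `nTrialsPerCondition` trials per task condition from that
#' condition's logit-shifted chain (each trial an independent stationary
#' draw). With `render = TRUE` the labels are rendered to EEG with
#' noise-only inter-trial gaps; otherwise label sequences are returned
#' directly (gaps omitted).
#'
#' @param cfg a [syntheticConfig()].
#' @param render render EEG recordings (default TRUE); FALSE returns
#'   [MicrostateSequence-class] objects.
#' @return list with `groundTruth` (templates, per-condition transition
#'   matrices `chains`, stationary distributions `stationary`, per-subject
#'   label paths `labelPaths`) and `recordings` (list of
#'   [EEGRecording-class]) or `sequences` (list of
#'   [MicrostateSequence-class]).
#' @export
generateCohort <- function(cfg, render = TRUE) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  templates <- generateTemplates(cfg$nChannels, cfg$KTrue, seed = cfg$seed)
  piBase <- rep(1 / cfg$KTrue, cfg$KTrue)
  chains <- list(rest = metastableChain(piBase, cfg$pStay))
  stationary <- list(rest = piBase)
  for (cond in names(cfg$conditionEffects)) {
    piC <- logitShift(piBase, cfg$conditionEffects[[cond]])
    chains[[cond]] <- metastableChain(piC, cfg$pStay)
    stationary[[cond]] <- piC
  }
  restN <- as.integer(round(cfg$restDurationS * cfg$srate))
  trialN <- as.integer(round(cfg$trialDurationS * cfg$srate))
  itiN <- as.integer(round(cfg$itiDurationS * cfg$srate))
  conds <- names(cfg$conditionEffects)
  recordings <- list(); sequences <- list(); labelPaths <- list()
  for (s in seq_len(cfg$nSubjects)) {
    sseed <- cfg$seed + 1000L * s
    labs <- generateMarkovSequence(restN, chains$rest, seed = sseed)
    ann <- data.frame(onset = 1L, duration = restN, condition = "rest")
    gapped <- labs
    trialIdx <- 0L
    for (cond in conds) for (tr in seq_len(cfg$nTrialsPerCondition)) {
      trialIdx <- trialIdx + 1L
      tl <- generateMarkovSequence(trialN, chains[[cond]],
                                   seed = sseed + trialIdx)
      if (render && itiN > 0L) {
        ann <- rbind(ann, data.frame(onset = length(gapped) + 1L,
                                     duration = itiN, condition = "iti"))
        gapped <- c(gapped, rep(NA_integer_, itiN))
      }
      ann <- rbind(ann, data.frame(onset = length(gapped) + 1L,
                                   duration = trialN, condition = cond))
      gapped <- c(gapped, tl)
    }
    labelPaths[[s]] <- gapped
    if (render) {
      x <- renderEEG(gapped, templates, snr = cfg$snr, seed = sseed,
                     srate = cfg$srate)
      recordings[[s]] <- EEGRecording(x, srate = cfg$srate,
                                      channelNames = colnames(templates),
                                      annotations = ann)
    } else {
      seg <- data.frame(start = ann$onset, end = ann$onset + ann$duration,
                        condition = ann$condition)
      sequences[[s]] <- MicrostateSequence(gapped, seg, srate = cfg$srate,
                                           K = cfg$KTrue)
    }
  }
  out <- list(groundTruth = list(templates = templates, chains = chains,
                                 stationary = stationary,
                                 labelPaths = labelPaths))
  if (render) out$recordings <- recordings else out$sequences <- sequences
  out
}
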