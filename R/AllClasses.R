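#' @import methods
NULL

# ---------------------------------------------------------------------------
# EEGRecording
# ---------------------------------------------------------------------------

#' EEGRecording: multichannel EEG with sampling rate and condition annotations
#'
#' Container for a channels x samples voltage matrix (microvolts), its
#' sampling rate, channel names, and a table of condition annotations.
#' Annotation intervals are 1-based half-open `[onset, onset + duration)`
#' in samples.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot srate sampling rate in Hz.
#' @slot channelNames character vector, one per row of `data`.
#' @slot annotations data.frame with columns `onset` (sample index, 1-based),
#'   `duration` (samples) and `condition` (character label).
#'
#' @seealso [EEGRecording()] for the user constructor,
#'   [preprocessEEG()], [globalFieldPower()]
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", srate = "numeric",
                 channelNames = "character", annotations = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@srate) != 1L || !is.finite(object@srate) ||
        object@srate <= 0)
      msg <- c(msg, "srate must be a single positive number")
    if (!is.numeric(object@data))
      msg <- c(msg, "data must be a numeric matrix")
    if (length(object@channelNames) != nrow(object@data))
      msg <- c(msg, "channelNames length must equal nrow(data)")
    if (anyNA(object@data))
      msg <- c(msg, "data must not contain NA")
    ann <- object@annotations
    need <- c("onset", "duration", "condition")
    if (!all(need %in% names(ann)))
      msg <- c(msg, "annotations needs columns onset, duration, condition")
    else if (nrow(ann) > 0) {
      if (any(ann$onset < 1L) ||
          any(ann$onset + ann$duration - 1L > ncol(object@data)))
        msg <- c(msg, "annotation intervals must lie within the recording")
      if (any(ann$duration < 1L))
        msg <- c(msg, "annotation durations must be >= 1 sample")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param srate sampling rate in Hz.
#' @param channelNames optional channel labels; defaults to `ch01`, `ch02`, ...
#' @param annotations data.frame with `onset`, `duration`, `condition`
#'   (1-based half-open sample intervals). Defaults to none.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 4, 50), srate = 250)
#' nChannels(rec)
#' @export
EEGRecording <- function(data, srate, channelNames = NULL,
                         annotations = NULL) {
  data <- as.matrix(data)
  if (is.null(channelNames))
    channelNames <- sprintf("ch%02d", seq_len(nrow(data)))
  if (is.null(annotations))
    annotations <- data.frame(onset = integer(), duration = integer(),
                              condition = character())
  new("EEGRecording", data = data, srate = srate,
      channelNames = as.character(channelNames),
      annotations = as.data.frame(annotations))
}

# ---------------------------------------------------------------------------
# GFPSeries
# ---------------------------------------------------------------------------

#' GFPSeries: global field power with detected peaks
#'
#' @slot values nonnegative numeric vector, one GFP value per sample.
#' @slot peakIndices sorted integer vector of strict interior local maxima.
#' @slot srate sampling rate of the originating recording (Hz).
#' @exportClass GFPSeries
setClass("GFPSeries",
  representation(values = "numeric", peakIndices = "integer",
                 srate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@values < 0)) msg <- c(msg, "GFP values must be >= 0")
    pk <- object@peakIndices
    if (length(pk)) {
      if (is.unsorted(pk, strictly = TRUE))
        msg <- c(msg, "peakIndices must be strictly increasing")
      if (min(pk) <= 1L || max(pk) >= length(object@values))
        msg <- c(msg, "peaks must be strictly interior")
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# TemplateSet
# ---------------------------------------------------------------------------

#' TemplateSet: fitted microstate topographies and diagnostics
#'
#' Rows of `maps` are unit-L2-norm, zero-mean (average-referenced)
#' template topographies from the polarity-invariant modified k-means.
#'
#' @slot maps K x channels numeric matrix.
#' @slot gev global explained variance in `[0, 1]`.
#' @slot residualNoise residual noise variance estimate.
#' @slot cv cross-validation criterion value (NA when not evaluated).
#' @slot seed integer seed used for the fit.
#' @slot restarts number of random restarts.
#' @slot channelNames channel labels matching the columns of `maps`.
#' @exportClass TemplateSet
setClass("TemplateSet",
  representation(maps = "matrix", gev = "numeric", residualNoise = "numeric",
                 cv = "numeric", seed = "integer", restarts = "integer",
                 channelNames = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@maps) < 1L) msg <- c(msg, "need at least one template")
    nrm <- sqrt(rowSums(object@maps^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "templates must have unit L2 norm")
    if (any(abs(rowMeans(object@maps)) > 1e-8))
      msg <- c(msg, "templates must have zero channel mean")
    if (!is.na(object@gev) && (object@gev < -1e-12 || object@gev > 1 + 1e-12))
      msg <- c(msg, "gev must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# ClusterFitResult
# ---------------------------------------------------------------------------

#' ClusterFitResult: per-K fit diagnostics and the selected K
#'
#' @slot table data.frame with columns `K`, `gev`, `residualNoise`, `cv`.
#' @slot selectedK the K minimising the cross-validation criterion
#'   (ties broken toward smaller K).
#' @slot templates list of [TemplateSet-class], one per searched K.
#' @exportClass ClusterFitResult
setClass("ClusterFitResult",
  representation(table = "data.frame", selectedK = "integer",
                 templates = "list"),
  validity = function(object) {
    msg <- character()
    need <- c("K", "gev", "residualNoise", "cv")
    if (!all(need %in% names(object@table)))
      msg <- c(msg, "table needs columns K, gev, residualNoise, cv")
    else {
      ok <- is.finite(object@table$cv)
      if (any(ok)) {
        best <- min(object@table$cv[ok])
        kbest <- min(object@table$K[ok][object@table$cv[ok] <= best + 1e-15])
        if (object@selectedK != kbest)
          msg <- c(msg, "selectedK must minimise cv (ties -> smaller K)")
      }
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# MicrostateSequence
# ---------------------------------------------------------------------------

#' MicrostateSequence: integer state labels with condition segments
#'
#' Labels are in `1..K` (NA outside segments is allowed); segments are
#' 1-based half-open `[start, end)` sample intervals tagged with a
#' condition label.
#'
#' @slot labels integer vector, one label per sample.
#' @slot segments data.frame with columns `start`, `end`, `condition`.
#' @slot srate sampling rate in Hz.
#' @slot K number of states.
#' @exportClass MicrostateSequence
setClass("MicrostateSequence",
  representation(labels = "integer", segments = "data.frame",
                 srate = "numeric", K = "integer"),
  validity = function(object) {
    msg <- character()
    seg <- object@segments
    if (!all(c("start", "end", "condition") %in% names(seg)))
      msg <- c(msg, "segments needs columns start, end, condition")
    else if (nrow(seg) > 0) {
      if (any(seg$start < 1L) || any(seg$end > length(object@labels) + 1L) ||
          any(seg$end <= seg$start))
        msg <- c(msg, "segments must be non-empty and within bounds")
      o <- order(seg$start)
      if (nrow(seg) > 1 && any(seg$end[o][-nrow(seg)] > seg$start[o][-1]))
        msg <- c(msg, "segments must not overlap")
      for (i in seq_len(nrow(seg))) {
        lab <- object@labels[seg$start[i]:(seg$end[i] - 1L)]
        if (anyNA(lab))
          msg <- c(msg, "labels must be defined inside every segment")
        else if (any(lab < 1L) || any(lab > object@K))
          msg <- c(msg, "labels inside segments must lie in 1..K")
      }
    }
    if (length(msg)) unique(msg) else TRUE
  })

#' Construct a MicrostateSequence
#'
#' @param labels integer vector of state labels (`1..K`; NA allowed outside
#'   segments).
#' @param segments data.frame with `start`, `end` (half-open, 1-based) and
#'   `condition`.
#' @param srate sampling rate in Hz.
#' @param K number of states; defaults to `max(labels, na.rm = TRUE)`.
#' @return A [MicrostateSequence-class].
#' @export
MicrostateSequence <- function(labels, segments, srate,
                               K = max(labels, na.rm = TRUE)) {
  new("MicrostateSequence", labels = as.integer(labels),
      segments = as.data.frame(segments), srate = srate, K = as.integer(K))
}

# ---------------------------------------------------------------------------
# CoverageDistribution
# ---------------------------------------------------------------------------

#' CoverageDistribution: microstate occupancy probabilities for a condition
#'
#' @slot pi numeric K-vector of probabilities summing to 1.
#' @slot condition the condition label.
#' @slot nSamples number of retained samples behind the estimate.
#' @exportClass CoverageDistribution
setClass("CoverageDistribution",
  representation(pi = "numeric", condition = "character",
                 nSamples = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@pi < 0)) msg <- c(msg, "probabilities must be >= 0")
    if (abs(sum(object@pi) - 1) > 1e-12)
      msg <- c(msg, "probabilities must sum to 1 (tol 1e-12)")
    if (length(msg)) msg else TRUE
  })

#' Construct a CoverageDistribution
#' @param pi numeric probability vector (renormalisation is NOT applied).
#' @param condition condition label.
#' @param nSamples sample count behind the estimate.
#' @return A [CoverageDistribution-class].
#' @export
CoverageDistribution <- function(pi, condition = "custom",
                                 nSamples = NA_integer_) {
  new("CoverageDistribution", pi = as.numeric(pi),
      condition = as.character(condition), nSamples = as.integer(nSamples))
}

# ---------------------------------------------------------------------------
# JointTransitionMatrix
# ---------------------------------------------------------------------------

#' JointTransitionMatrix: joint law of two consecutive microstates
#'
#' `Q[i, j] = Prob[k_{t-1} = i, k_t = j]` estimated over consecutive
#' within-segment sample pairs; the whole matrix sums to 1.
#'
#' @slot Q K x K nonnegative matrix summing to 1.
#' @slot nPairs number of consecutive pairs counted.
#' @exportClass JointTransitionMatrix
setClass("JointTransitionMatrix",
  representation(Q = "matrix", nPairs = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@Q) != ncol(object@Q)) msg <- c(msg, "Q must be square")
    if (any(object@Q < 0)) msg <- c(msg, "Q entries must be >= 0")
    if (abs(sum(object@Q) - 1) > 1e-12)
      msg <- c(msg, "Q must sum to 1 (tol 1e-12)")
    if (length(msg)) msg else TRUE
  })

#' Construct a JointTransitionMatrix
#' @param Q square nonnegative matrix summing to 1.
#' @param nPairs number of consecutive pairs behind the estimate.
#' @return A [JointTransitionMatrix-class].
#' @export
JointTransitionMatrix <- function(Q, nPairs = NA_integer_) {
  new("JointTransitionMatrix", Q = as.matrix(Q), nPairs = as.integer(nPairs))
}

# ---------------------------------------------------------------------------
# TransportProblem / BridgeSolution
# ---------------------------------------------------------------------------

#' TransportProblem: a discrete Schrodinger bridge instance
#'
#' Holds the resting two-step joint matrix `Q` (the reference coupling and
#' Gibbs kernel), the source and target marginals, and the transportation
#' cost matrix `C = -log Q` (`+Inf` exactly where `Q` is zero).
#'
#' @slot Q reference joint matrix (possibly pseudocount-smoothed).
#' @slot pi0 source (resting) marginal.
#' @slot piT target (task) marginal.
#' @slot C cost matrix, `-log(Q)`.
#' @exportClass TransportProblem
setClass("TransportProblem",
  representation(Q = "matrix", pi0 = "numeric", piT = "numeric",
                 C = "matrix"),
  prototype(Q = matrix(1, 1, 1), pi0 = 1, piT = 1, C = matrix(0, 1, 1)),
  validity = function(object) {
    msg <- character()
    K <- nrow(object@Q)
    if (length(object@pi0) != K || length(object@piT) != K)
      msg <- c(msg, "marginal lengths must match Q dimension")
    if (abs(sum(object@pi0) - 1) > 1e-9 || abs(sum(object@piT) - 1) > 1e-9)
      msg <- c(msg, "marginals must sum to 1")
    bad <- (object@Q > 0 & !is.finite(object@C)) |
           (object@Q == 0 & is.finite(object@C))
    if (any(bad))
      msg <- c(msg, "C must be -log Q with +Inf exactly on Q == 0")
    if (length(msg)) msg else TRUE
  })

#' BridgeSolution: Sinkhorn solution of a discrete Schrodinger bridge
#'
#' @slot P optimal transport plan (coupling) with the prescribed marginals.
#' @slot u,v Sinkhorn scaling vectors (on the active support).
#' @slot cost transition cost `D_KL(P || Q)` in nats.
#' @slot iterations Sinkhorn iterations used.
#' @slot marginalError worst absolute marginal violation at termination.
#' @exportClass BridgeSolution
setClass("BridgeSolution",
  representation(P = "matrix", u = "numeric", v = "numeric",
                 cost = "numeric", iterations = "integer",
                 marginalError = "numeric"))

# ---------------------------------------------------------------------------
# Accessor generics
# ---------------------------------------------------------------------------

#' Accessors for msbridge objects
#'
#' Small read-only accessors: `samplingRate`, `nChannels`, `nSamples`,
#' `channelNames`, `annotations`, `eegData`, `gfpValues`, `peakIndices`,
#' `templateMaps`, `nStates`, `gev`, `stateLabels`, `segments`,
#' `coverageProbs`, `jointMatrix`, `costMatrix`, `transportPlan`,
#' `transitionCost`.
#'
#' @param x an msbridge S4 object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases samplingRate nChannels nSamples channelNames annotations eegData
#'   gfpValues peakIndices templateMaps nStates gev stateLabels segments
#'   coverageProbs jointMatrix costMatrix transportPlan transitionCost
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("gfpValues", function(x) standardGeneric("gfpValues"))
#' @rdname accessors
#' @export
setGeneric("peakIndices", function(x) standardGeneric("peakIndices"))
#' @rdname accessors
#' @export
setGeneric("templateMaps", function(x) standardGeneric("templateMaps"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("gev", function(x) standardGeneric("gev"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("coverageProbs", function(x) standardGeneric("coverageProbs"))
#' @rdname accessors
#' @export
setGeneric("jointMatrix", function(x) standardGeneric("jointMatrix"))
#' @rdname accessors
#' @export
setGeneric("costMatrix", function(x) standardGeneric("costMatrix"))
#' @rdname accessors
#' @export
setGeneric("transportPlan", function(x) standardGeneric("transportPlan"))
#' @rdname accessors
#' @export
setGeneric("transitionCost", function(x) standardGeneric("transitionCost"))

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@srate)
#' @rdname accessors
setMethod("samplingRate", "MicrostateSequence", function(x) x@srate)
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))
#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname accessors
setMethod("channelNames", "TemplateSet", function(x) x@channelNames)
#' @rdname accessors
setMethod("annotations", "EEGRecording", function(x) x@annotations)
#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("gfpValues", "GFPSeries", function(x) x@values)
#' @rdname accessors
setMethod("peakIndices", "GFPSeries", function(x) x@peakIndices)
#' @rdname accessors
setMethod("templateMaps", "TemplateSet", function(x) x@maps)
#' @rdname accessors
setMethod("nStates", "TemplateSet", function(x) nrow(x@maps))
#' @rdname accessors
setMethod("nStates", "MicrostateSequence", function(x) x@K)
#' @rdname accessors
setMethod("nStates", "CoverageDistribution", function(x) length(x@pi))
#' @rdname accessors
setMethod("nStates", "JointTransitionMatrix", function(x) nrow(x@Q))
#' @rdname accessors
setMethod("gev", "TemplateSet", function(x) x@gev)
#' @rdname accessors
setMethod("stateLabels", "MicrostateSequence", function(x) x@labels)
#' @rdname accessors
setMethod("segments", "MicrostateSequence", function(x) x@segments)
#' @rdname accessors
setMethod("coverageProbs", "CoverageDistribution", function(x) x@pi)
#' @rdname accessors
setMethod("jointMatrix", "JointTransitionMatrix", function(x) x@Q)
#' @rdname accessors
setMethod("costMatrix", "TransportProblem", function(x) x@C)
#' @rdname accessors
setMethod("transportPlan", "BridgeSolution", function(x) x@P)
#' @rdname accessors
setMethod("transitionCost", "BridgeSolution", function(x) x@cost)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@srate,
              ncol(object@data) / object@srate))
  if (nrow(object@annotations))
    cat(sprintf("  annotations: %d intervals, conditions: %s\n",
                nrow(object@annotations),
                paste(unique(object@annotations$condition), collapse = ", ")))
})

setMethod("show", "GFPSeries", function(object) {
  cat(sprintf("GFPSeries: %d samples, %d peaks\n",
              length(object@values), length(object@peakIndices)))
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: K = %d templates over %d channels\n",
              nrow(object@maps), ncol(object@maps)))
  cat(sprintf("  GEV = %.4f, residual noise = %.4g, CV = %.4g\n",
              object@gev, object@residualNoise, object@cv))
})

setMethod("show", "ClusterFitResult", function(object) {
  cat(sprintf("ClusterFitResult: selected K = %d\n", object@selectedK))
  print(object@table, row.names = FALSE)
})

setMethod("show", "MicrostateSequence", function(object) {
  cat(sprintf("MicrostateSequence: %d samples, K = %d, %d segments @ %g Hz\n",
              length(object@labels), object@K, nrow(object@segments),
              object@srate))
})

setMethod("show", "CoverageDistribution", function(object) {
  cat(sprintf("CoverageDistribution (%s, n = %d):\n",
              object@condition, object@nSamples))
  print(round(object@pi, 4))
})

setMethod("show", "JointTransitionMatrix", function(object) {
  cat(sprintf("JointTransitionMatrix: K = %d, %d pairs\n",
              nrow(object@Q), object@nPairs))
  print(round(object@Q, 4))
})

setMethod("show", "BridgeSolution", function(object) {
  cat(sprintf(
    "BridgeSolution: cost = %.6g nats, %d iterations, marginal error %.3g\n",
    object@cost, object@iterations, object@marginalError))
})
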