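# EEG input/output and preprocessing: CSV+JSON reader/writer, zero-phase
# bandpass + downsampling, global field power, GFP peak extraction.

#' Read an EEG recording from a CSV matrix and a JSON sidecar
#'
#' The CSV holds the channels x samples matrix (one row per channel, a
#' header with channel names in the first column). The JSON sidecar holds
#' `srate` and an `annotations` array of `{onset, duration, condition}`
#' objects (1-based half-open sample intervals).
#'
#' @param csvPath path to the matrix CSV.
#' @param jsonPath path to the sidecar; defaults to `csvPath` with a
#'   `.json` extension.
#' @return An [EEGRecording-class].
#' @export
readEEGCsv <- function(csvPath, jsonPath = sub("\\.csv$", ".json", csvPath)) {
  if (!file.exists(csvPath))
    msbStop("msbridgeDataError", "EEG CSV not found: %s", csvPath)
  if (!file.exists(jsonPath))
    msbStop("msbridgeDataError", "JSON sidecar not found: %s", jsonPath)
  tab <- utils::read.csv(csvPath, check.names = FALSE)
  chn <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  side <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  ann <- side$annotations
  if (is.null(ann) || length(ann) == 0L)
    ann <- data.frame(onset = integer(), duration = integer(),
                      condition = character())
  EEGRecording(mat, srate = side$srate, channelNames = chn,
               annotations = as.data.frame(ann))
}

#' Write an EEG recording as CSV matrix + JSON sidecar
#'
#' @param rec an [EEGRecording-class].
#' @param csvPath destination CSV path.
#' @param jsonPath destination sidecar path (default: `.json` next to CSV).
#' @return Invisibly, the CSV path.
#' @export
writeEEGCsv <- function(rec, csvPath,
                        jsonPath = sub("\\.csv$", ".json", csvPath)) {
  tab <- data.frame(channel = channelNames(rec),
                    as.data.frame(eegData(rec)), check.names = FALSE)
  names(tab)[-1L] <- sprintf("s%d", seq_len(nSamples(rec)))
  utils::write.csv(tab, csvPath, row.names = FALSE)
  jsonlite::write_json(
    list(srate = samplingRate(rec), annotations = annotations(rec)),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' Zero-phase filter with odd-reflection padding
#'
#' Forward-backward filtering leaves edge transients whose size depends on
#' the initial conditions; extending the signal by odd reflection about its
#' endpoints before `signal::filtfilt` pushes those transients outside the
#' retained span. Padding covers several time constants of the slowest
#' filter pole.
#' @noRd
zeroPhasePad <- function(filt, x, padLen) {
  n <- length(x)
  padLen <- min(padLen, n - 1L)
  pre <- 2 * x[1L] - x[(padLen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padLen)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(padLen + 1L):(padLen + n)]
}

#' Bandpass-filter and downsample an EEG recording
#'
#' Applies a zero-phase Butterworth bandpass (order-2 high-pass at
#' `lowHz` and order-2 low-pass at `highHz`, each run forward-backward)
#' channel by channel, then decimates to `targetSrate`. The decimation
#' factor `srate / targetSrate` must be an integer, and `highHz` must lie
#' below the new Nyquist frequency so the bandpass itself anti-aliases.
#' Sample `t` of the output corresponds to input sample `t * factor`, so
#' an input of `n` samples yields `floor(n / factor)` output samples.
#' Annotation intervals are rescaled consistently (half-open arithmetic).
#'
#' @param rec an [EEGRecording-class].
#' @param lowHz,highHz band edges in Hz (defaults 1 and 40).
#' @param targetSrate output sampling rate in Hz (default 250).
#' @return The filtered, downsampled [EEGRecording-class].
#' @examples
#' rec <- EEGRecording(matrix(rnorm(64 * 1000), 64), srate = 500)
#' out <- preprocessEEG(rec)
#' samplingRate(out)  # 250
#' @export
preprocessEEG <- function(rec, lowHz = 1, highHz = 40, targetSrate = 250) {
  fs <- samplingRate(rec)
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2))
    msbStop("msbridgeParameterError",
            "band [%g, %g] Hz invalid for srate %g (need 0 < low < high < Nyquist)",
            lowHz, highHz, fs)
  factor <- fs / targetSrate
  if (abs(factor - round(factor)) > 1e-9)
    msbStop("msbridgeParameterError",
            "target srate %g must divide srate %g", targetSrate, fs)
  factor <- as.integer(round(factor))
  if (highHz >= targetSrate / 2)
    msbStop("msbridgeParameterError",
            "highHz %g must be below the target Nyquist %g", highHz,
            targetSrate / 2)
  hp <- signal::butter(2, lowHz / (fs / 2), type = "high")
  lp <- signal::butter(2, highHz / (fs / 2), type = "low")
  padLen <- as.integer(ceiling(3 * fs / lowHz))
  x <- eegData(rec)
  filt <- t(apply(x, 1L, function(ch)
    zeroPhasePad(hp, zeroPhasePad(lp, ch, padLen), padLen)))
  keep <- seq.int(factor, ncol(filt), by = factor)
  out <- filt[, keep, drop = FALSE]
  ann <- annotations(rec)
  if (nrow(ann)) {
    a0 <- ann$onset - 1L            # to 0-based half-open arithmetic
    e0 <- a0 + ann$duration
    a1 <- a0 %/% factor
    e1 <- e0 %/% factor
    ann <- data.frame(onset = a1 + 1L, duration = pmax(1L, e1 - a1),
                      condition = ann$condition)
    ann <- ann[ann$onset + ann$duration - 1L <= ncol(out), , drop = FALSE]
  }
  EEGRecording(out, srate = targetSrate, channelNames = channelNames(rec),
               annotations = ann)
}

#' Global field power of a recording
#'
#' GFP at time t is the population (divide-by-N) standard deviation of the
#' instantaneous scalp map across channels. Maps are average-referenced
#' first, which makes the GFP invariant to any common offset.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels.
#' @return A [GFPSeries-class] (peaks not yet detected).
#' @export
globalFieldPower <- function(rec) {
  if (nChannels(rec) < 2L)
    msbStop("msbridgeInputError",
            "GFP needs >= 2 channels, got %d", nChannels(rec))
  x <- avgReference(eegData(rec))
  vals <- sqrt(colMeans(x^2))
  new("GFPSeries", values = vals, peakIndices = integer(),
      srate = samplingRate(rec))
}

#' Detect strict local maxima of a GFP series
#'
#' A peak is an interior sample strictly greater than both neighbours.
#' When two peaks are closer than `minSeparation` samples, the larger one
#' is kept (ties keep the earlier index).
#'
#' @param g a [GFPSeries-class].
#' @param minSeparation minimum distance between retained peaks in samples
#'   (default 1: no thinning).
#' @return The [GFPSeries-class] with `peakIndices` filled in.
#' @export
detectGFPPeaks <- function(g, minSeparation = 1L) {
  if (minSeparation < 1L)
    msbStop("msbridgeParameterError", "minSeparation must be >= 1")
  v <- gfpValues(g)
  n <- length(v)
  pk <- integer()
  if (n >= 3L) {
    i <- 2L:(n - 1L)
    pk <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
  }
  if (minSeparation > 1L && length(pk) > 1L) {
    # greedy by height, earlier index wins ties
    ord <- order(-v[pk], pk)
    keep <- logical(length(pk))
    taken <- integer()
    for (j in ord) {
      if (!length(taken) || all(abs(pk[j] - taken) >= minSeparation)) {
        keep[j] <- TRUE
        taken <- c(taken, pk[j])
      }
    }
    pk <- sort(pk[keep])
  }
  new("GFPSeries", values = v, peakIndices = as.integer(pk), srate = g@srate)
}

#' Randomly sample peak topographies for clustering
#'
#' Draws `n` GFP-peak maps uniformly without replacement (reproducible for
#' a given seed) and average-references each.
#'
#' @param rec the preprocessed [EEGRecording-class].
#' @param g a [GFPSeries-class] with detected peaks.
#' @param n number of peak maps to draw (clamped error if more than
#'   available).
#' @param seed RNG seed.
#' @return An `n x channels` numeric matrix of average-referenced maps.
#' @export
samplePeakMaps <- function(rec, g, n, seed = 1L) {
  pk <- peakIndices(g)
  if (n > length(pk))
    msbStop("msbridgeInsufficientDataError",
            "requested %d peak maps but only %d peaks available",
            n, length(pk))
  if (n == 0L)
    return(matrix(numeric(), 0L, nChannels(rec),
                  dimnames = list(NULL, channelNames(rec))))
  sel <- withSeed(seed, sort(sample(pk, n)))
  maps <- t(eegData(rec)[, sel, drop = FALSE])
  maps <- avgReferenceRows(maps)
  colnames(maps) <- channelNames(rec)
  maps
}
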