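#' @import methods
NULL

#' EEGRecording: a multichannel EEG file in the platform's working format
#'
#' One EEG file is held as a list of recording-period matrices (channels x
#' samples, real microvolts) plus acquisition metadata, event tags, and an
#' append-only processing history. Recording periods are contiguous spans of
#' continuously recorded data; gaps between periods are never bridged by any
#' downstream operation.
#'
#' Sample indices are 0-based throughout the package (an event at 10.0 s in
#' a 250 Hz file has sample 2500); channel and period indices are 1-based as
#' usual in R. Channels flagged bad have their rows stored as \code{NA} and
#' are excluded from every average.
#'
#' @slot periods list of numeric matrices, one per recording period, each
#'   with \code{length(channelLabels)} rows.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector of channel names.
#' @slot layoutName acquisition electrode layout ("net type"), e.g.
#'   \code{"HydroCel GSN 128 1.0"}.
#' @slot tenTwentyMap named character vector mapping channel labels to 10-20
#'   system names (possibly partial).
#' @slot lineNoiseHz mains interference frequency for this file (50 or 60).
#' @slot dataType one of \code{"baseline"}, \code{"event_tagged"},
#'   \code{"conditioned_baseline"}.
#' @slot events data.frame with columns \code{label}, \code{period} (1-based),
#'   \code{sample} (0-based within period), \code{applied_offset_samples}.
#' @slot originalSamplingRate acquisition sampling rate before any resampling.
#' @slot badChannels integer vector of 1-based bad-channel indices.
#' @slot history append-only list of provenance entries, each a list with
#'   \code{module}, \code{parameters}, \code{timestamp}.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    periods = "list",
    samplingRate = "numeric",
    channelLabels = "character",
    layoutName = "character",
    tenTwentyMap = "character",
    lineNoiseHz = "numeric",
    dataType = "character",
    events = "data.frame",
    originalSamplingRate = "numeric",
    badChannels = "integer",
    history = "list"
  )
)

validEEGRecording <- function(object) {
  msgs <- character(0)
  nch <- length(object@channelLabels)
  if (length(object@periods) < 1L) msgs <- c(msgs, "recording must have at least one recording period")
  for (i in seq_along(object@periods)) {
    p <- object@periods[[i]]
    if (!is.matrix(p) || !is.numeric(p))
      msgs <- c(msgs, sprintf("period %d is not a numeric matrix", i))
    else if (nrow(p) != nch)
      msgs <- c(msgs, sprintf("period %d has %d rows but there are %d channel labels", i, nrow(p), nch))
  }
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a single positive number")
  if (!object@dataType %in% c("baseline", "event_tagged", "conditioned_baseline"))
    msgs <- c(msgs, sprintf("unknown data type '%s'", object@dataType))
  ev <- object@events
  req <- c("label", "period", "sample", "applied_offset_samples")
  if (!all(req %in% names(ev))) {
    msgs <- c(msgs, "events must have columns label, period, sample, applied_offset_samples")
  } else if (nrow(ev) > 0L) {
    for (j in seq_len(nrow(ev))) {
      pi <- ev$period[j]
      if (pi < 1L || pi > length(object@periods)) {
        msgs <- c(msgs, sprintf("event '%s' (row %d) refers to missing period %d", ev$label[j], j, pi))
      } else {
        n <- ncol(object@periods[[pi]])
        if (ev$sample[j] < 0 || ev$sample[j] >= n)
          msgs <- c(msgs, sprintf("event '%s' (row %d) at sample %g is outside period %d (0..%d)",
                                  ev$label[j], j, ev$sample[j], pi, n - 1L))
      }
    }
  }
  if (any(object@badChannels < 1L) || any(object@badChannels > nch))
    msgs <- c(msgs, "badChannels indices out of range")
  if (length(msgs)) msgs else TRUE
}
setValidity("EEGRecording", validEEGRecording)

#' ArtifactMask: unusable-sample intervals per recording period
#'
#' Half-open 0-based sample intervals \code{[start, end)} per recording
#' period, marking data in which any channel exceeded the amplitude
#' threshold, extended outward to the nearest zero-crossings (the full
#' rise-and-fall of each excursion). Intervals are sorted, non-overlapping
#' and merged when adjacent.
#'
#' @slot intervals list (one element per period) of 2-column matrices
#'   (columns \code{start}, \code{end}).
#' @slot thresholdUv amplitude threshold in microvolts.
#' @exportClass ArtifactMask
setClass("ArtifactMask",
  representation(intervals = "list", thresholdUv = "numeric")
)
setValidity("ArtifactMask", function(object) {
  for (iv in object@intervals) {
    if (nrow(iv) == 0L) next
    if (any(iv[, 2L] <= iv[, 1L])) return("mask intervals must satisfy start < end")
    if (nrow(iv) > 1L && any(diff(iv[, 1L]) <= 0)) return("mask intervals must be sorted")
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) return("mask intervals must be disjoint and merged")
  }
  if (object@thresholdUv <= 0) return("thresholdUv must be positive")
  TRUE
})

#' SegmentSet: a stack of equal-length EEG segments
#'
#' Segments (epochs) are stored as a channels x samples-per-segment x
#' n-segments array with per-segment keep/reject flags, the period and
#' absolute 0-based start sample each segment came from, and per-sample time
#' relative to the stimulus (event data) or segment start (baseline data).
#'
#' @slot data 3-D numeric array, channels x samples x segments.
#' @slot relTimeMs per-sample time in ms (length = samples per segment).
#' @slot keepFlags logical per segment; rejection only flips TRUE -> FALSE.
#' @slot conditionLabel condition / event label ("" for baseline).
#' @slot sourcePeriod integer per segment (1-based period index).
#' @slot sourceStart numeric per segment (0-based absolute start sample).
#' @slot channelLabels character vector.
#' @slot samplingRate Hz.
#' @slot skippedEvents number of events skipped because their window ran
#'   outside the recording period.
#' @exportClass SegmentSet
setClass("SegmentSet",
  representation(
    data = "array",
    relTimeMs = "numeric",
    keepFlags = "logical",
    conditionLabel = "character",
    sourcePeriod = "integer",
    sourceStart = "numeric",
    channelLabels = "character",
    samplingRate = "numeric",
    skippedEvents = "integer"
  )
)
setValidity("SegmentSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-D array (channels x samples x segments)")
  if (d[1L] != length(object@channelLabels)) return("channel dimension does not match channelLabels")
  if (d[2L] != length(object@relTimeMs)) return("sample dimension does not match relTimeMs")
  if (d[3L] != length(object@keepFlags)) return("segment dimension does not match keepFlags")
  if (d[3L] != length(object@sourcePeriod) || d[3L] != length(object@sourceStart))
    return("per-segment provenance vectors do not match the number of segments")
  TRUE
})

#' PsdResult: per-channel, per-segment power spectra
#'
#' Single-sided power, \code{2 |X_k|^2 / (l * sr)} per bin (factor 1 at the
#' DC and Nyquist bins), with the across-kept-segments mean in
#' \code{meanPower}.
#'
#' @slot power channels x freq-bins x kept-segments array (microvolt^2 scale).
#' @slot freqsHz bin centre frequencies, 0..sr/2.
#' @slot method "rectangular", "hanning" or "multitaper".
#' @slot fftLen transform length after zero-padding.
#' @slot meanPower channels x freq-bins matrix, mean over kept segments.
#' @slot channelLabels character.
#' @slot samplingRate Hz.
#' @slot segIndex original segment indices of the kept segments.
#' @exportClass PsdResult
setClass("PsdResult",
  representation(
    power = "array",
    freqsHz = "numeric",
    method = "character",
    fftLen = "integer",
    meanPower = "matrix",
    channelLabels = "character",
    samplingRate = "numeric",
    segIndex = "integer"
  )
)
setValidity("PsdResult", function(object) {
  if (any(object@power < -1e-12, na.rm = TRUE)) return("power must be non-negative")
  if (length(object@freqsHz) > 1L && any(diff(object@freqsHz) <= 0))
    return("freqsHz must be strictly increasing")
  TRUE
})

#' ItpcResult: inter-trial phase coherence surfaces
#'
#' Complex ITPC per channel, frequency bin and sliding time window: the
#' across-trial mean of unit-normalized spectral phasors. Magnitude
#' (\code{Mod}) is 0 for random phase and 1 for perfect phase locking;
#' phase is \code{Arg}.
#'
#' @slot itpc complex array, channels x freq-bins x time-windows.
#' @slot freqsHz subwindow transform bin frequencies.
#' @slot windowCentersMs centre time of each subwindow, in segment-relative ms.
#' @slot nTrials number of trials (kept segments) entering the average.
#' @slot subwindowMs subwindow length in ms.
#' @slot channelLabels character.
#' @exportClass ItpcResult
setClass("ItpcResult",
  representation(
    itpc = "array",
    freqsHz = "numeric",
    windowCentersMs = "numeric",
    nTrials = "integer",
    subwindowMs = "numeric",
    channelLabels = "character"
  )
)
setValidity("ItpcResult", function(object) {
  if (any(Mod(object@itpc) > 1 + 1e-12, na.rm = TRUE))
    return("|itpc| must not exceed 1")
  if (object@nTrials < 1L) return("nTrials must be >= 1")
  TRUE
})
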