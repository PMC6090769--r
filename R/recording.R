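#' Construct an EEGRecording from recording-period matrices
#'
#' Assembles the platform's working format from one amplitude matrix per
#' recording period (channels x samples, microvolts) plus acquisition
#' metadata. A 129-channel, 60 s recording sampled at 500 Hz is one
#' 129 x 30000 matrix.
#'
#' @param periods a matrix or list of matrices, channels x samples each.
#' @param samplingRate sampling rate in Hz (positive).
#' @param channelLabels channel names; defaults to \code{E1..En}.
#' @param events data.frame with columns \code{label}, \code{period},
#'   \code{sample} (0-based) and optionally \code{applied_offset_samples}.
#' @param layoutName electrode layout (net type) string.
#' @param lineNoiseHz mains frequency, default 60.
#' @param dataType \code{"baseline"} (default), \code{"event_tagged"} or
#'   \code{"conditioned_baseline"}.
#' @param tenTwentyMap optional named character vector mapping channel
#'   labels to 10-20 names.
#' @param badChannels integer indices of channels to store as missing.
#' @return an \linkS4class{EEGRecording} whose history holds one
#'   \code{"format"} entry.
#' @examples
#' rec <- makeRecording(matrix(0, 4, 250), samplingRate = 250)
#' nChannels(rec)
#' @export
makeRecording <- function(periods, samplingRate, channelLabels = NULL,
                          events = NULL, layoutName = "unknown",
                          lineNoiseHz = 60, dataType = "baseline",
                          tenTwentyMap = character(0),
                          badChannels = integer(0)) {
  if (is.matrix(periods)) periods <- list(periods)
  if (!is.list(periods) || length(periods) == 0L)
    stop("at least one recording period is required")
  nch <- unique(vapply(periods, nrow, integer(1)))
  if (length(nch) != 1L)
    stop("all recording periods must share the same channel count; got ",
         paste(nch, collapse = ", "))
  if (is.null(channelLabels)) channelLabels <- paste0("E", seq_len(nch))
  if (length(channelLabels) != nch)
    stop(sprintf("%d channel labels supplied for %d matrix rows",
                 length(channelLabels), nch))
  if (length(samplingRate) != 1L || !is.finite(samplingRate) || samplingRate <= 0)
    stop("samplingRate must be a single positive number")
  if (is.null(events)) events <- emptyEvents()
  if (is.null(events$applied_offset_samples))
    events$applied_offset_samples <- rep(0, nrow(events))
  if (is.null(events$period)) events$period <- rep(1L, nrow(events))
  events <- events[, c("label", "period", "sample", "applied_offset_samples")]
  events$period <- as.integer(events$period)
  periods <- lapply(periods, function(p) {
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  rec <- new("EEGRecording",
             periods = periods,
             samplingRate = as.numeric(samplingRate),
             channelLabels = as.character(channelLabels),
             layoutName = layoutName,
             tenTwentyMap = tenTwentyMap,
             lineNoiseHz = as.numeric(lineNoiseHz),
             dataType = dataType,
             events = events,
             originalSamplingRate = as.numeric(samplingRate),
             badChannels = as.integer(badChannels),
             history = list())
  rec <- appendHistory(rec, "format",
                       list(n_periods = length(periods),
                            sampling_rate = samplingRate,
                            layout = layoutName,
                            data_type = dataType))
  if (length(badChannels)) {
    for (i in seq_along(rec@periods)) rec@periods[[i]][badChannels, ] <- NA_real_
  }
  rec
}

## Append one provenance entry (module name + parameter set + timestamp).
## Every pipeline stage calls this exactly once, so history length counts
## stages run.
appendHistory <- function(rec, module, parameters = list()) {
  rec@history <- c(rec@history,
                   list(list(module = module, parameters = parameters,
                             timestamp = nowStamp())))
  rec
}

## Indices of channels not flagged bad.
goodChannels <- function(rec) setdiff(seq_along(rec@channelLabels), rec@badChannels)

#' @rdname accessors
#' @export
setMethod("recordingPeriods", "EEGRecording", function(x) x@periods)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("eventTags", "EEGRecording", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("dataType", "EEGRecording", function(x) x@dataType)
#' @rdname accessors
#' @export
setMethod("processingHistory", "EEGRecording", function(x) x@history)
#' @rdname accessors
#' @export
setMethod("badChannels", "EEGRecording", function(x) x@badChannels)
#' @rdname accessors
#' @export
setMethod("lineNoiseHz", "EEGRecording", function(x) x@lineNoiseHz)
#' @rdname accessors
#' @export
setMethod("layoutName", "EEGRecording", function(x) x@layoutName)
#' @rdname accessors
#' @export
setMethod("originalSamplingRate", "EEGRecording", function(x) x@originalSamplingRate)
#' @rdname accessors
#' @export
setMethod("nChannels", "EEGRecording", function(x) length(x@channelLabels))
#' @rdname accessors
#' @export
setMethod("nPeriods", "EEGRecording", function(x) length(x@periods))

setMethod("show", "EEGRecording", function(object) {
  durs <- vapply(object@periods, ncol, integer(1)) / object@samplingRate
  cat(sprintf("EEGRecording: %d channels (%s), %d period(s), %.1f s total @ %g Hz\n",
              length(object@channelLabels), object@layoutName,
              length(object@periods), sum(durs), object@samplingRate))
  cat(sprintf("  data type: %s; %d event tag(s); %d bad channel(s); line noise %g Hz\n",
              object@dataType, nrow(object@events),
              length(object@badChannels), object@lineNoiseHz))
  cat(sprintf("  history: %s\n",
              paste(vapply(object@history, function(h) h$module, character(1)),
                    collapse = " -> ")))
})

#' @rdname accessors
#' @export
setMethod("maskIntervals", "ArtifactMask", function(x) x@intervals)

setMethod("show", "ArtifactMask", function(object) {
  n <- sum(vapply(object@intervals, nrow, integer(1)))
  cat(sprintf("ArtifactMask: %d interval(s) over %d period(s), threshold %g uV\n",
              n, length(object@intervals), object@thresholdUv))
})

#' @rdname accessors
#' @export
setMethod("segmentData", "SegmentSet", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("keepFlags", "SegmentSet", function(x) x@keepFlags)
#' @rdname accessors
#' @export
setMethod("nSegments", "SegmentSet", function(x) dim(x@data)[3L])
#' @rdname accessors
#' @export
setMethod("relTimeMs", "SegmentSet", function(x) x@relTimeMs)
#' @rdname accessors
#' @export
setMethod("channelLabels", "SegmentSet", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SegmentSet", function(x) x@samplingRate)

setMethod("show", "SegmentSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("SegmentSet: %d segment(s) of %d sample(s) x %d channel(s) @ %g Hz (%d kept)\n",
              d[3L], d[2L], d[1L], object@samplingRate, sum(object@keepFlags)))
  if (nzchar(object@conditionLabel))
    cat(sprintf("  condition: %s\n", object@conditionLabel))
})

#' @rdname accessors
#' @export
setMethod("psdFreqs", "PsdResult", function(x) x@freqsHz)
#' @rdname accessors
#' @export
setMethod("meanPower", "PsdResult", function(x) x@meanPower)
#' @rdname accessors
#' @export
setMethod("channelLabels", "PsdResult", function(x) x@channelLabels)

setMethod("show", "PsdResult", function(object) {
  cat(sprintf("PsdResult (%s): %d channel(s) x %d bin(s) (0..%g Hz), %d segment(s), fft length %d\n",
              object@method, dim(object@meanPower)[1L], dim(object@meanPower)[2L],
              max(object@freqsHz), dim(object@power)[3L], object@fftLen))
})

#' @rdname accessors
#' @export
setMethod("itpcValues", "ItpcResult", function(x) x@itpc)
#' @rdname accessors
#' @export
setMethod("psdFreqs", "ItpcResult", function(x) x@freqsHz)
#' @rdname accessors
#' @export
setMethod("windowCentersMs", "ItpcResult", function(x) x@windowCentersMs)
#' @rdname accessors
#' @export
setMethod("channelLabels", "ItpcResult", function(x) x@channelLabels)

setMethod("show", "ItpcResult", function(object) {
  cat(sprintf("ItpcResult: %d channel(s) x %d freq bin(s) x %d window(s) (%g ms subwindows), %d trial(s)\n",
              dim(object@itpc)[1L], dim(object@itpc)[2L], dim(object@itpc)[3L],
              object@subwindowMs, object@nTrials))
})
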