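## Per-file acquisition harmonization: event-tag offsets, data-type
## assignment, recording-period selection, and the run-level safety checks
## (resampling vs low-pass Nyquist rule; ICA sample-size rule).

#' Read a per-file offset / override table
#'
#' One CSV harmonizes acquisition differences across a dataset: columns
#' \code{file_id}, \code{offset_samples} (event-tag offset in samples at
#' the file's original sampling rate), and optional \code{line_noise_hz},
#' \code{layout_name}, \code{periods} (semicolon-separated 1-based period
#' indices). Absent files fall back to offset 0 (with a warning at lookup).
#'
#' @param path CSV path.
#' @return data.frame with one row per file.
#' @export
readOffsetTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("file_id", "offset_samples") %in% names(tab)))
    stop("offset table must have columns file_id and offset_samples")
  tab
}

## Offset lookup with the table's default (0) and a logged warning for
## absent files.
lookupOffset <- function(offsetTable, fileId) {
  i <- match(fileId, offsetTable$file_id)
  if (is.na(i)) {
    warning(sprintf("file '%s' not in offset table; using default offset 0", fileId))
    return(0L)
  }
  as.integer(offsetTable$offset_samples[i])
}

#' Apply per-file event-tag offsets
#'
#' Shifts every event tag by the file's offset (in samples), recording the
#' applied offset on each event. Events shifted past their recording
#' period's end (or before its start) are dropped with a warning rather
#' than clamped. Applying offsets twice is an error.
#'
#' @param recording an event-tagged or conditioned-baseline
#'   \linkS4class{EEGRecording}.
#' @param offsetTable data.frame from \code{\link{readOffsetTable}}, or a
#'   single integer offset.
#' @param fileId file identifier used for table lookup.
#' @return the recording with shifted events.
#' @export
applyEventOffsets <- function(recording, offsetTable, fileId = "") {
  stopifnot(is(recording, "EEGRecording"))
  if (!recording@dataType %in% c("event_tagged", "conditioned_baseline"))
    stop("event offsets apply only to event_tagged or conditioned_baseline data")
  ev <- recording@events
  if (nrow(ev) && any(ev$applied_offset_samples != 0))
    stop("offsets already applied to this recording")
  off <- if (is.numeric(offsetTable) && length(offsetTable) == 1L) {
    as.integer(offsetTable)
  } else {
    lookupOffset(offsetTable, fileId)
  }
  nDropped <- 0L
  if (nrow(ev)) {
    ev$sample <- ev$sample + off
    ev$applied_offset_samples <- rep(off, nrow(ev))
    nper <- vapply(recording@periods, ncol, integer(1))
    inb <- ev$sample >= 0 & ev$sample < nper[ev$period]
    nDropped <- sum(!inb)
    if (nDropped > 0L) {
      warning(sprintf("%d event(s) shifted out of period bounds were dropped", nDropped))
      ev <- ev[inb, , drop = FALSE]
      rownames(ev) <- NULL
    }
  }
  recording@events <- ev
  appendHistory(recording, "apply_event_offsets",
                list(offset_samples = off, file_id = fileId,
                     n_dropped = nDropped))
}

#' Set the data type of a recording
#'
#' Marks a recording as \code{"baseline"}, \code{"event_tagged"} or
#' \code{"conditioned_baseline"}. For baseline data any event tags are
#' retained in the metadata but ignored by segmentation. Idempotent.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param dataType one of the three type strings.
#' @return the recording.
#' @export
setDataType <- function(recording, dataType) {
  stopifnot(is(recording, "EEGRecording"))
  if (!dataType %in% c("baseline", "event_tagged", "conditioned_baseline"))
    stop("unknown data type '", dataType, "'")
  recording@dataType <- dataType
  appendHistory(recording, "set_data_type", list(data_type = dataType))
}

#' Select (and reorder) recording periods
#'
#' Retains only the named recording periods, in the given order, together
#' with their events; downstream outputs are reported separately per
#' period.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param indices 1-based period indices to keep, in output order.
#' @return the reduced recording.
#' @export
selectRecordingPeriods <- function(recording, indices) {
  stopifnot(is(recording, "EEGRecording"))
  indices <- as.integer(indices)
  nper <- length(recording@periods)
  if (length(indices) == 0L || any(indices < 1L) || any(indices > nper))
    stop(sprintf("period indices out of range; valid range is 1..%d", nper))
  recording@periods <- recording@periods[indices]
  ev <- recording@events
  keep <- ev$period %in% indices
  ev <- ev[keep, , drop = FALSE]
  ev$period <- match(ev$period, indices)
  rownames(ev) <- NULL
  recording@events <- ev
  appendHistory(recording, "select_recording_periods",
                list(selected = indices))
}

#' Check the resampling-vs-low-pass Nyquist rule
#'
#' The minimum sampling rate a run will resample to must be at least twice
#' the low-pass cutoff, or aliasing would fold filtered-through energy back
#' into band. The boundary (exactly 2x) passes but is flagged: in practice
#' the low-pass cutoff should sit below, not at, the Nyquist frequency of
#' the resampling rate, because real filters have finite transition bands.
#'
#' @param lowpassHz low-pass filter cutoff, Hz.
#' @param minTargetRateHz minimum post-resampling rate in the run, Hz.
#' @return TRUE (pass) or FALSE (fail); a boundary pass carries a message.
#' @export
checkResampleVsLowpass <- function(lowpassHz, minTargetRateHz) {
  stopifnot(lowpassHz > 0, minTargetRateHz > 0)
  if (minTargetRateHz < 2 * lowpassHz) return(FALSE)
  if (minTargetRateHz == 2 * lowpassHz)
    message("low-pass cutoff sits exactly at the resampling Nyquist frequency; ",
            "a cutoff below Nyquist is recommended")
  TRUE
}

#' Check the ICA sample-size rule
#'
#' A stable ICA decomposition of c channels needs at least x * c^2 data
#' samples, with x at minimum 20 (up to 30 for a conservative choice);
#' effective samples should account for any downsampling.
#'
#' @param nChannels channel count entering ICA.
#' @param nSamples number of data samples (post-downsampling).
#' @param xFactor multiplier, default 20.
#' @return TRUE if \code{nSamples >= xFactor * nChannels^2}.
#' @export
checkIcaSamples <- function(nChannels, nSamples, xFactor = 20) {
  stopifnot(nChannels >= 1, nSamples >= 1, xFactor > 0)
  nSamples >= xFactor * nChannels^2
}
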