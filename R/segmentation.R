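## Division of continuous recordings into equal-length segments, with
## amplitude-threshold artifact handling either after segmentation
## (flag-based rejection) or before it (zero-crossing-extended masking of
## the continuous data), joint-probability rejection, within-segment
## detrending, sub-segmenting and baseline correction.
##
## Sample indices are 0-based; segment windows are half-open [start, end).
## Segments never span recording-period boundaries: non-continuous data
## are never concatenated.

newSegmentSet <- function(dataList, relTimeMs, sourcePeriod, sourceStart,
                          channelLabels, samplingRate, conditionLabel = "",
                          skippedEvents = 0L) {
  nch <- length(channelLabels)
  len <- length(relTimeMs)
  nseg <- length(dataList)
  d <- array(NA_real_, dim = c(nch, len, nseg))
  for (k in seq_len(nseg)) d[, , k] <- dataList[[k]]
  new("SegmentSet", data = d, relTimeMs = relTimeMs,
      keepFlags = rep(TRUE, nseg), conditionLabel = conditionLabel,
      sourcePeriod = as.integer(sourcePeriod), sourceStart = as.numeric(sourceStart),
      channelLabels = channelLabels, samplingRate = samplingRate,
      skippedEvents = as.integer(skippedEvents))
}

#' Cut stimulus-locked segments from event-tagged data
#'
#' For each event tag matching \code{eventLabel}, cuts the samples
#' \code{[s + round(startMs*sr/1000), s + round(endMs*sr/1000))} from the
#' event's recording period, where s is the (offset-corrected) event
#' sample. Start and end may be negative or positive. Events whose window
#' would run outside the period are skipped with a warning and counted in
#' the result's \code{skippedEvents}.
#'
#' @param recording an event-tagged \linkS4class{EEGRecording} (offsets
#'   already applied).
#' @param eventLabel event code(s) of the stimulus of interest.
#' @param startMs,endMs segment window relative to the stimulus, ms
#'   (\code{startMs < endMs}).
#' @return a \linkS4class{SegmentSet} with per-sample stimulus-relative
#'   times; empty (with a warning) if no event matches.
#' @export
segmentEvents <- function(recording, eventLabel, startMs, endMs) {
  stopifnot(is(recording, "EEGRecording"))
  if (recording@dataType != "event_tagged")
    stop("segmentEvents requires data_type 'event_tagged'")
  if (!(startMs < endMs)) stop("segment start must precede segment end")
  sr <- recording@samplingRate
  s0 <- roundHalfUp(startMs * sr / 1000)
  s1 <- roundHalfUp(endMs * sr / 1000)
  len <- s1 - s0
  relTimeMs <- (s0 + seq_len(len) - 1) * 1000 / sr
  ev <- recording@events
  ev <- ev[ev$label %in% eventLabel, , drop = FALSE]
  if (nrow(ev) == 0L) {
    warning("no events matching '", paste(eventLabel, collapse = "','"),
            "'; returning an empty segment set")
    return(newSegmentSet(list(), relTimeMs, integer(0), numeric(0),
                         recording@channelLabels, sr,
                         conditionLabel = paste(eventLabel, collapse = "+")))
  }
  segs <- list(); per <- integer(0); st <- numeric(0); skipped <- 0L
  for (j in seq_len(nrow(ev))) {
    p <- recording@periods[[ev$period[j]]]
    a <- ev$sample[j] + s0
    b <- ev$sample[j] + s1
    if (a < 0 || b > ncol(p)) { skipped <- skipped + 1L; next }
    segs[[length(segs) + 1L]] <- p[, (a + 1):b, drop = FALSE]
    per <- c(per, ev$period[j]); st <- c(st, a)
  }
  if (skipped > 0L)
    warning(sprintf("%d event(s) skipped: segment window exceeds period bounds", skipped))
  newSegmentSet(segs, relTimeMs, per, st, recording@channelLabels, sr,
                conditionLabel = paste(eventLabel, collapse = "+"),
                skippedEvents = skipped)
}

## Tile non-overlapping windows of segLen samples over half-open gaps
## [start, end); sub-length remainders are excluded. Returns 0-based starts.
tileStarts <- function(gaps, segLen) {
  starts <- numeric(0)
  for (g in seq_len(nrow(gaps))) {
    a <- gaps[g, 1L]; b <- gaps[g, 2L]
    k <- floor((b - a) / segLen)
    if (k >= 1) starts <- c(starts, a + segLen * (0:(k - 1)))
  }
  starts
}

segmentFromStarts <- function(recording, perStarts, segLen, conditionLabel = "") {
  sr <- recording@samplingRate
  relTimeMs <- (seq_len(segLen) - 1) * 1000 / sr
  segs <- list(); per <- integer(0); st <- numeric(0)
  for (i in seq_along(perStarts)) {
    p <- recording@periods[[i]]
    for (a in perStarts[[i]]) {
      segs[[length(segs) + 1L]] <- p[, (a + 1):(a + segLen), drop = FALSE]
      per <- c(per, i); st <- c(st, a)
    }
  }
  newSegmentSet(segs, relTimeMs, per, st, recording@channelLabels, sr,
                conditionLabel = conditionLabel)
}

#' Tile baseline data into non-overlapping segments
#'
#' Per recording period, consecutive non-overlapping windows of
#' \code{round(segmentLenS * sr)} samples starting at sample 0; the
#' trailing remainder, too short for its own segment, is excluded from
#' analysis. Periods are never concatenated. Event tags, if present, are
#' ignored for baseline data.
#'
#' @param recording a baseline \linkS4class{EEGRecording}.
#' @param segmentLenS segment length in seconds.
#' @return a \linkS4class{SegmentSet}; empty (with a warning) if every
#'   period is shorter than one segment.
#' @export
segmentBaseline <- function(recording, segmentLenS) {
  stopifnot(is(recording, "EEGRecording"), segmentLenS > 0)
  if (recording@dataType != "baseline")
    stop("segmentBaseline requires data_type 'baseline'")
  segLen <- roundHalfUp(segmentLenS * recording@samplingRate)
  perStarts <- lapply(recording@periods, function(p) {
    tileStarts(matrix(c(0, ncol(p)), 1L), segLen)
  })
  if (all(lengths(perStarts) == 0L))
    warning("segment length exceeds every recording period; empty segment set")
  segmentFromStarts(recording, perStarts, segLen)
}

## Zero-crossing-extended suprathreshold intervals for one channel.
## Maximal same-sign nonzero runs are delimited by exact zeros or sign
## flips; a run containing any |x| > threshold sample is masked from the
## crossing sample before it through the crossing sample after it
## (period edges when no crossing exists). Returns [start, end) rows.
channelMaskIntervals <- function(x, thresholdUv) {
  n <- length(x)
  over <- abs(x) > thresholdUv
  if (!any(over)) return(matrix(numeric(0), ncol = 2L))
  sgn <- sign(x)
  boundary <- sgn == 0 | c(FALSE, sgn[-1L] * sgn[-n] < 0)
  runId <- cumsum(boundary)
  bad <- unique(runId[over])
  iv <- matrix(0, length(bad), 2L)
  for (k in seq_along(bad)) {
    idx <- which(runId == bad[k] & sgn != 0)
    a <- idx[1L]; b <- idx[length(idx)]
    start <- if (a > 1L) a - 1L else 1L        # include the crossing sample
    end <- if (b < n) b + 1L else n
    iv[k, ] <- c(start - 1L, end)              # to 0-based half-open
  }
  iv
}

#' Build a zero-crossing-extended artifact mask
#'
#' Emulates hand-editing practice: every data point above threshold in any
#' channel is extended, in that channel, to the nearest zero-crossing at or
#' before and at or after it (the full rise and fall of the excursion;
#' period edges when no crossing exists). The mask is the union of these
#' intervals across channels, merged per period. Bad channels are excluded.
#'
#' @param recording a continuous \linkS4class{EEGRecording}.
#' @param thresholdUv amplitude threshold in microvolts (two-sided:
#'   \code{|x| > threshold}).
#' @return an \linkS4class{ArtifactMask}.
#' @export
buildArtifactMask <- function(recording, thresholdUv) {
  stopifnot(is(recording, "EEGRecording"), thresholdUv > 0)
  good <- goodChannels(recording)
  intervals <- lapply(recording@periods, function(p) {
    iv <- do.call(rbind, lapply(good, function(ch)
      channelMaskIntervals(p[ch, ], thresholdUv)))
    mergeIntervals(iv)
  })
  new("ArtifactMask", intervals = intervals, thresholdUv = thresholdUv)
}

#' Segment the data remaining between masked intervals
#'
#' Within each unmasked gap of each recording period, tiles non-overlapping
#' segments of the requested length from the gap's start; remainders too
#' short for a segment are excluded. With an empty mask this reduces
#' exactly to \code{\link{segmentBaseline}}.
#'
#' @param recording a baseline \linkS4class{EEGRecording}.
#' @param mask an \linkS4class{ArtifactMask} for the same recording.
#' @param segmentLenS segment length in seconds.
#' @return a \linkS4class{SegmentSet}.
#' @export
segmentMasked <- function(recording, mask, segmentLenS) {
  stopifnot(is(recording, "EEGRecording"), is(mask, "ArtifactMask"))
  if (length(mask@intervals) != length(recording@periods))
    stop("mask and recording disagree on the number of recording periods")
  segLen <- roundHalfUp(segmentLenS * recording@samplingRate)
  perStarts <- vector("list", length(recording@periods))
  for (i in seq_along(recording@periods)) {
    gaps <- intervalGaps(mask@intervals[[i]], ncol(recording@periods[[i]]))
    perStarts[[i]] <- tileStarts(gaps, segLen)
  }
  segmentFromStarts(recording, perStarts, segLen)
}

#' Reject segments crossing an amplitude threshold
#'
#' Flags as rejected every segment containing any sample with
#' \code{|x| > threshold} in any good channel. Data are retained; only
#' \code{keepFlags} flip, and only from TRUE to FALSE.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param thresholdUv amplitude threshold, microvolts.
#' @return the segment set with updated keep flags.
#' @export
rejectAmplitude <- function(segset, thresholdUv) {
  stopifnot(is(segset, "SegmentSet"), thresholdUv > 0)
  if (nSegments(segset) == 0L) return(segset)
  mx <- apply(abs(segset@data), 3L, max, na.rm = TRUE)
  segset@keepFlags <- segset@keepFlags & !(mx > thresholdUv)
  segset
}

#' Joint-probability segment rejection
#'
#' Estimates, per channel, the log-probability of each kept segment's
#' samples under the channel's empirical amplitude distribution (a 100-bin
#' histogram density over all kept segments, probabilities floored at
#' \code{1/(10 * N)} to avoid -Inf). A segment is rejected when the
#' z-score of its log-probability across segments exceeds the threshold in
#' absolute value for any single channel, or when the z-score of its
#' summed-across-channels log-probability does. Zero-variance channels are
#' skipped. With fewer than 8 kept segments the statistic is unstable, so
#' the operation warns and returns the set unchanged.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param zThreshold rejection threshold on |z| (default 3).
#' @return the segment set with updated keep flags.
#' @export
rejectJointProbability <- function(segset, zThreshold = 3) {
  stopifnot(is(segset, "SegmentSet"), zThreshold > 0)
  kept <- which(segset@keepFlags)
  if (length(kept) < 8L) {
    warning("fewer than 8 kept segments; joint-probability rejection skipped")
    return(segset)
  }
  nch <- dim(segset@data)[1L]
  L <- matrix(NA_real_, nch, length(kept))
  for (ch in seq_len(nch)) {
    pooled <- as.vector(segset@data[ch, , kept])
    if (all(is.na(pooled))) next
    rng <- range(pooled, na.rm = TRUE)
    if (diff(rng) == 0) next                       # degenerate channel
    brk <- seq(rng[1L], rng[2L], length.out = 101L)
    cnt <- tabulate(findInterval(pooled, brk, all.inside = TRUE), nbins = 100L)
    pr <- pmax(cnt / sum(cnt), 1 / (10 * length(pooled)))
    for (j in seq_along(kept)) {
      v <- segset@data[ch, , kept[j]]
      L[ch, j] <- sum(log(pr[findInterval(v, brk, all.inside = TRUE)]))
    }
  }
  ok <- rowSums(is.finite(L)) > 0L
  if (!any(ok)) return(segset)
  L <- L[ok, , drop = FALSE]
  zRow <- t(apply(L, 1L, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  colScore <- colSums(L)
  s <- stats::sd(colScore)
  zCol <- if (!is.finite(s) || s == 0) rep(0, length(colScore)) else
    (colScore - mean(colScore)) / s
  rej <- apply(abs(zRow) > zThreshold, 2L, any) | abs(zCol) > zThreshold
  segset@keepFlags[kept[rej]] <- FALSE
  segset
}

#' Tile conditioned-baseline spans into segments
#'
#' Conditioned baseline data is baseline-like EEG delimited by onset and
#' offset event tags (eyes open/closed blocks, sleep stages, ...). Each
#' onset is paired with the nearest following offset in the same period;
#' the half-open span between them is tiled with non-overlapping segments
#' like baseline data. Spans are never merged. An onset with no following
#' offset is dropped with a warning; an offset before any onset is ignored
#' with a warning; of consecutive onsets, the earlier is dropped.
#'
#' @param recording a conditioned-baseline \linkS4class{EEGRecording}.
#' @param onsetLabel,offsetLabel the event tags delimiting spans.
#' @param segmentLenS segment length in seconds.
#' @return a \linkS4class{SegmentSet}; empty (with a warning) if no
#'   onset/offset pair exists.
#' @export
segmentConditionedBaseline <- function(recording, onsetLabel, offsetLabel,
                                       segmentLenS) {
  stopifnot(is(recording, "EEGRecording"), segmentLenS > 0)
  if (recording@dataType != "conditioned_baseline")
    stop("segmentConditionedBaseline requires data_type 'conditioned_baseline'")
  segLen <- roundHalfUp(segmentLenS * recording@samplingRate)
  perStarts <- vector("list", length(recording@periods))
  anyPair <- FALSE
  for (i in seq_along(recording@periods)) {
    ev <- recording@events
    ev <- ev[ev$period == i & ev$label %in% c(onsetLabel, offsetLabel), , drop = FALSE]
    ev <- ev[order(ev$sample), , drop = FALSE]
    spans <- matrix(numeric(0), ncol = 2L)
    pendingOn <- NA_real_
    for (j in seq_len(nrow(ev))) {
      if (ev$label[j] %in% onsetLabel) {
        if (!is.na(pendingOn))
          warning("consecutive onsets: earlier onset dropped")
        pendingOn <- ev$sample[j]
      } else {
        if (is.na(pendingOn)) {
          warning("offset tag with no preceding onset ignored")
        } else {
          spans <- rbind(spans, c(pendingOn, ev$sample[j]))
          pendingOn <- NA_real_
        }
      }
    }
    if (!is.na(pendingOn))
      warning("onset tag with no following offset dropped")
    if (nrow(spans)) anyPair <- TRUE
    perStarts[[i]] <- tileStarts(spans, segLen)
  }
  if (!anyPair)
    warning("no onset/offset pairs found; empty segment set")
  segmentFromStarts(recording, perStarts, segLen,
                    conditionLabel = paste0(onsetLabel, "..", offsetLabel))
}

#' Within-segment linear detrend
#'
#' Removes, per channel and segment, the least-squares line. Idempotent.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @return the detrended segment set.
#' @export
detrendWithinSegment <- function(segset) {
  stopifnot(is(segset, "SegmentSet"))
  d <- segset@data
  nch <- dim(d)[1L]
  n <- dim(d)[2L]
  tc <- seq_len(n) - (n + 1) / 2
  for (k in seq_len(dim(d)[3L])) {
    g <- matrix(d[, , k], nch, n)
    mu <- rowMeans(g)
    slope <- as.numeric(g %*% tc) / sum(tc^2)
    d[, , k] <- g - mu - outer(slope, tc)
  }
  segset@data <- d
  segset
}

#' Extract a sub-segment
#'
#' Slices the columns whose stimulus-relative time lies in
#' \code{[fromMs, toMs)}; analyses can then focus on, e.g., an early or a
#' late post-stimulus response.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param fromMs,toMs sub-window in the set's \code{relTimeMs} units.
#' @return a \linkS4class{SegmentSet} over the sub-window.
#' @export
extractSubsegment <- function(segset, fromMs, toMs) {
  stopifnot(is(segset, "SegmentSet"))
  rt <- segset@relTimeMs
  sr <- segset@samplingRate
  half <- 1000 / sr / 2
  if (fromMs < rt[1L] - half || toMs > rt[length(rt)] + 1000 / sr)
    stop(sprintf("requested window [%g, %g) ms outside the segment range [%g, %g] ms",
                 fromMs, toMs, rt[1L], rt[length(rt)]))
  keep <- which(rt >= fromMs - half & rt < toMs - half)
  if (length(keep) == 0L) stop("sub-segment window selects no samples")
  segset@data <- segset@data[, keep, , drop = FALSE]
  segset@relTimeMs <- rt[keep]
  segset@sourceStart <- segset@sourceStart + (keep[1L] - 1L)
  segset
}

#' Baseline-correct segments to a reference window
#'
#' Subtracts, per channel and segment, the mean over the baseline window
#' (typically pre-stimulus) from every sample of the segment.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param baselineFromMs,baselineToMs baseline window in \code{relTimeMs}
#'   units (half-open).
#' @return the corrected segment set.
#' @export
baselineCorrect <- function(segset, baselineFromMs, baselineToMs) {
  stopifnot(is(segset, "SegmentSet"))
  rt <- segset@relTimeMs
  sr <- segset@samplingRate
  half <- 1000 / sr / 2
  sel <- which(rt >= baselineFromMs - half & rt < baselineToMs - half)
  if (length(sel) == 0L)
    stop(sprintf("baseline window [%g, %g) ms selects no samples; segment spans [%g, %g] ms",
                 baselineFromMs, baselineToMs, rt[1L], rt[length(rt)]))
  d <- segset@data
  nch <- dim(d)[1L]
  for (k in seq_len(dim(d)[3L])) {
    mu <- rowMeans(matrix(d[, sel, k], nch, length(sel)))
    d[, , k] <- matrix(d[, , k], nch, dim(d)[2L]) - mu
  }
  segset@data <- d
  segset
}
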