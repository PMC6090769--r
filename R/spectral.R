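## Spectral analyses on segmented data: single-sided FFT power with
## rectangular or Hanning windows, multitaper (Slepian) power, band-binned
## summaries, and inter-trial phase coherence.
##
## Power normalization per bin is 2 |X_k|^2 / (l * sr), with the
## single-sided doubling dropped at the DC and Nyquist bins so that the
## summed spectrum preserves total energy (Parseval); l is the
## post-padding transform length by default.

hanningWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

## Single-sided power of a (channels x samples) matrix: window, zero-pad to
## lfft, FFT, scale. Returns channels x (lfft/2 + 1).
singleSidedPower <- function(mat, w, lfft, sr, lNorm) {
  n <- ncol(mat)
  xw <- sweep(mat, 2L, w, `*`)
  pad <- matrix(0, nrow(mat), lfft)
  pad[, seq_len(n)] <- xw
  X <- t(stats::mvfft(t(pad)))
  nb <- lfft %/% 2L + 1L
  scale <- rep(2, nb)
  scale[1L] <- 1
  scale[nb] <- 1
  l <- if (lNorm == "padded") lfft else n
  sweep(Mod(X[, seq_len(nb), drop = FALSE])^2, 2L, scale, `*`) / (l * sr)
}

#' Power spectral density of a segment set (FFT, windowed)
#'
#' Per kept segment and channel: apply the window, zero-pad with trailing
#' zeros to the next power of 2, take the single-sided FFT, and scale each
#' bin as \code{2 |X_k|^2 / (l * sr)} (factor 1 at DC and Nyquist). A
#' bin-centred cosine of amplitude A microvolts under the rectangular
#' window yields \code{A^2 / 2 * l / sr ...}; concretely 2 microvolt^2 at
#' its bin for A = 2, l = sr. No window-gain compensation is applied for
#' the Hanning window unless requested.
#'
#' @param segset a \linkS4class{SegmentSet} with at least one kept segment.
#' @param window \code{"rectangular"} or \code{"hanning"}.
#' @param lNorm normalize by the \code{"padded"} transform length
#'   (default) or the pre-padding \code{"segment"} length.
#' @param windowCorrection if TRUE, divide the window by its coherent gain
#'   (mean) so sinusoid peak power matches the rectangular window.
#' @return a \linkS4class{PsdResult}; empty (with a warning) if no
#'   segments are kept.
#' @export
computePsd <- function(segset, window = c("rectangular", "hanning"),
                       lNorm = c("padded", "segment"),
                       windowCorrection = FALSE) {
  stopifnot(is(segset, "SegmentSet"))
  window <- match.arg(window)
  lNorm <- match.arg(lNorm)
  kept <- which(segset@keepFlags)
  n <- dim(segset@data)[2L]
  nch <- dim(segset@data)[1L]
  lfft <- nextPow2(max(n, 2L))
  nb <- lfft %/% 2L + 1L
  freqs <- (seq_len(nb) - 1) * segset@samplingRate / lfft
  if (length(kept) == 0L) {
    warning("no kept segments; empty PSD result")
    return(new("PsdResult", power = array(0, c(nch, nb, 0L)), freqsHz = freqs,
               method = window, fftLen = lfft,
               meanPower = matrix(NA_real_, nch, nb),
               channelLabels = segset@channelLabels,
               samplingRate = segset@samplingRate, segIndex = integer(0)))
  }
  w <- if (window == "rectangular") rep(1, n) else hanningWindow(n)
  if (windowCorrection) w <- w / mean(w)
  pw <- array(0, c(nch, nb, length(kept)))
  for (j in seq_along(kept))
    pw[, , j] <- singleSidedPower(matrix(segset@data[, , kept[j]], nch, n),
                                  w, lfft, segset@samplingRate, lNorm)
  mp <- apply(pw, c(1L, 2L), mean)
  new("PsdResult", power = pw, freqsHz = freqs, method = window,
      fftLen = lfft, meanPower = mp, channelLabels = segset@channelLabels,
      samplingRate = segset@samplingRate, segIndex = as.integer(kept))
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First \code{k} DPSS tapers of length \code{n} at time-bandwidth product
#' \code{nw}, computed from the standard symmetric tridiagonal eigenproblem.
#' Tapers are unit-energy rows of the returned k x n matrix, with the usual
#' polarity convention (non-negative mean for symmetric tapers).
#'
#' @param n taper length in samples.
#' @param k number of tapers.
#' @param nw time-bandwidth product.
#' @return k x n matrix of tapers.
#' @export
dpssTapers <- function(n, k, nw) {
  stopifnot(n >= 2, k >= 1, k <= n, nw > 0)
  W <- nw / n
  t <- 0:(n - 1)
  md <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- md
  A[cbind(1:(n - 1), 2:n)] <- od
  A[cbind(2:n, 1:(n - 1))] <- od
  eg <- eigen(A, symmetric = TRUE)
  tap <- t(eg$vectors[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {
    tap[i, ] <- tap[i, ] / sqrt(sum(tap[i, ]^2))
    if (sum(tap[i, ]) < 0) tap[i, ] <- -tap[i, ]
  }
  tap
}

#' Multitaper power spectral density
#'
#' Per kept segment and channel, the average of eigen-spectra over the
#' first \code{nTapers} Slepian tapers at time-bandwidth product
#' \code{NW = (nTapers + 1) / 2}, so the taper count alone determines the
#' estimator. Tapers are scaled to the rectangular window's energy, and the
#' same single-sided \code{2 |X|^2 / (l sr)} normalization as
#' \code{\link{computePsd}} applies; averaging over tapers trades a wider
#' main lobe for reduced estimator variance.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param nTapers number of tapers, between 1 and half the segment length.
#' @param lNorm as in \code{\link{computePsd}}.
#' @return a \linkS4class{PsdResult} with method \code{"multitaper"}.
#' @export
computePsdMultitaper <- function(segset, nTapers, lNorm = c("padded", "segment")) {
  stopifnot(is(segset, "SegmentSet"))
  lNorm <- match.arg(lNorm)
  n <- dim(segset@data)[2L]
  if (nTapers < 1L || nTapers > n %/% 2L)
    stop(sprintf("nTapers must be between 1 and %d for %d-sample segments",
                 n %/% 2L, n))
  kept <- which(segset@keepFlags)
  if (length(kept) == 0L) {
    warning("no kept segments; empty PSD result")
    return(computePsd(segset, "rectangular", lNorm))
  }
  nch <- dim(segset@data)[1L]
  lfft <- nextPow2(max(n, 2L))
  nb <- lfft %/% 2L + 1L
  freqs <- (seq_len(nb) - 1) * segset@samplingRate / lfft
  tap <- dpssTapers(n, nTapers, (nTapers + 1) / 2) * sqrt(n)
  pw <- array(0, c(nch, nb, length(kept)))
  for (j in seq_along(kept)) {
    acc <- matrix(0, nch, nb)
    for (i in seq_len(nTapers))
      acc <- acc + singleSidedPower(matrix(segset@data[, , kept[j]], nch, n),
                                    tap[i, ], lfft, segset@samplingRate, lNorm)
    pw[, , j] <- acc / nTapers
  }
  mp <- apply(pw, c(1L, 2L), mean)
  new("PsdResult", power = pw, freqsHz = freqs, method = "multitaper",
      fftLen = lfft, meanPower = mp, channelLabels = segset@channelLabels,
      samplingRate = segset@samplingRate, segIndex = as.integer(kept))
}

#' Bin mean power into user-defined frequency bands
#'
#' Per channel and band (bins with \code{lo <= f < hi}): absolute power is
#' the mean of \code{meanPower} over the band's bins; normalized power is
#' absolute divided by the channel's sum of absolute power over all defined
#' bands; natural-log and log10 of absolute power are included. Bands may
#' overlap. A band covering no bins yields NA with a warning.
#'
#' @param psd a \linkS4class{PsdResult}.
#' @param bands data.frame with columns \code{name}, \code{lo}, \code{hi}
#'   (Hz, \code{lo < hi}).
#' @return data.frame: channel, band, power_abs, power_norm, power_ln,
#'   power_log10.
#' @export
bandPower <- function(psd, bands) {
  stopifnot(is(psd, "PsdResult"))
  if (!all(c("name", "lo", "hi") %in% names(bands)))
    stop("bands must have columns name, lo, hi")
  if (any(bands$lo >= bands$hi)) stop("each band needs lo < hi")
  nch <- nrow(psd@meanPower)
  out <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- psd@freqsHz >= bands$lo[b] & psd@freqsHz < bands$hi[b]
    if (!any(sel)) {
      warning(sprintf("band '%s' (%g-%g Hz) covers no frequency bins", bands$name[b],
                      bands$lo[b], bands$hi[b]))
      absp <- rep(NA_real_, nch)
    } else {
      absp <- rowMeans(psd@meanPower[, sel, drop = FALSE])
    }
    out[[b]] <- data.frame(channel = psd@channelLabels, band = bands$name[b],
                           power_abs = absp, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tot <- tapply(tab$power_abs, tab$channel, sum)
  tab$power_norm <- tab$power_abs / as.numeric(tot[tab$channel])
  tab$power_ln <- log(tab$power_abs)
  tab$power_log10 <- log10(tab$power_abs)
  rownames(tab) <- NULL
  tab
}

#' Inter-trial phase coherence
#'
#' Slides a Hanning-tapered subwindow across the segments (hop =
#' \code{hopFraction} of the subwindow length) and, per channel, frequency
#' bin and window position, averages the trials' unit-normalized spectral
#' phasors: \code{itpc = (1/n) sum_k F_k / |F_k|}. Bins with \code{|F_k| =
#' 0} contribute a zero phasor. Magnitude is 0 for random phase and 1 for
#' perfect phase locking; with identical trials it is exactly 1 wherever
#' energy is nonzero.
#'
#' @param segset a \linkS4class{SegmentSet} with at least 2 kept segments.
#' @param subwindowMs subwindow length in ms (shorter than the segment).
#' @param hopFraction hop between window starts as a fraction of the
#'   subwindow (default 0.5: overlapping windows).
#' @return an \linkS4class{ItpcResult}.
#' @export
computeItpc <- function(segset, subwindowMs = 256, hopFraction = 0.5) {
  stopifnot(is(segset, "SegmentSet"))
  kept <- which(segset@keepFlags)
  if (length(kept) < 2L)
    stop("inter-trial phase coherence requires at least 2 kept segments")
  sr <- segset@samplingRate
  n <- dim(segset@data)[2L]
  m <- roundHalfUp(subwindowMs * sr / 1000)
  if (m < 2L || m > n)
    stop("subwindow must be at least 2 samples and no longer than the segment")
  hop <- max(1L, roundHalfUp(hopFraction * m))
  starts <- seq(1L, n - m + 1L, by = hop)
  nwin <- length(starts)
  nb <- m %/% 2L + 1L
  freqs <- (seq_len(nb) - 1) * sr / m
  nch <- dim(segset@data)[1L]
  w <- hanningWindow(m)
  itpc <- array(complex(real = 0), c(nch, nb, nwin))
  for (p in seq_len(nwin)) {
    sl <- starts[p]:(starts[p] + m - 1L)
    acc <- matrix(complex(real = 0), nch, nb)
    for (k in kept) {
      seg <- matrix(segset@data[, sl, k], nch, m) * rep(w, each = nch)
      FX <- t(stats::mvfft(t(seg)))[, seq_len(nb), drop = FALSE]
      md <- Mod(FX)
      ph <- FX
      ph[md > 0] <- FX[md > 0] / md[md > 0]
      ph[md == 0] <- 0
      acc <- acc + ph
    }
    itpc[, , p] <- acc / length(kept)
  }
  centers <- segset@relTimeMs[starts] + (m - 1) / 2 * 1000 / sr
  new("ItpcResult", itpc = itpc, freqsHz = freqs, windowCentersMs = centers,
      nTrials = length(kept), subwindowMs = subwindowMs,
      channelLabels = segset@channelLabels)
}

#' Summarize ITPC magnitude per channel
#'
#' Per channel: the maximum and mean of |itpc| over the selected rectangle
#' of window centres x frequency bins, plus where the maximum sits
#' (window-centre time and frequency). Optionally reports which channel of
#' a named channel group (e.g. a frontocentral set) attains the overall
#' maximum.
#'
#' @param itpcResult an \linkS4class{ItpcResult}.
#' @param timeRangeMs length-2 window-centre range (default: all windows).
#' @param freqRangeHz length-2 frequency range (default: all bins).
#' @param channelGroup optional character vector of channel labels.
#' @return list with \code{summary} (data.frame: channel, itpc_max,
#'   itpc_mean, argmax_time_ms, argmax_freq_hz) and, when a group is
#'   given, \code{argmaxChannel}.
#' @export
itpcSummary <- function(itpcResult, timeRangeMs = NULL, freqRangeHz = NULL,
                        channelGroup = NULL) {
  stopifnot(is(itpcResult, "ItpcResult"))
  tc <- itpcResult@windowCentersMs
  fr <- itpcResult@freqsHz
  tSel <- if (is.null(timeRangeMs)) seq_along(tc) else
    which(tc >= timeRangeMs[1L] & tc <= timeRangeMs[2L])
  fSel <- if (is.null(freqRangeHz)) seq_along(fr) else
    which(fr >= freqRangeHz[1L] & fr <= freqRangeHz[2L])
  if (length(tSel) == 0L || length(fSel) == 0L)
    stop("empty time/frequency selection for ITPC summary")
  mags <- Mod(itpcResult@itpc[, fSel, tSel, drop = FALSE])
  nch <- dim(mags)[1L]
  mx <- numeric(nch); mn <- numeric(nch)
  at <- numeric(nch); af <- numeric(nch)
  for (ch in seq_len(nch)) {
    m <- mags[ch, , , drop = TRUE]
    m <- matrix(m, length(fSel), length(tSel))
    mx[ch] <- max(m); mn[ch] <- mean(m)
    ij <- which(m == mx[ch], arr.ind = TRUE)[1L, ]
    af[ch] <- fr[fSel[ij[1L]]]
    at[ch] <- tc[tSel[ij[2L]]]
  }
  summary <- data.frame(channel = itpcResult@channelLabels,
                        itpc_max = mx, itpc_mean = mn,
                        argmax_time_ms = at, argmax_freq_hz = af,
                        stringsAsFactors = FALSE)
  out <- list(summary = summary)
  if (!is.null(channelGroup)) {
    idx <- which(itpcResult@channelLabels %in% channelGroup)
    if (length(idx) == 0L) stop("no channels match the requested channel group")
    out$argmaxChannel <- itpcResult@channelLabels[idx[which.max(mx[idx])]]
  }
  out
}
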