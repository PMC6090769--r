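## Continuous-data conditioning. Every operation consumes and emits a
## continuous EEGRecording, acts strictly within each recording period
## (period boundaries are never bridged), leaves bad channels as NA, and
## appends exactly one provenance entry.

## Windowed-sinc FIR design (Hamming window via signal::fir1). Tap count
## follows the Hamming transition-width rule ntaps ~ 3.3 / (tb / sr),
## forced odd so the centered single pass is exactly zero-phase.
designFir <- function(type, cutoffHz, sr, transitionHz, maxLen = Inf) {
  ntaps <- ceiling(3.3 * sr / transitionHz)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  maxOdd <- if (is.finite(maxLen)) {
    m <- as.integer(maxLen)
    if (m %% 2L == 0L) m - 1L else m
  } else ntaps
  if (ntaps > maxOdd) ntaps <- max(5L, maxOdd)
  w <- cutoffHz / (sr / 2)
  as.numeric(signal::fir1(ntaps - 1L, w, type))
}

## Exact zero-phase application of an odd-length symmetric FIR: reflect-pad
## each channel by the group delay, convolve by FFT (all channels at once),
## and take the centered output.
applyFirZeroPhaseMatrix <- function(mat, h) {
  p <- (length(h) - 1L) %/% 2L
  n <- ncol(mat)
  if (p == 0L) return(mat * h)
  left <- mat[, pmin(n, (p + 1L):2L), drop = FALSE]
  right <- mat[, pmax(1L, (n - 1L):(n - p)), drop = FALSE]
  xp <- cbind(left, mat, right)
  m <- ncol(xp)
  L <- nextPow2(m + length(h) - 1L)
  H <- stats::fft(c(h, numeric(L - length(h))))
  pad <- matrix(0, nrow(mat), L)
  pad[, seq_len(m)] <- xp
  Y <- t(stats::mvfft(t(pad)))
  Y <- sweep(Y, 2L, H, `*`)
  y <- Re(t(stats::mvfft(t(Y), inverse = TRUE))) / L
  y[, (2L * p + 1L):(2L * p + n), drop = FALSE]
}

filterPeriod <- function(mat, filters, good) {
  for (h in filters) {
    mat[good, ] <- applyFirZeroPhaseMatrix(mat[good, , drop = FALSE], h)
  }
  mat
}

#' Zero-phase FIR filtering of a continuous recording
#'
#' Applies the requested high-pass, low-pass and/or notch (band-stop)
#' filters to every recording period, per channel, with a zero-phase
#' windowed-sinc FIR realization (transition bandwidth
#' \code{max(2, 0.25 * cutoff)} Hz for high/low pass; half the notch width
#' for the notch). If any requested cutoff is not below the file's Nyquist
#' frequency the whole filter stage is skipped for that file with a logged
#' notification, and the pipeline continues on the unfiltered data.
#'
#' @param recording a continuous \linkS4class{EEGRecording}.
#' @param highpass optional high-pass cutoff, Hz.
#' @param lowpass optional low-pass cutoff, Hz.
#' @param notch optional notch centre frequency, Hz; \code{TRUE} uses the
#'   recording's line-noise frequency.
#' @param notchWidth full stop-band width of the notch in Hz (default 2).
#' @return the filtered recording (or, when skipped, the input with a
#'   "filter" history entry recording \code{skipped = TRUE}).
#' @export
filterRecording <- function(recording, highpass = NULL, lowpass = NULL,
                            notch = NULL, notchWidth = 2) {
  stopifnot(is(recording, "EEGRecording"))
  if (isTRUE(notch)) notch <- recording@lineNoiseHz
  if (!is.null(highpass) && !is.null(lowpass) && highpass >= lowpass)
    stop("high-pass cutoff must be below the low-pass cutoff")
  sr <- recording@samplingRate
  cutoffs <- c(highpass, lowpass,
               if (!is.null(notch)) notch + notchWidth / 2)
  params <- list(highpass_hz = highpass, lowpass_hz = lowpass,
                 notch_hz = notch, notch_width_hz = notchWidth)
  if (length(cutoffs) == 0L)
    return(appendHistory(recording, "filter", c(params, list(skipped = FALSE))))
  if (any(cutoffs >= sr / 2)) {
    msg <- sprintf("filtering skipped: requested cutoff(s) at or above Nyquist (%g Hz) for sampling rate %g Hz",
                   sr / 2, sr)
    message(msg)
    return(appendHistory(recording, "filter",
                         c(params, list(skipped = TRUE, notice = msg))))
  }
  minLen <- min(vapply(recording@periods, ncol, integer(1)))
  filters <- list()
  if (!is.null(highpass))
    filters <- c(filters, list(designFir("high", highpass, sr,
                                         max(2, 0.25 * highpass), minLen)))
  if (!is.null(lowpass))
    filters <- c(filters, list(designFir("low", lowpass, sr,
                                         max(2, 0.25 * lowpass), minLen)))
  if (!is.null(notch))
    filters <- c(filters, list(designFir("stop",
                                         c(notch - notchWidth / 2, notch + notchWidth / 2),
                                         sr, notchWidth / 4, minLen)))
  good <- goodChannels(recording)
  recording@periods <- lapply(recording@periods, filterPeriod, filters, good)
  appendHistory(recording, "filter", c(params, list(skipped = FALSE)))
}

#' Resample a recording by linear interpolation
#'
#' Each recording period is linearly interpolated onto a uniform grid at
#' the target rate that shares the first sample's timestamp. Event samples
#' are remapped by \code{sample * target / source}, rounded half-up to the
#' nearest sample. The original acquisition rate is preserved in
#' \code{originalSamplingRate}. Upsampling is allowed but logged.
#'
#' @param recording a continuous \linkS4class{EEGRecording}.
#' @param targetHz target sampling rate, Hz (> 0).
#' @return the resampled recording.
#' @export
resampleRecording <- function(recording, targetHz) {
  stopifnot(is(recording, "EEGRecording"))
  if (!is.numeric(targetHz) || length(targetHz) != 1L || targetHz <= 0)
    stop("target sampling rate must be a single positive number")
  sr <- recording@samplingRate
  up <- targetHz > sr
  if (up) message(sprintf("upsampling from %g to %g Hz", sr, targetHz))
  good <- goodChannels(recording)
  recording@periods <- lapply(recording@periods, function(p) {
    n <- ncol(p)
    tIn <- (seq_len(n) - 1) / sr
    nOut <- floor((n - 1) * targetHz / sr) + 1
    tOut <- (seq_len(nOut) - 1) / targetHz
    out <- matrix(NA_real_, nrow(p), nOut)
    for (ch in good)
      out[ch, ] <- stats::approx(tIn, p[ch, ], xout = tOut, rule = 2)$y
    out
  })
  ev <- recording@events
  if (nrow(ev)) {
    ev$sample <- roundHalfUp(ev$sample * targetHz / sr)
    nper <- vapply(recording@periods, ncol, integer(1))
    inb <- ev$sample >= 0 & ev$sample < nper[ev$period]
    if (any(!inb)) {
      warning(sprintf("%d event(s) fell outside the resampled grid and were dropped", sum(!inb)))
      ev <- ev[inb, , drop = FALSE]
      rownames(ev) <- NULL
    }
    recording@events <- ev
  }
  recording@samplingRate <- as.numeric(targetHz)
  appendHistory(recording, "resample",
                list(target_hz = targetHz, source_hz = sr, upsampled = up))
}

#' Re-reference a recording
#'
#' Subtracts, at every timepoint, the mean over a reference set: all good
#' channels (\code{"average"}), one named channel
#' (\code{"single_channel"}), or a user-defined subset
#' (\code{"channel_subset"}). Bad channels are excluded from every mean and
#' left as NA; referencing to a bad channel is an error.
#'
#' @param recording a continuous \linkS4class{EEGRecording}.
#' @param scheme one of \code{"average"}, \code{"single_channel"},
#'   \code{"channel_subset"}.
#' @param channels channel labels or 1-based indices (for single/subset).
#' @return the re-referenced recording.
#' @export
rereferenceRecording <- function(recording,
                                 scheme = c("average", "single_channel", "channel_subset"),
                                 channels = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  scheme <- match.arg(scheme)
  good <- goodChannels(recording)
  if (scheme == "average") {
    refIdx <- good
  } else {
    if (is.null(channels) || length(channels) == 0L)
      stop("reference channels must be given for scheme '", scheme, "'")
    refIdx <- if (is.character(channels)) {
      i <- match(channels, recording@channelLabels)
      if (anyNA(i)) stop("unknown reference channel(s): ",
                         paste(channels[is.na(i)], collapse = ", "))
      i
    } else as.integer(channels)
    if (scheme == "single_channel" && length(refIdx) != 1L)
      stop("single_channel referencing takes exactly one channel")
    bad <- intersect(refIdx, recording@badChannels)
    if (length(bad) == length(refIdx))
      stop("reference set consists entirely of bad channels")
    if (length(bad))
      stop("reference channel(s) flagged bad: ",
           paste(recording@channelLabels[bad], collapse = ", "))
  }
  recording@periods <- lapply(recording@periods, function(p) {
    ref <- colMeans(p[refIdx, , drop = FALSE])
    p[good, ] <- sweep(p[good, , drop = FALSE], 2L, ref)
    p
  })
  appendHistory(recording, "rereference",
                list(scheme = scheme,
                     channels = if (scheme == "average") NULL else
                       recording@channelLabels[refIdx]))
}

## Scalar local-level Kalman filter + RTS smoother. The gain sequence is
## data-independent, so it is computed once and the state recursions run
## vectorized across channels (rows of y). Returns the smoothed level.
kalmanLevel <- function(y, qOverR) {
  n <- ncol(y)
  nch <- nrow(y)
  Q <- qOverR; R <- 1
  Pp <- numeric(n); Pf <- numeric(n); K <- numeric(n)
  P <- 1e7 * R                       # diffuse start
  for (t in seq_len(n)) {
    Pp[t] <- P + Q
    K[t] <- Pp[t] / (Pp[t] + R)
    P <- (1 - K[t]) * Pp[t]
    Pf[t] <- P
  }
  af <- matrix(0, nch, n)
  a <- y[, 1L]
  a[!is.finite(a)] <- 0
  for (t in seq_len(n)) {
    innov <- y[, t] - a
    innov[!is.finite(innov)] <- 0
    a <- a + K[t] * innov
    af[, t] <- a
  }
  as <- af
  for (t in (n - 1L):1L) {
    C <- Pf[t] / Pp[t + 1L]
    as[, t] <- af[, t] + C * (as[, t + 1L] - af[, t + 1L])
  }
  as
}

#' Detrend a continuous recording
#'
#' Per channel and recording period: \code{"mean"} subtracts the channel
#' mean; \code{"linear"} subtracts the least-squares line; \code{"kalman"}
#' subtracts the smoothed state of a local-level model (random-walk level
#' observed in white noise) estimated by a Kalman filter with
#' Rauch-Tung-Striebel smoothing. Only the ratio Q/R matters: it sets the
#' smoother's cutoff (roughly \code{sr * sqrt(Q/R) / (2 pi)} Hz), i.e. how
#' fast a drift it will track. The default 1e-6 targets very slow drift.
#'
#' @param recording a continuous \linkS4class{EEGRecording}.
#' @param method "mean", "linear" or "kalman".
#' @param qOverR process-to-observation variance ratio for Kalman
#'   detrending (default 1e-6).
#' @return the detrended recording.
#' @export
detrendRecording <- function(recording, method = c("mean", "linear", "kalman"),
                             qOverR = 1e-6) {
  stopifnot(is(recording, "EEGRecording"))
  method <- match.arg(method)
  stopifnot(qOverR > 0)
  good <- goodChannels(recording)
  recording@periods <- lapply(recording@periods, function(p) {
    g <- p[good, , drop = FALSE]
    if (any(!is.finite(g)))
      stop("non-finite data outside the bad-channel sentinel; cannot detrend")
    if (method == "mean") {
      p[good, ] <- g - rowMeans(g)
    } else if (method == "linear") {
      n <- ncol(g)
      tc <- seq_len(n) - (n + 1) / 2
      slope <- as.numeric(g %*% tc) / sum(tc^2)
      p[good, ] <- g - rowMeans(g) - outer(slope, tc)
    } else {
      p[good, ] <- g - kalmanLevel(g, qOverR)
    }
    p
  })
  appendHistory(recording, "detrend",
                list(method = method,
                     q_over_r = if (method == "kalman") qOverR else NULL))
}
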