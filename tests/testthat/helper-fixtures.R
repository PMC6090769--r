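## Fixtures and independent oracles shared across the suite. All data are
## generated in code under fixed seeds; nothing is read from disk except
## files the tests themselves write to tempdirs.

## SegmentSet straight from a list of channels x samples matrices.
segSetFromList <- function(mats, sr = 250, startMs = 0, labels = NULL) {
  nch <- nrow(mats[[1L]])
  len <- ncol(mats[[1L]])
  if (is.null(labels)) labels <- paste0("E", seq_len(nch))
  rel <- startMs + (seq_len(len) - 1) * 1000 / sr
  eegbatch:::newSegmentSet(mats, rel, rep(1L, length(mats)),
                           rep(0, length(mats)), labels, sr)
}

## Brute-force artifact-mask oracle: for every suprathreshold sample, scan
## outward sample by sample for the nearest zero-crossing (exact zero or
## sign flip relative to the excursion) at or before and at or after it;
## union the per-sample intervals. Implements the masking rule literally
## and independently of the vectorized implementation.
bruteMask <- function(x, thr) {
  n <- length(x)
  keep <- rep(FALSE, n)
  for (t in which(abs(x) > thr)) {
    sgn <- sign(x[t])
    a <- t
    while (a > 1L && x[a - 1L] != 0 && sign(x[a - 1L]) == sgn) a <- a - 1L
    if (a > 1L) a <- a - 1L            # the crossing sample itself
    b <- t
    while (b < n && x[b + 1L] != 0 && sign(x[b + 1L]) == sgn) b <- b + 1L
    if (b < n) b <- b + 1L
    keep[a:b] <- TRUE
  }
  if (!any(keep)) return(matrix(numeric(0), ncol = 2L))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values] - 1L, ends[r$values])    # 0-based half-open
}

## Multi-channel brute mask: union over channels, merged.
bruteMaskMatrix <- function(mat, thr) {
  iv <- do.call(rbind, lapply(seq_len(nrow(mat)), function(ch)
    bruteMask(mat[ch, ], thr)))
  eegbatch:::mergeIntervals(iv)
}

## A random piecewise-smooth test signal with occasional large excursions.
randomArtifactSignal <- function(n, seed) {
  set.seed(seed)
  x <- stats::filter(rnorm(n, sd = 30), rep(1 / 5, 5), circular = TRUE)
  nArt <- sample(0:3, 1)
  for (k in seq_len(nArt)) {
    a <- sample.int(n - 20L, 1)
    len <- sample(5:20, 1)
    x[a:(a + len - 1L)] <- x[a:(a + len - 1L)] +
      sample(c(-1, 1), 1) * runif(1, 120, 300) * sin(pi * seq_len(len) / len)
  }
  as.numeric(x)
}

## Tiny event-tagged recording with a deterministic sine on every channel.
sineEventRecording <- function(nch = 2, sr = 250, durS = 12,
                               eventTimes = c(2, 5, 8), label = "stim") {
  n <- durS * sr
  tt <- (0:(n - 1)) / sr
  mat <- matrix(rep(sin(2 * pi * 10 * tt), each = nch), nch, n)
  makeRecording(mat, sr,
                events = data.frame(label = label, period = 1L,
                                    sample = eventTimes * sr),
                dataType = "event_tagged")
}
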