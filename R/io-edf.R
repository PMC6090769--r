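## Minimal EDF / EDF+C reader and writer (16-bit, one annotations channel
## holding timestamped annotation lists). EDF is the one external exchange
## format supported for continuous data; amplitudes are expected in
## microvolts ("uV"; "mV" is converted, anything else is an error).

edfField <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  sprintf(paste0("%-", width, "s"), s)
}

edfNum <- function(x, width) edfField(format(x, trim = TRUE, scientific = FALSE, digits = 7), width)

#' Write an EEGRecording as an EDF+C file
#'
#' Writes a single-recording-period EEGRecording as 16-bit EDF+ with one
#' "EDF Annotations" channel carrying the event tags. The data length must
#' be a whole number of seconds (1 s data records). Amplitudes are scaled
#' channel-wise to the full 16-bit digital range, so re-import agrees with
#' the source within one digital quantization step.
#'
#' @param recording an \linkS4class{EEGRecording} with exactly one period.
#' @param path output file path (.edf).
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  if (length(recording@periods) != 1L)
    stop("EDF export supports a single recording period; got ",
         length(recording@periods))
  x <- recording@periods[[1L]]
  sr <- recording@samplingRate
  if (abs(sr - round(sr)) > 1e-9) stop("EDF export requires an integer sampling rate")
  sr <- as.integer(round(sr))
  n <- ncol(x)
  if (n %% sr != 0L)
    stop("EDF export requires a whole number of seconds of data (1 s records)")
  nRec <- n %/% sr
  nch <- nrow(x)

  ## channel-wise physical scaling to the full 16-bit range
  digMin <- -32768L; digMax <- 32767L
  physMax <- apply(abs(x), 1L, function(v) {
    m <- suppressWarnings(max(v, na.rm = TRUE))
    if (!is.finite(m) || m == 0) 1 else signif(m * 1.0001, 6)
  })
  physMin <- -physMax
  gain <- (physMax - physMin) / (digMax - digMin)
  dig <- matrix(0L, nch, n)
  for (i in seq_len(nch)) {
    v <- x[i, ]
    v[!is.finite(v)] <- 0
    dig[i, ] <- as.integer(pmin(digMax, pmax(digMin,
                round((v - physMin[i]) / gain[i]) + digMin)))
  }

  ## annotation byte payload per record: timestamp TAL + event TALs
  ev <- recording@events
  annBytes <- vector("list", nRec)
  for (r in seq_len(nRec)) {
    payload <- c(charToRaw(sprintf("+%d", r - 1L)), as.raw(c(0x14, 0x14, 0x00)))
    if (nrow(ev)) {
      onset <- ev$sample / sr
      inRec <- which(onset >= (r - 1L) & onset < r)
      for (j in inRec) {
        payload <- c(payload,
                     charToRaw(sprintf("+%.6f", onset[j])), as.raw(0x14),
                     charToRaw(ev$label[j]), as.raw(c(0x14, 0x00)))
      }
    }
    annBytes[[r]] <- payload
  }
  annLen <- max(16L, max(vapply(annBytes, length, integer(1))))
  if (annLen %% 2L == 1L) annLen <- annLen + 1L
  annSamp <- annLen %/% 2L

  nSig <- nch + 1L
  headerBytes <- 256L * (nSig + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edfField("0", 8L),
    edfField("X X X X", 80L),
    edfField("Startdate X X X X", 80L),
    "01.01.00", "00.00.00",
    edfField(headerBytes, 8L),
    edfField("EDF+C", 44L),
    edfField(nRec, 8L),
    edfField("1", 8L),
    edfField(nSig, 4L)), con, eos = NULL)
  labs <- c(edfField(recording@channelLabels, 16L), edfField("EDF Annotations", 16L))
  writeChar(paste0(
    paste0(labs, collapse = ""),
    paste0(rep(edfField("", 80L), nSig), collapse = ""),          # transducer
    paste0(c(rep(edfField("uV", 8L), nch), edfField("", 8L)), collapse = ""),
    paste0(c(edfNum(physMin, 8L), edfField("-1", 8L)), collapse = ""),
    paste0(c(edfNum(physMax, 8L), edfField("1", 8L)), collapse = ""),
    paste0(c(rep(edfField(digMin, 8L), nch), edfField(digMin, 8L)), collapse = ""),
    paste0(c(rep(edfField(digMax, 8L), nch), edfField(digMax, 8L)), collapse = ""),
    paste0(rep(edfField("", 80L), nSig), collapse = ""),          # prefiltering
    paste0(edfField(c(rep(sr, nch), annSamp), 8L), collapse = ""),
    paste0(rep(edfField("", 32L), nSig), collapse = "")), con, eos = NULL)
  for (r in seq_len(nRec)) {
    sl <- ((r - 1L) * sr + 1L):(r * sr)
    writeBin(as.integer(t(dig[, sl, drop = FALSE])), con, size = 2L, endian = "little")
    pad <- raw(annLen)
    pad[seq_along(annBytes[[r]])] <- annBytes[[r]]
    writeBin(pad, con)
  }
  invisible(path)
}

## Decode EDF+ timestamped annotation lists from one record's raw bytes.
## TALs are NUL-separated; within a TAL, byte 0x14 separates the onset
## field (optionally "onset<0x15>duration") from the annotation texts.
## Timestamp-only TALs (no text) are dropped.
decodeTALs <- function(bytes) {
  out <- list()
  zero <- as.raw(0L)
  grp <- cumsum(bytes == zero)
  for (chunk in split(bytes, grp)) {
    chunk <- chunk[chunk != zero]
    if (length(chunk) == 0L) next
    s <- rawToChar(chunk)
    parts <- strsplit(s, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    onsetField <- strsplit(parts[1L], "\x15", fixed = TRUE)[[1]][1L]
    onset <- suppressWarnings(as.numeric(onsetField))
    if (is.na(onset)) next
    texts <- parts[-1L]
    texts <- texts[nzchar(texts)]
    for (txt in texts) out[[length(out) + 1L]] <- data.frame(
      onset_s = onset, label = txt, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(onset_s = numeric(0), label = character(0), stringsAsFactors = FALSE)
}

#' Import an EDF/EDF+ file as an EEGRecording
#'
#' Reads signals, header metadata and EDF+ annotations (which become event
#' tags at sample \code{round(onset_s * sr)}). All ordinary signals must
#' share one sampling rate; physical dimension must be "uV" (or "mV",
#' converted). The file is treated as one contiguous recording period.
#'
#' @param path EDF file.
#' @param layoutName electrode layout name to record (default "unknown").
#' @param lineNoiseHz mains frequency for this file (default 60).
#' @param dataType data type to assign (default "baseline").
#' @return an \linkS4class{EEGRecording}.
#' @export
importEDF <- function(path, layoutName = "unknown", lineNoiseHz = 60,
                      dataType = "baseline") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L)
    stop("EDF format error: truncated header in ", path)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  nRec <- as.integer(fld(hdr, 237L, 8L))
  recDur <- as.numeric(fld(hdr, 245L, 8L))
  nSig <- as.integer(fld(hdr, 253L, 4L))
  if (is.na(nSig) || nSig < 1L) stop("EDF format error: bad signal count")
  sig <- readChar(con, 256L * nSig, useBytes = TRUE)
  grab <- function(off, len) {
    vapply(seq_len(nSig), function(i)
      trimws(substr(sig, off * nSig + (i - 1L) * len + 1L, off * nSig + i * len)),
      character(1))
  }
  ## offsets in bytes preceding each block within the signal header
  pos <- 0L
  take <- function(len) {
    out <- vapply(seq_len(nSig), function(i)
      trimws(substr(sig, pos + (i - 1L) * len + 1L, pos + i * len)), character(1))
    pos <<- pos + len * nSig
    out
  }
  labels <- take(16L); take(80L)
  physDim <- take(8L)
  physMin <- as.numeric(take(8L)); physMax <- as.numeric(take(8L))
  digMin <- as.numeric(take(8L)); digMax <- as.numeric(take(8L))
  take(80L)
  nSamp <- as.integer(take(8L))
  isAnn <- labels == "EDF Annotations"
  ord <- which(!isAnn)
  if (length(ord) == 0L) stop("EDF format error: no data signals")
  rates <- nSamp[ord] / recDur
  if (length(unique(rates)) != 1L)
    stop("unsupported layout: signals with differing sampling rates in one EDF file")
  sr <- rates[1L]
  conv <- numeric(nSig)
  for (i in ord) {
    pd <- physDim[i]
    if (pd %in% c("uV", "µV", "")) conv[i] <- 1
    else if (pd == "mV") conv[i] <- 1000
    else stop(sprintf("EDF physical dimension '%s' on channel '%s' is not convertible to uV",
                      pd, labels[i]))
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  recSamples <- sum(nSamp)
  data <- matrix(NA_real_, length(ord), nRec * nSamp[ord[1L]])
  ann <- list()
  offsets <- c(0L, cumsum(nSamp))
  for (r in seq_len(nRec)) {
    raw16 <- readBin(con, "integer", n = recSamples, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(raw16) < recSamples)
      stop("EDF format error: truncated data record ", r)
    for (k in seq_along(ord)) {
      i <- ord[k]
      v <- raw16[(offsets[i] + 1L):offsets[i + 1L]]
      data[k, ((r - 1L) * nSamp[i] + 1L):(r * nSamp[i])] <-
        ((v - digMin[i]) * gain[i] + physMin[i]) * conv[i]
    }
    for (i in which(isAnn)) {
      b <- writeBinRaw(raw16[(offsets[i] + 1L):offsets[i + 1L]])
      ann[[length(ann) + 1L]] <- decodeTALs(b)
    }
  }
  events <- if (length(ann)) do.call(rbind, ann) else
    data.frame(onset_s = numeric(0), label = character(0))
  evTab <- if (nrow(events)) {
    data.frame(label = events$label, period = 1L,
               sample = roundHalfUp(events$onset_s * sr),
               applied_offset_samples = 0, stringsAsFactors = FALSE)
  } else emptyEvents()
  makeRecording(list(data), samplingRate = sr, channelLabels = labels[ord],
                events = evTab, layoutName = layoutName,
                lineNoiseHz = lineNoiseHz, dataType = dataType)
}

## int16 vector back to its little-endian raw bytes (for annotation decode)
writeBinRaw <- function(v) {
  writeBin(as.integer(v), raw(), size = 2L, endian = "little")
}
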