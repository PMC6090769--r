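## Seeded synthetic-EEG fixture generator. Emulates the structure of a
## multi-acquisition infant-EEG dataset: mixed 250/500 Hz sampling, 64- and
## 128-channel geodesic layouts, 60 Hz line noise, event-tag offsets of
## 0/8/18 samples, and baseline plus auditory-oddball-style event streams
## (standard/native/non-native at 80/10/10%). Every fixture carries its
## ground truth (true artifact intervals, true stimulus samples, component
## table) so each pipeline stage is testable without external downloads.

#' Specification for one synthetic EEG recording
#'
#' Defaults describe a plausible infant resting EEG: pink (1/f) background
#' at slope -1, a little white sensor noise, 60 Hz mains at low amplitude,
#' and narrowband oscillatory components. The same spec and seed always
#' produce bit-identical data.
#'
#' @param nChannels channel count (default 128).
#' @param samplingRate Hz (default 250).
#' @param durationS per-period duration(s) in seconds; a vector makes one
#'   recording period per element (default 30).
#' @param components data.frame(freq, amp, phase) of sinusoids added to
#'   every channel; NA phase draws one phase per channel.
#' @param noiseWhiteSd white noise SD, microvolts.
#' @param pinkSd 1/f background SD, microvolts.
#' @param pinkSlope spectral slope of the background (default -1).
#' @param lineNoiseHz,lineNoiseAmp mains frequency and amplitude.
#' @param artifacts data.frame(period, start_s, duration_s, peak_uv) of
#'   triangular high-amplitude excursions (zero at both ends) injected on
#'   \code{artifactChannels}.
#' @param artifactChannels channels receiving artifacts (default 1).
#' @param events data.frame(label, time_s, period) of true stimulus times;
#'   recorded tags are written \code{trueOffsetSamples} early, so applying
#'   the offset table recovers the truth.
#' @param trueOffsetSamples event-tag transmission delay in samples.
#' @param burst NULL, or list(freq, amp, fromMs, toMs): a phase-locked
#'   oscillatory burst added after every event (Hann-enveloped, phase 0 at
#'   burst onset on every trial).
#' @param layoutName,tenTwentyMap acquisition layout metadata.
#' @param seed RNG seed.
#' @return a list of class \code{"SynthSpec"}.
#' @export
synthSpec <- function(nChannels = 128, samplingRate = 250, durationS = 30,
                      components = data.frame(freq = c(6, 10),
                                              amp = c(3, 4), phase = NA),
                      noiseWhiteSd = 1, pinkSd = 8, pinkSlope = -1,
                      lineNoiseHz = 60, lineNoiseAmp = 2,
                      artifacts = NULL, artifactChannels = 1L,
                      events = NULL, trueOffsetSamples = 0L,
                      burst = NULL,
                      layoutName = "HydroCel GSN 128 1.0",
                      tenTwentyMap = character(0),
                      seed = 1L) {
  spec <- list(nChannels = nChannels, samplingRate = samplingRate,
               durationS = durationS, components = components,
               noiseWhiteSd = noiseWhiteSd, pinkSd = pinkSd,
               pinkSlope = pinkSlope, lineNoiseHz = lineNoiseHz,
               lineNoiseAmp = lineNoiseAmp, artifacts = artifacts,
               artifactChannels = as.integer(artifactChannels),
               events = events, trueOffsetSamples = as.integer(trueOffsetSamples),
               burst = burst, layoutName = layoutName,
               tenTwentyMap = tenTwentyMap, seed = as.integer(seed))
  if (!is.null(components) && nrow(components) &&
      any(components$freq >= samplingRate / 2))
    stop("component frequency at or above Nyquist")
  if (!is.null(burst) && burst$freq >= samplingRate / 2)
    stop("burst frequency at or above Nyquist")
  class(spec) <- "SynthSpec"
  spec
}

## 1/f^(-slope) noise by spectral shaping of white noise, scaled to sd.
pinkNoise <- function(n, sr, slope, sd) {
  X <- stats::fft(stats::rnorm(n))
  f <- (0:(n - 1)) * sr / n
  f[f > sr / 2] <- sr - f[f > sr / 2]       # fold to physical frequency
  shape <- c(0, f[-1]^(slope / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x * sd / s else x
}

#' Generate a synthetic EEGRecording with ground truth
#'
#' @param spec a \code{\link{synthSpec}}.
#' @return list with \code{recording} (an \linkS4class{EEGRecording}) and
#'   \code{truth}: true artifact sample intervals (0-based, half-open),
#'   true stimulus samples before tag-offset corruption, and the component
#'   table.
#' @export
generateRecording <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  set.seed(spec$seed)
  sr <- spec$samplingRate
  nch <- spec$nChannels
  periods <- list()
  truthArt <- list()
  for (pidx in seq_along(spec$durationS)) {
    n <- roundHalfUp(spec$durationS[pidx] * sr)
    tt <- (0:(n - 1)) / sr
    mat <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      x <- pinkNoise(n, sr, spec$pinkSlope, spec$pinkSd) +
        stats::rnorm(n, sd = spec$noiseWhiteSd)
      if (spec$lineNoiseAmp > 0)
        x <- x + spec$lineNoiseAmp * sin(2 * pi * spec$lineNoiseHz * tt + stats::runif(1, 0, 2 * pi))
      cmp <- spec$components
      if (!is.null(cmp) && nrow(cmp)) for (j in seq_len(nrow(cmp))) {
        ph <- if (is.na(cmp$phase[j])) stats::runif(1, 0, 2 * pi) else cmp$phase[j]
        x <- x + cmp$amp[j] * sin(2 * pi * cmp$freq[j] * tt + ph)
      }
      mat[ch, ] <- x
    }
    art <- spec$artifacts
    if (!is.null(art) && nrow(art)) for (j in which(art$period == pidx)) {
      a <- roundHalfUp(art$start_s[j] * sr)
      len <- roundHalfUp(art$duration_s[j] * sr)
      u <- (seq_len(len) - 1) / (len - 1)
      tri <- art$peak_uv[j] * (1 - abs(2 * u - 1))
      for (ch in spec$artifactChannels)
        mat[ch, (a + 1):(a + len)] <- mat[ch, (a + 1):(a + len)] + tri
      truthArt[[length(truthArt) + 1L]] <-
        data.frame(period = pidx, start = a, end = a + len,
                   peak_uv = art$peak_uv[j])
    }
    periods[[pidx]] <- mat
  }
  ## events: true stimulus samples; tags are recorded early by the offset
  evTruth <- NULL
  evTab <- emptyEvents()
  ev <- spec$events
  if (!is.null(ev) && nrow(ev)) {
    ev$period <- ev$period %||% 1L
    trueSample <- roundHalfUp(ev$time_s * sr)
    tagSample <- trueSample - spec$trueOffsetSamples
    nper <- vapply(periods, ncol, integer(1))
    ok <- tagSample >= 0 & tagSample < nper[ev$period] &
      trueSample < nper[ev$period]
    evTruth <- data.frame(label = ev$label[ok], period = ev$period[ok],
                          true_sample = trueSample[ok],
                          tag_sample = tagSample[ok])
    evTab <- data.frame(label = ev$label[ok], period = as.integer(ev$period[ok]),
                        sample = tagSample[ok],
                        applied_offset_samples = 0,
                        stringsAsFactors = FALSE)
    ## phase-locked post-stimulus burst at the TRUE stimulus time
    if (!is.null(spec$burst)) {
      b <- spec$burst
      for (j in seq_len(nrow(evTruth))) {
        p <- evTruth$period[j]
        a <- evTruth$true_sample[j] + roundHalfUp(b$fromMs * sr / 1000)
        len <- roundHalfUp((b$toMs - b$fromMs) * sr / 1000)
        if (a < 0 || a + len > ncol(periods[[p]])) next
        tt <- (seq_len(len) - 1) / sr
        env <- hanningWindow(len)
        wave <- b$amp * sin(2 * pi * b$freq * tt) * env
        periods[[p]][, (a + 1):(a + len)] <-
          periods[[p]][, (a + 1):(a + len)] + rep(wave, each = nch)
      }
    }
  }
  dtype <- if (!is.null(spec$events) && nrow(spec$events %||% data.frame()))
    "event_tagged" else "baseline"
  rec <- makeRecording(periods, samplingRate = sr,
                       channelLabels = paste0("E", seq_len(nch)),
                       events = evTab, layoutName = spec$layoutName,
                       lineNoiseHz = spec$lineNoiseHz, dataType = dtype,
                       tenTwentyMap = spec$tenTwentyMap)
  truth <- list(
    artifacts = if (length(truthArt)) do.call(rbind, truthArt) else NULL,
    events = evTruth,
    components = spec$components,
    true_offset_samples = spec$trueOffsetSamples
  )
  list(recording = rec, truth = truth)
}

#' Default synthetic-batch layout
#'
#' The file table the batch generator emulates by default: ten baseline and
#' ten auditory-oddball files across two sampling rates (250/500 Hz), two
#' net types (64/128 channels), and event-tag offsets of 0/8/18 samples.
#'
#' @return data.frame with columns file_id, data_type, sampling_rate,
#'   layout_name, n_channels, offset_samples.
#' @export
defaultBatchTable <- function() {
  base <- data.frame(
    file_id = sprintf("baselineEEG%02d", 1:10),
    data_type = "baseline",
    sampling_rate = c(rep(250, 7), rep(500, 3)),
    layout_name = ifelse(1:10 %in% c(2, 3), "Geodesic Sensor Net 64 2.0",
                         "HydroCel GSN 128 1.0"),
    n_channels = ifelse(1:10 %in% c(2, 3), 64L, 128L),
    offset_samples = 0L,
    stringsAsFactors = FALSE)
  evt <- data.frame(
    file_id = sprintf("auditoryEEG%02d", 1:10),
    data_type = "event_tagged",
    sampling_rate = c(rep(250, 7), rep(500, 3)),
    layout_name = ifelse(1:10 %in% c(2, 3), "Geodesic Sensor Net 64 2.0",
                         "HydroCel GSN 128 1.0"),
    n_channels = ifelse(1:10 %in% c(2, 3), 64L, 128L),
    offset_samples = c(rep(0L, 6), 8L, 18L, 18L, 18L),
    stringsAsFactors = FALSE)
  rbind(base, evt)
}

#' Generate a batch of synthetic EEG files with an offset table
#'
#' Writes a mixed-rate, mixed-layout file set to \code{dir}: one EDF per
#' file, a parallel native container under \code{native/}, a ground-truth
#' JSON sidecar under \code{truth/}, and \code{offsets.csv} (columns
#' file_id, offset_samples, line_noise_hz, layout_name, periods). Event
#' files carry an auditory-oddball-style stream (standard/native/
#' non-native labels drawn at 80/10/10%) with a phase-locked 6 Hz burst
#' 150-300 ms after every stimulus, and their tags are written early by
#' the per-file offset so that offset correction is exercised end-to-end.
#'
#' @param dir output directory.
#' @param table file table (defaults to \code{defaultBatchTable()}:
#'   10 baseline + 10 event files, rates 250/500 Hz, offsets 0/8/18).
#' @param durationS per-file duration in seconds (default 30).
#' @param seed batch seed; per-file seeds derive from it.
#' @param writeEdf also write EDF copies (default TRUE).
#' @return the manifest data.frame (table plus file paths), invisibly.
#' @export
generateBatch <- function(dir, table = defaultBatchTable(), durationS = 30,
                          seed = 42L, writeEdf = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "native"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  set.seed(seed)
  fileSeeds <- sample.int(1e6, nrow(table))
  paths <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    events <- NULL; burst <- NULL
    if (row$data_type == "event_tagged") {
      set.seed(fileSeeds[i])
      ## jittered ISI so periodic background activity is not phase-locked
      ## to the stimulus train
      times <- seq(1.0, durationS - 1.2, by = 1.8)
      times <- times + stats::runif(length(times), -0.2, 0.2)
      labels <- sample(c("standard", "native", "nonnative"), length(times),
                       replace = TRUE, prob = c(0.8, 0.1, 0.1))
      events <- data.frame(label = labels, time_s = times, period = 1L,
                           stringsAsFactors = FALSE)
      burst <- list(freq = 6, amp = 8, fromMs = 150, toMs = 300)
    }
    spec <- synthSpec(nChannels = row$n_channels,
                      samplingRate = row$sampling_rate,
                      durationS = durationS,
                      events = events,
                      trueOffsetSamples = row$offset_samples,
                      burst = burst,
                      layoutName = row$layout_name,
                      seed = fileSeeds[i])
    gen <- generateRecording(spec)
    rec <- gen$recording
    writeNative(rec, file.path(dir, "native", row$file_id))
    if (writeEdf) {
      paths[i] <- file.path(dir, paste0(row$file_id, ".edf"))
      writeEDF(rec, paths[i])
    } else {
      paths[i] <- file.path(dir, "native", row$file_id)
    }
    jsonlite::write_json(gen$truth, file.path(dir, "truth", paste0(row$file_id, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  offsets <- data.frame(file_id = table$file_id,
                        offset_samples = table$offset_samples,
                        line_noise_hz = 60,
                        layout_name = table$layout_name,
                        periods = "1",
                        data_type = table$data_type,
                        stringsAsFactors = FALSE)
  utils::write.csv(offsets, file.path(dir, "offsets.csv"), row.names = FALSE)
  manifest <- cbind(table, path = paths, stringsAsFactors = FALSE)
  invisible(manifest)
}
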