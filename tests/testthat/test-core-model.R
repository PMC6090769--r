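test_that("recording period dimensions follow duration x sampling rate", {
  rec <- makeRecording(matrix(0, 129, 60 * 500), 500)
  expect_equal(dim(recordingPeriods(rec)[[1]]), c(129L, 30000L))

  rec2 <- makeRecording(list(matrix(0, 3, 10 * 250), matrix(0, 3, 20 * 250)), 250)
  expect_equal(vapply(recordingPeriods(rec2), ncol, integer(1)), c(2500L, 5000L))

  ## column-count law on generated periods
  set.seed(11)
  for (i in 1:10) {
    sr <- sample(c(250, 500), 1)
    dur <- round(runif(1, 0.5, 5), 2)
    g <- generateRecording(synthSpec(nChannels = 2, samplingRate = sr,
                                     durationS = dur, seed = i))
    expect_equal(ncol(recordingPeriods(g$recording)[[1]]), floor(dur * sr + 0.5))
  }
})

test_that("recording construction validates its inputs", {
  expect_error(makeRecording(list(), 250), "at least one recording period")
  expect_error(makeRecording(matrix(0, 4, 10), 250,
                             channelLabels = c("a", "b")), "channel labels")
  expect_error(makeRecording(list(matrix(0, 3, 10), matrix(0, 4, 10)), 250),
               "channel count")
  expect_error(makeRecording(matrix(0, 2, 10), -5), "positive")
  expect_error(makeRecording(matrix(0, 2, 10), 250,
                             events = data.frame(label = "tooLate", period = 1,
                                                 sample = 10)),
               "tooLate")
})

test_that("native container round-trips every field bit-exactly", {
  set.seed(21)
  for (i in 1:4) {
    nper <- sample(1:3, 1)
    nch <- sample(2:6, 1)
    periods <- lapply(seq_len(nper), function(p)
      matrix(rnorm(nch * sample(50:200, 1)), nch))
    ev <- data.frame(label = c("on", "off"), period = 1L, sample = c(3, 17))
    rec <- makeRecording(periods, sample(c(250, 500), 1), events = ev,
                         layoutName = "HydroCel GSN 128 1.0",
                         badChannels = sample(nch, 1))
    rec <- setDataType(rec, "conditioned_baseline")
    d <- file.path(tempfile(), "nat")
    writeNative(rec, d)
    back <- readNative(d)
    expect_identical(recordingPeriods(back), recordingPeriods(rec))
    expect_identical(eventTags(back), eventTags(rec))
    expect_identical(badChannels(back), badChannels(rec))
    expect_identical(dataType(back), dataType(rec))
    expect_identical(channelLabels(back), channelLabels(rec))
    expect_equal(processingHistory(back), processingHistory(rec))
    unlink(d, recursive = TRUE)
  }
})

test_that("corrupt native containers raise format errors naming the section", {
  rec <- makeRecording(matrix(rnorm(20), 2, 10), 250)
  d <- file.path(tempdir(), "nat-corrupt")
  writeNative(rec, d)
  file.remove(file.path(d, "metadata.json"))
  expect_error(readNative(d), "metadata")
  writeNative(rec, d)
  file.remove(file.path(d, "period_001.bin"))
  expect_error(readNative(d), "period")
  ## truncated array
  writeNative(rec, d)
  con <- file(file.path(d, "period_001.bin"), "wb")
  writeBin(1.0, con); close(con)
  expect_error(readNative(d), "expected")
  unlink(d, recursive = TRUE)
})

test_that("processing history grows by exactly one entry per stage", {
  rec <- makeRecording(matrix(rnorm(2 * 2500), 2, 2500), 250)
  n0 <- length(processingHistory(rec))
  rec <- filterRecording(rec, highpass = 1)
  expect_length(processingHistory(rec), n0 + 1L)
  rec <- resampleRecording(rec, 125)
  expect_length(processingHistory(rec), n0 + 2L)
  rec <- rereferenceRecording(rec, "average")
  expect_length(processingHistory(rec), n0 + 3L)
  rec <- detrendRecording(rec, "mean")
  expect_length(processingHistory(rec), n0 + 4L)
  entry <- processingHistory(rec)[[n0 + 4L]]
  expect_identical(entry$module, "detrend")
  expect_identical(entry$parameters$method, "mean")
})

test_that("EDF round trip preserves structure, events and amplitudes", {
  spec <- synthSpec(nChannels = 16, samplingRate = 250, durationS = 30,
                    events = data.frame(label = c("a", "a", "b", "a", "a"),
                                        time_s = c(2, 5, 10, 15, 20),
                                        period = 1L),
                    seed = 7)
  gen <- generateRecording(spec)
  f <- tempfile(fileext = ".edf")
  writeEDF(gen$recording, f)
  imp <- importEDF(f, dataType = "event_tagged")
  expect_equal(dim(recordingPeriods(imp)[[1]]), c(16L, 7500L))
  expect_equal(nrow(eventTags(imp)), 5L)
  ## annotation at 10.0 s in a 250 Hz file -> event sample 2500
  expect_equal(eventTags(imp)$sample[eventTags(imp)$label == "b"], 2500)
  expect_equal(eventTags(imp)$sample, eventTags(gen$recording)$sample)
  ## amplitudes within the 16-bit quantization bound
  bound <- max(abs(recordingPeriods(gen$recording)[[1]])) * 1.0001 * 2 / 65535
  expect_lt(max(abs(recordingPeriods(imp)[[1]] -
                      recordingPeriods(gen$recording)[[1]])), 2 * bound)
  file.remove(f)
})

test_that("EDF with zero annotations imports with an empty event table", {
  g <- generateRecording(synthSpec(nChannels = 4, samplingRate = 250,
                                   durationS = 5, seed = 3))
  f <- tempfile(fileext = ".edf")
  writeEDF(g$recording, f)
  imp <- importEDF(f)
  expect_equal(nrow(eventTags(imp)), 0L)
  expect_identical(dataType(imp), "baseline")
  file.remove(f)
})

test_that("an independent EDF reader agrees on header, signals and annotations", {
  g <- generateRecording(synthSpec(nChannels = 8, samplingRate = 250,
                                   durationS = 10,
                                   events = data.frame(label = "ev",
                                                       time_s = c(1.5, 4),
                                                       period = 1L),
                                   seed = 12))
  f <- tempfile(fileext = ".edf")
  writeEDF(g$recording, f)
  py <- paste(
    "import mne, numpy as np, json, sys",
    sprintf("raw = mne.io.read_raw_edf(%s, preload=True, verbose='error')",
            shQuote(f)),
    "out = dict(sfreq=raw.info['sfreq'], nchan=len(raw.ch_names),",
    "  onsets=list(map(float, raw.annotations.onset)),",
    "  labels=list(raw.annotations.description),",
    "  x0=list((raw.get_data()[0, :50]*1e6)))",
    "print(json.dumps(out))", sep = "\n")
  res <- system2("python", c("-c", shQuote(py)), stdout = TRUE, stderr = FALSE)
  parsed <- jsonlite::fromJSON(res[length(res)])
  expect_equal(parsed$sfreq, 250)
  expect_equal(parsed$nchan, 8)
  expect_equal(parsed$onsets, c(1.5, 4))
  expect_equal(parsed$labels, c("ev", "ev"))
  expect_lt(max(abs(parsed$x0 - recordingPeriods(g$recording)[[1]][1, 1:50])),
            0.01)
  file.remove(f)
})

test_that("segment export writes the 3-D array plus a faithful sidecar", {
  rec <- sineEventRecording(nch = 129, durS = 12, sr = 250,
                            eventTimes = seq(1, 10, length.out = 10))
  ss <- segmentEvents(rec, "stim", -100, 800)
  expect_equal(dim(segmentData(ss)), c(129L, 225L, 10L))
  d <- file.path(tempdir(), "segexp")
  exportSegments(ss, d)
  side <- jsonlite::read_json(file.path(d, "segments.json"), simplifyVector = TRUE)
  expect_equal(as.integer(side$dims), c(129L, 225L, 10L))
  expect_length(side$rel_time_ms, 225L)
  back <- importSegments(d)
  expect_identical(segmentData(back), segmentData(ss))
  expect_equal(relTimeMs(back), relTimeMs(ss))
  unlink(d, recursive = TRUE)

  ## all segments rejected: warning, nothing written
  ss@keepFlags[] <- FALSE
  d2 <- file.path(tempdir(), "segexp-none")
  expect_warning(out <- exportSegments(ss, d2), "no segments")
  expect_null(out)
  expect_false(file.exists(file.path(d2, "segments.bin")))
})
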