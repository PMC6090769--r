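test_that("event segmentation windows follow the stimulus-relative arithmetic", {
  rec <- makeRecording(matrix(seq_len(2000), 1, 2000) * 1.0, 250,
                       events = data.frame(label = "std", period = 1L,
                                           sample = 1018),
                       dataType = "event_tagged")
  ss <- segmentEvents(rec, "std", -100, 800)
  expect_equal(dim(segmentData(ss)), c(1L, 225L, 1L))
  ## samples [993, 1218): matrix is 1..n so values are 994..1218
  expect_equal(segmentData(ss)[1, 1, 1], 994)
  expect_equal(segmentData(ss)[1, 225, 1], 1218)
  expect_equal(ss@sourceStart, 993)
  expect_equal(range(relTimeMs(ss)), c(-100, 796))
  expect_error(segmentEvents(rec, "std", 0, 0), "precede")
})

test_that("events too close to the period edge are skipped with a warning", {
  rec <- makeRecording(matrix(0, 1, 1000), 250,
                       events = data.frame(label = "std", period = 1L,
                                           sample = c(10, 500)),
                       dataType = "event_tagged")
  expect_warning(ss <- segmentEvents(rec, "std", -100, 800), "skipped")
  expect_equal(nSegments(ss), 1L)
  expect_equal(ss@skippedEvents, 1L)
  ## no matching events: empty set plus warning, not an error
  expect_warning(empty <- segmentEvents(rec, "absent", -100, 800), "no events")
  expect_equal(nSegments(empty), 0L)
})

test_that("baseline tiling is exact and never crosses period boundaries", {
  rec60 <- makeRecording(matrix(0, 1, 60 * 250), 250)
  expect_equal(nSegments(segmentBaseline(rec60, 1)), 60L)

  ## 61.5 s: the 125-sample remainder is excluded
  rec615 <- makeRecording(matrix(0, 1, 61.5 * 250), 250)
  ss <- segmentBaseline(rec615, 1)
  expect_equal(nSegments(ss), 61L)
  expect_equal(max(ss@sourceStart) + 250, 61 * 250)

  ## two 1.5 s periods: one segment each, never one spanning the gap
  rec2 <- makeRecording(list(matrix(0, 1, 375), matrix(0, 1, 375)), 250)
  ss2 <- segmentBaseline(rec2, 1)
  expect_equal(nSegments(ss2), 2L)
  expect_equal(ss2@sourcePeriod, c(1L, 2L))

  expect_warning(e <- segmentBaseline(makeRecording(matrix(0, 1, 100), 250), 1),
                 "exceeds")
  expect_equal(nSegments(e), 0L)
})

test_that("the artifact mask matches the worked triangular-excursion example", {
  x <- numeric(300)
  x[92:110] <- approx(c(91, 100, 111), c(0, 150, 0), 92:110)$y
  rec <- makeRecording(matrix(x, 1, 300), 250)
  mask <- buildArtifactMask(rec, 100)
  expect_equal(unname(maskIntervals(mask)[[1]]),
               matrix(c(90, 111), 1), ignore_attr = TRUE)
  ## all sub-threshold: empty mask
  expect_equal(nrow(maskIntervals(buildArtifactMask(rec, 200))[[1]]), 0L)
  ## excursion at the period start extends to sample 0
  x0 <- c(150, 120, 80, -5, numeric(96))
  m0 <- buildArtifactMask(makeRecording(matrix(x0, 1, 100), 250), 100)
  expect_equal(unname(maskIntervals(m0)[[1]][1, 1]), 0)
})

test_that("the mask equals a brute-force outward-scan oracle on random signals", {
  for (seed in 1:50) {
    x <- randomArtifactSignal(400, seed)
    rec <- makeRecording(matrix(x, 1, 400), 250)
    got <- unname(maskIntervals(buildArtifactMask(rec, 100))[[1]])
    want <- unname(bruteMask(x, 100))
    expect_equal(got, want, ignore_attr = TRUE,
                 label = sprintf("seed %d", seed))
  }
  ## multi-channel union
  set.seed(99)
  mat <- rbind(randomArtifactSignal(400, 101), randomArtifactSignal(400, 102))
  got <- unname(maskIntervals(buildArtifactMask(
    makeRecording(mat, 250), 100))[[1]])
  expect_equal(got, unname(bruteMaskMatrix(mat, 100)), ignore_attr = TRUE)
})

test_that("masked intervals contain a suprathreshold sample and same-sign interiors", {
  for (seed in 51:70) {
    x <- randomArtifactSignal(400, seed)
    iv <- maskIntervals(buildArtifactMask(makeRecording(matrix(x, 1, 400), 250),
                                          100))[[1]]
    for (r in seq_len(nrow(iv))) {
      seg <- x[(iv[r, 1] + 1):iv[r, 2]]
      expect_true(any(abs(seg) > 100))
      ## the samples just inside the bounding zero-crossings carry the sign
      ## of the nearest suprathreshold excursion
      over <- which(abs(seg) > 100)
      inner <- seg[2:(length(seg) - 1)]
      firstNz <- inner[inner != 0][1]
      lastNz <- rev(inner[inner != 0])[1]
      expect_equal(sign(firstNz), sign(seg[over[1]]))
      expect_equal(sign(lastNz), sign(seg[over[length(over)]]))
    }
  }
})

test_that("segmenting the unmasked gaps tiles from each gap start", {
  rec <- makeRecording(matrix(0, 1, 2500), 250)
  mask <- new("ArtifactMask", intervals = list(matrix(c(1000, 1400), 1)),
              thresholdUv = 100)
  ss <- segmentMasked(rec, mask, 1)
  expect_equal(nSegments(ss), 8L)
  expect_equal(ss@sourceStart, c(0, 250, 500, 750, 1400, 1650, 1900, 2150))

  ## empty mask reduces exactly to plain baseline segmentation
  set.seed(7)
  rec2 <- makeRecording(matrix(rnorm(1250), 1, 1250), 250)
  empty <- new("ArtifactMask", intervals = list(matrix(numeric(0), ncol = 2)),
               thresholdUv = 100)
  expect_identical(segmentData(segmentMasked(rec2, empty, 1)),
                   segmentData(segmentBaseline(rec2, 1)))

  ## a 0.9 s gap contributes no segments
  mask3 <- new("ArtifactMask", intervals = list(matrix(c(225, 2500), 1)),
               thresholdUv = 100)
  expect_equal(nSegments(segmentMasked(rec, mask3, 1)), 0L)
})

test_that("amplitude rejection flags exactly the segments with threshold crossings", {
  m1 <- matrix(50, 2, 100); m2 <- matrix(50, 2, 100); m2[1, 40] <- 101
  ss <- rejectAmplitude(segSetFromList(list(m1, m2, m1)), 100)
  expect_equal(keepFlags(ss), c(TRUE, FALSE, TRUE))
  ## identical sub-threshold segments: none rejected
  ss2 <- rejectAmplitude(segSetFromList(list(m1, m1)), 100)
  expect_true(all(keepFlags(ss2)))

  ## equivalence with a brute-force per-segment max oracle after tiling
  set.seed(15)
  x <- randomArtifactSignal(2000, 301)
  rec <- makeRecording(matrix(x, 1, 2000), 250)
  ss3 <- rejectAmplitude(segmentBaseline(rec, 1), 100)
  want <- vapply(seq_len(nSegments(ss3)), function(k) {
    a <- ss3@sourceStart[k]
    max(abs(x[(a + 1):(a + 250)])) <= 100
  }, logical(1))
  expect_equal(keepFlags(ss3), want)
})

test_that("rejection ops only ever flip keep flags from TRUE to FALSE", {
  set.seed(23)
  mats <- lapply(1:12, function(i) matrix(rnorm(200, sd = 40), 2, 100))
  ss <- segSetFromList(mats)
  ss@keepFlags[c(2, 5)] <- FALSE
  out <- rejectAmplitude(ss, 90)
  expect_true(all(keepFlags(out)[!keepFlags(ss)] == FALSE))
  out2 <- rejectJointProbability(ss, 3)
  expect_true(all(keepFlags(out2)[!keepFlags(ss)] == FALSE))
})

test_that("joint-probability rejection flags a gross variance outlier", {
  set.seed(8)
  mats <- c(lapply(1:50, function(i) matrix(rnorm(100), 1, 100)),
            list(matrix(rnorm(100, sd = 10), 1, 100)))
  ss <- rejectJointProbability(segSetFromList(mats), 3)
  expect_false(keepFlags(ss)[51])
  expect_true(all(keepFlags(ss)[1:50]))

  ## identical segments: no rejections (all z = 0)
  same <- lapply(1:10, function(i) matrix(sin(1:100), 1, 100))
  expect_true(all(keepFlags(rejectJointProbability(segSetFromList(same), 3))))

  ## infinite threshold: no rejections
  expect_true(all(keepFlags(rejectJointProbability(segSetFromList(mats), Inf))))

  ## fewer than 8 kept: warn and skip
  few <- lapply(1:5, function(i) matrix(rnorm(100), 1, 100))
  expect_warning(out <- rejectJointProbability(segSetFromList(few), 3), "fewer than 8")
  expect_true(all(keepFlags(out)))
})

test_that("conditioned-baseline spans are tiled per onset/offset pair", {
  sr <- 250
  ev <- data.frame(label = c("on", "off", "on", "off"),
                   period = 1L, sample = c(0, 5, 10, 12.5) * sr)
  rec <- makeRecording(matrix(0, 1, 15 * sr), sr, events = ev,
                       dataType = "conditioned_baseline")
  ss <- segmentConditionedBaseline(rec, "on", "off", 1)
  expect_equal(nSegments(ss), 7L)   # 5 + 2

  ## no pairs: empty set with warning
  recNo <- makeRecording(matrix(0, 1, 1000), sr, dataType = "conditioned_baseline")
  expect_warning(e <- segmentConditionedBaseline(recNo, "on", "off", 1), "no onset")
  expect_equal(nSegments(e), 0L)

  ## (on, on, off): the earlier onset is dropped with a warning
  ev2 <- data.frame(label = c("on", "on", "off"), period = 1L,
                    sample = c(0, 500, 1000))
  rec2 <- makeRecording(matrix(0, 1, 1500), sr, events = ev2,
                        dataType = "conditioned_baseline")
  expect_warning(ss2 <- segmentConditionedBaseline(rec2, "on", "off", 1),
                 "consecutive onsets")
  expect_equal(nSegments(ss2), 2L)
  expect_equal(ss2@sourceStart, c(500, 750))
})

test_that("within-segment detrending is exact on ramps and idempotent", {
  ramps <- lapply(1:3, function(i) {
    m <- matrix(0, 2, 100)
    m[1, ] <- seq(0, i, length.out = 100); m[2, ] <- seq(i, 0, length.out = 100)
    m
  })
  ss <- detrendWithinSegment(segSetFromList(ramps))
  expect_lt(max(abs(segmentData(ss))), 1e-9)

  set.seed(12)
  noisy <- segSetFromList(lapply(1:4, function(i) matrix(rnorm(200), 2, 100)))
  once <- detrendWithinSegment(noisy)
  twice <- detrendWithinSegment(once)
  expect_equal(segmentData(twice), segmentData(once), tolerance = 1e-9)

  ## an integer number of sinusoid cycles survives with amplitude intact
  tt <- (0:249) / 250
  sine <- segSetFromList(list(matrix(sin(2 * pi * 8 * tt), 1, 250)))
  out <- detrendWithinSegment(sine)
  expect_equal(sqrt(mean(segmentData(out)^2)), sqrt(0.5), tolerance = 0.01)
})

test_that("sub-segmenting and baseline correction slice and centre exactly", {
  rec <- sineEventRecording(nch = 2, durS = 12, eventTimes = c(2, 5, 8))
  ss <- segmentEvents(rec, "stim", -100, 800)
  sub <- extractSubsegment(ss, 0, 800)
  expect_equal(dim(segmentData(sub))[2], 200L)
  expect_error(extractSubsegment(ss, -500, 800), "outside")

  const <- segSetFromList(list(matrix(4, 2, 100)), startMs = 0)
  bc <- baselineCorrect(const, 0, 400)
  expect_true(all(segmentData(bc) == 0))

  bc2 <- baselineCorrect(ss, -100, 0)
  sel <- relTimeMs(bc2) >= -100 & relTimeMs(bc2) < 0
  for (k in seq_len(nSegments(bc2)))
    expect_lt(max(abs(rowMeans(segmentData(bc2)[, sel, k]))), 1e-12)
})

test_that("mask-before and reject-after thresholding agree in their guarantees", {
  for (seed in 201:215) {
    x <- randomArtifactSignal(2000, seed)
    rec <- makeRecording(matrix(x, 1, 2000), 250)
    thr <- 100
    mask <- buildArtifactMask(rec, thr)
    pre <- segmentMasked(rec, mask, 1)
    post <- rejectAmplitude(segmentBaseline(rec, 1), thr)
    if (nrow(maskIntervals(mask)[[1]]) == 0L) {
      ## with no artifact the two paths agree exactly
      expect_identical(segmentData(pre), segmentData(post))
      expect_true(all(keepFlags(post)))
    } else {
      ## the pre-mask path never keeps a suprathreshold sample
      if (nSegments(pre) > 0L)
        expect_lte(max(abs(segmentData(pre))), thr)
      ## no sample is claimed twice, and kept samples never exceed recorded
      starts <- pre@sourceStart
      expect_true(all(diff(sort(starts)) >= 250))
      expect_lte(nSegments(pre) * 250, 2000)
    }
  }
})
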