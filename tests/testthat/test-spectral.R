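binAt <- function(psd, f) which.min(abs(psdFreqs(psd) - f))

test_that("a bin-centred cosine yields its analytic single-sided power", {
  ## x = 2 cos(2 pi 10 t), sr 256, l 256: |X| = A l / 2 so the printed
  ## formula gives 2 |X|^2 / (l sr) = 2 at the 10 Hz bin, 0 elsewhere
  x <- 2 * cos(2 * pi * 10 * (0:255) / 256)
  ss <- segSetFromList(list(matrix(x, 1, 256)), sr = 256)
  psd <- computePsd(ss, "rectangular")
  expect_equal(meanPower(psd)[1, binAt(psd, 10)], 2, tolerance = 1e-9)
  expect_lt(sum(meanPower(psd)[1, -binAt(psd, 10)]), 1e-9)

  ## all-zero input: all-zero power
  z <- computePsd(segSetFromList(list(matrix(0, 1, 256)), sr = 256))
  expect_true(all(meanPower(z) == 0))
})

test_that("segments are zero-padded to the next power of 2", {
  ss <- segSetFromList(list(matrix(rnorm(225), 1, 225)), sr = 250)
  psd <- computePsd(ss)
  expect_equal(psd@fftLen, 256L)
  expect_equal(diff(psdFreqs(psd))[1], 250 / 256)
  expect_equal(range(psdFreqs(psd)), c(0, 125))
})

test_that("the summed spectrum preserves signal energy (Parseval)", {
  set.seed(44)
  for (i in 1:10) {
    y <- rnorm(256); y <- y - mean(y)
    psd <- computePsd(segSetFromList(list(matrix(y, 1, 256)), sr = 256))
    expect_equal(sum(meanPower(psd)), sum(y^2) / 256, tolerance = 0.01)
  }
})

test_that("Hanning windowing scales a sinusoid peak by the coherent gain", {
  x <- 2 * cos(2 * pi * 16 * (0:255) / 256)
  ss <- segSetFromList(list(matrix(x, 1, 256)), sr = 256)
  rectPk <- meanPower(computePsd(ss, "rectangular"))[1, binAt(computePsd(ss), 16)]
  hannPk <- meanPower(computePsd(ss, "hanning"))[1, binAt(computePsd(ss), 16)]
  ## coherent gain of the Hanning window is 1/2, so peak power scales by 1/4
  expect_equal(hannPk / rectPk, 0.25, tolerance = 0.02)
  corrPk <- meanPower(computePsd(ss, "hanning", windowCorrection = TRUE))[1, binAt(computePsd(ss), 16)]
  expect_equal(corrPk / rectPk, 1, tolerance = 0.02)
})

test_that("PSD is additive in power for independent sources", {
  set.seed(55)
  n <- 200
  mx <- lapply(1:n, function(i) matrix(rnorm(256), 1, 256))
  my <- lapply(1:n, function(i) matrix(rnorm(256, sd = 2), 1, 256))
  ms <- Map(`+`, mx, my)
  px <- meanPower(computePsd(segSetFromList(mx, sr = 256)))
  py <- meanPower(computePsd(segSetFromList(my, sr = 256)))
  ps <- meanPower(computePsd(segSetFromList(ms, sr = 256)))
  expect_equal(mean(ps), mean(px + py), tolerance = 0.05)
})

test_that("Slepian tapers are orthonormal and concentrated", {
  tap <- dpssTapers(128, 5, 3)
  expect_equal(dim(tap), c(5L, 128L))
  expect_equal(tap %*% t(tap), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  ## the leading taper is bell-shaped: maximum in the middle half
  expect_true(which.max(tap[1, ]) %in% 32:96)
})

test_that("multitaper estimation reduces spectral variance on white noise", {
  set.seed(66)
  mats <- lapply(1:100, function(i) matrix(rnorm(128), 1, 128))
  ss <- segSetFromList(mats, sr = 128)
  p1 <- computePsdMultitaper(ss, 1)
  p5 <- computePsdMultitaper(ss, 5)
  v1 <- mean(apply(p1@power[1, , ], 2, var))
  v5 <- mean(apply(p5@power[1, , ], 2, var))
  expect_lt(v5, v1)
  expect_error(computePsdMultitaper(ss, 65), "between 1 and")
  z <- computePsdMultitaper(segSetFromList(list(matrix(0, 1, 128)), sr = 128), 3)
  expect_true(all(meanPower(z) == 0))
})

test_that("multitaper white-noise power is flat across octave bands", {
  set.seed(77)
  mats <- lapply(1:200, function(i) matrix(rnorm(256), 1, 256))
  psd <- computePsdMultitaper(segSetFromList(mats, sr = 256), 5)
  bands <- data.frame(name = c("o1", "o2", "o3", "o4"),
                      lo = c(8, 16, 32, 64), hi = c(16, 32, 64, 128))
  bp <- bandPower(psd, bands)
  expect_lt(diff(range(bp$power_abs)) / mean(bp$power_abs), 0.1)
})

test_that("band binning normalizes, logs, and flags empty bands", {
  x <- 2 * cos(2 * pi * 10 * (0:255) / 256)
  psd <- computePsd(segSetFromList(list(matrix(x, 1, 256)), sr = 256))
  one <- bandPower(psd, data.frame(name = "all", lo = 0, hi = 129))
  expect_equal(one$power_norm, 1)

  ## flat spectrum splits evenly between two equal bands
  flat <- psd
  flat@meanPower[] <- 3
  two <- bandPower(flat, data.frame(name = c("lo", "hi"), lo = c(0, 10),
                                    hi = c(10, 20)))
  expect_equal(two$power_abs[1], two$power_abs[2])
  expect_equal(two$power_norm, c(0.5, 0.5))
  expect_equal(two$power_log10, log10(two$power_abs), tolerance = 1e-12)
  expect_equal(two$power_ln, log(two$power_abs), tolerance = 1e-12)

  expect_warning(bad <- bandPower(psd, data.frame(name = "none", lo = 125.5,
                                                  hi = 125.9)), "no frequency bins")
  expect_true(is.na(bad$power_abs))

  ## normalized power sums to 1 whenever the bands partition the spectrum
  part <- bandPower(psd, data.frame(name = c("a", "b", "c"),
                                    lo = c(0, 20, 60), hi = c(20, 60, 129)))
  expect_equal(sum(part$power_norm), 1)
})

test_that("ITPC reaches its analytic limits", {
  x <- matrix(2 * cos(2 * pi * 10 * (0:255) / 256), 1, 256)
  same <- computeItpc(segSetFromList(list(x, x, x, x), sr = 256),
                      subwindowMs = 500, hopFraction = 0.5)
  ## identical trials: |itpc| = 1 at every nonzero-energy bin
  expect_lt(max(abs(Mod(itpcValues(same)) - 1)), 1e-12)

  anti <- computeItpc(segSetFromList(list(x, -x), sr = 256), subwindowMs = 500)
  expect_lt(max(Mod(itpcValues(anti))), 1e-12)

  expect_error(computeItpc(segSetFromList(list(x), sr = 256)), "at least 2")
  ## |itpc| never exceeds 1 on arbitrary data
  set.seed(88)
  rnd <- segSetFromList(lapply(1:6, function(i) matrix(rnorm(512), 2, 256)),
                        sr = 256)
  expect_lte(max(Mod(itpcValues(computeItpc(rnd, 250)))), 1 + 1e-12)
})

test_that("uniform random phases give E|itpc|^2 = 1/n", {
  ## 2000 independent replicates ride along the channel dimension: each
  ## channel holds the same 8 Hz tone with i.i.d. uniform phase per trial
  nrep <- 2000; ntrial <- 8; m <- 32; sr <- 32
  set.seed(123)
  tt <- (0:(m - 1)) / sr
  mats <- lapply(seq_len(ntrial), function(k) {
    ph <- runif(nrep, 0, 2 * pi)
    t(vapply(seq_len(nrep), function(r) cos(2 * pi * 8 * tt + ph[r]),
             numeric(m)))
  })
  ss <- segSetFromList(mats, sr = sr)
  res <- computeItpc(ss, subwindowMs = 1000 * m / sr, hopFraction = 1)
  bin <- which.min(abs(psdFreqs(res) - 8))
  msq <- Mod(res@itpc[, bin, 1])^2
  se <- sd(msq) / sqrt(nrep)
  expect_lt(abs(mean(msq) - 1 / ntrial), 3 * se)
})

test_that("ITPC summaries report max, mean and the argmax location", {
  x <- matrix(2 * cos(2 * pi * 10 * (0:255) / 256), 2, 256, byrow = TRUE)
  res <- computeItpc(segSetFromList(list(x, x, x), sr = 256), 500)
  s <- itpcSummary(res)
  expect_equal(s$summary$itpc_max, c(1, 1))
  expect_equal(s$summary$itpc_mean, c(1, 1))
  ## max >= mean always
  set.seed(9)
  rnd <- computeItpc(segSetFromList(lapply(1:5, function(i)
    matrix(rnorm(512), 2, 256)), sr = 256), 250)
  sr2 <- itpcSummary(rnd)
  expect_true(all(sr2$summary$itpc_max >= sr2$summary$itpc_mean))
  g <- itpcSummary(res, channelGroup = c("E1", "E2"))
  expect_true(g$argmaxChannel %in% c("E1", "E2"))
  expect_error(itpcSummary(res, timeRangeMs = c(5000, 6000)), "empty")
})

test_that("a phase-locked post-stimulus burst dominates the ITPC surface", {
  set.seed(131)
  spec <- synthSpec(nChannels = 4, samplingRate = 250, durationS = 40,
                    events = data.frame(label = "stim",
                                        time_s = seq(1, 38, by = 1.8) +
                                          round(runif(21, -0.2, 0.2), 3),
                                        period = 1L),
                    burst = list(freq = 6, amp = 8, fromMs = 150, toMs = 300),
                    seed = 31)
  rec <- generateRecording(spec)$recording
  ss <- segmentEvents(rec, "stim", -100, 800)
  res <- computeItpc(ss, 256)
  s <- itpcSummary(res, freqRangeHz = c(2, 20))
  best <- s$summary$argmax_time_ms[which.max(s$summary$itpc_max)]
  expect_gte(best, 150)
  expect_lte(best, 300)
})
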