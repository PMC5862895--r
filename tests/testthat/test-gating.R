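simpleLog <- function(frameTimes, pressure = rep(1, length(frameTimes)),
                      trig = c(0, 400, 800), rpk = seq(0, 800, by = 100)) {
  new("AcquisitionLog", frameTimes = frameTimes,
      ventTriggerTimes = trig, ecgRpeakTimes = rpk,
      airwayPressure = pressure, params = list())
}

test_that("a frame exactly at a ventilation trigger starts phase 0", {
  log <- simpleLog(c(400, 410))
  g <- doubleGateFrames(log)
  expect_true(1L %in% g@ventBins[[1]])           # bin 0 (half-open cycle)
})

test_that("a frame midway through an RR interval lands in cardiac bin 4 of 8", {
  log <- simpleLog(c(150), pressure = 1)         # 50% of the 100-ms RR
  g <- doubleGateFrames(log)
  expect_true(1L %in% g@cardBins[[5]])           # floor(0.5 * 8) = 4
})

test_that("high-pressure frames stay ventilation-binned but leave cardiac bins", {
  log <- simpleLog(c(150, 250), pressure = c(10, 1))
  g <- doubleGateFrames(log, pressureThreshold = 4)
  expect_true(1L %in% unlist(g@ventBins))
  expect_false(1L %in% unlist(g@cardBins))
  expect_true(1L %in% g@excludedFromCardiac)
  expect_true(2L %in% unlist(g@cardBins))
  # the filter is strictly '<': pressure exactly at threshold is excluded
  log2 <- simpleLog(c(150), pressure = 4)
  g2 <- doubleGateFrames(log2)
  expect_false(1L %in% unlist(g2@cardBins))
})

test_that("frames before the first trigger are reported unbinnable, not dropped", {
  log <- simpleLog(c(5, 50), trig = c(40, 440, 840), rpk = c(45, 145, 245))
  g <- doubleGateFrames(log)
  expect_equal(g@unbinnableVent, 1L)
  expect_equal(g@unbinnableCard, 1L)
  expect_equal(sum(lengths(g@ventBins)) + length(g@unbinnableVent), 2L)
})

test_that("bin assignment matches the brute-force phase computation on random logs", {
  for (seed in 1:5) {
    log <- generateAcquisitionLog(4000, frameRate = 125, jitter = 3,
                                  pressureNoise = 0.3, seed = seed)
    g <- doubleGateFrames(log)
    n <- length(log@frameTimes)
    got <- binVectors(g, n)
    ref <- bruteForceGating(log)
    expect_identical(got$vent, ref$vent)
    expect_identical(got$card, ref$card)
    # partition: every frame ventilation-binned or unbinnable, exactly once
    expect_equal(sum(lengths(g@ventBins)) + length(g@unbinnableVent), n)
    expect_false(anyDuplicated(unlist(g@ventBins)) > 0)
    # exclusion: no high-pressure frame in any cardiac bin
    expect_length(intersect(unlist(g@cardBins),
                            which(log@airwayPressure >= 4)), 0L)
  }
})
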