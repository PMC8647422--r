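test_that("default phantom carries the configured regurgitant volume", {
  truth <- phantomNoiseFree$truth
  expect_equal(trueVolume(truth), 16)
  # stored flow curve integrates to the analytic volume within 0.1%
  fc <- trueFlowCurve(truth)
  integ <- sum(diff(curveTimes(fc)) *
                 (head(rates(fc), -1) + tail(rates(fc), -1)) / 2) / 1000
  expect_equal(integ, 16, tolerance = 1e-3)
  # mid-to-late systolic window on the 38 ms frame grid
  expect_identical(truth@activeFrames, 7:12)
  expect_false(any(atrialROI(truth) & staticMask(truth)))
})

test_that("discrete core flux matches the analytic flow rate (brute-force oracle)", {
  ph <- phantomNoiseFree
  peakFrame <- 9L  # half-sine near maximum
  fc <- trueFlowCurve(ph$truth)
  qTrue <- approx(curveTimes(fc), rates(fc),
                  xout = frameTimes(ph$field)[peakFrame])$y
  qOracle <- bruteForceFlux(ph$field, ph$truth, peakFrame, aMid = 25)
  expect_equal(qOracle, qTrue, tolerance = 0.05)
})

test_that("phantom rejects degenerate configurations", {
  expect_error(phantomConfig(jetOnset = 300, jetOffset = 300), "exceed")
  expect_error(phantomConfig(coreRadius = 3), "3 voxels")
  expect_error(
    generateJetPhantom(phantomConfig(orificeCenter = c(90, 90, 90))),
    "exits grid")
})

test_that("phantom generation is deterministic given the seed", {
  a <- generateJetPhantom(phantomConfig(noiseSd = 5, seed = 11L))
  b <- generateJetPhantom(phantomConfig(noiseSd = 5, seed = 11L))
  expect_identical(velocities(a$field), velocities(b$field))
  c <- generateJetPhantom(phantomConfig(noiseSd = 5, seed = 12L))
  expect_false(identical(velocities(a$field), velocities(c$field)))
})

test_that("doubling the target volume doubles the truth and the estimate", {
  ph1 <- generateJetPhantom(phantomConfig(noiseSd = 0, targetVolume = 8))
  ph2 <- generateJetPhantom(phantomConfig(noiseSd = 0, targetVolume = 16))
  expect_equal(trueVolume(ph2$truth), 2 * trueVolume(ph1$truth))
  v1 <- totalMRVolume(trackMitralRegurgitation(ph1$field, atrialROI(ph1$truth)))
  v2 <- totalMRVolume(trackMitralRegurgitation(ph2$field, atrialROI(ph2$truth)))
  expect_equal(v2 / v1, 2, tolerance = 0.1)
})

test_that("velocity wrapping follows the modular formula", {
  arr <- array(0, c(1, 3, 3, 3, 3))
  arr[1, 1, 1, 1, 1] <- 180
  arr[1, 2, 1, 1, 1] <- 100
  arr[1, 3, 1, 1, 1] <- -160
  f <- velocityField4D(arr, spacing = c(1, 1, 1), venc = 150)
  w <- velocities(wrapVelocities(f))
  expect_equal(w[1, 1, 1, 1, 1], -120)
  expect_equal(w[1, 2, 1, 1, 1], 100)
  expect_equal(w[1, 3, 1, 1, 1], 140)
  expect_true(all(abs(w) <= 150))
})

test_that("indirect inputs close the loop with the jet truth", {
  truth <- phantomNoiseFree$truth
  io <- generateIndirectInputs(truth, forwardVolume = 79)
  cv <- strokeVolumeMetrics(io$volumeCurve)
  expect_equal(cv@sv, 79 + 16)  # EDV - ESV = forward + MR by construction
  expect_equal(aorticForwardVolume(io$flowCurve), 79, tolerance = 1e-9)
  mr <- indirectMRVolume(cv@sv, aorticForwardVolume(io$flowCurve))
  expect_equal(mr, trueVolume(truth), tolerance = 0.1)
  expect_error(generateIndirectInputs(truth, forwardVolume = -5), "positive")
})

test_that("zero-MR truth yields stroke volume equal to forward volume", {
  ph0 <- generateJetPhantom(phantomConfig(targetVolume = 0, noiseSd = 0))
  expect_equal(trueVolume(ph0$truth), 0)
  io <- generateIndirectInputs(ph0$truth, forwardVolume = 70)
  expect_equal(strokeVolumeMetrics(io$volumeCurve)@sv, 70)
})
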