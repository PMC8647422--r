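test_that("regurgitant frame detection recovers the phantom's jet timing", {
  ph <- phantomNoiseFree
  jets <- detectRegurgitantFrames(ph$field, atrialROI(ph$truth))
  expect_length(jets, 1L)
  expect_identical(as.integer(jets[[1]]$frames), ph$truth@activeFrames)
})

test_that("a pure-noise phantom yields no jets", {
  ph0 <- generateJetPhantom(phantomConfig(targetVolume = 0, noiseSd = 5,
                                          seed = 5L))
  jets <- detectRegurgitantFrames(ph0$field, atrialROI(ph0$truth))
  expect_length(jets, 0L)
  expect_error(detectRegurgitantFrames(ph0$field,
                                       array(FALSE, dim(atrialROI(ph0$truth)))),
               "nonempty")
})

test_that("two disjoint jets are detected as two jets", {
  ph <- generateJetPhantom(twoJetConfig(noiseSd = 0))
  jets <- detectRegurgitantFrames(ph$field, atrialROI(ph$truth))
  expect_length(jets, 2L)
})

test_that("the jet peak lies on the axis and points along the flow", {
  ph <- phantomNoiseFree
  jets <- detectRegurgitantFrames(ph$field, atrialROI(ph$truth))
  fr <- 9L
  pk <- locateJetPeak(ph$field, fr, jets[[1]]$voxels[[as.character(fr)]])
  ax <- ph$truth@jetAxisPerFrame[fr, ]
  rel <- pk$location - ph$truth@orificeCenter
  rho <- sqrt(sum(rel^2) - sum(rel * ax)^2)
  expect_lt(rho, max(spacing(ph$field)))        # within one voxel of the axis
  expect_gt(sum(pk$direction * ax), 0.98)
})

test_that("a single-voxel component is its own peak", {
  arr <- array(0, c(1, 5, 5, 5, 3))
  arr[1, 3, 3, 3, ] <- c(30, 0, 40)
  f <- velocityField4D(arr, spacing = c(2, 2, 2), venc = 150)
  vox <- which(array(seq_len(125), c(5, 5, 5)) == 63)  # linear index of (3,3,3)
  pk <- locateJetPeak(f, 1L, vox)
  expect_equal(pk$speed, 50)
  expect_equal(pk$direction, c(0.6, 0, 0.8))
  expect_equal(pk$location, c(4, 4, 4))
})

test_that("an aliased global maximum defers to the unflagged maximum downstream", {
  arr <- array(0, c(1, 9, 3, 3, 3))
  arr[1, 2, 2, 2, 1] <- 140   # flagged global max
  arr[1, 6, 2, 2, 1] <- 120   # unflagged secondary max, downstream
  arr[1, 4, 2, 2, 1] <- 60
  flags <- array(FALSE, c(1, 9, 3, 3))
  flags[1, 2, 2, 2] <- TRUE
  f <- velocityField4D(arr, spacing = c(1, 1, 1), venc = 150,
                       aliasFlags = flags)
  comp <- which(array(arr[1, , , , 1] != 0, c(9, 3, 3)))
  pk <- locateJetPeak(f, 1L, comp)
  expect_equal(pk$speed, 120)
  expect_equal(pk$location[1], 5)  # voxel 6, 0-based mm coordinate 5
  flags[1, , , ] <- TRUE
  fAll <- velocityField4D(arr, spacing = c(1, 1, 1), venc = 150,
                          aliasFlags = flags)
  expect_error(locateJetPeak(fAll, 1L, comp), "aliasing")
})

test_that("through-plane sampling projects a uniform field correctly", {
  f <- uniformField(c(0, 0, 100))
  mid <- c(11, 11, 11)
  pl <- mprPlane(mid, c(0, 0, 1), extent = 10, pixelSpacing = 1)
  smp <- sampleThroughPlane(f, 1L, pl)
  expect_true(all(abs(smp@throughPlane[!smp@outOfBounds] - 100) < 1e-9))
  plNeg <- mprPlane(mid, c(0, 0, -1), extent = 10, pixelSpacing = 1)
  smpNeg <- sampleThroughPlane(f, 1L, plNeg)
  expect_true(all(abs(smpNeg@throughPlane[!smpNeg@outOfBounds] + 100) < 1e-9))
  # normal at 60 degrees to the flow -> cosine projection
  n60 <- c(sin(pi / 3), 0, cos(pi / 3))
  smp60 <- sampleThroughPlane(f, 1L, mprPlane(mid, n60, extent = 10))
  expect_true(all(abs(smp60@throughPlane[!smp60@outOfBounds] - 50) < 1e-6))
  # plane entirely outside the volume
  expect_error(sampleThroughPlane(f, 1L, mprPlane(c(500, 500, 500), c(0, 0, 1),
                                                  extent = 10)),
               "outside")
})

test_that("plane frames are orthonormal and right-handed", {
  for (n in list(c(1, 0, 0), c(0.3, -0.5, 0.8), c(-1, 1, 1))) {
    pl <- mprPlane(c(0, 0, 0), n)
    B <- rbind(pl@inPlaneU, pl@inPlaneV, pl@normal)
    expect_equal(B %*% t(B), diag(3), tolerance = 1e-12)
    expect_equal(mrjet:::.cross3(pl@inPlaneU, pl@inPlaneV), pl@normal,
                 tolerance = 1e-12)
  }
})

test_that("cross-section segmentation matches the analytic disk area", {
  # top-hat disk radius 5 mm on a 1 mm raster, zero background
  n <- 41L
  xy <- (seq_len(n) - (n + 1) / 2)
  rr <- sqrt(outer(xy^2, xy^2, `+`))
  tp <- ifelse(rr <= 5, 150, 0)
  smp <- new("PlaneSample", throughPlane = tp,
             jetMask = matrix(FALSE, n, n),
             outOfBounds = matrix(FALSE, n, n), pixelArea = 1,
             frameIndex = 1L)
  seg <- segmentJetCrossSection(smp, relativeThreshold = 0.25, dilatePx = 0L)
  expect_equal(sum(seg@jetMask), pi * 25, tolerance = 0.1)
  # all-zero plane -> empty mask, zero flow
  zero <- new("PlaneSample", throughPlane = matrix(0, n, n),
              jetMask = matrix(FALSE, n, n),
              outOfBounds = matrix(FALSE, n, n), pixelArea = 1,
              frameIndex = 1L)
  segZero <- segmentJetCrossSection(zero)
  expect_equal(sum(segZero@jetMask), 0)
  expect_equal(computeFlowRate(segZero), 0)
  # two disjoint blobs: only the one containing the origin is kept
  tp2 <- matrix(0, n, n)
  tp2[18:24, 18:24] <- 100
  tp2[2:5, 2:5] <- 100
  blob <- new("PlaneSample", throughPlane = tp2,
              jetMask = matrix(FALSE, n, n),
              outOfBounds = matrix(FALSE, n, n), pixelArea = 1,
              frameIndex = 1L)
  segBlob <- segmentJetCrossSection(blob, dilatePx = 0L)
  expect_equal(sum(segBlob@jetMask), 49)
  expect_false(any(segBlob@jetMask[2:5, 2:5]))
})

test_that("flow rate is the area-weighted through-plane sum", {
  n <- 20L
  tp <- matrix(0, n, n)
  tp[1:10, 1:20] <- 100  # 200 pixels at 100 cm/s over 1 mm^2
  smp <- new("PlaneSample", throughPlane = tp, jetMask = tp > 0,
             outOfBounds = matrix(FALSE, n, n), pixelArea = 1,
             frameIndex = 1L)
  expect_equal(computeFlowRate(smp), 200)
})

test_that("spline integration reproduces closed-form and trapezoid oracles", {
  # half-sine: closed form 2*Qmax*T/pi
  t <- seq(0, 200, 40)
  q <- 100 * sin(pi * t / 200)
  expect_equal(integrateRegurgitantCurve(t, q), 2 * 100 * 0.2 / pi,
               tolerance = 0.02)
  # constant rate: trapezoid under the same anchor convention gives
  # 9.0 mL; the spline bulges slightly at the shoulders
  vConst <- integrateRegurgitantCurve(seq(0, 160, 40), rep(50, 5))
  expect_equal(vConst, 9.0, tolerance = 0.06)
  expect_equal(vConst, 9.513144, tolerance = 1e-6)  # frozen regression value
  # single-frame conventions
  expect_equal(integrateRegurgitantCurve(100, 0, 38), 0)
  expect_equal(integrateRegurgitantCurve(100, 60, 40), 60 * 40 / 2 / 1000)
  expect_error(integrateRegurgitantCurve(c(0, 0), c(1, 2)), "increasing")
})

test_that("tracked volume is invariant under spatial translation", {
  base <- phantomConfig(noiseSd = 0)
  shifted <- phantomConfig(noiseSd = 0,
                           orificeCenter = c(25, 28, 22) + c(5, 2.5, -2.5))
  v0 <- totalMRVolume(trackMitralRegurgitation(
    generateJetPhantom(base)$field, atrialROI(generateJetPhantom(base)$truth)))
  phS <- generateJetPhantom(shifted)
  v1 <- totalMRVolume(trackMitralRegurgitation(phS$field, atrialROI(phS$truth)))
  expect_equal(v1, v0, tolerance = 0.01)
})

test_that("flow rates scale linearly with a global velocity factor", {
  ph <- phantomNoiseFree
  fr <- 9L
  jets <- detectRegurgitantFrames(ph$field, atrialROI(ph$truth))
  pk <- locateJetPeak(ph$field, fr, jets[[1]]$voxels[[as.character(fr)]])
  pl <- mprPlane(pk$location, pk$direction)
  q1 <- computeFlowRate(segmentJetCrossSection(
    sampleThroughPlane(ph$field, fr, pl)))
  scaled <- velocityField4D(velocities(ph$field) * 1.5,
                            spacing = spacing(ph$field),
                            frameTimes = frameTimes(ph$field),
                            venc = venc(ph$field))
  q2 <- computeFlowRate(segmentJetCrossSection(
    sampleThroughPlane(scaled, fr, pl)))
  expect_equal(q2, 1.5 * q1, tolerance = 1e-9)
})

test_that("the jet-aligned plane sees positive flow across the core", {
  ph <- phantomNoiseFree
  res <- trackMitralRegurgitation(ph$field, atrialROI(ph$truth))
  fr <- 9L
  jets <- detectRegurgitantFrames(ph$field, atrialROI(ph$truth))
  pk <- locateJetPeak(ph$field, fr, jets[[1]]$voxels[[as.character(fr)]])
  smp <- segmentJetCrossSection(sampleThroughPlane(
    ph$field, fr, mprPlane(pk$location, pk$direction)), dilatePx = 0L)
  expect_true(all(smp@throughPlane[smp@jetMask] > 0))
  # result invariants
  expect_equal(totalMRVolume(res), sum(perJetVolumes(res)))
  tm <- mrTiming(res)
  expect_equal(unname(tm["duration"]), unname(tm["end"] - tm["start"] + 1L))
  expect_lte(abs(tm[["duration"]] - length(ph$truth@activeFrames)), 1L)
})
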