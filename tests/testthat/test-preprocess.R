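test_that("an isolated aliased voxel is unwrapped toward its neighbours", {
  # single wrapped voxel at -120 among neighbours near +130, VENC 150:
  # exhaustive k-choice oracle picks k = +1 -> +180
  arr <- array(130, c(1, 3, 3, 3, 3))
  arr[1, , , , 2:3] <- 0
  arr[1, 2, 2, 2, 1] <- -120
  f <- velocityField4D(arr, spacing = c(1, 1, 1), venc = 150)
  ks <- -1:1
  oracle <- ks[which.min(abs(-120 + 2 * ks * 150 - 130))]
  expect_identical(oracle, 1L)
  u <- unwrapAliasing(f)
  expect_equal(velocities(u)[1, 2, 2, 2, 1], -120 + 2 * oracle * 150)
  expect_true(aliasFlags(u)[1, 2, 2, 2])
  expect_equal(sum(aliasFlags(u)), 1)
})

test_that("alias-free smooth fields pass through unchanged", {
  ph <- phantomNoiseFree
  u <- unwrapAliasing(ph$field)
  expect_equal(velocities(u), velocities(ph$field))
  expect_equal(sum(aliasFlags(u)), 0)
})

test_that("wrap/unwrap round trip restores an aliased jet", {
  ph <- generateJetPhantom(aliasedJetConfig())
  wrapped <- wrapVelocities(ph$field)
  expect_true(max(abs(velocities(wrapped))) <= venc(ph$field))
  expect_gt(sum(abs(velocities(wrapped) - velocities(ph$field)) > 1), 0)
  u <- unwrapAliasing(wrapped)
  dv <- abs(velocities(u) - velocities(ph$field))
  core <- ph$truth@coreMask
  restored <- vapply(ph$truth@activeFrames, function(fr) {
    dmax <- apply(dv[fr, , , , ], 1:3, max)
    mean(dmax[core] < 1e-3)
  }, numeric(1))
  expect_gte(mean(restored), 0.99)
  # unwrapping only ever moves a voxel by a multiple of 2*venc
  delta <- velocities(u) - velocities(wrapped)
  expect_true(all(abs(delta / (2 * venc(ph$field)) -
                        round(delta / (2 * venc(ph$field)))) < 1e-9))
  # idempotence
  u2 <- unwrapAliasing(u)
  expect_equal(velocities(u2), velocities(u))
})

test_that("background offset correction removes constant and planar offsets", {
  ph <- phantomNoiseFree
  f <- ph$field
  mkField <- function(v) velocityField4D(v, spacing = spacing(f),
                                         frameTimes = frameTimes(f),
                                         venc = venc(f))
  # constant offset on all components
  cor1 <- correctBackgroundOffset(mkField(velocities(f) + 5),
                                  staticMask(ph$truth))
  expect_equal(velocities(cor1), velocities(f), tolerance = 1e-6)
  # linear-in-x offset matches the first-order fit exactly
  d <- dim(velocities(f))
  xs <- ((seq_len(d[2]) - 1)) * spacing(f)[1]
  v2 <- velocities(f) + rep(0.05 * xs, each = d[1])
  cor2 <- correctBackgroundOffset(mkField(v2), staticMask(ph$truth))
  expect_equal(velocities(cor2), velocities(f), tolerance = 1e-6)
  # offset-free field unchanged; correction idempotent
  cor3 <- correctBackgroundOffset(f, staticMask(ph$truth))
  expect_equal(velocities(cor3), velocities(f), tolerance = 1e-6)
  # static-region mean is zero after correction
  sel <- staticMask(ph$truth)
  expect_lt(max(abs(vapply(1:3, function(comp)
    mean(array(velocities(cor2)[1, , , , comp], d[2:4])[sel]),
    numeric(1)))), 1e-8)
  expect_error(correctBackgroundOffset(f, array(FALSE, d[2:4])), "nonempty")
})

test_that("flow-curve offset correction zeroes the diastasis window", {
  fc <- flowCurve(seq(0, 700, 20), sin(seq(0, 700, 20) / 50) + 3)
  corr <- correctBackgroundOffset(fc, window = c(600, 700))
  sel <- curveTimes(corr) >= 600
  expect_equal(mean(rates(corr)[sel]), 0, tolerance = 1e-12)
  twice <- correctBackgroundOffset(corr, window = c(600, 700))
  expect_equal(rates(twice), rates(corr), tolerance = 1e-12)
})
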