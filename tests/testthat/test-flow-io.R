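test_that("velocity field survives a write/read round trip", {
  ph <- phantomNoiseFree
  td <- withr::local_tempdir()
  pref <- file.path(td, "ph")
  files <- writeVelocityField(ph$field, pref)
  expect_true(all(file.exists(files)))
  back <- readVelocityField(pref)
  expect_equal(velocities(back), velocities(ph$field), tolerance = 1e-6)
  expect_equal(frameTimes(back), frameTimes(ph$field))
  expect_equal(spacing(back), spacing(ph$field))
  expect_equal(venc(back), venc(ph$field))
})

test_that("alias flags are persisted through the round trip", {
  ph <- generateJetPhantom(aliasedJetConfig())
  unwrapped <- unwrapAliasing(wrapVelocities(ph$field))
  expect_gt(sum(aliasFlags(unwrapped)), 0)
  td <- withr::local_tempdir()
  pref <- file.path(td, "aliased")
  writeVelocityField(unwrapped, pref)
  back <- readVelocityField(pref)
  expect_identical(aliasFlags(back), aliasFlags(unwrapped))
})

test_that("reader rejects mismatched component series and bad metadata", {
  td <- withr::local_tempdir()
  arrA <- array(0, c(4L, 6, 6, 6, 3))
  arrB <- array(0, c(3L, 6, 6, 6, 3))
  fa <- velocityField4D(arrA, spacing = c(2, 2, 2), venc = 150)
  fb <- velocityField4D(arrB, spacing = c(2, 2, 2), venc = 150)
  writeVelocityField(fa, file.path(td, "a"))
  writeVelocityField(fb, file.path(td, "b"))
  mixed <- c(file.path(td, "a_velx.nii.gz"), file.path(td, "a_vely.nii.gz"),
             file.path(td, "b_velz.nii.gz"))
  expect_error(readVelocityField(mixed, file.path(td, "a_meta.json")),
               "mismatched")
  # sidecar with venc = 0 fails validation
  meta <- jsonlite::read_json(file.path(td, "a_meta.json"))
  meta$venc_cms <- 0
  jsonlite::write_json(meta, file.path(td, "bad_meta.json"),
                       auto_unbox = TRUE)
  paths <- file.path(td, paste0("a", c("_velx", "_vely", "_velz"),
                                ".nii.gz"))
  expect_error(readVelocityField(paths, file.path(td, "bad_meta.json")),
               "venc")
  # missing metadata key
  meta$venc_cms <- NULL
  jsonlite::write_json(meta, file.path(td, "nokey_meta.json"),
                       auto_unbox = TRUE)
  expect_error(readVelocityField(paths, file.path(td, "nokey_meta.json")),
               "venc_cms")
})

test_that("containers enforce their invariants", {
  expect_error(velocityField4D(array(0, c(0, 4, 4, 4, 3)),
                               spacing = c(1, 1, 1), venc = 150),
               "at least one frame")
  expect_error(velocityField4D(array(0, c(2, 4, 4, 4, 3)),
                               spacing = c(1, 1, 1), venc = 0), "venc")
  expect_error(velocityField4D(array(0, c(2, 4, 4, 4, 3)),
                               spacing = c(1, -1, 1), venc = 100), "spacing")
  expect_error(flowCurve(c(0, 10, 10), c(1, 2, 3)), "increasing")
  expect_error(volumeCurve(c(0, 10), c(-1, 5)), "nonnegative")
})

test_that("curve CSVs round trip at full printed precision", {
  td <- withr::local_tempdir()
  fc <- flowCurve(c(0, 38.5, 77.123), c(-12.25, 301.5, 0.001))
  readBack <- readFlowCurve(writeFlowCurve(fc, file.path(td, "f.csv")))
  expect_equal(rates(readBack), rates(fc), tolerance = 1e-12)
  expect_equal(curveTimes(readBack), curveTimes(fc), tolerance = 1e-12)
  vc <- volumeCurve(c(0, 40), c(134.2, 41.8))
  vb <- readVolumeCurve(writeVolumeCurve(vc, file.path(td, "v.csv")))
  expect_equal(volumes(vb), volumes(vc), tolerance = 1e-12)
})
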