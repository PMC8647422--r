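# Shared fixtures, built in code. The default noise-free phantom is
# generated once per test run and reused read-only.

phantomNoiseFree <- generateJetPhantom(phantomConfig(noiseSd = 0))

# Two simultaneous, well-separated jets (10 mL and 7 mL).
twoJetConfig <- function(noiseSd = 5, seed = 42L) {
  second <- phantomConfig(orificeCenter = c(75, 70, 22),
                          jetAxis = c(-0.9, -0.2, 1.1),
                          jetDrift = c(-0.1, -0.15, 0), targetVolume = 7)
  phantomConfig(orificeCenter = c(25, 25, 22), jetAxis = c(1, 0.2, 1.1),
                targetVolume = 10, noiseSd = noiseSd, seed = seed,
                secondJet = second)
}

# Narrow smooth jet whose peak core velocity (~180 cm/s) exceeds
# VENC 150, for aliasing wrap/unwrap round trips: the dominant-axis
# orientation makes a single component alias, and the one-voxel-wide
# wrapped core is within the unwrapping algorithm's domain.
aliasedJetConfig <- function() {
  Aeff <- mrjet:::.effectiveArea(7, "gaussian", 2.5)
  V <- 2 * (180 * Aeff / 100) * 0.228 / pi
  phantomConfig(targetVolume = V, coreRadius = 7,
                velocityProfile = "gaussian", noiseSd = 0, jetLength = 45,
                orificeCenter = c(45, 40, 15), jetAxis = c(0.15, 0.1, 1),
                jetDrift = c(0.05, -0.05, 0))
}

# Small uniform-velocity field for plane-sampling checks.
uniformField <- function(v = c(0, 0, 100), n = 12L, spacing = 2) {
  arr <- array(0, c(1L, n, n, n, 3L))
  for (comp in 1:3) arr[1, , , , comp] <- v[comp]
  velocityField4D(arr, spacing = rep(spacing, 3), frameTimes = 19,
                  venc = 150)
}

# Independent brute-force flux oracle: mean through-plane flux of a
# slab of voxels around axial position aMid, in mL/s.
bruteForceFlux <- function(field, truth, frame, aMid, halfWidth = 5) {
  v <- velocities(field)
  d <- dim(v)[2:4]
  sp <- spacing(field)
  P <- cbind(rep((seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3]),
             rep(rep((seq_len(d[2]) - 1) * sp[2], each = d[1]), times = d[3]),
             rep((seq_len(d[3]) - 1) * sp[3], each = d[1] * d[2]))
  ax <- truth@jetAxisPerFrame[frame, ]
  a <- as.vector(sweep(P, 2, truth@orificeCenter) %*% ax)
  slab <- a >= aMid - halfWidth & a <= aMid + halfWidth
  vn <- array(0, d)
  for (comp in 1:3) vn <- vn + array(v[frame, , , , comp], d) * ax[comp]
  # v [cm/s] * 10 -> mm/s; voxel volume / slab thickness -> area; -> mL/s
  sum(vn[slab]) * 10 * prod(sp) / (2 * halfWidth) / 1000
}
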