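# Digital 4D flow jet phantom: an eccentric regurgitant jet with a
# prescribed half-sine orifice flow-rate pulse inside an "atrial" ROI,
# plus matched ventricle/aorta curves for the indirect method.

#' Configure the digital regurgitant-jet phantom
#'
#' Defaults emulate the imaging conditions of a clinical 4D flow
#' protocol (2.5 mm isotropic voxels, 20 frames at 38 ms, VENC
#' 150 cm/s) carrying a mild (16 mL), eccentric, mid-to-late-systolic
#' regurgitant jet whose direction drifts over the regurgitant window.
#' The orifice flow rate is a half-sine over \code{[jetOnset, jetOffset]}
#' scaled so that its analytic integral (\eqn{2 Q_{max} T / \pi}) equals
#' \code{targetVolume}; \code{targetVolume = 0} produces a no-jet
#' (pure-noise) phantom.
#'
#' @param gridShape integer(3) voxels per axis.
#' @param spacing numeric(3) mm.
#' @param nFrames number of timeframes.
#' @param frameSpacing ms between frames (mid-frame times are
#'   \code{(i - 0.5) * frameSpacing}).
#' @param venc velocity-encoding limit, cm/s.
#' @param orificeCenter mm, jet origin.
#' @param jetAxis mean jet direction (normalized internally).
#' @param jetDrift linear axis deviation over the regurgitant window
#'   (the instantaneous axis is \code{unit(jetAxis + s * jetDrift)} with
#'   \code{s} ramping -1..1); set to \code{c(0,0,0)} for a fixed axis.
#' @param jetOnset,jetOffset regurgitant window, ms.
#' @param targetVolume regurgitant volume, mL.
#' @param coreRadius jet core radius, mm.
#' @param jetLength jet core length, mm.
#' @param velocityProfile \code{"tophat"} (flat core with a one-voxel
#'   partial-volume ramp, modelling intra-voxel averaging) or
#'   \code{"gaussian"} (smooth radial profile, sd \code{coreRadius/2}).
#' @param noiseSd additive Gaussian velocity noise sd per component, cm/s.
#' @param secondJet \code{NULL} or another \code{PhantomConfig} whose
#'   jet-geometry fields define a second simultaneous jet.
#' @param seed RNG seed for the noise field.
#' @return a validated [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(targetVolume = 16, noiseSd = 5, seed = 7)
#' @export
phantomConfig <- function(gridShape = c(40L, 40L, 40L),
                          spacing = c(2.5, 2.5, 2.5),
                          nFrames = 20L, frameSpacing = 38,
                          venc = 150,
                          orificeCenter = c(25, 28, 22),
                          jetAxis = c(1, 0.5, 1.1),
                          jetDrift = c(0.15, -0.18, 0.05),
                          jetOnset = 228, jetOffset = 456,
                          targetVolume = 16, coreRadius = 5,
                          jetLength = 50,
                          velocityProfile = c("tophat", "gaussian"),
                          noiseSd = 5, secondJet = NULL, seed = 1L) {
  velocityProfile <- match.arg(velocityProfile)
  new("PhantomConfig", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), nFrames = as.integer(nFrames),
      frameSpacing = as.numeric(frameSpacing), venc = as.numeric(venc),
      orificeCenter = as.numeric(orificeCenter),
      jetAxis = as.numeric(jetAxis), jetDrift = as.numeric(jetDrift),
      jetOnset = as.numeric(jetOnset), jetOffset = as.numeric(jetOffset),
      targetVolume = as.numeric(targetVolume),
      coreRadius = as.numeric(coreRadius), jetLength = as.numeric(jetLength),
      velocityProfile = velocityProfile, noiseSd = as.numeric(noiseSd),
      secondJet = secondJet, seed = as.integer(seed))
}

# Radial profile value at distances rho (mm); f in [0, 1].
.radialProfile <- function(rho, radius, profile, ramp) {
  if (profile == "tophat") {
    pmin(pmax((radius + ramp / 2 - rho) / ramp, 0), 1)
  } else {
    sigma <- radius / 2
    ifelse(rho <= 2.5 * sigma, exp(-rho^2 / (2 * sigma^2)), 0)
  }
}

# Effective cross-section area (mm^2) of the radial profile, by 1-D
# quadrature, so that core velocity can be scaled to carry Q(t) exactly.
.effectiveArea <- function(radius, profile, ramp) {
  rmax <- if (profile == "tophat") radius + ramp else 2.5 * radius / 2
  rho <- seq(0, rmax, length.out = 4000L)
  f <- .radialProfile(rho, radius, profile, ramp)
  .trapz(rho, 2 * pi * rho * f)
}

# Half-sine orifice flow-rate pulse with integral targetVolume (mL);
# t in ms, Q in mL/s.
.halfSineQ <- function(t, onset, offset, targetVolume) {
  Tsec <- (offset - onset) / 1000
  qmax <- pi * targetVolume / (2 * Tsec)
  ifelse(t > onset & t < offset,
         qmax * sin(pi * (t - onset) / (offset - onset)), 0)
}

# Instantaneous jet axis at frame time t (drift ramps -1..1 over the window).
.jetAxisAt <- function(cfg, t) {
  s <- if (cfg@jetOffset > cfg@jetOnset)
    2 * (t - (cfg@jetOnset + cfg@jetOffset) / 2) / (cfg@jetOffset - cfg@jetOnset)
  else 0
  .unitize(cfg@jetAxis + pmin(pmax(s, -1), 1) * cfg@jetDrift)
}

# Truth record for one jet of a config (no noise, no field).
.jetTruth <- function(cfg, frameTimesMs) {
  active <- which(frameTimesMs > cfg@jetOnset & frameTimesMs < cfg@jetOffset)
  tFine <- seq(cfg@jetOnset, cfg@jetOffset, length.out = 501L)
  axes <- t(vapply(frameTimesMs, function(t) .jetAxisAt(cfg, t), numeric(3)))
  list(trueVolume = cfg@targetVolume,
       trueFlowCurve = flowCurve(tFine,
         .halfSineQ(tFine, cfg@jetOnset, cfg@jetOffset, cfg@targetVolume)),
       orificeCenter = cfg@orificeCenter,
       axisPerFrame = axes,
       activeFrames = as.integer(active))
}

#' Generate a digital 4D flow phantom with a known regurgitant jet
#'
#' Builds a velocity field whose jet core carries, at every active
#' frame, a cross-sectional flux equal to the half-sine orifice flow
#' rate Q(t), with zero mean velocity plus Gaussian noise elsewhere.
#' Core velocities are scaled by the numerically computed effective
#' cross-section area of the radial profile so the discrete flux tracks
#' Q(t). Deterministic given \code{config@seed}.
#'
#' @param config a [PhantomConfig-class].
#' @return a list with elements \code{field} ([VelocityField4D-class])
#'   and \code{truth} ([PhantomTruth-class]).
#' @examples
#' ph <- generateJetPhantom(phantomConfig(noiseSd = 0))
#' trueVolume(ph$truth)
#' @export
generateJetPhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  d <- config@gridShape
  sp <- config@spacing
  nt <- config@nFrames
  ft <- (seq_len(nt) - 0.5) * config@frameSpacing
  extent <- (d - 1L) * sp

  jetCfgs <- list(config)
  if (!is.null(config@secondJet)) jetCfgs <- c(jetCfgs, list(config@secondJet))
  jetCfgs <- Filter(function(cf) cf@targetVolume > 0, jetCfgs)

  # voxel centres in physical mm (0-based index convention)
  P <- cbind(rep((seq_len(d[1L]) - 1) * sp[1L], times = d[2L] * d[3L]),
             rep(rep((seq_len(d[2L]) - 1) * sp[2L], each = d[1L]), times = d[3L]),
             rep((seq_len(d[3L]) - 1) * sp[3L], each = d[1L] * d[2L]))

  vel <- array(0, c(nt, d, 3L))
  ramp <- mean(sp)
  perJet <- list()
  coreUnion <- array(FALSE, d)

  for (cf in jetCfgs) {
    tr <- .jetTruth(cf, ft)
    Aeff <- .effectiveArea(cf@coreRadius, cf@velocityProfile, ramp)
    jetCore <- array(FALSE, d)
    for (fr in tr$activeFrames) {
      ax <- tr$axisPerFrame[fr, ]
      # cylinder must stay inside the voxel-centre hull
      ends <- rbind(cf@orificeCenter, cf@orificeCenter + cf@jetLength * ax)
      if (any(apply(ends, 2L, min) - cf@coreRadius < -1e-6) ||
          any(apply(ends, 2L, max) + cf@coreRadius > extent + 1e-6))
        stop("jet exits grid bounds; shrink jetLength or move orificeCenter")
      rel <- sweep(P, 2L, cf@orificeCenter)
      a <- as.vector(rel %*% ax)
      inAxial <- a >= 0 & a <= cf@jetLength
      rho2 <- rowSums(rel^2) - a^2
      rmax <- if (cf@velocityProfile == "tophat") cf@coreRadius + ramp
              else 1.25 * cf@coreRadius
      cand <- which(inAxial & rho2 <= rmax^2)
      if (!length(cand)) next
      f <- .radialProfile(sqrt(pmax(rho2[cand], 0)), cf@coreRadius,
                          cf@velocityProfile, ramp)
      q <- .halfSineQ(ft[fr], cf@jetOnset, cf@jetOffset, cf@targetVolume)
      v0 <- 100 * q / Aeff                       # cm/s carrying Q exactly
      co <- arrayInd(cand, d)
      for (comp in 1:3) {
        lin <- cbind(fr, co, comp)
        vel[lin] <- vel[lin] + v0 * f * ax[comp]
      }
      jetCore[cand[f > 0.5]] <- TRUE
    }
    tr$coreMask <- jetCore
    coreUnion <- coreUnion | jetCore
    perJet <- c(perJet, list(tr))
  }

  # atrial ROI: union of spheres enclosing each jet (with margin);
  # static tissue: bottom slab of the grid, minus the ROI
  roi <- array(FALSE, d)
  if (length(perJet)) {
    for (i in seq_along(perJet)) {
      cf <- jetCfgs[[i]]
      ctr <- cf@orificeCenter + .unitize(cf@jetAxis) * cf@jetLength / 2
      rad <- cf@jetLength / 2 + cf@coreRadius + 10
      roi <- roi | array(rowSums(sweep(P, 2L, ctr)^2) <= rad^2, d)
    }
    if (any(coreUnion & !roi))
      stop("internal error: atrial ROI does not cover the jet core")
  } else {
    ctr <- extent / 2
    roi <- array(rowSums(sweep(P, 2L, ctr)^2) <= (min(extent) / 2.5)^2, d)
  }
  static <- array(FALSE, d)
  static[, , 1:2] <- TRUE
  static <- static & !roi

  # seeded noise, restoring the caller's RNG state
  if (config@noiseSd > 0) {
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
    }, add = TRUE)
    set.seed(config@seed)
    vel <- vel + array(stats::rnorm(length(vel), sd = config@noiseSd), dim(vel))
  }

  field <- velocityField4D(vel, spacing = sp, frameTimes = ft,
                           venc = config@venc)

  # combined true flow curve over the union of all jets' fine grids
  if (length(perJet)) {
    tAll <- sort(unique(unlist(lapply(perJet, function(tr) tr$trueFlowCurve@times))))
    qAll <- rowSums(vapply(seq_along(perJet), function(i) {
      cf <- jetCfgs[[i]]
      .halfSineQ(tAll, cf@jetOnset, cf@jetOffset, cf@targetVolume)
    }, numeric(length(tAll))))
    totalCurve <- flowCurve(tAll, qAll)
    totalVol <- sum(vapply(perJet, function(tr) tr$trueVolume, numeric(1)))
    axes <- perJet[[1L]]$axisPerFrame
    orifice <- perJet[[1L]]$orificeCenter
    activeFrames <- sort(unique(unlist(lapply(perJet, `[[`, "activeFrames"))))
  } else {
    totalCurve <- flowCurve(ft, rep(0, nt))
    totalVol <- 0
    axes <- matrix(0, nt, 3L)
    orifice <- rep(NA_real_, 3L)
    activeFrames <- integer()
  }

  truth <- new("PhantomTruth", trueFlowCurve = totalCurve,
               trueVolume = totalVol, jetAxisPerFrame = axes,
               orificeCenter = orifice, atrialROI = roi,
               staticMask = static, activeFrames = as.integer(activeFrames),
               coreMask = coreUnion, perJet = perJet, seed = config@seed)
  list(field = field, truth = truth)
}

#' Apply velocity-encoding (VENC) wrapping to a field
#'
#' Simulates phase-wrap aliasing: each component v is replaced by
#' \code{((v + venc) mod 2 venc) - venc}, so the output lies in
#' \code{[-venc, venc)}. Velocities already below VENC are unchanged.
#'
#' @param field a [VelocityField4D-class].
#' @return a wrapped [VelocityField4D-class] (alias flags cleared: a
#'   freshly wrapped field carries no unwrapping record).
#' @seealso [unwrapAliasing()]
#' @export
wrapVelocities <- function(field) {
  stopifnot(is(field, "VelocityField4D"))
  v <- field@velocities
  w <- ((v + field@venc) %% (2 * field@venc)) - field@venc
  velocityField4D(w, spacing = field@spacing, frameTimes = field@frameTimes,
                  venc = field@venc, affine = field@affine)
}

#' Ventricle/aorta curves consistent with a phantom's jet truth
#'
#' Constructs a left-ventricular volume curve and an aortic flow-rate
#' curve such that, by construction, LV stroke volume (EDV - ESV)
#' equals the aortic forward volume plus the phantom's true regurgitant
#' volume - the closed-loop input for the indirect volumetric method.
#' The sampled aortic curve is rescaled so that its positive-part
#' trapezoidal integral equals \code{forwardVolume} exactly.
#'
#' @param truth a [PhantomTruth-class].
#' @param forwardVolume aortic forward volume, mL (> 0).
#' @param edv end-diastolic volume, mL.
#' @param nFrames frames in the LV volume curve.
#' @param cycleLength cardiac cycle length, ms.
#' @return list with \code{volumeCurve} ([VolumeCurve-class]) and
#'   \code{flowCurve} ([FlowCurve-class]).
#' @export
generateIndirectInputs <- function(truth, forwardVolume = 70, edv = 134,
                                   nFrames = 30L, cycleLength = 760) {
  stopifnot(is(truth, "PhantomTruth"))
  if (forwardVolume <= 0) stop("forwardVolume must be positive")
  sv <- forwardVolume + truth@trueVolume
  esv <- edv - sv
  if (esv < 0) stop("edv too small for the requested stroke volume")
  tes <- 0.55 * cycleLength
  tlv <- seq(0, cycleLength, length.out = nFrames)
  raw <- ifelse(tlv <= tes,
                (1 + cos(pi * tlv / tes)) / 2,
                (1 - cos(pi * (tlv - tes) / (cycleLength - tes))) / 2)
  # rescale so the sampled extrema hit EDV/ESV exactly
  raw <- (raw - min(raw)) / (max(raw) - min(raw))
  lv <- volumeCurve(tlv, esv + raw * (edv - esv))

  tao <- seq(0, cycleLength, by = 10)
  sysOn <- 40; sysOff <- 0.55 * cycleLength
  r <- ifelse(tao > sysOn & tao < sysOff,
              sin(pi * (tao - sysOn) / (sysOff - sysOn)), 0)
  # small early-diastolic backflow lobe (excluded by positive-part integration)
  dias <- tao >= sysOff & tao <= sysOff + 60
  r[dias] <- -0.04 * sin(pi * (tao[dias] - sysOff) / 60)
  posInt <- .trapz(tao, pmax(r, 0)) / 1000
  ao <- flowCurve(tao, r * forwardVolume / posInt)
  list(volumeCurve = lv, flowCurve = ao)
}
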