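#' @import methods
NULL

#' VelocityField4D: time-resolved three-directional velocity field
#'
#' Container for 4D flow CMR velocity data: a five-axis array with
#' dimensions (time, x, y, z, component), velocities in cm/s, voxel
#' spacing in mm, mid-frame times in ms, and the velocity-encoding limit
#' (VENC) in cm/s. An optional logical array of the same (time, x, y, z)
#' extent flags voxels whose value was changed by aliasing unwrapping.
#'
#' @slot velocities five-axis numeric array (time, x, y, z, component), cm/s.
#' @slot spacing numeric(3), voxel size per spatial axis in mm.
#' @slot frameTimes numeric, strictly increasing mid-frame times in ms.
#' @slot venc numeric(1), velocity-encoding limit in cm/s.
#' @slot aliasFlags \code{NULL} or logical array (time, x, y, z).
#' @slot affine 4x4 voxel-index (0-based) to physical-mm mapping.
#'
#' @seealso [velocityField4D()], [readVelocityField()], [generateJetPhantom()]
#' @export
setClass("VelocityField4D",
  representation(velocities = "array", spacing = "numeric",
                 frameTimes = "numeric", venc = "numeric",
                 aliasFlags = "ANY", affine = "matrix"))

setValidity("VelocityField4D", function(object) {
  msg <- character()
  d <- dim(object@velocities)
  if (length(d) != 5L || d[5L] != 3L)
    msg <- c(msg, "velocities must be a 5-axis array (time, x, y, z, component=3)")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive values (mm)")
  if (length(d) == 5L && length(object@frameTimes) != d[1L])
    msg <- c(msg, "length(frameTimes) must equal the time extent")
  if (length(object@frameTimes) > 1L && any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (length(object@venc) != 1L || !is.finite(object@venc) || object@venc <= 0)
    msg <- c(msg, "venc must be a single positive value (cm/s)")
  if (!is.null(object@aliasFlags)) {
    if (!is.logical(object@aliasFlags) ||
        !identical(dim(object@aliasFlags), d[1:4]))
      msg <- c(msg, "aliasFlags must be a logical array with dims (time, x, y, z)")
  }
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' FlowCurve: a time-resolved flow-rate curve
#'
#' Signed flow rate in mL/s over time (ms). Positive means forward
#' (antegrade) flow in the curve's declared direction convention; for a
#' regurgitant curve positive means regurgitant flow.
#'
#' @slot times numeric, strictly increasing, ms.
#' @slot rates numeric, mL/s, same length as \code{times}.
#' @export
setClass("FlowCurve", representation(times = "numeric", rates = "numeric"))

setValidity("FlowCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@rates))
    msg <- c(msg, "times and rates must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' VolumeCurve: left-ventricular cavity volume over time
#'
#' @slot times numeric, strictly increasing, ms.
#' @slot volumes numeric, nonnegative cavity volumes in mL.
#' @export
setClass("VolumeCurve", representation(times = "numeric", volumes = "numeric"))

setValidity("VolumeCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@volumes))
    msg <- c(msg, "times and volumes must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@volumes < 0))
    msg <- c(msg, "volumes must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' MPRPlane: an oblique multiplanar-reformat plane
#'
#' A finite oblique plane raster placed at the jet's peak-velocity
#' landmark and oriented perpendicular to the jet, i.e. with its normal
#' along the jet flow so that regurgitant flow is positive through-plane.
#'
#' @slot origin numeric(3), plane centre in physical mm.
#' @slot normal numeric(3), unit through-plane direction.
#' @slot inPlaneU,inPlaneV numeric(3), unit in-plane axes;
#'   \code{u x v = normal} (right-handed).
#' @slot extent numeric(1), side length of the square raster in mm.
#' @slot pixelSpacing numeric(1), raster pixel size in mm.
#' @export
setClass("MPRPlane",
  representation(origin = "numeric", normal = "numeric",
                 inPlaneU = "numeric", inPlaneV = "numeric",
                 extent = "numeric", pixelSpacing = "numeric"))

setValidity("MPRPlane", function(object) {
  msg <- character()
  for (s in c("origin", "normal", "inPlaneU", "inPlaneV"))
    if (length(slot(object, s)) != 3L)
      msg <- c(msg, sprintf("%s must have length 3", s))
  if (!length(msg)) {
    B <- rbind(object@inPlaneU, object@inPlaneV, object@normal)
    if (max(abs(B %*% t(B) - diag(3))) > 1e-8)
      msg <- c(msg, "{u, v, normal} must be orthonormal")
    else if (max(abs(.cross3(object@inPlaneU, object@inPlaneV) - object@normal)) > 1e-8)
      msg <- c(msg, "{u, v, normal} must be right-handed (u x v = normal)")
  }
  npix <- object@extent / object@pixelSpacing
  if (abs(npix - round(npix)) > 1e-8)
    msg <- c(msg, "extent must be an integer multiple of pixelSpacing")
  if (length(msg)) msg else TRUE
})

#' PlaneSample: a reformatted through-plane velocity raster
#'
#' @slot throughPlane numeric matrix, through-plane velocity (cm/s);
#'   the interpolated velocity projected onto the plane normal.
#' @slot jetMask logical matrix, segmented jet cross-section.
#' @slot outOfBounds logical matrix, pixels outside the imaged volume.
#' @slot pixelArea numeric(1), pixel area in mm^2.
#' @slot frameIndex integer(1), source timeframe.
#' @export
setClass("PlaneSample",
  representation(throughPlane = "matrix", jetMask = "matrix",
                 outOfBounds = "matrix", pixelArea = "numeric",
                 frameIndex = "integer"))

setValidity("PlaneSample", function(object) {
  msg <- character()
  if (!identical(dim(object@jetMask), dim(object@throughPlane)) ||
      !identical(dim(object@outOfBounds), dim(object@throughPlane)))
    msg <- c(msg, "masks must have the same shape as the velocity raster")
  if (any(object@jetMask & object@outOfBounds))
    msg <- c(msg, "jetMask must exclude out-of-bounds pixels")
  if (object@pixelArea <= 0)
    msg <- c(msg, "pixelArea must be positive")
  if (length(msg)) msg else TRUE
})

#' JetTrackResult: direct jet-tracking quantification result
#'
#' Per-jet frame-by-frame tracking output and integrated regurgitant
#' volumes. Each element of \code{jets} is a list with a per-frame
#' data.frame (\code{frame}, \code{time}, \code{peakX/Y/Z},
#' \code{peakSpeed}, \code{flowRate}), the jet's MPR planes, its
#' integrated volume and its start/end frames.
#'
#' @slot jets list of per-jet tracking records.
#' @slot perJetVolumes numeric, integrated volume per jet, mL.
#' @slot totalVolume numeric(1), total MR volume in mL (sum over jets).
#' @slot mrStartFrame,mrEndFrame integer(1), first/last frame with MR
#'   (NA when no jet).
#' @slot mrDurationFrames integer(1), \code{end - start + 1} (0 when no jet).
#' @slot nJets integer(1).
#' @export
setClass("JetTrackResult",
  representation(jets = "list", perJetVolumes = "numeric",
                 totalVolume = "numeric",
                 mrStartFrame = "integer", mrEndFrame = "integer",
                 mrDurationFrames = "integer", nJets = "integer"))

setValidity("JetTrackResult", function(object) {
  msg <- character()
  if (length(object@perJetVolumes) != object@nJets)
    msg <- c(msg, "perJetVolumes must have one entry per jet")
  if (abs(object@totalVolume - sum(object@perJetVolumes)) > 1e-9)
    msg <- c(msg, "totalVolume must equal the sum of per-jet volumes")
  if (object@totalVolume < 0)
    msg <- c(msg, "totalVolume must be nonnegative")
  if (object@nJets == 0L) {
    if (object@totalVolume != 0)
      msg <- c(msg, "zero jets implies zero total volume")
    if (object@mrDurationFrames != 0L)
      msg <- c(msg, "zero jets implies zero MR duration")
  } else if (!is.na(object@mrStartFrame) && !is.na(object@mrEndFrame) &&
             object@mrDurationFrames !=
               object@mrEndFrame - object@mrStartFrame + 1L) {
    msg <- c(msg, "mrDurationFrames must equal end - start + 1")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomConfig: configuration of the digital regurgitant-jet phantom
#'
#' Defaults emulate a mild, eccentric, mid-to-late-systolic mitral
#' regurgitation jet on a clinical 4D flow protocol: 2.5 mm isotropic
#' voxels, 20 frames at 38 ms temporal resolution, VENC 150 cm/s, and a
#' 16 mL regurgitant volume delivered as a half-sine orifice flow pulse
#' between 228 and 456 ms.
#'
#' @slot gridShape integer(3), voxels per spatial axis.
#' @slot spacing numeric(3), mm.
#' @slot nFrames integer(1); \code{frameSpacing} numeric(1), ms.
#' @slot frameSpacing numeric(1), ms between frames.
#' @slot venc numeric(1), cm/s.
#' @slot orificeCenter numeric(3), mm; jet origin.
#' @slot jetAxis numeric(3), mean jet direction (normalized internally).
#' @slot jetDrift numeric(3), linear per-frame deviation added to the
#'   axis over the regurgitant window (models a direction-varying jet);
#'   zero for a fixed axis.
#' @slot jetOnset,jetOffset numeric(1), ms; regurgitant window.
#' @slot targetVolume numeric(1), mL; total regurgitant volume (0 = no jet).
#' @slot coreRadius numeric(1), mm; jet core radius.
#' @slot jetLength numeric(1), mm.
#' @slot velocityProfile "tophat" or "gaussian" radial profile.
#' @slot noiseSd numeric(1), additive Gaussian velocity noise sd, cm/s.
#' @slot secondJet \code{NULL} or a nested \code{PhantomConfig} whose
#'   jet-geometry fields define a second simultaneous jet.
#' @slot seed integer(1), RNG seed for the noise field.
#' @export
setClass("PhantomConfig",
  representation(gridShape = "integer", spacing = "numeric",
                 nFrames = "integer", frameSpacing = "numeric",
                 venc = "numeric", orificeCenter = "numeric",
                 jetAxis = "numeric", jetDrift = "numeric",
                 jetOnset = "numeric", jetOffset = "numeric",
                 targetVolume = "numeric", coreRadius = "numeric",
                 jetLength = "numeric", velocityProfile = "character",
                 noiseSd = "numeric", secondJet = "ANY", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@jetOffset <= object@jetOnset)
    msg <- c(msg, "jetOffset must exceed jetOnset")
  if (object@targetVolume < 0)
    msg <- c(msg, "targetVolume must be nonnegative")
  if (object@targetVolume > 0 &&
      2 * object@coreRadius < 3 * max(object@spacing))
    msg <- c(msg, "jet core diameter must span at least 3 voxels")
  if (!object@velocityProfile %in% c("tophat", "gaussian"))
    msg <- c(msg, "velocityProfile must be 'tophat' or 'gaussian'")
  if (object@venc <= 0) msg <- c(msg, "venc must be positive")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (!is.null(object@secondJet) && !is(object@secondJet, "PhantomConfig"))
    msg <- c(msg, "secondJet must be NULL or a PhantomConfig")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth of a simulated jet phantom
#'
#' @slot trueFlowCurve [FlowCurve-class], finely sampled total orifice
#'   flow rate Q(t).
#' @slot trueVolume numeric(1), mL; analytic integral of Q(t).
#' @slot jetAxisPerFrame numeric matrix (frames x 3), main-jet axis.
#' @slot orificeCenter numeric(3), mm, main jet.
#' @slot atrialROI logical 3-D array, atrial search region.
#' @slot staticMask logical 3-D array, static-tissue region (disjoint
#'   from the atrial ROI).
#' @slot activeFrames integer, frames with nonzero regurgitant flow.
#' @slot coreMask logical 3-D array, union over frames of the jet core.
#' @slot perJet list, one entry per jet with its own truth
#'   (\code{trueVolume}, \code{trueFlowCurve}, \code{orificeCenter},
#'   \code{axisPerFrame}, \code{activeFrames}, \code{coreMask}).
#' @slot seed integer(1).
#' @export
setClass("PhantomTruth",
  representation(trueFlowCurve = "FlowCurve", trueVolume = "numeric",
                 jetAxisPerFrame = "matrix", orificeCenter = "numeric",
                 atrialROI = "array", staticMask = "array",
                 activeFrames = "integer", coreMask = "array",
                 perJet = "list", seed = "integer"))

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (any(object@atrialROI & object@staticMask))
    msg <- c(msg, "atrial ROI and static mask must be disjoint")
  if (length(object@trueFlowCurve@times) >= 2L) {
    integ <- .trapz(object@trueFlowCurve@times, object@trueFlowCurve@rates) / 1000
    if (object@trueVolume > 0 &&
        abs(integ - object@trueVolume) > 1e-3 * object@trueVolume)
      msg <- c(msg, "trueVolume must match the integral of trueFlowCurve within 0.1%")
  }
  if (length(msg)) msg else TRUE
})

#' CardiacVolumes: indirect volumetric measurements
#'
#' Left-ventricular volumetric indices and the indirect MR volume
#' (stroke volume minus aortic forward flow). Optional BSA indexing by
#' the Mosteller formula.
#'
#' @slot edv,esv,sv numeric(1), mL; \code{sv = edv - esv}.
#' @slot ef numeric(1), percent.
#' @slot aorticForward numeric(1), mL (NA until supplied).
#' @slot mrVolumeIndirect numeric(1), mL (may be negative; see
#'   [indirectMRVolume()]).
#' @slot bsa numeric(1), m^2 (optional).
#' @slot indexed named numeric, BSA-indexed variants in mL/m^2 (optional).
#' @export
setClass("CardiacVolumes",
  representation(edv = "numeric", esv = "numeric", sv = "numeric",
                 ef = "numeric", aorticForward = "numeric",
                 mrVolumeIndirect = "numeric", bsa = "numeric",
                 indexed = "numeric"))

setValidity("CardiacVolumes", function(object) {
  msg <- character()
  if (is.finite(object@edv) && is.finite(object@esv)) {
    if (abs(object@sv - (object@edv - object@esv)) > 1e-9)
      msg <- c(msg, "sv must equal edv - esv")
    if (is.finite(object@ef) &&
        (object@ef < 0 || object@ef > 100 ||
         (object@edv > 0 && abs(object@ef - 100 * object@sv / object@edv) > 1e-6)))
      msg <- c(msg, "ef must equal 100*sv/edv and lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' PairedMeasurements: paired values (and grades) for agreement analysis
#'
#' @slot id character, subject identifiers.
#' @slot valuesA,valuesB numeric, paired measurements in the same units.
#' @slot labelsA,labelsB character, optional severity grades.
#' @export
setClass("PairedMeasurements",
  representation(id = "character", valuesA = "numeric", valuesB = "numeric",
                 labelsA = "character", labelsB = "character"))

setValidity("PairedMeasurements", function(object) {
  msg <- character()
  n <- length(object@valuesA)
  if (length(object@valuesB) != n)
    msg <- c(msg, "valuesA and valuesB must have equal length")
  if (length(object@id) && length(object@id) != n)
    msg <- c(msg, "id must match the number of pairs")
  if (length(object@labelsA) && length(object@labelsA) != n)
    msg <- c(msg, "labelsA must match the number of pairs")
  if (length(object@labelsB) && length(object@labelsB) != n)
    msg <- c(msg, "labelsB must match the number of pairs")
  if (length(msg)) msg else TRUE
})

#' AgreementResult: agreement-statistics battery output
#'
#' Holds ICC(2,1) with its F-test p-value, Bland-Altman bias and limits
#' of agreement, Cohen's kappa with observed/expected agreement and its
#' large-sample p-value, the paired Wilcoxon signed-rank p-value, and
#' interpretation labels. The paired-difference direction is fixed as
#' (first argument minus second) and recorded in \code{direction}.
#'
#' @slot icc,iccP,bias,loaLow,loaHigh,kappa,kappaP,pObserved,pExpected,wilcoxonP
#'   numeric(1); NA where a statistic was not requested/applicable.
#' @slot iccLabel,kappaLabel character(1) interpretation bands.
#' @slot direction character(1), "a-b".
#' @slot n integer(1), number of pairs.
#' @export
setClass("AgreementResult",
  representation(icc = "numeric", iccP = "numeric",
                 bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
                 kappa = "numeric", kappaP = "numeric",
                 pObserved = "numeric", pExpected = "numeric",
                 wilcoxonP = "numeric", iccLabel = "character",
                 kappaLabel = "character", direction = "character",
                 n = "integer"))

setValidity("AgreementResult", function(object) {
  msg <- character()
  if (all(is.finite(c(object@loaLow, object@bias, object@loaHigh))) &&
      !(object@loaLow <= object@bias && object@bias <= object@loaHigh))
    msg <- c(msg, "limits of agreement must bracket the bias")
  if (is.finite(object@kappa) && abs(object@kappa) > 1 + 1e-12)
    msg <- c(msg, "kappa must lie in [-1, 1]")
  if (is.finite(object@icc) && abs(object@icc) > 1 + 1e-12)
    msg <- c(msg, "icc must lie in [-1, 1]")
  for (s in c("pObserved", "pExpected"))
    if (is.finite(slot(object, s)) &&
        (slot(object, s) < 0 || slot(object, s) > 1))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  if (length(msg)) msg else TRUE
})
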