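# Constructors, accessors and show methods for the core containers.

#' Construct a VelocityField4D
#'
#' @param velocities 5-axis numeric array (time, x, y, z, component) in cm/s.
#' @param spacing numeric(3) voxel size in mm.
#' @param frameTimes strictly increasing mid-frame times in ms; defaults
#'   to \code{(1:nt - 0.5) * 38} ms.
#' @param venc velocity-encoding limit in cm/s.
#' @param aliasFlags optional logical array (time, x, y, z).
#' @param affine optional 4x4 voxel-to-mm matrix; defaults to
#'   \code{diag(c(spacing, 1))} with origin 0.
#' @return a validated [VelocityField4D-class].
#' @examples
#' v <- array(0, c(2, 4, 4, 4, 3))
#' f <- velocityField4D(v, spacing = c(2.5, 2.5, 2.5), venc = 150)
#' nFrames(f)
#' @export
velocityField4D <- function(velocities, spacing, frameTimes = NULL,
                            venc, aliasFlags = NULL, affine = NULL) {
  d <- dim(velocities)
  if (length(d) != 5L)
    stop("velocities must be a 5-axis array (time, x, y, z, component)")
  if (d[1L] == 0L) stop("velocity field must contain at least one frame")
  if (is.null(frameTimes)) frameTimes <- (seq_len(d[1L]) - 0.5) * 38
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  new("VelocityField4D", velocities = velocities, spacing = as.numeric(spacing),
      frameTimes = as.numeric(frameTimes), venc = as.numeric(venc),
      aliasFlags = aliasFlags, affine = affine)
}

#' @rdname FlowCurve-class
#' @param times ms, strictly increasing.
#' @param rates mL/s, signed.
#' @export
flowCurve <- function(times, rates)
  new("FlowCurve", times = as.numeric(times), rates = as.numeric(rates))

#' @rdname VolumeCurve-class
#' @param times ms, strictly increasing.
#' @param volumes mL, nonnegative.
#' @export
volumeCurve <- function(times, volumes)
  new("VolumeCurve", times = as.numeric(times), volumes = as.numeric(volumes))

#' @rdname PairedMeasurements-class
#' @param valuesA,valuesB paired numeric measurements.
#' @param id optional subject identifiers.
#' @param labelsA,labelsB optional severity grades.
#' @export
pairedMeasurements <- function(valuesA, valuesB, id = character(),
                               labelsA = character(), labelsB = character()) {
  new("PairedMeasurements", id = as.character(id),
      valuesA = as.numeric(valuesA), valuesB = as.numeric(valuesB),
      labelsA = as.character(labelsA), labelsB = as.character(labelsB))
}

#' @rdname VelocityField4D-class
#' @export
setMethod("velocities", "VelocityField4D", function(x) x@velocities)
#' @rdname VelocityField4D-class
#' @export
setMethod("spacing", "VelocityField4D", function(x) x@spacing)
#' @rdname VelocityField4D-class
#' @export
setMethod("frameTimes", "VelocityField4D", function(x) x@frameTimes)
#' @rdname VelocityField4D-class
#' @export
setMethod("venc", "VelocityField4D", function(x) x@venc)
#' @rdname VelocityField4D-class
#' @export
setMethod("aliasFlags", "VelocityField4D", function(x) x@aliasFlags)
#' @rdname VelocityField4D-class
#' @export
setMethod("nFrames", "VelocityField4D", function(x) dim(x@velocities)[1L])

#' @rdname FlowCurve-class
#' @export
setMethod("curveTimes", "FlowCurve", function(x) x@times)
#' @rdname FlowCurve-class
#' @export
setMethod("rates", "FlowCurve", function(x) x@rates)
#' @rdname VolumeCurve-class
#' @export
setMethod("curveTimes", "VolumeCurve", function(x) x@times)
#' @rdname VolumeCurve-class
#' @export
setMethod("volumes", "VolumeCurve", function(x) x@volumes)

#' @rdname JetTrackResult-class
#' @export
setMethod("totalMRVolume", "JetTrackResult", function(x) x@totalVolume)
#' @rdname JetTrackResult-class
#' @export
setMethod("perJetVolumes", "JetTrackResult", function(x) x@perJetVolumes)
#' @rdname JetTrackResult-class
#' @export
setMethod("nJets", "JetTrackResult", function(x) x@nJets)
#' @rdname JetTrackResult-class
#' @export
setMethod("jets", "JetTrackResult", function(x) x@jets)
#' @rdname JetTrackResult-class
#' @export
setMethod("mrTiming", "JetTrackResult", function(x)
  c(start = x@mrStartFrame, end = x@mrEndFrame,
    duration = x@mrDurationFrames))

#' @rdname PhantomTruth-class
#' @export
setMethod("trueVolume", "PhantomTruth", function(x) x@trueVolume)
#' @rdname PhantomTruth-class
#' @export
setMethod("trueFlowCurve", "PhantomTruth", function(x) x@trueFlowCurve)
#' @rdname PhantomTruth-class
#' @export
setMethod("atrialROI", "PhantomTruth", function(x) x@atrialROI)
#' @rdname PhantomTruth-class
#' @export
setMethod("staticMask", "PhantomTruth", function(x) x@staticMask)

setMethod("show", "VelocityField4D", function(object) {
  d <- dim(object@velocities)
  cat("VelocityField4D:", d[1L], "frames,",
      paste(d[2:4], collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(signif(object@spacing, 4), collapse = " x "),
      " VENC:", object@venc, "cm/s\n")
  cat("  frame times (ms):", signif(object@frameTimes[1L], 4), "...",
      signif(object@frameTimes[d[1L]], 4), "\n")
  if (!is.null(object@aliasFlags))
    cat("  alias flags set on", sum(object@aliasFlags), "voxel-frames\n")
})

setMethod("show", "JetTrackResult", function(object) {
  cat("JetTrackResult:", object@nJets, "jet(s), total MR volume",
      sprintf("%.2f mL\n", object@totalVolume))
  if (object@nJets > 0L) {
    cat("  per-jet volumes (mL):",
        paste(sprintf("%.2f", object@perJetVolumes), collapse = ", "), "\n")
    cat("  MR frames:", object@mrStartFrame, "-", object@mrEndFrame,
        sprintf("(%d frames)\n", object@mrDurationFrames))
  }
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth:", length(object@perJet), "jet(s), true volume",
      sprintf("%.2f mL\n", object@trueVolume))
  if (length(object@activeFrames))
    cat("  active frames:", min(object@activeFrames), "-",
        max(object@activeFrames), "\n")
})

setMethod("show", "CardiacVolumes", function(object) {
  cat(sprintf("CardiacVolumes: EDV %.1f, ESV %.1f, SV %.1f mL, EF %.1f%%\n",
              object@edv, object@esv, object@sv, object@ef))
  if (is.finite(object@aorticForward))
    cat(sprintf("  aortic forward %.1f mL, indirect MR volume %.1f mL\n",
                object@aorticForward, object@mrVolumeIndirect))
  if (is.finite(object@bsa))
    cat(sprintf("  BSA %.2f m^2\n", object@bsa))
})

setMethod("show", "AgreementResult", function(object) {
  cat("AgreementResult (difference direction", object@direction,
      "; n =", object@n, ")\n")
  if (is.finite(object@icc))
    cat(sprintf("  ICC(2,1) %.3f (%s), p = %.4g\n",
                object@icc, object@iccLabel, object@iccP))
  if (is.finite(object@bias))
    cat(sprintf("  Bland-Altman bias %.2f, LOA [%.2f, %.2f]\n",
                object@bias, object@loaLow, object@loaHigh))
  if (is.finite(object@kappa))
    cat(sprintf("  Cohen's kappa %.3f (%s), p = %.4g\n",
                object@kappa, object@kappaLabel, object@kappaP))
  if (is.finite(object@wilcoxonP))
    cat(sprintf("  Wilcoxon signed-rank p = %.4g\n", object@wilcoxonP))
})
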