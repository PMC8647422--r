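#' @rdname VelocityField4D-class
#' @param object,x an object.
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("venc", function(x) standardGeneric("venc"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("aliasFlags", function(x) standardGeneric("aliasFlags"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FlowCurve-class
#' @param x an object.
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))

#' @rdname FlowCurve-class
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname VolumeCurve-class
#' @param x an object.
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname JetTrackResult-class
#' @param x an object.
#' @export
setGeneric("totalMRVolume", function(x) standardGeneric("totalMRVolume"))

#' @rdname JetTrackResult-class
#' @export
setGeneric("perJetVolumes", function(x) standardGeneric("perJetVolumes"))

#' @rdname JetTrackResult-class
#' @export
setGeneric("nJets", function(x) standardGeneric("nJets"))

#' @rdname JetTrackResult-class
#' @export
setGeneric("jets", function(x) standardGeneric("jets"))

#' @rdname JetTrackResult-class
#' @export
setGeneric("mrTiming", function(x) standardGeneric("mrTiming"))

#' @rdname PhantomTruth-class
#' @param x an object.
#' @export
setGeneric("trueVolume", function(x) standardGeneric("trueVolume"))

#' @rdname PhantomTruth-class
#' @export
setGeneric("trueFlowCurve", function(x) standardGeneric("trueFlowCurve"))

#' @rdname PhantomTruth-class
#' @export
setGeneric("atrialROI", function(x) standardGeneric("atrialROI"))

#' @rdname PhantomTruth-class
#' @export
setGeneric("staticMask", function(x) standardGeneric("staticMask"))

#' Background offset correction (eddy currents / baseline)
#'
#' For a [VelocityField4D-class], fits a spatial polynomial (default
#' first order: offset plus linear trend per axis) to each frame and
#' component over static-tissue voxels and subtracts the fitted surface
#' from the whole volume. For a [FlowCurve-class], subtracts the mean
#' rate over a declared diastasis window. Both corrections are
#' idempotent within fitting tolerance.
#'
#' @param x a \code{VelocityField4D} or \code{FlowCurve}.
#' @param ... method-specific arguments; see
#'   \code{\link{correctBackgroundOffset,VelocityField4D-method}}.
#' @return the corrected object, same class as \code{x}.
#' @export
setGeneric("correctBackgroundOffset",
           function(x, ...) standardGeneric("correctBackgroundOffset"))
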