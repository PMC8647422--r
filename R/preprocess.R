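# Pre-processing corrections applied before quantification: velocity
# aliasing unwrap and eddy-current background offset removal.

#' Unwrap velocity aliasing by neighbourhood-median comparison
#'
#' For every voxel, frame and component, chooses the wrap count
#' k in \{-1, 0, +1\} that adds \code{2 k venc} to the value so as to
#' minimize the absolute difference from the median of the six
#' face-neighbours, iterating until no voxel changes. Single-wrap
#' correction only: at clinical VENC settings (150-250 cm/s) velocities
#' beyond \code{2 venc} are not expected. Voxels whose final wrap count
#' is nonzero are recorded in \code{aliasFlags}. Idempotent on
#' alias-free fields, and only ever changes a voxel by a multiple of
#' \code{2 venc}.
#'
#' @param field a wrapped [VelocityField4D-class] (components within
#'   \code{[-venc, venc]}).
#' @param maxIter iteration cap per frame/component.
#' @return the unwrapped [VelocityField4D-class] with
#'   \code{aliasFlags} set.
#' @seealso [wrapVelocities()]
#' @export
unwrapAliasing <- function(field, maxIter = 12L) {
  stopifnot(is(field, "VelocityField4D"))
  v <- field@velocities
  d <- dim(v)
  nt <- d[1L]
  venc2 <- 2 * field@venc
  flags <- array(FALSE, d[1:4])
  for (fr in seq_len(nt)) for (comp in 1:3) {
    a <- array(v[fr, , , , comp], d[2:4])
    k <- array(0L, d[2:4])
    for (it in seq_len(maxIter)) {
      med <- .neighbourMedian6(a)
      cand0 <- abs(a - med)
      candP <- abs(a + venc2 - med)
      candM <- abs(a - venc2 - med)
      stepUp <- candP < cand0 & candP <= candM & k < 1L
      stepDn <- candM < cand0 & candM < candP & k > -1L
      if (!any(stepUp) && !any(stepDn)) break
      a[stepUp] <- a[stepUp] + venc2
      k[stepUp] <- k[stepUp] + 1L
      a[stepDn] <- a[stepDn] - venc2
      k[stepDn] <- k[stepDn] - 1L
    }
    v[fr, , , , comp] <- a
    flags[fr, , , ] <- flags[fr, , , ] | (k != 0L)
  }
  velocityField4D(v, spacing = field@spacing, frameTimes = field@frameTimes,
                  venc = field@venc, aliasFlags = flags,
                  affine = field@affine)
}

# Median over the 6 face-neighbours of each voxel of a 3-D array
# (edge voxels use replicated-edge padding).
.neighbourMedian6 <- function(a) {
  d <- dim(a)
  ix <- function(n) c(1L, seq_len(n), n)
  p <- a[ix(d[1L]), ix(d[2L]), ix(d[3L])]
  ii <- 2:(d[1L] + 1L); jj <- 2:(d[2L] + 1L); kk <- 2:(d[3L] + 1L)
  m <- cbind(as.vector(p[ii - 1L, jj, kk]), as.vector(p[ii + 1L, jj, kk]),
             as.vector(p[ii, jj - 1L, kk]), as.vector(p[ii, jj + 1L, kk]),
             as.vector(p[ii, jj, kk - 1L]), as.vector(p[ii, jj, kk + 1L]))
  array(.rowMedian6(m), d)
}

#' @describeIn correctBackgroundOffset subtracts, per frame and
#'   component, a spatial polynomial (default first order: plane)
#'   fitted over static-tissue voxels from the whole volume.
#' @param staticMask logical 3-D array of static-tissue voxels
#'   (nonempty; should be disjoint from the jet region).
#' @param order polynomial order of the spatial fit, 0 (constant) or 1
#'   (plane, the default).
#' @export
setMethod("correctBackgroundOffset", "VelocityField4D",
  function(x, staticMask, order = 1L, ...) {
    if (missing(staticMask) || !any(staticMask))
      stop("static mask must be nonempty")
    d <- dim(x@velocities)
    if (!identical(dim(staticMask), d[2:4]))
      stop("static mask shape must match the voxel grid")
    sp <- x@spacing
    dd <- d[2:4]
    P <- cbind(rep((seq_len(dd[1L]) - 1) * sp[1L], times = dd[2L] * dd[3L]),
               rep(rep((seq_len(dd[2L]) - 1) * sp[2L], each = dd[1L]),
                   times = dd[3L]),
               rep((seq_len(dd[3L]) - 1) * sp[3L], each = dd[1L] * dd[2L]))
    X <- if (order >= 1L) cbind(1, P) else matrix(1, nrow(P), 1L)
    sel <- as.vector(staticMask)
    qrS <- qr(X[sel, , drop = FALSE])
    v <- x@velocities
    for (fr in seq_len(d[1L])) for (comp in 1:3) {
      a <- as.vector(v[fr, , , , comp])
      beta <- qr.coef(qrS, a[sel])
      v[fr, , , , comp] <- a - as.vector(X %*% beta)
    }
    velocityField4D(v, spacing = sp, frameTimes = x@frameTimes,
                    venc = x@venc, aliasFlags = x@aliasFlags,
                    affine = x@affine)
  })

#' @describeIn correctBackgroundOffset subtracts the mean rate over a
#'   declared diastasis window from the whole curve.
#' @param window numeric(2), ms; diastasis window over which the curve
#'   should be zero on average.
#' @export
setMethod("correctBackgroundOffset", "FlowCurve",
  function(x, window, ...) {
    sel <- x@times >= window[1L] & x@times <= window[2L]
    if (!any(sel)) stop("diastasis window contains no samples")
    flowCurve(x@times, x@rates - mean(x@rates[sel]))
  })
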