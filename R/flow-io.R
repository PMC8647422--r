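# NIfTI + JSON sidecar I/O for velocity fields; CSV I/O for curves.
#
# On disk a field is one 4-D NIfTI series per velocity component
# (x-index, y-index, z-index, time), a JSON sidecar with spacing_mm,
# frame_times_ms and venc_cms, and optionally a 0/1 NIfTI of alias
# flags. Internally the array layout is (time, x, y, z, component).

.componentSuffixes <- c("_velx.nii.gz", "_vely.nii.gz", "_velz.nii.gz")

#' Write a velocity field to NIfTI volumes plus a JSON sidecar
#'
#' @param field a [VelocityField4D-class].
#' @param outPrefix path prefix; writes \code{<prefix>_velx.nii.gz},
#'   \code{_vely}, \code{_velz}, \code{<prefix>_meta.json} and, when
#'   alias flags are present, \code{<prefix>_aliasflags.nii.gz}.
#' @return invisibly, the character vector of files written.
#' @seealso [readVelocityField()]
#' @export
writeVelocityField <- function(field, outPrefix) {
  stopifnot(is(field, "VelocityField4D"))
  validObject(field)
  d <- dim(field@velocities)
  if (d[1L] == 0L) stop("cannot write a velocity field with zero frames")
  dir.create(dirname(outPrefix), recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (comp in 1:3) {
    vol <- aperm(field@velocities[, , , , comp, drop = FALSE][, , , , 1L],
                 c(2L, 3L, 4L, 1L))
    path <- paste0(outPrefix, .componentSuffixes[comp])
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(field@spacing, 1)), path)
    files <- c(files, path)
  }
  meta <- list(spacing_mm = field@spacing,
               frame_times_ms = field@frameTimes,
               venc_cms = field@venc,
               affine = as.vector(field@affine),
               has_alias_flags = !is.null(field@aliasFlags))
  metaPath <- paste0(outPrefix, "_meta.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  files <- c(files, metaPath)
  if (!is.null(field@aliasFlags)) {
    flagVol <- aperm(array(as.integer(field@aliasFlags), d[1:4]),
                     c(2L, 3L, 4L, 1L))
    flagPath <- paste0(outPrefix, "_aliasflags.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(flagVol, pixdim = c(field@spacing, 1)),
                       flagPath)
    files <- c(files, flagPath)
  }
  invisible(files)
}

#' Read a velocity field from NIfTI volumes plus a JSON sidecar
#'
#' @param componentPaths character(3), NIfTI series for the x, y, z
#'   velocity components (each dims x, y, z, time), or a single prefix
#'   as written by [writeVelocityField()].
#' @param metadataPath JSON sidecar with \code{spacing_mm},
#'   \code{frame_times_ms} and \code{venc_cms}; defaults to
#'   \code{<prefix>_meta.json} when a prefix is given.
#' @return a validated [VelocityField4D-class] in cm/s and mm.
#' @export
readVelocityField <- function(componentPaths, metadataPath = NULL) {
  if (length(componentPaths) == 1L && !file.exists(componentPaths)) {
    prefix <- componentPaths
    componentPaths <- paste0(prefix, .componentSuffixes)
    if (is.null(metadataPath)) metadataPath <- paste0(prefix, "_meta.json")
  }
  if (length(componentPaths) != 3L)
    stop("componentPaths must name three component series (x, y, z)")
  if (is.null(metadataPath) || !file.exists(metadataPath))
    stop("metadata sidecar not found")
  meta <- jsonlite::read_json(metadataPath, simplifyVector = TRUE)
  for (key in c("spacing_mm", "frame_times_ms", "venc_cms"))
    if (is.null(meta[[key]]))
      stop(sprintf("metadata sidecar is missing '%s'", key))
  vols <- lapply(componentPaths, function(p) {
    v <- RNifti::readNifti(p)
    arr <- array(as.numeric(v), dim(v))
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
    arr
  })
  dims <- lapply(vols, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("component series have mismatched grid dimensions or frame counts")
  d <- dims[[1L]]
  vel <- array(0, c(d[4L], d[1L], d[2L], d[3L], 3L))
  for (comp in 1:3)
    vel[, , , , comp] <- aperm(vols[[comp]], c(4L, 1L, 2L, 3L))
  flags <- NULL
  if (isTRUE(meta$has_alias_flags)) {
    flagPath <- sub("_velx\\.nii\\.gz$", "_aliasflags.nii.gz",
                    componentPaths[1L])
    if (file.exists(flagPath)) {
      fv <- RNifti::readNifti(flagPath)
      fa <- array(as.numeric(fv), dim(fv))
      if (length(dim(fa)) == 3L) dim(fa) <- c(dim(fa), 1L)
      flags <- array(aperm(fa, c(4L, 1L, 2L, 3L)) > 0.5, c(d[4L], d[1:3]))
    }
  }
  affine <- if (!is.null(meta$affine)) matrix(unlist(meta$affine), 4L, 4L)
            else NULL
  velocityField4D(vel, spacing = unlist(meta$spacing_mm),
                  frameTimes = unlist(meta$frame_times_ms),
                  venc = meta$venc_cms, aliasFlags = flags, affine = affine)
}

#' Read / write flow and volume curves as two-column CSV
#'
#' Flow curves are stored with columns \code{time_ms}, \code{rate_mls};
#' volume curves with \code{time_ms}, \code{volume_ml}.
#'
#' @param curve a [FlowCurve-class] or [VolumeCurve-class].
#' @param path CSV file path.
#' @return the curve (readers) or, invisibly, \code{path} (writers).
#' @name curve-io
NULL

#' @rdname curve-io
#' @export
writeFlowCurve <- function(curve, path) {
  stopifnot(is(curve, "FlowCurve"))
  utils::write.csv(data.frame(time_ms = curve@times, rate_mls = curve@rates),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname curve-io
#' @export
readFlowCurve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "rate_mls") %in% names(df)))
    stop("flow-curve CSV must have columns time_ms, rate_mls")
  flowCurve(df$time_ms, df$rate_mls)
}

#' @rdname curve-io
#' @export
writeVolumeCurve <- function(curve, path) {
  stopifnot(is(curve, "VolumeCurve"))
  utils::write.csv(data.frame(time_ms = curve@times, volume_ml = curve@volumes),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname curve-io
#' @export
readVolumeCurve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "volume_ml") %in% names(df)))
    stop("volume-curve CSV must have columns time_ms, volume_ml")
  volumeCurve(df$time_ms, df$volume_ml)
}
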