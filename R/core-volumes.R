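#' Construct an ImageVolume
#'
#' @param values 3D numeric array (axis order: in-plane x, in-plane y, slice).
#' @param spacing voxel spacing in mm, length 3.
#' @param origin physical position (mm) of the centre of voxel (1,1,1).
#' @param unit value scale, e.g. "HU", "RED", "Gy".
#' @return an [ImageVolume].
#' @examples
#' vol <- imageVolume(array(0, c(4, 4, 2)), spacing = c(1, 1, 3))
#' spacing(vol)
#' @export
imageVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        unit = "HU") {
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), unit = unit)
}

#' Construct a BinaryMask
#'
#' @param values 3D logical array.
#' @param spacing,origin grid geometry in mm.
#' @param label role of the mask.
#' @return a [BinaryMask].
#' @export
binaryMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       label = "mask") {
  storage.mode(values) <- "logical"
  new("BinaryMask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), label = label)
}

# Mask on the grid of a parent volume or mask.
maskLike <- function(parent, values, label) {
  binaryMask(values, spacing = parent@spacing, origin = parent@origin,
             label = label)
}

#' @rdname ImageVolume-class
#' @export
setMethod("voxels", "ImageVolume", function(x) x@values)
#' @rdname ImageVolume-class
#' @export
setMethod("voxels", "BinaryMask", function(x) x@values)
#' @rdname ImageVolume-class
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname ImageVolume-class
#' @export
setMethod("spacing", "BinaryMask", function(x) x@spacing)
#' @rdname ImageVolume-class
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)
#' @rdname ImageVolume-class
#' @export
setMethod("origin", "BinaryMask", function(x) x@origin)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume [%s]: %d x %d x %d voxels, spacing %s mm\n",
              object@unit, d[1], d[2], d[3],
              paste(fmtNum(object@spacing), collapse = " x ")))
  cat(sprintf("  value range: %s .. %s\n",
              fmtNum(min(object@values)), fmtNum(max(object@values))))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask '%s': %d x %d x %d voxels, %d foreground\n",
              object@label, d[1], d[2], d[3], sum(object@values)))
})

#' Read / write volumes as NIfTI-1
#'
#' The canonical on-disk format is NIfTI-1 with spacing carried in the pixdim
#' header fields and origin in the sform. Masks are stored as 0/1 labelmaps.
#'
#' @param path file path (".nii" or ".nii.gz").
#' @param unit value scale to tag the volume with on read.
#' @return [ImageVolume] (or [BinaryMask] from [readMask()]).
#' @export
readVolume <- function(path, unit = "HU") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  arr <- array(as.numeric(img), dim = dim(img))
  xf <- RNifti::xform(img)
  imageVolume(arr, spacing = abs(diag(xf)[1:3]), origin = xf[1:3, 4],
              unit = unit)
}

#' @rdname readVolume
#' @param vol an [ImageVolume] or [BinaryMask].
#' @export
writeVolume <- function(vol, path) {
  arr <- vol@values
  if (is.logical(arr)) { arr <- arr + 0L; dim(arr) <- dim(vol@values) }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol@spacing
  affine <- diag(c(vol@spacing, 1))
  affine[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname readVolume
#' @param label mask label to attach on read.
#' @export
readMask <- function(path, label = "mask") {
  vol <- readVolume(path, unit = "mask")
  binaryMask(vol@values != 0, spacing = vol@spacing, origin = vol@origin,
             label = label)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Values are interpolated at the physical positions of the reference grid's
#' voxel centres. Positions outside the moving volume's field of view receive
#' a radiologically/dosimetrically inert fill value: -1000 for HU volumes,
#' 0 otherwise, FALSE for masks. Masks are resampled with nearest-neighbour
#' interpolation.
#'
#' @param moving the [ImageVolume] or [BinaryMask] to resample.
#' @param reference the [ImageVolume] (or [BinaryMask]) defining the target
#'   grid.
#' @param interpolation "trilinear" (default for volumes) or "nearest".
#' @param fill out-of-field fill value; default chosen from the unit.
#' @return resampled object on the reference grid.
#' @export
resampleTo <- function(moving, reference,
                       interpolation = c("trilinear", "nearest"),
                       fill = NULL) {
  isMask <- is(moving, "BinaryMask")
  interpolation <- if (isMask) "nearest" else match.arg(interpolation)
  if (sameGrid(moving, reference)) return(moving)

  extM <- physicalExtent(moving); extR <- physicalExtent(reference)
  if (any(extM[1, ] > extR[2, ] | extM[2, ] < extR[1, ]))
    stop("physical extents do not overlap: moving [",
         paste(apply(extM, 2, function(e) sprintf("%.1f..%.1f", e[1], e[2])),
               collapse = ", "), "] mm vs reference [",
         paste(apply(extR, 2, function(e) sprintf("%.1f..%.1f", e[1], e[2])),
               collapse = ", "), "] mm", call. = FALSE)

  d <- dim(reference@values)
  # physical positions of reference voxel centres -> moving index space
  ax <- lapply(1:3, function(a)
    (reference@origin[a] + (seq_len(d[a]) - 1) * reference@spacing[a] -
       moving@origin[a]) / moving@spacing[a] + 1)
  pts <- cbind(rep(ax[[1]], times = d[2] * d[3]),
               rep(rep(ax[[2]], each = d[1]), times = d[3]),
               rep(ax[[3]], each = d[1] * d[2]))
  if (isMask) {
    vals <- nearestLogical(moving@values, pts)
    dim(vals) <- d
    return(binaryMask(vals, spacing = reference@spacing,
                      origin = reference@origin, label = moving@label))
  }
  if (is.null(fill))
    fill <- if (identical(moving@unit, "HU")) -1000 else 0
  vals <- if (interpolation == "trilinear") {
    trilinearSample(moving@values, pts, fill = fill)
  } else {
    dm <- dim(moving@values)
    i <- round(pts[, 1]); j <- round(pts[, 2]); k <- round(pts[, 3])
    ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
    v <- rep(fill, nrow(pts))
    v[ok] <- moving@values[cbind(i[ok], j[ok], k[ok])]
    v
  }
  dim(vals) <- d
  imageVolume(vals, spacing = reference@spacing, origin = reference@origin,
              unit = moving@unit)
}

#' Extract the patient body contour from an HU volume
#'
#' Thresholds the volume, keeps the largest 3D connected component
#' (26-connectivity) and fills internal cavities slice-wise, so that interior
#' air (trachea, sinuses) belongs to the body.
#'
#' @param volume an HU [ImageVolume].
#' @param threshold HU above which a voxel is initially considered body
#'   (default -300).
#' @param connectivity connectivity for the component search (26 or 6).
#' @return a [BinaryMask] labelled "body": one connected component with
#'   interior holes filled.
#' @export
extractBodyContour <- function(volume, threshold = -300, connectivity = 26L) {
  fg <- volume@values > threshold
  if (!any(fg)) stop("no body found: no voxels above ", threshold, " HU")
  body <- largestComponent(fg, connectivity)
  body <- .cpp_fill_holes_2d(body)
  maskLike(volume, body, "body")
}

#' Construct a calibration curve
#'
#' @param hu strictly increasing HU breakpoints.
#' @param red matching non-decreasing RED values; must include (0, 1).
#' @return a [CalibrationCurve].
#' @export
calibrationCurve <- function(hu, red) {
  new("CalibrationCurve", hu = as.numeric(hu), red = as.numeric(red))
}

#' Default generic HU-RED calibration curve
#'
#' Piecewise linear through (-1000, 0), (0, 1), (1000, 1.55), (3000, 2.5):
#' air maps to zero electron density, water to 1, with a flattening slope
#' through bone, as generic treatment-planning curves do.
#'
#' @return a [CalibrationCurve].
#' @export
defaultCalibrationCurve <- function() {
  calibrationCurve(c(-1000, 0, 1000, 3000), c(0, 1, 1.55, 2.5))
}

#' Read a calibration curve from a two-column CSV (HU, RED)
#'
#' @param path CSV path; first column HU, second RED, header optional.
#' @return a [CalibrationCurve].
#' @export
readCalibrationCurve <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^\\s*-?[0-9]", first)
  tab <- utils::read.csv(path, header = hasHeader)
  calibrationCurve(tab[[1]], tab[[2]])
}

#' @rdname readCalibrationCurve
#' @param curve a [CalibrationCurve].
#' @export
writeCalibrationCurve <- function(curve, path) {
  utils::write.csv(data.frame(hu = curve@hu, red = curve@red), path,
                   row.names = FALSE)
  invisible(path)
}

interpRed <- function(hu, curve) {
  r <- approx(curve@hu, curve@red, xout = hu, rule = 2)$y
  r
}

#' @rdname huToRed
#' @export
setMethod("huToRed", "numeric", function(x, curve) interpRed(x, curve))

#' @rdname huToRed
#' @export
setMethod("huToRed", "ImageVolume", function(x, curve) {
  vals <- interpRed(as.vector(x@values), curve)
  dim(vals) <- dim(x@values)
  imageVolume(vals, spacing = x@spacing, origin = x@origin, unit = "RED")
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: %d points, HU %s..%s -> RED %s..%s\n",
              length(object@hu), fmtNum(min(object@hu)), fmtNum(max(object@hu)),
              fmtNum(min(object@red)), fmtNum(max(object@red))))
})
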