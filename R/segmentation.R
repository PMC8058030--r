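#' Tissue segmentation thresholds
#'
#' Head-and-neck tissue classes by HU: bone above 250 HU, air below -200 HU,
#' soft tissue the closed interval in between (both boundary values are
#' assigned to soft tissue, giving a clean partition of the body).
#'
#' @param boneMin HU above which a voxel is bone (default 250).
#' @param airMax HU below which a voxel is air (default -200).
#' @return a [SegmentationThresholds].
#' @export
segmentationThresholds <- function(boneMin = 250, airMax = -200) {
  new("SegmentationThresholds", boneMin = boneMin, airMax = airMax)
}

#' Threshold-based tissue-class segmentation
#'
#' Within the body mask: bone = HU > boneMin, air = HU < airMax, soft tissue
#' the remainder. Outside the body every class is FALSE; bone, soft and air
#' partition the body exactly.
#'
#' @param volume an HU [ImageVolume].
#' @param body the body [BinaryMask] on the same grid.
#' @param thresholds a [SegmentationThresholds].
#' @param source which volume the set derives from ("reference"/"candidate").
#' @return a [SegmentSet].
#' @export
segmentTissues <- function(volume, body,
                           thresholds = segmentationThresholds(),
                           source = "reference") {
  assertSameGrid(volume, body, "volume and body mask")
  hu <- volume@values
  b <- body@values
  bone <- b & hu > thresholds@boneMin
  air <- b & hu < thresholds@airMax
  soft <- b & !bone & !air
  new("SegmentSet",
      body = body,
      bone = maskLike(volume, bone, "bone"),
      soft = maskLike(volume, soft, "soft"),
      air = maskLike(volume, air, "air"),
      source = source)
}

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet (%s): body %d | bone %d | soft %d | air %d voxels\n",
              object@source, sum(object@body@values), sum(object@bone@values),
              sum(object@soft@values), sum(object@air@values)))
})

#' Build the evaluation ROI from the PTV extent
#'
#' The evaluation window is the craniocaudal slice range spanned by the PTV
#' plus a margin (default 15 mm) on each side, converted to slices with a
#' ceiling so the stated margin is never under-covered, clipped to the
#' volume, with artefact slices removed afterwards.
#'
#' @param ptv the PTV [BinaryMask].
#' @param marginMm craniocaudal margin in mm (default 15).
#' @param excludedSlices integer slice indices to omit (e.g. slices with
#'   intense dental streak artefacts, identified by the user).
#' @return an [EvaluationROI].
#' @export
buildROI <- function(ptv, marginMm = 15, excludedSlices = integer()) {
  zAny <- apply(ptv@values, 3, any)
  if (!any(zAny)) stop("empty PTV mask")
  nz <- dim(ptv@values)[3]
  marginSlices <- ceiling(marginMm / ptv@spacing[3])
  first <- max(1L, min(which(zAny)) - marginSlices)
  last <- min(nz, max(which(zAny)) + marginSlices)
  excludedSlices <- as.integer(excludedSlices)
  if (any(excludedSlices < 1L | excludedSlices > nz))
    stop("excluded slices outside the volume")
  new("EvaluationROI", firstSlice = as.integer(first),
      lastSlice = as.integer(last),
      excludedSlices = excludedSlices)
}

#' @rdname buildROI
#' @param roi an [EvaluationROI].
#' @return `roiSlices()`: the integer slice indices the ROI evaluates.
#' @export
roiSlices <- function(roi) {
  setdiff(seq(roi@firstSlice, roi@lastSlice), roi@excludedSlices)
}

#' @rdname buildROI
#' @param dims volume dimensions the selector is for.
#' @return `roiVoxelSelector()`: logical 3D array, TRUE on evaluated slices.
#' @export
roiVoxelSelector <- function(roi, dims) {
  sel <- array(FALSE, dims)
  keep <- roiSlices(roi)
  keep <- keep[keep >= 1L & keep <= dims[3]]
  sel[, , keep] <- TRUE
  sel
}

# ROI covering a whole volume (used when no PTV windowing is wanted).
fullROI <- function(dims) {
  new("EvaluationROI", firstSlice = 1L, lastSlice = as.integer(dims[3]),
      excludedSlices = integer())
}

setMethod("show", "EvaluationROI", function(object) {
  cat(sprintf("EvaluationROI: slices %d..%d (%d evaluated, %d excluded)\n",
              object@firstSlice, object@lastSlice, length(roiSlices(object)),
              length(object@excludedSlices)))
})
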