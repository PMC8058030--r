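#' Mean and mean-absolute HU error within a segment
#'
#' Signed mean error (ME) and mean absolute error (MAE) of the candidate
#' volume against the reference over the voxels of one tissue segment inside
#' the evaluation ROI. Segments are taken from the reference volume's
#' segmentation so both errors are measured on the same voxel set.
#'
#' @param reference,candidate HU [ImageVolume]s on one grid.
#' @param segment [BinaryMask] of the tissue class (from the reference
#'   segmentation).
#' @param roi an [EvaluationROI]; defaults to the full volume.
#' @return a one-row data.frame: label, me_hu, mae_hu, n_voxels.
#' @export
meanErrors <- function(reference, candidate, segment, roi = NULL) {
  assertSameGrid(reference, candidate)
  assertSameGrid(reference, segment, "volume and segment")
  if (is.null(roi)) roi <- fullROI(dim(reference@values))
  sel <- segment@values & roiVoxelSelector(roi, dim(reference@values))
  n <- sum(sel)
  if (n == 0L)
    stop("segment '", segment@label, "' has no voxels inside the ROI")
  diff <- candidate@values[sel] - reference@values[sel]
  data.frame(label = segment@label, me_hu = mean(diff),
             mae_hu = mean(abs(diff)), n_voxels = n,
             stringsAsFactors = FALSE)
}

#' Dice similarity coefficient of two masks within a ROI
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}, computed over the ROI slices.
#'
#' @param maskA,maskB [BinaryMask]s on one grid.
#' @param roi an [EvaluationROI]; defaults to the full volume.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(maskA, maskB, roi = NULL) {
  assertSameGrid(maskA, maskB, "masks")
  if (is.null(roi)) roi <- fullROI(dim(maskA@values))
  sel <- roiVoxelSelector(roi, dim(maskA@values))
  a <- maskA@values & sel
  b <- maskB@values & sel
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L)
    stop("Dice undefined: both masks empty inside the ROI")
  2 * sum(a & b) / (na + nb)
}

#' Hausdorff distance between two masks within a ROI
#'
#' Symmetric Hausdorff distance between the surface voxel sets of the two
#' masks, with Euclidean distances in mm (anisotropic spacing respected).
#' Surfaces are mask voxels with at least one face-adjacent non-mask
#' neighbour. The classic maximum is returned by default; a percentile
#' (e.g. 95) gives the robust variant.
#'
#' Implementation: directed distances are read off an exact Euclidean
#' distance transform of each surface, evaluated at the other surface's
#' voxels.
#'
#' @param maskA,maskB [BinaryMask]s on one grid.
#' @param roi an [EvaluationROI]; defaults to the full volume.
#' @param percentile percentile of the directed surface distances (100 =
#'   classic maximum).
#' @return Hausdorff distance in mm.
#' @export
hausdorffDistance <- function(maskA, maskB, roi = NULL, percentile = 100) {
  assertSameGrid(maskA, maskB, "masks")
  dims <- dim(maskA@values)
  if (is.null(roi)) roi <- fullROI(dims)
  sel <- roiVoxelSelector(roi, dims)
  a <- maskA@values & sel
  b <- maskB@values & sel
  if (!any(a) || !any(b))
    stop("Hausdorff undefined: a mask is empty inside the ROI")
  sa <- maskSurface(a); sb <- maskSurface(b)
  dToB <- distanceTo(sb, maskA@spacing)
  dToA <- distanceTo(sa, maskA@spacing)
  dAB <- dToB[sa]   # for each surface voxel of A, distance to surface of B
  dBA <- dToA[sb]
  if (percentile >= 100) max(max(dAB), max(dBA))
  else max(quantile(dAB, percentile / 100, names = FALSE),
           quantile(dBA, percentile / 100, names = FALSE))
}

#' Per-class image agreement metrics for a volume pair
#'
#' Convenience wrapper producing the standard evaluation table: ME and MAE
#' per tissue class on the reference segmentation, plus Dice and Hausdorff
#' between the reference and candidate segmentations of each class.
#'
#' @param reference,candidate HU [ImageVolume]s on one grid.
#' @param segRef,segCand [SegmentSet]s of the two volumes.
#' @param roi an [EvaluationROI].
#' @return data.frame with one row per class (body, soft, bone, air):
#'   label, me_hu, mae_hu, dsc, hd_mm, n_voxels.
#' @export
imageMetricsTable <- function(reference, candidate, segRef, segCand,
                              roi = NULL) {
  classes <- c("body", "soft", "bone", "air")
  rows <- lapply(classes, function(cl) {
    segR <- slot(segRef, cl)
    segC <- slot(segCand, cl)
    err <- meanErrors(reference, candidate, segR, roi)
    dsc <- tryCatch(diceCoefficient(segR, segC, roi), error = function(e) NA_real_)
    hd <- tryCatch(hausdorffDistance(segR, segC, roi), error = function(e) NA_real_)
    cbind(err, dsc = dsc, hd_mm = hd)
  })
  do.call(rbind, rows)
}
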