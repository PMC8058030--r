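#' Evaluation rules for dose comparison
#'
#' @param skinMarginMm PTV voxels closer than this to the body surface are
#'   excluded from DVH evaluation (default 4 mm).
#' @param oarGateFraction an OAR is evaluated only if its reference mean
#'   dose reaches this fraction of the prescription (default 0.10; with a
#'   68 Gy prescription the gate is 6.8 Gy).
#' @param prescriptionGy prescribed dose to the primary target in Gy (the
#'   highest level in dual-level plans).
#' @return an [EvaluationRules].
#' @export
evaluationRules <- function(skinMarginMm = 4, oarGateFraction = 0.10,
                            prescriptionGy = 68) {
  new("EvaluationRules", skinMarginMm = skinMarginMm,
      oarGateFraction = oarGateFraction, prescriptionGy = prescriptionGy)
}

# logical shift along one axis with explicit out-of-grid fill
shiftLogical <- function(m, axis, by, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  n <- d[axis]
  if (by == 1L) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
  else          { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Harmonize the candidate body contour with the reference before dose
#' comparison
#'
#' To compare dose on a common geometry, the candidate (sCT) volume is
#' edited so its body matches the reference contour: candidate tissue
#' extending outside the reference body is assigned to air (-1000 HU), and
#' air inside the reference body that is face-connected (6-connectivity) to
#' the body contour - e.g. a gap between the skin and the reference contour -
#' is assigned to water (0 HU). Fully enclosed interior air (trachea,
#' sinuses) is preserved.
#'
#' @param candidateHu candidate HU [ImageVolume].
#' @param candidateBody body [BinaryMask] of the candidate.
#' @param referenceBody body [BinaryMask] of the reference.
#' @param airMax HU below which a voxel counts as air (default -200).
#' @return harmonized HU [ImageVolume] on the candidate grid.
#' @export
harmonizeBody <- function(candidateHu, candidateBody, referenceBody,
                          airMax = -200) {
  assertSameGrid(candidateHu, candidateBody, "volume and candidate body")
  assertSameGrid(candidateHu, referenceBody, "volume and reference body")
  hu <- candidateHu@values
  refB <- referenceBody@values

  outsideShell <- candidateBody@values & !refB
  hu[outsideShell] <- -1000

  air <- refB & hu < airMax
  if (any(air)) {
    # air is contour-connected when face-adjacent to an outside-body voxel;
    # the grid edge itself is not a contour (an air tube leaving the field
    # of view stays interior air)
    notBody <- !refB
    touchesOutside <- array(FALSE, dim(hu))
    for (axis in 1:3)
      for (by in c(1L, -1L))
        touchesOutside <- touchesOutside | shiftLogical(notBody, axis, by, fill = FALSE)
    labels <- .cpp_label3d(air, 6L)
    seedLabels <- unique(labels[air & touchesOutside])
    seedLabels <- seedLabels[seedLabels > 0L]
    if (length(seedLabels))
      hu[labels %in% seedLabels] <- 0
  }
  imageVolume(hu, spacing = candidateHu@spacing, origin = candidateHu@origin,
              unit = "HU")
}

#' Remove PTV voxels within a skin margin
#'
#' Drops PTV voxels whose Euclidean distance (mm) to the body surface is
#' below the margin, using an exact distance transform of the body surface
#' voxels (body voxels with a face-adjacent outside neighbour; faces where
#' the body is merely clipped by the field of view do not count as skin).
#'
#' @param ptv PTV [BinaryMask].
#' @param body body [BinaryMask] on the same grid.
#' @param marginMm skin margin in mm (default 4; 0 is a no-op).
#' @return cropped PTV [BinaryMask].
#' @export
cropPtvFromSkin <- function(ptv, body, marginMm = 4) {
  assertSameGrid(ptv, body, "masks")
  if (marginMm <= 0) return(ptv)
  # a body clipped by the field of view has no skin at the clipped faces
  surf <- maskSurface(body@values, edgeIsOutside = FALSE)
  if (!any(surf)) return(ptv)
  d <- distanceTo(surf, ptv@spacing)
  keep <- ptv@values & d >= marginMm
  if (!any(keep))
    stop("PTV '", ptv@label, "' lies entirely within the ", marginMm,
         " mm skin margin")
  maskLike(ptv, keep, ptv@label)
}

# Dose received by the hottest x% of the masked volume: linear interpolation
# of the inverse cumulative volume curve over the sorted voxel doses.
doseAtHottest <- function(sortedDesc, xPct, method = c("interpolate", "nearest")) {
  method <- match.arg(method)
  n <- length(sortedDesc)
  p <- xPct / 100
  if (method == "nearest") return(sortedDesc[max(1L, ceiling(p * n))])
  f <- seq_len(n) / n
  if (p <= f[1]) return(sortedDesc[1])
  k <- findInterval(p, f)
  if (k >= n) return(sortedDesc[n])
  sortedDesc[k] + (sortedDesc[k + 1] - sortedDesc[k]) * (p - f[k]) / (f[k + 1] - f[k])
}

#' DVH summary of a structure
#'
#' Mean dose and the near-maximum / near-minimum DVH points D_2\% and
#' D_98\% (dose received by the hottest 2\% / 98\% of the structure volume),
#' computed by linear interpolation of the inverse cumulative volume curve
#' over the sorted voxel doses. A nearest-rank option is available for
#' cross-checks.
#'
#' @param dose dose [ImageVolume] in Gy.
#' @param mask structure [BinaryMask] on the dose grid.
#' @param method "interpolate" (default) or "nearest" (nearest-rank).
#' @return a [DVHSummary].
#' @export
dvhSummary <- function(dose, mask, method = c("interpolate", "nearest")) {
  assertSameGrid(dose, mask, "dose and mask")
  method <- match.arg(method)
  v <- dose@values[mask@values]
  if (length(v) == 0L) stop("empty mask '", mask@label, "' on the dose grid")
  s <- sort(v, decreasing = TRUE)
  new("DVHSummary", structure = mask@label, dMean = mean(v),
      d2 = doseAtHottest(s, 2, method), d98 = doseAtHottest(s, 98, method),
      volumeCc = length(v) * prod(dose@spacing) / 1000)
}

#' @rdname DVHSummary-class
#' @export
setMethod("dMean", "DVHSummary", function(x) x@dMean)
#' @rdname DVHSummary-class
#' @export
setMethod("dNearMax", "DVHSummary", function(x) x@d2)
#' @rdname DVHSummary-class
#' @export
setMethod("dNearMin", "DVHSummary", function(x) x@d98)

setMethod("show", "DVHSummary", function(object) {
  cat(sprintf(
    "DVHSummary '%s': D_mean %.2f Gy | D_2%% %.2f Gy | D_98%% %.2f Gy | %.1f cc\n",
    object@structure, object@dMean, object@d2, object@d98, object@volumeCc))
})

# DVH parameters evaluated per structure role
roleParameters <- function(role) {
  switch(role,
         ptv_t = c("D_mean", "D_98", "D_2"),
         ptv_n = "D_98",
         serial_oar = "D_2",
         parallel_oar = "D_mean",
         body = c("D_mean", "D_2"),
         stop("unknown structure role: ", role))
}

dvhParameter <- function(summary, parameter) {
  switch(parameter, D_mean = summary@dMean, D_2 = summary@d2,
         D_98 = summary@d98)
}

#' Compare DVH parameters of two dose distributions
#'
#' For each structure, the role decides the evaluated DVH parameters:
#' primary PTV (\code{ptv_t}) D_mean / D_98\% / D_2\%, nodal PTV
#' (\code{ptv_n}) D_98\% only, serial OARs (\code{serial_oar}, e.g. PRV
#' spinal cord) D_2\%, parallel OARs (\code{parallel_oar}) D_mean, and the
#' body D_mean and D_2\%. PTVs are cropped away from the skin surface
#' beforehand; an OAR enters the comparison only if its reference mean dose
#' reaches the gate fraction of the prescription. The relative difference is
#' local: 100 x (candidate - reference) / reference.
#'
#' @param doseRef,doseCand co-registered dose [ImageVolume]s (reference =
#'   CT-based plan, candidate = sCT-based plan).
#' @param structures named list of [BinaryMask]s.
#' @param roles named character vector mapping structure name to role
#'   ("ptv_t", "ptv_n", "serial_oar", "parallel_oar", "body").
#' @param rules an [EvaluationRules].
#' @param body body [BinaryMask] used for the PTV skin crop (reference
#'   contour). If NULL, the structure with role "body" is used.
#' @return data.frame: structure, role, parameter, ref_gy, cand_gy,
#'   rel_diff_pct, abs_diff_gy, included, reason. Per-structure failures are
#'   recorded as excluded rows; the run continues.
#' @export
comparePlans <- function(doseRef, doseCand, structures, roles,
                         rules = evaluationRules(), body = NULL) {
  assertSameGrid(doseRef, doseCand, "dose grids")
  if (is.null(names(structures)) || !all(names(structures) %in% names(roles)))
    stop("every structure needs a named role")
  if (is.null(body)) {
    bodyIdx <- which(roles[names(structures)] == "body")
    if (length(bodyIdx)) body <- structures[[bodyIdx[1]]]
  }
  gateGy <- rules@oarGateFraction * rules@prescriptionGy

  rows <- list()
  for (nm in names(structures)) {
    role <- unname(roles[[nm]])
    res <- tryCatch({
      mask <- structures[[nm]]
      assertSameGrid(doseRef, mask, paste("dose and structure", nm))
      if (role %in% c("ptv_t", "ptv_n") && !is.null(body))
        mask <- cropPtvFromSkin(mask, body, rules@skinMarginMm)
      sRef <- dvhSummary(doseRef, mask)
      sCand <- dvhSummary(doseCand, mask)
      included <- TRUE; reason <- "evaluated"
      if (role %in% c("serial_oar", "parallel_oar") && sRef@dMean < gateGy) {
        included <- FALSE
        reason <- sprintf("reference D_mean %.2f Gy below %.1f Gy gate",
                          sRef@dMean, gateGy)
      }
      pars <- roleParameters(role)
      do.call(rbind, lapply(pars, function(p) {
        r <- dvhParameter(sRef, p); cnd <- dvhParameter(sCand, p)
        data.frame(structure = nm, role = role, parameter = p,
                   ref_gy = r, cand_gy = cnd,
                   rel_diff_pct = if (r > 0) 100 * (cnd - r) / r else NA_real_,
                   abs_diff_gy = cnd - r,
                   included = included, reason = reason,
                   stringsAsFactors = FALSE)
      }))
    }, error = function(e) {
      data.frame(structure = nm, role = role, parameter = NA_character_,
                 ref_gy = NA_real_, cand_gy = NA_real_,
                 rel_diff_pct = NA_real_, abs_diff_gy = NA_real_,
                 included = FALSE, reason = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[nm]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
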