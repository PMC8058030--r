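#' @useDynLib sctqa, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats approx quantile rnorm pt qt sd setNames
#' @importFrom utils write.csv head tail
NULL

#' ImageVolume: a 3D scalar grid with physical geometry
#'
#' The central container of the package: a 3D array of scalar voxel values
#' (Hounsfield units, relative electron density, or absorbed dose in Gy)
#' together with its physical geometry. Axis order is (x = row within slice,
#' y = column within slice, z = slice index, craniocaudal). Voxel centres sit
#' at \code{origin + (index - 1) * spacing} mm (1-based R indices).
#'
#' @slot values 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel spacing in mm per axis; all positive.
#' @slot origin numeric(3), physical position in mm of the centre of voxel
#'   (1, 1, 1).
#' @slot unit character scalar describing the value scale ("HU", "RED", "Gy").
#'
#' @seealso [imageVolume()], [readVolume()], [resampleTo()]
#' @export
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", unit = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite numbers (mm)")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "all voxel values must be finite")
    if (length(object@unit) != 1L)
      msg <- c(msg, "unit must be a single string")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a labelled boolean volume on a parent grid
#'
#' @slot values 3D logical array, same shape as the parent [ImageVolume].
#' @slot spacing,origin grid geometry, as for [ImageVolume].
#' @slot label role of the mask ("body", "bone", "soft", "air", "PTV_T", ...).
#'
#' @export
setClass("BinaryMask",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L || !is.logical(object@values))
      msg <- c(msg, "values must be a 3D logical array")
    if (any(is.na(object@values)))
      msg <- c(msg, "mask values must not contain NA")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite numbers (mm)")
    if (length(object@label) != 1L)
      msg <- c(msg, "label must be a single string")
    if (length(msg)) msg else TRUE
  })

#' CalibrationCurve: monotone HU to relative electron density lookup
#'
#' Piecewise-linear conversion from Hounsfield units to relative electron
#' density (RED, water = 1). Outside the tabulated range the end values are
#' clamped. The curve must contain the water anchor (HU 0, RED 1).
#'
#' @slot hu numeric, strictly increasing HU breakpoints.
#' @slot red numeric, non-negative non-decreasing RED values, same length.
#'
#' @seealso [calibrationCurve()], [defaultCalibrationCurve()], [huToRed()]
#' @export
setClass("CalibrationCurve",
  representation(hu = "numeric", red = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@hu) < 2L)
      msg <- c(msg, "curve needs at least two points")
    if (length(object@hu) != length(object@red))
      msg <- c(msg, "hu and red must have the same length")
    if (any(!is.finite(object@hu)) || any(!is.finite(object@red)))
      msg <- c(msg, "curve points must be finite")
    if (any(diff(object@hu) <= 0))
      msg <- c(msg, "HU breakpoints must be strictly increasing")
    if (any(object@red < 0) || any(diff(object@red) < 0))
      msg <- c(msg, "RED must be non-negative and non-decreasing")
    if (!any(object@hu == 0 & object@red == 1))
      msg <- c(msg, "curve must contain the water anchor (HU 0, RED 1)")
    if (length(msg)) msg else TRUE
  })

#' SegmentationThresholds: HU thresholds for tissue classes
#'
#' Bone is HU above \code{boneMin}, air below \code{airMax}; the closed
#' interval between them (boundaries included) is soft tissue.
#'
#' @slot boneMin HU above which a voxel is bone (default 250).
#' @slot airMax HU below which a voxel is air (default -200).
#' @export
setClass("SegmentationThresholds",
  representation(boneMin = "numeric", airMax = "numeric"),
  validity = function(object) {
    if (length(object@boneMin) != 1L || length(object@airMax) != 1L)
      return("thresholds must be single numbers")
    if (!(object@airMax < object@boneMin))
      return("airMax must be below boneMin")
    TRUE
  })

#' SegmentSet: body, bone, soft and air masks of one volume
#'
#' Bone, soft and air are pairwise disjoint and partition the body mask.
#'
#' @slot body,bone,soft,air [BinaryMask] objects on one grid.
#' @slot source which volume the set was derived from ("reference" or
#'   "candidate").
#' @export
setClass("SegmentSet",
  representation(body = "BinaryMask", bone = "BinaryMask",
                 soft = "BinaryMask", air = "BinaryMask",
                 source = "character"))

#' EvaluationROI: slice range for metric evaluation
#'
#' Craniocaudal slice window derived from the PTV extent plus a margin, with
#' explicit exclusion of artefact slices.
#'
#' @slot firstSlice,lastSlice 1-based inclusive slice range.
#' @slot excludedSlices integer slice indices removed from the range
#'   (e.g. slices degraded by dental streak artefacts).
#' @export
setClass("EvaluationROI",
  representation(firstSlice = "integer", lastSlice = "integer",
                 excludedSlices = "integer"),
  validity = function(object) {
    if (object@firstSlice > object@lastSlice)
      return("slice range is empty")
    if (length(setdiff(seq(object@firstSlice, object@lastSlice),
                       object@excludedSlices)) == 0L)
      return("all slices in range are excluded")
    TRUE
  })

#' WEDProfile: radial water-equivalent depth on one slice
#'
#' @slot region region label ("vertebra_Th1_C7", "mid_mandible", "mid_nose",
#'   or custom).
#' @slot sliceIndex 1-based slice the profile was computed on.
#' @slot center (x, y) physical centre in mm the rays start from.
#' @slot angles direction angles in degrees, uniform over [0, 360);
#'   0 = anterior, increasing clockwise viewed from cranial.
#' @slot wed water-equivalent depth in mm per direction.
#' @export
setClass("WEDProfile",
  representation(region = "character", sliceIndex = "integer",
                 center = "numeric", angles = "numeric", wed = "numeric"),
  validity = function(object) {
    if (length(object@angles) != length(object@wed))
      return("angles and wed must have the same length")
    if (any(object@wed < 0)) return("wed must be non-negative")
    TRUE
  })

#' DVHSummary: dose-volume histogram parameters of one structure
#'
#' @slot structure structure label.
#' @slot dMean mean absorbed dose in the structure (Gy).
#' @slot d2 near-maximum dose: minimum dose to the hottest 2\% of volume (Gy).
#' @slot d98 near-minimum dose: minimum dose to the hottest 98\% of volume (Gy).
#' @slot volumeCc structure volume in cm^3.
#' @export
setClass("DVHSummary",
  representation(structure = "character", dMean = "numeric",
                 d2 = "numeric", d98 = "numeric", volumeCc = "numeric"),
  validity = function(object) {
    if (object@volumeCc <= 0) return("volume must be positive")
    if (object@d98 > object@d2 + 1e-9) return("d98 must not exceed d2")
    TRUE
  })

#' EvaluationRules: PTV and OAR inclusion rules for dose comparison
#'
#' @slot skinMarginMm PTVs are not evaluated closer than this to the body
#'   surface (default 4 mm).
#' @slot oarGateFraction an OAR is evaluated only if its reference mean dose
#'   is at least this fraction of the prescription (default 0.10).
#' @slot prescriptionGy prescribed dose to the primary target (Gy); with
#'   several dose levels, the highest.
#' @export
setClass("EvaluationRules",
  representation(skinMarginMm = "numeric", oarGateFraction = "numeric",
                 prescriptionGy = "numeric"),
  validity = function(object) {
    if (object@skinMarginMm < 0) return("skinMarginMm must be >= 0")
    if (object@oarGateFraction <= 0 || object@oarGateFraction >= 1)
      return("oarGateFraction must be in (0, 1)")
    if (object@prescriptionGy <= 0) return("prescriptionGy must be positive")
    TRUE
  })

#' GammaParams: criteria for the 3D gamma evaluation
#'
#' @slot doseCriterionFraction local dose-difference criterion as a fraction
#'   of the local reference dose (default 0.02, i.e. 2\% local).
#' @slot dtaMm distance-to-agreement criterion in mm (default 1).
#' @slot cutoffFraction reference voxels below this fraction of the
#'   prescription are not evaluated (default 0.10).
#' @slot searchRadiusMm spatial search radius in mm (default 3 x dtaMm;
#'   beyond it the distance term alone exceeds 3).
#' @slot interpStepMm step of the interpolation lattice used in the search
#'   (default dtaMm / 3).
#' @export
setClass("GammaParams",
  representation(doseCriterionFraction = "numeric", dtaMm = "numeric",
                 cutoffFraction = "numeric", searchRadiusMm = "numeric",
                 interpStepMm = "numeric"),
  validity = function(object) {
    vals <- c(object@doseCriterionFraction, object@dtaMm,
              object@cutoffFraction, object@searchRadiusMm,
              object@interpStepMm)
    if (any(vals <= 0)) return("all gamma parameters must be positive")
    if (object@interpStepMm > object@dtaMm)
      return("interpStepMm must not exceed dtaMm")
    TRUE
  })

#' GammaResult: gamma map and passing rate
#'
#' @slot gammaMap 3D array of gamma values, NaN below the dose cutoff.
#' @slot passRatePct percentage of evaluated voxels with gamma <= 1.
#' @slot nEvaluated number of voxels above the dose cutoff.
#' @slot nIncomplete evaluated voxels whose search sphere was truncated by
#'   the grid edge (scored from the available samples only).
#' @slot params the [GammaParams] used.
#' @export
setClass("GammaResult",
  representation(gammaMap = "array", passRatePct = "numeric",
                 nEvaluated = "integer", nIncomplete = "integer",
                 params = "GammaParams"))

#' TOSTResult: paired two one-sided t-test equivalence outcome
#'
#' @slot n number of paired differences.
#' @slot meanDiff,sdDiff sample mean and sd of the differences (\%).
#' @slot margin half-width of the equivalence interval (\%).
#' @slot alpha one-sided significance level.
#' @slot tLower,tUpper t statistics against the lower/upper margins.
#' @slot pLower,pUpper one-sided p-values.
#' @slot ci90,ci95 two-sided 90\% and 95\% confidence intervals for the mean.
#' @slot equivalent TRUE iff both one-sided p-values are below alpha.
#' @slot degenerate TRUE when the sd is zero and the mean sits exactly on a
#'   margin, where the p-values are undefined.
#' @export
setClass("TOSTResult",
  representation(n = "integer", meanDiff = "numeric", sdDiff = "numeric",
                 margin = "numeric", alpha = "numeric",
                 tLower = "numeric", tUpper = "numeric",
                 pLower = "numeric", pUpper = "numeric",
                 ci90 = "numeric", ci95 = "numeric",
                 equivalent = "logical", degenerate = "logical"))
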