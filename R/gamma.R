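#' Gamma evaluation criteria
#'
#' Defaults implement the 2\% local dose difference / 1 mm
#' distance-to-agreement criterion with a 10\% dose cutoff. The spatial
#' search is confined to 3 x DTA (beyond that the distance term alone
#' exceeds gamma 3) on an interpolation lattice of DTA / 3.
#'
#' @param doseCriterionFraction local dose criterion (default 0.02).
#' @param dtaMm distance-to-agreement in mm (default 1).
#' @param cutoffFraction dose cutoff as a fraction of prescription
#'   (default 0.10).
#' @param searchRadiusMm search radius in mm (default 3 x dtaMm).
#' @param interpStepMm interpolation lattice step (default dtaMm / 3).
#' @return a [GammaParams].
#' @export
gammaParams <- function(doseCriterionFraction = 0.02, dtaMm = 1,
                        cutoffFraction = 0.10,
                        searchRadiusMm = 3 * dtaMm,
                        interpStepMm = dtaMm / 3) {
  new("GammaParams", doseCriterionFraction = doseCriterionFraction,
      dtaMm = dtaMm, cutoffFraction = cutoffFraction,
      searchRadiusMm = searchRadiusMm, interpStepMm = interpStepMm)
}

# offset lattice within the search sphere, ordered by distance;
# columns: di, dj, dk (lattice steps), dist_mm
gammaOffsets <- function(params) {
  step <- params@interpStepMm
  m <- floor(params@searchRadiusMm / step + 1e-9)
  g <- expand.grid(di = -m:m, dj = -m:m, dk = -m:m)
  dist <- step * sqrt(g$di^2 + g$dj^2 + g$dk^2)
  keep <- dist <= params@searchRadiusMm + 1e-9
  g <- g[keep, , drop = FALSE]
  dist <- dist[keep]
  o <- order(dist)
  cbind(as.matrix(g[o, ]), dist_mm = dist[o])
}

#' 3D gamma evaluation with local dose normalization
#'
#' For every reference voxel at or above the dose cutoff, the gamma index is
#' the minimum over candidate positions \eqn{c} within the search radius of
#' \deqn{\sqrt{ |c-r|^2 / \mathrm{DTA}^2 +
#'   (D_{eval}(c) - D_{ref}(r))^2 / (f \cdot D_{ref}(r))^2 }}
#' with \eqn{f} the local dose criterion and \eqn{D_{eval}} trilinearly
#' interpolated on the lattice. A voxel passes iff gamma <= 1 (inclusive,
#' up to floating-point tolerance). The reference is the CT-based dose and
#' the evaluated distribution the sCT-based dose.
#'
#' The search visits lattice offsets in order of increasing distance and
#' stops once the distance term alone exceeds every voxel's current minimum,
#' which cannot change the result. Voxels whose search sphere is truncated
#' by the grid edge are scored from the available samples only and counted
#' in \code{nIncomplete}.
#'
#' @param doseRef,doseEval co-registered dose [ImageVolume]s in Gy.
#' @param params a [GammaParams].
#' @param prescriptionGy prescription dose defining the cutoff level.
#' @return a [GammaResult].
#' @seealso [gammaBruteForce()] for the exhaustive reference implementation.
#' @export
gamma3d <- function(doseRef, doseEval, params = gammaParams(),
                    prescriptionGy) {
  assertSameGrid(doseRef, doseEval, "dose grids")
  if (prescriptionGy <= 0) stop("prescription must be positive")
  d <- dim(doseRef@values)
  sp <- doseRef@spacing
  cutoff <- params@cutoffFraction * prescriptionGy

  refv <- as.vector(doseRef@values)
  evalArr <- doseEval@values
  sel <- which(refv >= cutoff)
  gmap <- array(NaN, d)
  if (length(sel) == 0L)
    return(new("GammaResult", gammaMap = gmap, passRatePct = NaN,
               nEvaluated = 0L, nIncomplete = 0L, params = params))

  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ii <- ((sel - 1L) %% nx) + 1L
  jj <- (((sel - 1L) %/% nx) %% ny) + 1L
  kk <- ((sel - 1L) %/% (nx * ny)) + 1L
  refSel <- refv[sel]
  denom <- params@doseCriterionFraction * refSel
  stopifnot(all(refSel > 0))

  offs <- gammaOffsets(params)
  step <- params@interpStepMm
  gmin <- rep(Inf, length(sel))

  for (t in seq_len(nrow(offs))) {
    distTerm <- offs[t, 4] / params@dtaMm
    act <- which(gmin > distTerm)
    if (length(act) == 0L) break
    # constant physical offset -> constant fractional interpolation weights
    ov <- offs[t, 1:3] * step / sp
    fo <- floor(ov); fr <- ov - fo
    bi <- ii[act] + fo[1]; bj <- jj[act] + fo[2]; bk <- kk[act] + fo[3]
    hiI <- if (fr[1] > 0) 1L else 0L
    hiJ <- if (fr[2] > 0) 1L else 0L
    hiK <- if (fr[3] > 0) 1L else 0L
    ok <- bi >= 1 & (bi + hiI) <= nx & bj >= 1 & (bj + hiJ) <= ny &
          bk >= 1 & (bk + hiK) <= nz
    if (!any(ok)) next
    aok <- act[ok]
    base <- bi[ok] + (bj[ok] - 1) * nx + (bk[ok] - 1) * nx * ny
    val <- 0
    for (a in 0:hiI) for (b in 0:hiJ) for (cc in 0:hiK) {
      w <- (if (a) fr[1] else 1 - fr[1]) *
           (if (b) fr[2] else 1 - fr[2]) *
           (if (cc) fr[3] else 1 - fr[3])
      if (w > 0)
        val <- val + w * evalArr[base + a + b * nx + cc * nx * ny]
    }
    doseTerm <- (val - refSel[aok]) / denom[aok]
    gcand <- sqrt(distTerm^2 + doseTerm^2)
    gmin[aok] <- pmin(gmin[aok], gcand)
  }

  # voxels whose search sphere extends past the grid edge
  R <- params@searchRadiusMm
  incomplete <- (ii - 1) * sp[1] < R | (nx - ii) * sp[1] < R |
                (jj - 1) * sp[2] < R | (ny - jj) * sp[2] < R |
                (kk - 1) * sp[3] < R | (nz - kk) * sp[3] < R

  gmap[sel] <- gmin
  new("GammaResult", gammaMap = gmap,
      passRatePct = 100 * mean(gmin <= 1 + 1e-9),
      nEvaluated = length(sel), nIncomplete = sum(incomplete),
      params = params)
}

#' Exhaustive brute-force gamma evaluation (verification oracle)
#'
#' Same contract as [gamma3d()] but evaluates every lattice position within
#' the search radius for every voxel with a general trilinear interpolator
#' and no pruning. Restricted to grids of at most 32^3 voxels.
#'
#' @inheritParams gamma3d
#' @return a [GammaResult].
#' @export
gammaBruteForce <- function(doseRef, doseEval, params = gammaParams(),
                            prescriptionGy) {
  assertSameGrid(doseRef, doseEval, "dose grids")
  d <- dim(doseRef@values)
  if (prod(d) > 32^3) stop("brute-force gamma is guarded to grids <= 32^3")
  sp <- doseRef@spacing
  cutoff <- params@cutoffFraction * prescriptionGy

  refv <- as.vector(doseRef@values)
  sel <- which(refv >= cutoff)
  gmap <- array(NaN, d)
  if (length(sel) == 0L)
    return(new("GammaResult", gammaMap = gmap, passRatePct = NaN,
               nEvaluated = 0L, nIncomplete = 0L, params = params))

  nx <- d[1]; ny <- d[2]
  offs <- gammaOffsets(params)
  step <- params@interpStepMm
  offVox <- sweep(offs[, 1:3, drop = FALSE] * step, 2, sp, "/")
  distTerm2 <- (offs[, 4] / params@dtaMm)^2

  gmin <- numeric(length(sel))
  for (v in seq_along(sel)) {
    p <- sel[v]
    i <- ((p - 1L) %% nx) + 1L
    j <- (((p - 1L) %/% nx) %% ny) + 1L
    k <- ((p - 1L) %/% (nx * ny)) + 1L
    pts <- cbind(i + offVox[, 1], j + offVox[, 2], k + offVox[, 3])
    val <- trilinearSample(doseEval@values, pts)
    doseTerm2 <- ((val - refv[p]) /
                    (params@doseCriterionFraction * refv[p]))^2
    gmin[v] <- sqrt(min(distTerm2 + doseTerm2, na.rm = TRUE))
  }
  R <- params@searchRadiusMm
  ii <- ((sel - 1L) %% nx) + 1L
  jj <- (((sel - 1L) %/% nx) %% ny) + 1L
  kk <- ((sel - 1L) %/% (nx * ny)) + 1L
  incomplete <- (ii - 1) * sp[1] < R | (nx - ii) * sp[1] < R |
                (jj - 1) * sp[2] < R | (ny - jj) * sp[2] < R |
                (kk - 1) * sp[3] < R | (d[3] - kk) * sp[3] < R

  gmap[sel] <- gmin
  new("GammaResult", gammaMap = gmap,
      passRatePct = 100 * mean(gmin <= 1 + 1e-9),
      nEvaluated = length(sel), nIncomplete = sum(incomplete),
      params = params)
}

#' @rdname GammaResult-class
#' @export
setMethod("passRate", "GammaResult", function(x) x@passRatePct)
#' @rdname GammaResult-class
#' @export
setMethod("gammaMap", "GammaResult", function(x) x@gammaMap)

setMethod("show", "GammaResult", function(object) {
  cat(sprintf(
    "GammaResult (%.0f%%/%g mm local, %.0f%% cutoff): pass %.1f%% of %d voxels (%d edge-truncated)\n",
    100 * object@params@doseCriterionFraction, object@params@dtaMm,
    100 * object@params@cutoffFraction, object@passRatePct,
    object@nEvaluated, object@nIncomplete))
})
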