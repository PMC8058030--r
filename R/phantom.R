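#' Head-and-neck digital phantom specification
#'
#' Parameterizes a stylized head-and-neck patient on a regular grid:
#' a per-zone elliptical body (shoulders, neck, head), a vertebral column
#' with spinal canal, a mandible arc, an interior air trachea, oral and
#' nasal air cavities, paired parotid-like OARs, a laryngeal OAR, and
#' primary / nodal PTVs. Tissue HU values are Gaussian around per-class
#' means. The same seed always yields the bitwise-identical phantom.
#'
#' @param dim grid size, default c(96, 96, 48) voxels.
#' @param spacing voxel spacing in mm, default c(2.5, 2.5, 3)
#'   (240 x 240 x 144 mm field of view).
#' @param origin physical origin (mm), default c(0, 0, 0).
#' @param seed integer seed driving all randomness of the phantom.
#' @param huMean named HU means for background, soft, bone, air.
#' @param huSd named HU standard deviations (set to 0 for a noiseless
#'   phantom).
#' @param geometry named list of structure parameters (positions in mm
#'   relative to the in-plane centre, z extents as fractions of the grid);
#'   entries override the defaults.
#' @param dentalStreaks add a streak-artifact pattern around the dental
#'   filling (reference-CT-like metal artefact); the affected slices are
#'   reported so they can be excluded from evaluation.
#' @return a PhantomSpec object.
#' @export
phantomSpec <- function(dim = c(96L, 96L, 48L), spacing = c(2.5, 2.5, 3),
                        origin = c(0, 0, 0), seed = 1L,
                        huMean = c(background = -1000, soft = 40,
                                   bone = 700, air = -950),
                        huSd = c(background = 10, soft = 30,
                                 bone = 100, air = 30),
                        geometry = list(), dentalStreaks = FALSE) {
  geo <- list(
    shoulders = list(zfrac = c(0.00, 0.20), semi = c(115, 72)),
    neck      = list(zfrac = c(0.20, 0.55), semi = c(55, 62)),
    head      = list(zfrac = c(0.55, 1.00), semi = c(75, 88)),
    spine     = list(center = c(0, 28), outerR = 11, innerR = 4.5,
                     zfrac = c(0, 0.78)),
    mandible  = list(radius = 44, halfThick = 5, zfrac = c(0.58, 0.66)),
    trachea   = list(center = c(0, -18), r = 8, zfrac = c(0, 0.45)),
    larynx    = list(center = c(0, -18), semi = c(16, 16),
                     zfrac = c(0.40, 0.50)),
    oral      = list(center = c(0, -35), semi = c(26, 16),
                     zfrac = c(0.60, 0.66)),
    nasal     = list(offset = 9, center_y = -55, semi = c(6, 10),
                     zfrac = c(0.85, 0.95)),
    parotid   = list(offset = 52, center_y = 6, semi = c(11, 14),
                     zfrac = c(0.58, 0.70)),
    ptv_t     = list(center = c(14, -8), semi = c(20, 17),
                     zfrac = c(0.42, 0.60)),
    ptv_n     = list(center = c(-36, 4), semi = c(12, 12),
                     zfrac = c(0.35, 0.50)),
    filling   = list(center = c(0, -40), r = 4, zfrac = c(0.61, 0.63)),
    regions   = c(vertebra_Th1_C7 = 0.30, mid_mandible = 0.62,
                  mid_nose = 0.90))
  geo[names(geometry)] <- geometry
  stopifnot(huMean["air"] < huMean["soft"], huMean["soft"] < huMean["bone"])
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), seed = as.integer(seed),
                 huMean = huMean, huSd = huSd, geometry = geo,
                 dentalStreaks = isTRUE(dentalStreaks)),
            class = "PhantomSpec")
}

withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a phantom: reference CT, structure masks and tissue truth
#'
#' @param spec a [phantomSpec()].
#' @return list with \code{ct} (HU [ImageVolume]), \code{masks} (named
#'   [BinaryMask] list: body, ptv_t, ptv_n, prv_spinal_cord, parotid_sin,
#'   parotid_dx, larynx), \code{truth} (tissue-class masks: body, bone,
#'   soft, air), \code{regionSlices} (named slice indices of the three WED
#'   regions), \code{streakSlices} (slices degraded when
#'   \code{dentalStreaks} is on), and the \code{spec}.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  d <- spec$dim; sp <- spec$spacing; or <- spec$origin
  g <- spec$geometry
  x <- or[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- or[2] + (seq_len(d[2]) - 1) * sp[2]
  z <- or[3] + (seq_len(d[3]) - 1) * sp[3]
  cx <- mean(range(x)); cy <- mean(range(y))
  X <- array(rep(x - cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y - cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  zmm <- function(f) or[3] + f * (d[3] - 1) * sp[3]
  zIdx <- function(f) pmin(d[3], pmax(1L, as.integer(round(1 + f * (d[3] - 1)))))

  zBand <- function(zfrac) Z >= zmm(zfrac[1]) - 1e-9 & Z <= zmm(zfrac[2]) + 1e-9
  ellipseZone <- function(semi, zfrac)
    (X / semi[1])^2 + (Y / semi[2])^2 <= 1 & zBand(zfrac)
  ellipsoid <- function(center, semi, zfrac) {
    zc <- mean(zmm(zfrac)); zr <- diff(range(zmm(zfrac))) / 2
    ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
      ((Z - zc) / max(zr, sp[3] / 2))^2 <= 1
  }
  cylinder <- function(center, r, zfrac)
    (X - center[1])^2 + (Y - center[2])^2 <= r^2 & zBand(zfrac)

  body <- ellipseZone(g$shoulders$semi, g$shoulders$zfrac) |
          ellipseZone(g$neck$semi, g$neck$zfrac) |
          ellipseZone(g$head$semi, g$head$zfrac)

  spineOuter <- cylinder(g$spine$center, g$spine$outerR, g$spine$zfrac)
  canal <- cylinder(g$spine$center, g$spine$innerR, g$spine$zfrac)
  spineBone <- spineOuter & !canal
  rad <- sqrt(X^2 + Y^2)
  mandible <- rad >= g$mandible$radius - g$mandible$halfThick &
              rad <= g$mandible$radius + g$mandible$halfThick &
              Y < 0 & zBand(g$mandible$zfrac)
  filling <- cylinder(g$filling$center, g$filling$r, g$filling$zfrac)

  trachea <- cylinder(g$trachea$center, g$trachea$r, g$trachea$zfrac)
  oral <- ellipsoid(g$oral$center, g$oral$semi, g$oral$zfrac)
  nasal <- ellipsoid(c(-g$nasal$offset, g$nasal$center_y), g$nasal$semi,
                     g$nasal$zfrac) |
           ellipsoid(c(g$nasal$offset, g$nasal$center_y), g$nasal$semi,
                     g$nasal$zfrac)

  bone <- (spineBone | mandible | filling) & body
  air <- (trachea | oral | nasal) & body & !bone
  soft <- body & !bone & !air

  # structures must not exceed the body
  for (nm in c("spineBone", "mandible", "trachea", "oral", "nasal")) {
    m <- get(nm)
    if (any(m & !body))
      stop("phantom structure '", nm, "' extends outside the body")
  }

  ptvT <- ellipsoid(g$ptv_t$center, g$ptv_t$semi, g$ptv_t$zfrac) & body
  ptvN <- ellipsoid(g$ptv_n$center, g$ptv_n$semi, g$ptv_n$zfrac) & body
  parotidSin <- ellipsoid(c(-g$parotid$offset, g$parotid$center_y),
                          g$parotid$semi, g$parotid$zfrac) & body
  parotidDx <- ellipsoid(c(g$parotid$offset, g$parotid$center_y),
                         g$parotid$semi, g$parotid$zfrac) & body
  larynx <- ellipsoid(g$larynx$center, g$larynx$semi, g$larynx$zfrac) & body
  cord <- canal & body

  mu <- spec$huMean; sdv <- spec$huSd
  hu <- withSeed(spec$seed, {
    h <- array(rnorm(prod(d), mu[["background"]], sdv[["background"]]), d)
    h[soft] <- rnorm(sum(soft), mu[["soft"]], sdv[["soft"]])
    h[bone] <- rnorm(sum(bone), mu[["bone"]], sdv[["bone"]])
    h[air] <- rnorm(sum(air), mu[["air"]], sdv[["air"]])
    h[filling] <- 3000                      # dental filling: metal
    h
  })

  streakSlices <- integer()
  if (spec$dentalStreaks) {
    streakSlices <- zIdx(g$filling$zfrac[1]):zIdx(g$filling$zfrac[2])
    fx <- g$filling$center[1]; fy <- g$filling$center[2]
    th <- atan2(Y - fy, X - fx)
    rr <- sqrt((X - fx)^2 + (Y - fy)^2)
    streak <- 400 * cos(8 * th) * exp(-rr / 40)
    sel <- body & zBand(g$filling$zfrac) & rr > g$filling$r & rr < 80
    hu[sel] <- hu[sel] + streak[sel]
  }

  mk <- function(vals, label) binaryMask(vals, spacing = sp, origin = or,
                                         label = label)
  list(ct = imageVolume(hu, spacing = sp, origin = or, unit = "HU"),
       masks = list(body = mk(body, "body"),
                    ptv_t = mk(ptvT, "PTV_T"),
                    ptv_n = mk(ptvN, "PTV_N"),
                    prv_spinal_cord = mk(cord, "PRV_spinal_cord"),
                    parotid_sin = mk(parotidSin, "Parotid_Sin"),
                    parotid_dx = mk(parotidDx, "Parotid_Dx"),
                    larynx = mk(larynx, "Larynx")),
       truth = list(body = mk(body, "body"), bone = mk(bone, "bone"),
                    soft = mk(soft, "soft"), air = mk(air, "air")),
       regionSlices = vapply(g$regions, zIdx, integer(1)),
       streakSlices = streakSlices,
       spec = spec)
}

#' Synthetic-CT perturbation specification
#'
#' Defaults emulate the error structure of CNN-generated sCT in the head
#' and neck: a systematic underestimation of bone HU (-62), overestimation
#' of air HU (+107), near-zero soft-tissue bias (-1), with per-tissue
#' residual noise, optional body-contour dilation/erosion, and an optional
#' signal-void patch at the dental filling (sCT metal voids are small
#' compared with CT streaks).
#'
#' @param biasHu named per-tissue HU bias (bone, air, soft).
#' @param noiseSdHu named per-tissue HU noise sd; the defaults put the
#'   per-class mean absolute errors in a realistic range.
#' @param contourMm body contour change in mm: > 0 dilates, < 0 erodes,
#'   0 leaves the contour untouched.
#' @param dentalVoid carve a signal-void patch around the dental filling.
#' @param dentalVoidRadiusMm radius of the void patch (default 6 mm).
#' @param seed integer seed for the perturbation noise.
#' @return a PerturbationSpec object.
#' @export
perturbationSpec <- function(biasHu = c(bone = -62, air = 107, soft = -1),
                             noiseSdHu = c(bone = 230, air = 230, soft = 50),
                             contourMm = 0, dentalVoid = FALSE,
                             dentalVoidRadiusMm = 6, seed = 1L) {
  structure(list(biasHu = biasHu, noiseSdHu = noiseSdHu,
                 contourMm = contourMm, dentalVoid = isTRUE(dentalVoid),
                 dentalVoidRadiusMm = dentalVoidRadiusMm,
                 seed = as.integer(seed)),
            class = "PerturbationSpec")
}

#' @rdname perturbationSpec
#' @return `zeroPerturbation()`: a spec under which the candidate equals
#'   the reference bitwise.
#' @export
zeroPerturbation <- function() {
  perturbationSpec(biasHu = c(bone = 0, air = 0, soft = 0),
                   noiseSdHu = c(bone = 0, air = 0, soft = 0))
}

#' Degrade a reference CT into a synthetic-CT-like candidate
#'
#' Adds the per-tissue biases and seeded Gaussian noise of the perturbation
#' spec on the tissue-truth masks, optionally deforms the body contour
#' (dilated voxels get soft-tissue HU, eroded voxels background air), and
#' optionally carves a signal-void patch at the dental filling.
#'
#' @param reference HU [ImageVolume] from [generatePhantom()].
#' @param truth tissue-truth mask list (body, bone, soft, air).
#' @param spec a [perturbationSpec()].
#' @param fillingCenterMm physical (x, y, z) centre of the dental void, if
#'   \code{dentalVoid} is on; defaults to the phantom's filling location.
#' @return candidate HU [ImageVolume] on the reference grid.
#' @export
perturbToSct <- function(reference, truth, spec = perturbationSpec(),
                         fillingCenterMm = NULL) {
  hu <- reference@values
  d <- dim(hu); sp <- reference@spacing; or <- reference@origin
  bone <- truth$bone@values; air <- truth$air@values
  soft <- truth$body@values & !bone & !air

  hu <- withSeed(spec$seed, {
    for (cls in c("bone", "air", "soft")) {
      m <- switch(cls, bone = bone, air = air, soft = soft)
      n <- sum(m)
      if (n == 0L) next
      noise <- if (spec$noiseSdHu[[cls]] > 0)
        rnorm(n, 0, spec$noiseSdHu[[cls]]) else 0
      hu[m] <- hu[m] + spec$biasHu[[cls]] + noise
    }
    if (spec$contourMm > 0) {
      dOut <- distanceTo(truth$body@values, sp)
      added <- !truth$body@values & dOut > 0 & dOut <= spec$contourMm
      if (any(added))
        hu[added] <- rnorm(sum(added), 40 + spec$biasHu[["soft"]],
                           max(spec$noiseSdHu[["soft"]], 1))
    } else if (spec$contourMm < 0) {
      dIn <- distanceTo(!truth$body@values, sp)
      removed <- truth$body@values & dIn <= -spec$contourMm
      if (any(removed)) hu[removed] <- -1000
    }
    hu
  })

  if (spec$dentalVoid) {
    if (is.null(fillingCenterMm)) {
      x <- or[1] + (seq_len(d[1]) - 1) * sp[1]
      y <- or[2] + (seq_len(d[2]) - 1) * sp[2]
      z <- or[3] + (seq_len(d[3]) - 1) * sp[3]
      fillingCenterMm <- c(mean(range(x)) + 0, mean(range(y)) - 40,
                           or[3] + 0.62 * (d[3] - 1) * sp[3])
    }
    x <- or[1] + (seq_len(d[1]) - 1) * sp[1]
    y <- or[2] + (seq_len(d[2]) - 1) * sp[2]
    z <- or[3] + (seq_len(d[3]) - 1) * sp[3]
    X <- array(rep(x, times = d[2] * d[3]), d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
    Z <- array(rep(z, each = d[1] * d[2]), d)
    void <- (X - fillingCenterMm[1])^2 + (Y - fillingCenterMm[2])^2 +
            (Z - fillingCenterMm[3])^2 <= spec$dentalVoidRadiusMm^2
    hu[void] <- -1000
  }
  imageVolume(hu, spacing = sp, origin = or, unit = "HU")
}

#' Toy beam specification for the attenuation dose engine
#'
#' The toy engine is a deliberately simple parallel-beam exponential
#' attenuation model - not a clinical dose algorithm. It exists so that HU
#' differences propagate into dose differences with the right sign and a
#' plausible magnitude: each beam deposits
#' \eqn{D \propto \mathrm{RED}(r) \exp(-\mu\, \mathrm{WED}(r))} along
#' parallel rays, with lateral Gaussian smearing; beams are summed and the
#' sum scaled so the target-point dose equals the prescription.
#'
#' @param nBeams number of equispaced coplanar gantry angles (default 8).
#' @param muPerMm effective attenuation per mm of unit-RED path
#'   (default 0.005, a clinically plausible MV depth falloff).
#' @param kernelSdMm lateral Gaussian kernel sd in mm (default 5).
#' @param prescriptionGy prescription dose at the target point (default 68).
#' @return a ToyBeamSpec object.
#' @export
toyBeamSpec <- function(nBeams = 8L, muPerMm = 0.005, kernelSdMm = 5,
                        prescriptionGy = 68) {
  stopifnot(nBeams >= 1, muPerMm > 0, kernelSdMm >= 0, prescriptionGy > 0)
  structure(list(nBeams = as.integer(nBeams), muPerMm = muPerMm,
                 kernelSdMm = kernelSdMm, prescriptionGy = prescriptionGy),
            class = "ToyBeamSpec")
}

# in-plane rotation resampling of a volume's slices by angle (radians)
# about the grid centre; bilinear, outside filled with `fill`.
rotateSlices <- function(arr, sp, angle, fill = 0) {
  d <- dim(arr)
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  Xg <- matrix(rep(x, times = d[2]), d[1])
  Yg <- matrix(rep(y, each = d[1]), d[1])
  xs <- cos(angle) * Xg - sin(angle) * Yg
  ys <- sin(angle) * Xg + cos(angle) * Yg
  pts <- cbind(as.vector(xs / sp[1] + (d[1] + 1) / 2),
               as.vector(ys / sp[2] + (d[2] + 1) / 2))
  out <- array(fill, d)
  for (k in seq_len(d[3]))
    out[, , k] <- bilinearSample(arr[, , k], pts, fill = fill)
  out
}

#' Toy attenuation dose calculation
#'
#' Computes a dose grid from an HU volume with the parallel-beam
#' exponential model of [toyBeamSpec()]. When \code{scale} is NULL the dose
#' is normalized so the target point receives the prescription; to compare
#' two volumes under identical beam parameters, calibrate on the reference
#' and reuse the returned scale for the candidate (see [toyDosePair()]).
#'
#' @param volumeHu HU [ImageVolume].
#' @param curve a [CalibrationCurve] for HU to RED conversion.
#' @param beams a [toyBeamSpec()].
#' @param targetPoint physical (x, y, z) mm of the dose normalization
#'   point, typically the PTV centroid.
#' @param scale Gy per unit of raw engine output; NULL calibrates at the
#'   target point.
#' @param body optional body [BinaryMask]; if given, an error is raised
#'   when the target lies outside the body.
#' @return list with \code{dose} (Gy [ImageVolume]) and \code{scale}.
#' @export
toyDose <- function(volumeHu, curve = defaultCalibrationCurve(),
                    beams = toyBeamSpec(), targetPoint, scale = NULL,
                    body = NULL) {
  d <- dim(volumeHu@values); sp <- volumeHu@spacing; or <- volumeHu@origin
  tIdx <- round((targetPoint - or) / sp + 1)
  if (any(tIdx < 1 | tIdx > d))
    stop("target point outside the volume")
  if (!is.null(body) && !body@values[tIdx[1], tIdx[2], tIdx[3]])
    stop("target point outside the body")

  red <- huToRed(volumeHu, curve)@values
  angles <- (seq_len(beams$nBeams) - 1) * 2 * pi / beams$nBeams
  sigmaVox <- c(0, beams$kernelSdMm / sp[2], beams$kernelSdMm / sp[3])
  total <- array(0, d)
  for (a in angles) {
    redRot <- rotateSlices(red, sp, a, fill = 0)
    # radiological path from the beam entry edge to each voxel (midpoint rule)
    cum <- apply(redRot, c(2, 3), cumsum)
    path <- (cum - redRot / 2) * sp[1]
    dose <- redRot * exp(-beams$muPerMm * path)
    dose <- gaussianSmooth3d(dose, sigmaVox)
    total <- total + rotateSlices(dose, sp, -a, fill = 0)
  }
  if (is.null(scale)) {
    raw <- total[tIdx[1], tIdx[2], tIdx[3]]
    if (raw <= 0) stop("no dose reaches the target point")
    scale <- beams$prescriptionGy / raw
  }
  list(dose = imageVolume(total * scale, spacing = sp, origin = or,
                          unit = "Gy"),
       scale = scale)
}

#' @rdname toyDose
#' @param reference,candidate HU [ImageVolume]s; the scale is calibrated on
#'   the reference and reused for the candidate (identical beam parameters).
#' @return `toyDosePair()`: list with \code{ref} and \code{cand} dose
#'   [ImageVolume]s and the shared \code{scale}.
#' @export
toyDosePair <- function(reference, candidate, curve = defaultCalibrationCurve(),
                        beams = toyBeamSpec(), targetPoint, body = NULL) {
  r <- toyDose(reference, curve, beams, targetPoint, scale = NULL, body = body)
  c2 <- toyDose(candidate, curve, beams, targetPoint, scale = r$scale)
  list(ref = r$dose, cand = c2$dose, scale = r$scale)
}

#' Centroid of a mask in physical coordinates
#'
#' @param mask a [BinaryMask].
#' @return numeric (x, y, z) mm.
#' @export
maskCentroid <- function(mask) {
  idx <- which(mask@values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask '", mask@label, "'")
  mask@origin + (colMeans(idx) - 1) * mask@spacing
}
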