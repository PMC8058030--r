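# Internal geometry and array helpers shared across modules.

sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a@values), dim(b@values)) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

assertSameGrid <- function(a, b, what = "volumes") {
  if (!sameGrid(a, b))
    stop(what, " must share shape, spacing and origin; got dims ",
         paste(dim(a@values), collapse = "x"), " vs ",
         paste(dim(b@values), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

# Physical bounding box of voxel centres, rows = (min, max), cols = axes.
physicalExtent <- function(vol) {
  d <- dim(vol@values)
  rbind(vol@origin, vol@origin + (d - 1) * vol@spacing)
}

# Trilinear sampling of a 3D array at fractional 1-based index coordinates.
# pts: n x 3 matrix. Points outside the array return `fill` (default NA).
trilinearSample <- function(arr, pts, fill = NA_real_) {
  d <- dim(arr)
  i <- pts[, 1]; j <- pts[, 2]; k <- pts[, 3]
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]; k <- k[ok]
  i0 <- pmax(pmin(floor(i), d[1] - 1L), 1L)
  j0 <- pmax(pmin(floor(j), d[2] - 1L), 1L)
  k0 <- pmax(pmin(floor(k), d[3] - 1L), 1L)
  fx <- i - i0; fy <- j - j0; fz <- k - k0
  # upper corner clamped for singleton axes (its weight is then zero)
  dx <- as.numeric(i0 < d[1]); dy <- as.numeric(j0 < d[2]) * d[1]
  dz <- as.numeric(k0 < d[3]) * d[1] * d[2]
  n12 <- d[1] * d[2]
  base <- (i0 - 1) + (j0 - 1) * d[1] + (k0 - 1) * n12 + 1
  v000 <- arr[base];           v100 <- arr[base + dx]
  v010 <- arr[base + dy];      v110 <- arr[base + dy + dx]
  v001 <- arr[base + dz];      v101 <- arr[base + dz + dx]
  v011 <- arr[base + dy + dz]; v111 <- arr[base + dy + dz + dx]
  val <- (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                     fy * ((1 - fx) * v010 + fx * v110)) +
         fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
               fy * ((1 - fx) * v011 + fx * v111))
  out[ok] <- val
  out
}

# Bilinear sampling of a 2D matrix at fractional 1-based (row, col) points.
bilinearSample <- function(mat, pts, fill = NA_real_) {
  d <- dim(mat)
  i <- pts[, 1]; j <- pts[, 2]
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]
  i0 <- pmax(pmin(floor(i), d[1] - 1L), 1L)
  j0 <- pmax(pmin(floor(j), d[2] - 1L), 1L)
  fx <- i - i0; fy <- j - j0
  dx <- as.numeric(i0 < d[1]); dy <- as.numeric(j0 < d[2]) * d[1]
  base <- (i0 - 1) + (j0 - 1) * d[1] + 1
  v00 <- mat[base]; v10 <- mat[base + dx]
  v01 <- mat[base + dy]; v11 <- mat[base + dy + dx]
  out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v10) +
             fy * ((1 - fx) * v01 + fx * v11)
  out
}

# Nearest-neighbour lookup in a logical 3D array; outside -> FALSE.
nearestLogical <- function(arr, pts) {
  d <- dim(arr)
  i <- round(pts[, 1]); j <- round(pts[, 2]); k <- round(pts[, 3])
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(FALSE, nrow(pts))
  if (any(ok))
    out[ok] <- arr[cbind(i[ok], j[ok], k[ok])]
  out
}

# Surface voxels of a mask: TRUE voxels with at least one face-adjacent
# FALSE neighbour. `edgeIsOutside` controls whether positions beyond the
# grid count as outside (TRUE, the default, suits overlap metrics) or as
# continuation of the mask (FALSE, so a field-of-view clip is not treated
# as an anatomical surface).
maskSurface <- function(mask, edgeIsOutside = TRUE) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift1 <- function(m, axis, by) {
    out <- array(!edgeIsOutside, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    n <- d[axis]
    if (by == 1L) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
    else          { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (axis in 1:3)
    for (by in c(1L, -1L))
      interior <- interior & shift1(mask, axis, by)
  mask & !interior
}

# Largest 26-connected component of a logical array.
largestComponent <- function(mask, connectivity = 26L) {
  labels <- .cpp_label3d(mask, as.integer(connectivity))
  if (max(labels) == 0L) return(array(FALSE, dim(mask)))
  tab <- tabulate(labels[labels > 0L])
  out <- labels == which.max(tab)
  dim(out) <- dim(mask)
  out
}

# Distance (mm) from every voxel to the nearest TRUE voxel of `feature`.
distanceTo <- function(feature, spacing) {
  .cpp_edt3d(feature, as.numeric(spacing))
}

# Separable Gaussian smoothing with per-axis sigma in voxels (0 = skip axis).
gaussianSmooth3d <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- exp(-0.5 * ((-r):r / s)^2)
    kern <- kern / sum(kern)
    arr <- convolveAxis(arr, kern, axis)
  }
  arr
}

# Convolve along one axis with replicate (edge-clamp) padding.
convolveAxis <- function(arr, kern, axis) {
  d <- dim(arr)
  r <- (length(kern) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  n <- da[1]
  padTop <- m[rep(1L, r), , drop = FALSE]
  padBot <- m[rep(n, r), , drop = FALSE]
  mp <- rbind(padTop, m, padBot)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(kern))
    out <- out + kern[t] * mp[t:(t + n - 1L), , drop = FALSE]
  res <- array(out, da)
  aperm(res, order(perm))
}

fmtNum <- function(x, digits = 3) formatC(x, digits = digits, format = "fg")
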