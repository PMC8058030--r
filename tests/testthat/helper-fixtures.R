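# Programmatic fixtures shared across the suite. All randomness is locally
# seeded so tests are order-independent.

# uniform-value box volume with an embedded rectangular "body"
boxPhantom <- function(dims = c(20, 20, 6), spacing = c(1, 1, 1),
                       bodyHu = 0, backgroundHu = -1000,
                       bodyIdx = list(6:15, 6:15, seq_len(dims[3]))) {
  hu <- array(backgroundHu, dims)
  hu[bodyIdx[[1]], bodyIdx[[2]], bodyIdx[[3]]] <- bodyHu
  body <- array(FALSE, dims)
  body[bodyIdx[[1]], bodyIdx[[2]], bodyIdx[[3]]] <- TRUE
  list(vol = imageVolume(hu, spacing), body = binaryMask(body, spacing, label = "body"))
}

# water disk (single thick slice replicated) for WED tests
diskPhantom <- function(radiusMm = 50, spacingMm = 1, n = 128, nSlices = 3,
                        insideHu = 0, outsideHu = -1000) {
  cx <- (n + 1) / 2
  x <- (seq_len(n) - cx) * spacingMm
  X <- matrix(rep(x, times = n), n)
  Y <- matrix(rep(x, each = n), n)
  disk <- X^2 + Y^2 <= radiusMm^2
  hu <- array(outsideHu, c(n, n, nSlices))
  body <- array(FALSE, c(n, n, nSlices))
  for (k in seq_len(nSlices)) {
    hu[, , k][disk] <- insideHu
    body[, , k] <- disk
  }
  sp <- c(spacingMm, spacingMm, 3)
  list(vol = imageVolume(hu, sp), body = binaryMask(body, sp, label = "body"),
       disk = disk)
}

# smooth positive dose-like random field
smoothDose <- function(dims, seed, base = 60, amp = 6, spacing = c(2, 2, 2)) {
  set.seed(seed)
  f <- array(rnorm(prod(dims)), dims)
  f <- sctqa:::gaussianSmooth3d(f, c(1.5, 1.5, 1.5))
  imageVolume(base + amp * f / max(abs(f)), spacing, unit = "Gy")
}

# random blob mask on a small grid
randomMask <- function(dims, seed, p = 0.3, spacing = c(1, 1, 1), label = "m") {
  set.seed(seed)
  m <- array(runif(prod(dims)) < p, dims)
  binaryMask(m, spacing, label = label)
}

# brute-force directed Hausdorff over explicit surface point pairs
bruteHausdorff <- function(maskA, maskB) {
  sp <- spacing(maskA)
  pa <- which(sctqa:::maskSurface(voxels(maskA)), arr.ind = TRUE)
  pb <- which(sctqa:::maskSurface(voxels(maskB)), arr.ind = TRUE)
  pa <- sweep(pa - 1, 2, sp, "*")
  pb <- sweep(pb - 1, 2, sp, "*")
  dm <- as.matrix(dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                       nrow(pa) + seq_len(nrow(pb)),
                                       drop = FALSE]
  max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
}

# brute-force DVH point: linear interpolation of sorted doses vs volume
bruteDvhPoint <- function(doses, xPct) {
  s <- sort(doses, decreasing = TRUE)
  f <- seq_along(s) / length(s)
  if (xPct / 100 <= f[1]) s[1] else approx(f, s, xout = xPct / 100)$y
}

smallPhantomSpec <- function(seed = 1L, ...) {
  phantomSpec(dim = c(64L, 64L, 32L), spacing = c(3.75, 3.75, 4.5),
              seed = seed, ...)
}
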