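#' @include AllClasses.R
NULL

# periodic Gaussian low-pass of a 3D array via FFT
.gaussSmooth3d <- function(x, sigma) {
  dm <- dim(x)
  kern <- lapply(dm, function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
    exp(-2 * pi^2 * sigma^2 * k^2)
  })
  G <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
  dim(G) <- dm
  Re(fft(fft(x) * G, inverse = TRUE)) / prod(dm)
}

# periodic trilinear sampling of a 3D array at fractional voxel coordinates
.trilinearPeriodic <- function(vol, xi, yi, zi) {
  dm <- dim(vol)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  ix0 <- (x0 - 1) %% dm[1] + 1; ix1 <- x0 %% dm[1] + 1
  iy0 <- (y0 - 1) %% dm[2] + 1; iy1 <- y0 %% dm[2] + 1
  iz0 <- (z0 - 1) %% dm[3] + 1; iz1 <- z0 %% dm[3] + 1
  at <- function(i, j, k) vol[cbind(i, j, k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(ix0, iy0, iz0) +
                          fx       * at(ix1, iy0, iz0)) +
              fy       * ((1 - fx) * at(ix0, iy1, iz0) +
                          fx       * at(ix1, iy1, iz0))) +
  fz       * ((1 - fy) * ((1 - fx) * at(ix0, iy0, iz1) +
                          fx       * at(ix1, iy0, iz1)) +
              fy       * ((1 - fx) * at(ix0, iy1, iz1) +
                          fx       * at(ix1, iy1, iz1)))
}

#' Generate a speckle phantom pair with known displacement
#'
#' Builds a band-passed random speckle volume (difference-of-Gaussians of
#' seeded white noise, blob scale about 4-8 voxels so correlation peaks are
#' well conditioned) and warps it through a known displacement field:
#' `deformed(x) = reference(x - u(x))`, sampled with periodic trilinear
#' interpolation, so features move by `+u` voxels. An all-zero field gives
#' a bit-identical pair; an integer uniform shift gives a circularly rolled
#' copy.
#'
#' @param shape integer length-3 array dimensions.
#' @param trueDisplacement either `NULL` (zero field), a length-3 numeric
#'   (uniform shift, voxels), or a 4D array `c(shape, 3)` of per-voxel
#'   displacements in voxels. Magnitudes should stay small relative to the
#'   volume extent.
#' @param noiseLevel s.d. of additive Gaussian noise on the deformed
#'   volume, as a fraction of the speckle s.d.
#' @param blobSize characteristic speckle blob diameter, voxels.
#' @param voxelSize isotropic voxel size, micrometres (default 15).
#' @param seed integer seed; identical seeds give bit-identical pairs.
#' @return a [SpeckleVolumePair-class]
#' @export
generateSpeckleVolumePair <- function(shape, trueDisplacement = NULL,
                                      noiseLevel = 0, blobSize = 6,
                                      voxelSize = 15, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L))
  if (is.null(trueDisplacement)) trueDisplacement <- c(0, 0, 0)
  if (is.numeric(trueDisplacement) && is.null(dim(trueDisplacement))) {
    stopifnot(length(trueDisplacement) == 3L)
    u <- array(rep(trueDisplacement, each = prod(shape)), c(shape, 3L))
  } else {
    u <- trueDisplacement
    if (!identical(dim(u), c(shape, 3L)))
      stop("trueDisplacement must have shape c(shape, 3)")
  }

  set.seed(as.integer(seed))
  wn <- array(rnorm(prod(shape)), shape)
  sLo <- blobSize / 5
  sHi <- blobSize / 2
  ref <- .gaussSmooth3d(wn, sLo) - .gaussSmooth3d(wn, sHi)
  ref <- ref / sd(ref)

  if (all(u == 0)) {
    def <- ref
  } else {
    gx <- rep(seq_len(shape[1]), times = shape[2] * shape[3])
    gy <- rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3])
    gz <- rep(seq_len(shape[3]), each = shape[1] * shape[2])
    def <- .trilinearPeriodic(ref,
                              gx - as.vector(u[, , , 1]),
                              gy - as.vector(u[, , , 2]),
                              gz - as.vector(u[, , , 3]))
    dim(def) <- shape
  }
  if (noiseLevel > 0)
    def <- def + rnorm(length(def), 0, noiseLevel)

  new("SpeckleVolumePair",
      reference = ref, deformed = def, voxelSize = voxelSize,
      trueDisplacement = u,
      params = list(seed = seed, noiseLevel = noiseLevel,
                    blobSize = blobSize))
}
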