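#' @include AllClasses.R
NULL

# circular 3D cross-correlation via FFT; peak at the modal displacement
.windowCorrelation <- function(A, B) {
  Re(fft(Conj(fft(A)) * fft(B), inverse = TRUE)) / length(A)
}

# 3-point Gaussian sub-voxel refinement along one axis
.gaussRefine <- function(cm, c0, cp) {
  if (cm <= 0 || c0 <= 0 || cp <= 0 || c0 < cm || c0 < cp) {
    den <- cm - 2 * c0 + cp        # parabolic fallback
    if (den == 0) return(0)
    return(0.5 * (cm - cp) / den)
  }
  lm <- log(cm); l0 <- log(c0); lp <- log(cp)
  den <- lm - 2 * l0 + lp
  if (den == 0) return(0)
  0.5 * (lm - lp) / den
}

#' 3D cross-correlation velocimetry
#'
#' Measures the modal displacement of the material within cubic
#' interrogation regions between two volumes by windowed 3D
#' cross-correlation: for each region the mean-subtracted windows are
#' correlated in the frequency domain, the correlation peak offset is the
#' integer displacement, the moving window is re-extracted at that offset
#' (so the residual correlation peak is symmetric and integer shifts are
#' recovered exactly), and a 3-point Gaussian fit per axis refines the
#' residual peak to sub-voxel precision. At the default `window = 32` and `spacing = 16`
#' with 15 um voxels each region represents a 480 um cube on a 240 um
#' pitch. Equal correlation maxima are broken toward the lowest offset
#' norm. Flat (zero-variance) windows and windows not fully inside `mask`
#' are flagged invalid (`NA` displacement), never reported as zero.
#'
#' @param volA,volB 3D arrays of identical shape (successive gated
#'   volumes, or a [SpeckleVolumePair-class]'s reference/deformed pair).
#' @param window interrogation window edge, voxels (default 32).
#' @param spacing lattice pitch between window centres, voxels
#'   (default 16; must be <= `window`).
#' @param mask optional logical array; a region is valid only if its
#'   window lies entirely inside the mask.
#' @param maxShift largest displacement searched per axis, voxels
#'   (default `window %/% 4`).
#' @param voxelSize voxel size, micrometres (metadata only).
#' @return a [RegionGrid-class] with per-region displacement in voxels
#'   (positive = material moved toward increasing index from `volA` to
#'   `volB`).
#' @export
crossCorrelateDisplacement <- function(volA, volB, window = 32L,
                                       spacing = 16L, mask = NULL,
                                       maxShift = window %/% 4,
                                       voxelSize = 15) {
  if (!identical(dim(volA), dim(volB)))
    stop("volumes must have the same shape")
  window <- as.integer(window); spacing <- as.integer(spacing)
  if (spacing > window) stop("spacing must be <= window")
  dm <- dim(volA)
  if (any(window > dm)) stop("window must fit inside the volume")
  if (!is.null(mask) && !identical(dim(mask), dm))
    stop("mask must match the volume shape")

  nw <- (dm - window) %/% spacing + 1L
  starts <- lapply(1:3, function(a) 1L + (seq_len(nw[a]) - 1L) * spacing)
  nReg <- prod(nw)
  centers <- matrix(0, nReg, 3)
  disp <- matrix(NA_real_, nReg, 3)
  valid <- logical(nReg)

  sh <- c(-maxShift:maxShift)
  idxOf <- function(s, n) (s %% n) + 1L    # shift -> circular array index
  shIdx <- idxOf(sh, window)
  normGrid <- sqrt(outer(outer(sh^2, sh^2, "+"), sh^2, "+"))

  # integer peak of the circular correlation, restricted to a shift range
  intPeak <- function(A, B, shifts, idx, norms) {
    C <- .windowCorrelation(A - mean(A), B - mean(B))
    Cs <- C[idx, idx, idx]
    m <- max(Cs)
    cand <- which(Cs == m)
    if (length(cand) > 1L) cand <- cand[which.min(norms[cand])]
    list(u = shifts[as.vector(arrayInd(cand, dim(Cs)))], C = C, m = m)
  }
  shRes <- -(maxShift + 3L):(maxShift + 3L)  # residual range, second pass
  shResIdx <- idxOf(shRes, window)
  normRes <- sqrt(outer(outer(shRes^2, shRes^2, "+"), shRes^2, "+"))

  r <- 0L
  for (k in starts[[3]]) for (j in starts[[2]]) for (i in starts[[1]]) {
    r <- r + 1L
    centers[r, ] <- c(i, j, k) + (window - 1) / 2
    wi <- i:(i + window - 1L); wj <- j:(j + window - 1L)
    wk <- k:(k + window - 1L)
    if (!is.null(mask) && !all(mask[wi, wj, wk])) next
    A <- volA[wi, wj, wk]; B <- volB[wi, wj, wk]
    if (var(as.vector(A)) == 0 || var(as.vector(B)) == 0) next
    u0 <- intPeak(A, B, sh, shIdx, normGrid)$u
    # second pass: re-extract the moving window at the integer offset so
    # the residual correlation peak is symmetric (unbiased sub-voxel fit)
    off <- pmax(pmin(u0, dm - window + 1L - c(i, j, k)),
                1L - c(i, j, k))
    B2 <- volB[wi + off[1], wj + off[2], wk + off[3]]
    if (var(as.vector(B2)) == 0) next
    p2 <- intPeak(A, B2, shRes, shResIdx, normRes)
    u1 <- p2$u
    for (a in 1:3) {
      sm <- u1; sp <- u1
      sm[a] <- u1[a] - 1L; sp[a] <- u1[a] + 1L
      cm <- p2$C[idxOf(sm[1], window), idxOf(sm[2], window),
                 idxOf(sm[3], window)]
      cp <- p2$C[idxOf(sp[1], window), idxOf(sp[2], window),
                 idxOf(sp[3], window)]
      disp[r, a] <- off[a] + u1[a] + .gaussRefine(cm, p2$m, cp)
    }
    valid[r] <- TRUE
  }

  new("RegionGrid",
      centersVoxel = centers, gridDim = nw, window = window,
      spacing = spacing, displacement = disp, valid = valid,
      expansion = rep(NA_real_, nReg),
      params = list(voxelSize = voxelSize, maxShift = maxShift,
                    pitch_um = spacing * voxelSize,
                    window_um = window * voxelSize))
}

# one lattice derivative with central differences, one-sided at edges /
# next to invalid neighbours; x is (n1,n2,n3) with NA marking invalid
.latticeGradient <- function(x, axis, h) {
  dm <- dim(x)
  shift <- function(dir) {
    idx <- lapply(dm, seq_len)
    idx[[axis]] <- idx[[axis]] + dir
    out <- array(NA_real_, dm)
    ok <- idx[[axis]] >= 1L & idx[[axis]] <= dm[axis]
    sel <- lapply(dm, seq_len)
    sel[[axis]] <- which(ok)
    src <- sel
    src[[axis]] <- idx[[axis]][ok]
    do.call(`[<-`, c(list(out), sel, list(do.call(`[`, c(list(x), src)))))
  }
  up <- shift(1L)    # value at i+1
  dn <- shift(-1L)   # value at i-1
  g <- (up - dn) / (2 * h)
  oneUp <- is.na(dn) & !is.na(up) & !is.na(x)
  g[oneUp] <- (up[oneUp] - x[oneUp]) / h
  oneDn <- is.na(up) & !is.na(dn) & !is.na(x)
  g[oneDn] <- (x[oneDn] - dn[oneDn]) / h
  g
}

#' Volumetric expansion from a displacement lattice
#'
#' Computes the fractional volume change of each region from the local
#' displacement gradients: `expansion = det(I + grad u) - 1`, with
#' `grad u` estimated by central finite differences on the region lattice
#' (one-sided at lattice edges and next to invalid regions). The
#' determinant form is exact at finite strain and reduces to the trace
#' (divergence) for small strains; any rigid translation gives exactly
#' zero expansion. Regions whose gradient cannot be estimated (isolated
#' valid regions) keep `NA`.
#'
#' @param grid a [RegionGrid-class] from [crossCorrelateDisplacement()].
#' @param spacing lattice pitch in voxels (defaults to the grid's).
#' @return the grid with its `expansion` slot filled; metadata records the
#'   determinant definition.
#' @export
expansionFromDisplacement <- function(grid, spacing = grid@spacing) {
  stopifnot(is(grid, "RegionGrid"))
  dm <- grid@gridDim
  G <- array(NA_real_, c(dm, 3, 3))
  for (comp in 1:3) {
    u <- grid@displacement[, comp]
    u[!grid@valid] <- NA_real_
    dim(u) <- dm
    for (axis in 1:3)
      G[, , , comp, axis] <- .latticeGradient(u, axis, spacing)
  }
  n <- prod(dm)
  dim(G) <- c(n, 3, 3)
  expansion <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    g <- G[r, , ]
    if (any(is.na(g))) next
    expansion[r] <- det(diag(3) + g) - 1
  }
  grid@expansion <- expansion
  grid@params$expansionDefinition <- "det(I + grad u) - 1"
  grid
}
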