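# hand-built displacement lattice for expansion tests
latticeGrid <- function(nw = c(5, 5, 5), spacing = 16L, window = 16L,
                        ufun = function(x, y, z) cbind(0, 0, 0)) {
  centers <- as.matrix(expand.grid(
    x = (seq_len(nw[1]) - 1) * spacing,
    y = (seq_len(nw[2]) - 1) * spacing,
    z = (seq_len(nw[3]) - 1) * spacing))
  # expand.grid varies x fastest, matching the array layout used by
  # expansionFromDisplacement (dim = nw)
  u <- ufun(centers[, 1], centers[, 2], centers[, 3])
  new("RegionGrid", centersVoxel = centers, gridDim = as.integer(nw),
      window = as.integer(window), spacing = as.integer(spacing),
      displacement = u, valid = rep(TRUE, nrow(centers)),
      expansion = rep(NA_real_, nrow(centers)), params = list())
}

test_that("identical volumes give zero displacement in every region", {
  sp <- generateSpeckleVolumePair(c(48, 48, 48), seed = 1)
  g <- crossCorrelateDisplacement(sp@reference, sp@reference,
                                  window = 16, spacing = 16)
  expect_true(all(g@valid))
  expect_equal(max(abs(g@displacement)), 0, tolerance = 1e-9)
})

test_that("integer shifts are recovered exactly in interior regions", {
  s <- c(3, -2, 5)
  sp <- generateSpeckleVolumePair(c(96, 96, 96), s, seed = 4)
  g <- crossCorrelateDisplacement(sp@reference, sp@deformed)
  ctr <- g@centersVoxel
  interior <- ctr[, 1] > 24 & ctr[, 1] < 72 & ctr[, 2] > 24 &
    ctr[, 2] < 72 & ctr[, 3] > 24 & ctr[, 3] < 72
  expect_true(any(interior))
  err <- abs(sweep(g@displacement[interior, , drop = FALSE], 2, s))
  expect_lt(max(err), 1e-9)
})

test_that("flat windows and masked-out windows are flagged invalid, not zero", {
  vol <- array(0, c(32, 32, 32))
  sp <- generateSpeckleVolumePair(c(32, 32, 32), seed = 2)
  g <- crossCorrelateDisplacement(vol, vol, window = 32, spacing = 16)
  expect_false(any(g@valid))
  expect_true(all(is.na(g@displacement)))
  mask <- array(FALSE, c(32, 32, 32))
  g2 <- crossCorrelateDisplacement(sp@reference, sp@deformed,
                                   window = 32, spacing = 16, mask = mask)
  expect_false(any(g2@valid))
})

test_that("rigid translation yields exactly zero expansion", {
  g <- latticeGrid(ufun = function(x, y, z) cbind(x * 0 + 3.2, -1.5, 0.7))
  g <- expansionFromDisplacement(g)
  expect_lt(max(abs(g@expansion)), 1e-12)
})

test_that("uniform dilation reproduces the closed-form volume change", {
  a <- 0.01
  g <- latticeGrid(ufun = function(x, y, z) cbind(a * x, a * y, a * z))
  g <- expansionFromDisplacement(g)
  expect_equal(unique(round(g@expansion, 12)), (1 + a)^3 - 1,
               tolerance = 1e-9)
})

test_that("pure shear has zero volumetric expansion", {
  g <- latticeGrid(ufun = function(x, y, z) cbind(0.05 * y, 0 * x, 0 * x))
  g <- expansionFromDisplacement(g)
  expect_lt(max(abs(g@expansion)), 1e-12)
})

test_that("frequency-domain correlation matches plain spatial correlation", {
  set.seed(6)
  A <- array(rnorm(6^3), c(6, 6, 6))
  B <- array(rnorm(6^3), c(6, 6, 6))
  C <- pendelluft:::.windowCorrelation(A, B)
  # brute-force circular correlation at a few shifts
  for (s in list(c(0, 0, 0), c(1, 0, 0), c(2, -1, 3))) {
    idx <- lapply(1:3, function(a) ((seq_len(6) - 1 + s[a]) %% 6) + 1)
    manual <- sum(A * B[idx[[1]], idx[[2]], idx[[3]]])
    expect_equal(C[(s[1] %% 6) + 1, (s[2] %% 6) + 1, (s[3] %% 6) + 1],
                 manual, tolerance = 1e-9)
  }
})
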