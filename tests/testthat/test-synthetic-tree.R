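test_that("the smallest tree is a single trachea with no bifurcations", {
  tr <- generateAirwayTree(1, seed = 1)
  expect_equal(nSegments(tr), 1L)
  seg <- segmentTable(tr)
  expect_true(is.na(seg$parent_id))
  expect_equal(seg$generation, 0L)
  expect_length(terminalIds(tr), 0L)   # the trachea has no parent
})

test_that("terminal radii follow the closed-form contraction and land in the distal band", {
  r0 <- 0.6; ratio <- 0.83; nGen <- 15L
  tr <- generateAirwayTree(nGen, tracheaRadius = r0, radiusRatio = ratio,
                           seed = 3)
  seg <- segmentTable(tr)
  expect_equal(max(seg$generation), nGen - 1L)
  termR <- seg$radius_mm[seg$id %in% terminalIds(tr)]
  expect_equal(unique(termR), r0 * ratio^(nGen - 1L), tolerance = 1e-12)
  # generation-14 terminals: diameter within the 85-100 um band
  dUm <- 2000 * unique(termR)
  expect_gt(dUm, 85)
  expect_lt(dUm, 100)
})

test_that("tree generation is deterministic in the seed", {
  a <- generateAirwayTree(5, seed = 42)
  b <- generateAirwayTree(5, seed = 42)
  expect_identical(segmentTable(a), segmentTable(b))
  c <- generateAirwayTree(5, seed = 43)
  expect_false(identical(segmentTable(a), segmentTable(c)))
})

test_that("invalid generation parameters are rejected", {
  expect_error(generateAirwayTree(0), "nGenerations")
  expect_error(generateAirwayTree(3, tracheaRadius = 0), "tracheaRadius")
  expect_error(generateAirwayTree(3, radiusRatio = 1), "radiusRatio")
  expect_error(generateAirwayTree(3, radiusRatio = -0.1), "radiusRatio")
})

test_that("the segment table validity invariants are enforced", {
  tr <- generateAirwayTree(3, seed = 1)
  seg <- segmentTable(tr)
  bad <- seg; bad$radius_mm[2] <- -1
  expect_error(AirwayTree(bad), "radii")
  bad <- seg; bad$parent_id[1] <- NA; bad$parent_id[2] <- NA
  expect_error(AirwayTree(bad), "root|parent")
  bad <- seg; bad$generation[2] <- 5L
  expect_error(AirwayTree(bad), "generation")
  bad <- seg[seg$id != 7L, ]            # drop one leaf: single-child node
  expect_error(AirwayTree(bad), "0 or 2 children")
})

test_that("trees round-trip through the CSV edge list", {
  tr <- generateAirwayTree(4, seed = 7)
  path <- tempfile(fileext = ".csv")
  writeAirwayTree(tr, path)
  tr2 <- readAirwayTree(path)
  expect_equal(segmentTable(tr2), segmentTable(tr), tolerance = 1e-12)
  unlink(path)
})
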