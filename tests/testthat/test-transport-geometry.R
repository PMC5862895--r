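test_that("cylinder simplification preserves volume and topology", {
  tr <- generateAirwayTree(4, seed = 1)
  geom <- simplifyGeometry(tr)
  expect_equal(as.numeric(gasVolume(geom)), gasVolume(tr),
               tolerance = 1e-12)
  # closed-form total volume
  seg <- segmentTable(tr)
  len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 +
                (seg$z2 - seg$z1)^2)
  expect_equal(as.numeric(gasVolume(geom)),
               sum(pi * seg$radius_mm^2 * len), tolerance = 1e-12)
  # child counts preserved per node
  el <- geom@elements
  kidsGeom <- table(factor(el$parent, levels = el$elem))
  kidsTree <- table(factor(match(seg$parent_id, seg$id),
                           levels = seq_len(nrow(seg))))
  expect_equal(as.integer(kidsGeom), as.integer(kidsTree))
})

test_that("trumpet attachment builds one compartment per terminal with the right volume", {
  tr <- generateAirwayTree(3, seed = 2)
  tab <- makeTrumpetTable(2, 6, startDiameter = 0.2, startLength = 0.5)
  geom <- attachTrumpetModel(simplifyGeometry(tr), tab)
  nT <- length(terminalIds(tr))
  expect_equal(nrow(geom@compartments), nT)
  # quadrature: trumpet volume is the piecewise sum of area x length
  v <- gasVolume(geom)
  expect_equal(as.numeric(v) - gasVolume(tr),
               nT * sum(tab$area_mm2 * tab$length_mm), tolerance = 1e-12)
  expect_equal(unique(geom@compartments$area_mm2),
               tab$area_mm2[nrow(tab)])
  # equal areas at all generations: the trumpet degenerates to a cylinder
  tabEq <- data.frame(generation = 3:6, area_mm2 = 0.05, length_mm = 0.4)
  geomEq <- attachTrumpetModel(simplifyGeometry(tr), tabEq)
  expect_equal(as.numeric(gasVolume(geomEq)) - gasVolume(tr),
               nT * 0.05 * 1.6, tolerance = 1e-12)
})

test_that("trumpet table defects are rejected", {
  tr <- generateAirwayTree(2, seed = 1)
  geom <- simplifyGeometry(tr)
  tab <- makeTrumpetTable(1, 5)
  expect_error(attachTrumpetModel(geom, tab[-2, ]), "contiguous")
  expect_error(attachTrumpetModel(geom, tab[, 1:2]), "columns")
  badArea <- tab; badArea$area_mm2[2] <- -1
  expect_error(attachTrumpetModel(geom, badArea), "> 0")
  # decreasing area violates the trumpet invariant (validity method)
  dec <- tab; dec$area_mm2 <- rev(sort(dec$area_mm2))
  expect_error(attachTrumpetModel(geom, dec), "non-decreasing")
})

test_that("the default trumpet table grows in area toward the periphery", {
  tab <- makeTrumpetTable()
  expect_equal(tab$generation, 15:23)
  expect_true(all(diff(tab$area_mm2) > 0))
  expect_true(all(diff(tab$length_mm) < 0))
  # self-similar closed form for the first piece
  expect_equal(tab$area_mm2[1], 2 * pi / 4 * (0.095 * 0.85)^2,
               tolerance = 1e-12)
})

test_that("Womersley numbers follow the closed form and flag fast oscillations", {
  geom <- singleCylinderGeometry(radius = 0.6, length = 10)
  f <- 7.5
  expect_equal(womersleyNumbers(geom, f),
               0.6 * sqrt(2 * pi * f / 15.6), tolerance = 1e-12)
  st <- seedTracers(geom, quantum = 0.5, seed = 1)
  fl <- constantFlowSeries(1L, 0.5, period = 1000 / f)
  cfg <- transportConfig(D = 0, dt = 1, quantum = 0.5)
  expect_warning(
    runTransport(geom, fl, cfg, duration = 2, state = st, seed = 1),
    "Womersley")
})
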