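test_that("regions map to the nearest terminal airway, ties to the lower id", {
  tr <- generateAirwayTree(2, seed = 1)      # terminals 2 and 3
  seg <- segmentTable(tr)
  ends <- as.matrix(seg[match(c(2L, 3L), seg$id), c("x2", "y2", "z2")])
  set.seed(1)
  centers <- matrix(rnorm(30), 10, 3)
  expect_true(all(assignRegionsToTerminals(centers, tr) %in% c(2L, 3L)))
  # a region at a terminal's own end point maps to that terminal
  expect_equal(assignRegionsToTerminals(ends[2, , drop = FALSE], tr), 3L)
  # exact tie: midpoint of the two terminal end points goes to id 2
  mid <- matrix(colMeans(ends), 1, 3)
  expect_equal(assignRegionsToTerminals(mid, tr), 2L)
  expect_error(assignRegionsToTerminals(matrix(0, 0, 3), tr), "non-empty")
})

test_that("region assignment equals a brute-force nearest-endpoint search", {
  for (seed in 1:3) {
    tr <- randomBinaryTree(8, seed = seed)
    set.seed(seed + 100)
    centers <- matrix(rnorm(300, sd = 2), 100, 3)
    got <- assignRegionsToTerminals(centers, tr)
    seg <- segmentTable(tr)
    tids <- terminalIds(tr)
    ends <- as.matrix(seg[match(tids, seg$id), c("x2", "y2", "z2")])
    ref <- apply(centers, 1, function(p) {
      d <- colSums((t(ends) - p)^2)
      tids[which.min(d)]
    })
    expect_identical(got, ref)
  }
})

test_that("terminal flow is the time derivative of assigned region volumes", {
  # constant volumes -> zero flow
  V <- matrix(5, 3, 19)
  tt <- (0:18) / 19 * 400
  fl <- computeTerminalFlows(V, map = c(1L, 1L, 1L), times = tt,
                             period = 400)
  expect_equal(max(abs(flowMatrix(fl))), 0)
  # V = V0 + A sin(wt) -> Q = A w cos(wt) within 1% at 19 phases
  w <- 2 * pi / 400; A <- 3
  V1 <- matrix(10 + A * sin(w * tt), 1)
  fl1 <- computeTerminalFlows(V1, map = 7L, times = tt, period = 400)
  expect_lt(max(abs(flowMatrix(fl1) - A * w * cos(w * tt))) / (A * w),
            0.01)
  # linearity: two regions on one terminal sum their flows
  V2 <- rbind(V1, 2 * V1)
  fl2 <- computeTerminalFlows(V2, map = c(7L, 7L), times = tt,
                              period = 400)
  expect_equal(flowMatrix(fl2), 3 * flowMatrix(fl1), tolerance = 1e-12)
  expect_error(computeTerminalFlows(V[, 1, drop = FALSE], map = rep(1L, 3),
                                    times = 0, period = 400), "2 phases")
})

test_that("flow propagation sums daughters into parents", {
  tr <- generateAirwayTree(2, seed = 1)
  tf <- constantFlowSeries(c(2L, 3L), c(1, 2))
  fl <- propagateFlows(tr, tf)
  expect_equal(flowMatrix(fl)[match(1L, airwayIds(fl)), ], c(3, 3))
  # sign symmetry: negating the terminals negates every segment
  tfNeg <- constantFlowSeries(c(2L, 3L), c(-1, -2))
  expect_equal(flowMatrix(propagateFlows(tr, tfNeg)),
               -flowMatrix(fl), tolerance = 1e-12)
  expect_error(propagateFlows(tr, constantFlowSeries(2L, 1)), "id")
})

test_that("propagated flows equal the brute-force descendant-terminal sums", {
  for (seed in 1:5) {
    tr <- randomBinaryTree(12, seed = seed)
    tids <- terminalIds(tr)
    set.seed(seed)
    tf <- new("FlowSeries", airwayIds = tids,
              times = c(0, 100, 200, 300),
              flows = matrix(rnorm(4 * length(tids)), length(tids), 4),
              period = 400, params = list())
    fl <- propagateFlows(tr, tf)
    ref <- bruteForceSegmentFlows(tr, tf)
    expect_equal(flowMatrix(fl)[match(as.integer(rownames(ref)),
                                      airwayIds(fl)), ],
                 unname(ref), tolerance = 1e-12)
  }
})

test_that("volume metrics reproduce the closed forms", {
  tt <- (0:199) / 200 * 2 * pi * 1000
  V <- matrix(1000 + 100 * sin(tt / 1000), 1)     # ml-scale in mm^3
  vm <- computeVolumeMetrics(V, cycleFrequency = 150, times = tt)
  expect_equal(vm@tidalVolume, 0.2, tolerance = 1e-3)
  expect_equal(vm@minuteVolume, vm@tidalVolume * 150, tolerance = 1e-12)
  expect_equal(computeVolumeMetrics(matrix(5, 2, 4), cycleFrequency = 150,
                                    times = 1:4)@tidalVolume, 0)
  # displacement: path length of the centre track over the cycle
  ct <- array(0, c(1, 3, 4))
  ct[1, 1, ] <- c(0, 1, 1, 0)                     # 1 mm out and back
  vm2 <- computeVolumeMetrics(matrix(5, 1, 4), cycleFrequency = 150,
                              times = 1:4, centerTrack = ct)
  expect_equal(vm2@regionDisplacement, 2000)      # um
})

test_that("bifurcation decomposition reproduces the three flow regimes", {
  q <- 2
  bulk <- decomposeBifurcationFlow(q, q / 2, q / 2)
  expect_equal(bulk$Qtot, 2 * q)
  expect_equal(bulk$Qbulk, 2 * q)
  expect_equal(bulk$Qpend, 0)
  pend <- decomposeBifurcationFlow(0, q, -q)
  expect_equal(pend$Qbulk, 0)
  expect_equal(pend$Qpend, 2 * q)
  mixed <- decomposeBifurcationFlow(1, 2, -1)
  expect_equal(unlist(mixed), c(Qtot = 4, Qbulk = 2, Qpend = 2))
  expect_error(decomposeBifurcationFlow(1, 2, 2), "continuity")
})

test_that("decomposition identities hold at every time on random flows", {
  set.seed(3)
  for (k in 1:20) {
    qB <- rnorm(10); qC <- rnorm(10); qA <- qB + qC
    d <- decomposeBifurcationFlow(qA, qB, qC)
    expect_equal(d$Qtot, d$Qbulk + d$Qpend, tolerance = 1e-15)
    expect_true(all(d$Qpend >= -1e-15))
    expect_true(all(d$Qpend <= d$Qtot + 1e-15))
  }
})

test_that("whole-tree aggregation captures synchrony, antiphase and time reversal", {
  tr <- generateAirwayTree(2, seed = 1)
  tt <- (0:39) / 40 * 400
  # synchronous expansion: positive multiples of one waveform -> no pendelluft
  w <- sin(2 * pi * tt / 400)
  tfS <- new("FlowSeries", airwayIds = c(2L, 3L), times = tt,
             flows = rbind(1.3 * w, 0.4 * w), period = 400, params = list())
  dS <- aggregateFlowDecomposition(propagateFlows(tr, tfS), tr)
  expect_lt(dS@totals[["Qpend"]], 1e-12 * dS@totals[["Qtot"]])
  # equal-amplitude antiphase -> pure pendelluft
  tfA <- new("FlowSeries", airwayIds = c(2L, 3L), times = tt,
             flows = rbind(w, -w), period = 400, params = list())
  dA <- aggregateFlowDecomposition(propagateFlows(tr, tfA), tr)
  expect_lt(dA@totals[["Qbulk"]], 1e-12)
  expect_equal(dA@pendelluftFraction, 1)
  # time reversal leaves all three components unchanged
  tfR <- new("FlowSeries", airwayIds = c(2L, 3L), times = tt,
             flows = rbind(rev(w), rev(-w)), period = 400, params = list())
  dR <- aggregateFlowDecomposition(propagateFlows(tr, tfR), tr)
  expect_equal(dR@totals, dA@totals, tolerance = 1e-12)
})

test_that("continuity closure: root flow equals the lung volume derivative", {
  tr <- generateAirwayTree(4, seed = 2)
  f <- generateExpansionField(tr, seed = 3)
  map <- assignRegionsToTerminals(f, tr)
  fl <- propagateFlows(tr, computeTerminalFlows(f, map))
  rootQ <- flowMatrix(fl)[match(1L, airwayIds(fl)), ]
  dV <- pendelluft:::.periodicDeriv(
    matrix(colSums(regionVolumes(f)), 1), phaseTimes(f), cyclePeriod(f))
  expect_lt(sqrt(mean((rootQ - dV)^2)) / max(abs(dV)), 0.01)
})
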