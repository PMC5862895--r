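# shared fixtures: random trees, hand-built geometries and tracer states

# random rooted binary tree grown by splitting random terminals;
# every interior node has exactly 2 children
randomBinaryTree <- function(nTerminals, seed = 1L) {
  set.seed(seed)
  seg <- data.frame(id = 1L, parent_id = NA_integer_,
                    x1 = 0, y1 = 0, z1 = 0, x2 = 0, y2 = 0, z2 = 3,
                    radius_mm = 0.5, generation = 0L)
  while (sum(!(seg$id %in% seg$parent_id)) -
         sum(is.na(seg$parent_id) & !(seg$id %in% seg$parent_id)) + 1L <
         nTerminals) {
    term <- seg$id[!(seg$id %in% seg$parent_id)]
    p <- if (length(term) == 1L) term else sample(term, 1L)
    pr <- seg[seg$id == p, ]
    d <- c(pr$x2 - pr$x1, pr$y2 - pr$y1, pr$z2 - pr$z1)
    d <- d / sqrt(sum(d^2))
    for (k in 1:2) {
      nd <- d + rnorm(3, 0, 0.6)
      nd <- nd / sqrt(sum(nd^2))
      len <- runif(1, 0.5, 1.5) * 0.8
      seg <- rbind(seg, data.frame(
        id = max(seg$id) + 1L, parent_id = p,
        x1 = pr$x2, y1 = pr$y2, z1 = pr$z2,
        x2 = pr$x2 + len * nd[1], y2 = pr$y2 + len * nd[2],
        z2 = pr$z2 + len * nd[3],
        radius_mm = pr$radius_mm * runif(1, 0.6, 0.85),
        generation = pr$generation + 1L))
    }
  }
  AirwayTree(seg)
}

# brute-force flow through every segment: sum over descendant terminals
bruteForceSegmentFlows <- function(tree, terminalFlows) {
  seg <- segmentTable(tree)
  tids <- terminalIds(tree)
  Q <- flowMatrix(terminalFlows)
  descendantTerminals <- function(id) {
    kids <- seg$id[!is.na(seg$parent_id) & seg$parent_id == id]
    if (length(kids) == 0L) return(id)
    unlist(lapply(kids, descendantTerminals))
  }
  out <- matrix(0, nrow(seg), ncol(Q))
  for (i in seq_len(nrow(seg))) {
    dt <- intersect(descendantTerminals(seg$id[i]), tids)
    out[i, ] <- colSums(Q[match(dt, airwayIds(terminalFlows)), ,
                          drop = FALSE])
  }
  rownames(out) <- seg$id
  out
}

# single sealed cylinder as a transport geometry
singleCylinderGeometry <- function(radius = 1, length = 50) {
  seg <- data.frame(id = 1L, parent_id = NA_integer_,
                    x1 = 0, y1 = 0, z1 = 0, x2 = 0, y2 = 0, z2 = length,
                    radius_mm = radius, generation = 0L)
  simplifyGeometry(AirwayTree(seg))
}

constantFlowSeries <- function(ids, q, period = 400) {
  new("FlowSeries", airwayIds = as.integer(ids), times = c(0, period / 2),
      flows = matrix(rep(q, each = 2), length(ids), 2, byrow = TRUE),
      period = period, params = list())
}

# tracer state at explicit coordinates
makeTracerState <- function(elem, z, rrel, theta = 0, type = 1L,
                            nComp = 0L) {
  n <- max(length(elem), length(z), length(rrel), length(theta))
  new("TracerState",
      type = rep_len(as.integer(type), n),
      elem = rep_len(as.integer(elem), n),
      z = rep_len(z, n), rrel = rep_len(rrel, n),
      theta = rep_len(theta, n),
      tallyA = numeric(nComp), tallyB = numeric(nComp),
      tracheaAccumulator = 0, compartmentOutflux = numeric(nComp),
      counts = c(seeded = n, injected = 0, expiredA = 0, expiredB = 0,
                 heldAtJunction = 0, forfeitedSubSteps = 0,
                 emptyReleases = 0, diffusiveExchanges = 0))
}

# one-airway + one-compartment washout toy (degenerate trumpet)
washoutToy <- function(radius = 0.15, length = 12, trumpetLen = 0.5,
                       compVolume = 25) {
  seg <- data.frame(id = 1L, parent_id = NA_integer_,
                    x1 = 0, y1 = 0, z1 = 0, x2 = 0, y2 = 0, z2 = length,
                    radius_mm = radius, generation = 0L)
  tree <- AirwayTree(seg)
  tab <- data.frame(generation = 1L, area_mm2 = pi * radius^2,
                    length_mm = trumpetLen)
  list(tree = tree,
       geometry = attachTrumpetModel(simplifyGeometry(tree), tab,
                                     compartmentVolume = compVolume))
}

# brute-force per-frame double gating (independent oracle)
bruteForceGating <- function(log, nVent = 19L, nCard = 8L, pmax = 4) {
  phaseOf <- function(t, trig) {
    if (t < trig[1]) return(NA_real_)
    i <- max(which(trig <= t))
    if (i < length(trig)) return((t - trig[i]) / (trig[i + 1] - trig[i]))
    med <- median(diff(trig))
    ((t - trig[length(trig)]) / med) %% 1
  }
  n <- length(log@frameTimes)
  vent <- card <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pv <- phaseOf(log@frameTimes[i], log@ventTriggerTimes)
    if (!is.na(pv)) vent[i] <- as.integer(min(floor(pv * nVent), nVent - 1))
    pc <- phaseOf(log@frameTimes[i], log@ecgRpeakTimes)
    if (!is.na(pc) && log@airwayPressure[i] < pmax)
      card[i] <- as.integer(min(floor(pc * nCard), nCard - 1))
  }
  list(vent = vent, card = card)
}

# bin-assignment vectors from a GatingResult, for oracle comparison
binVectors <- function(g, n) {
  vent <- card <- rep(NA_integer_, n)
  for (b in seq_along(g@ventBins)) vent[g@ventBins[[b]]] <- b - 1L
  for (b in seq_along(g@cardBins)) card[g@cardBins[[b]]] <- b - 1L
  list(vent = vent, card = card)
}
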