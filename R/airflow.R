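#' @include expansion-field.R velocimetry.R
NULL

#' Assign tissue regions to their supplying terminal airways
#'
#' Each region is associated with its closest supplying airway: the
#' terminal segments (a parent but no daughters) are the airways feeding
#' the imaged tissue, and the region maps to the one whose distal end
#' point is nearest in Euclidean distance. Exact ties go to the lower
#' airway id.
#'
#' @param regionCenters numeric matrix (nRegions x 3), mm, or an
#'   [ExpansionField-class].
#' @param tree an [AirwayTree-class] with at least one terminal airway.
#' @return integer vector of terminal airway ids, one per region
#' @export
assignRegionsToTerminals <- function(regionCenters, tree) {
  if (is(regionCenters, "ExpansionField"))
    regionCenters <- regionCenters@regionCenters
  if (!is.matrix(regionCenters) || nrow(regionCenters) == 0L)
    stop("region set must be a non-empty n x 3 matrix")
  seg <- segmentTable(tree)
  tids <- terminalIds(tree)
  if (length(tids) == 0L) stop("tree has no terminal airway")
  ends <- as.matrix(seg[match(tids, seg$id), c("x2", "y2", "z2")])
  # distance matrix regions x terminals; ties resolved by lower id because
  # tids is sorted and which.min returns the first minimum
  d2 <- outer(rowSums(regionCenters^2), rep(1, length(tids))) -
    2 * regionCenters %*% t(ends) +
    outer(rep(1, nrow(regionCenters)), rowSums(ends^2))
  tids[apply(d2, 1, which.min)]
}

# periodic time derivative of each row of V sampled at times over period T;
# 5-point 4th-order central stencil on uniform grids, local 3-point weights
# on non-uniform grids
.periodicDeriv <- function(V, times, period) {
  P <- length(times)
  if (P < 2L) stop("at least 2 phases are required")
  h <- diff(c(times, times[1] + period))
  uniform <- diff(range(h)) < 1e-9 * mean(h)
  if (uniform && P >= 5L) {
    hh <- h[1]
    idx <- function(s) ((seq_len(P) - 1 + s) %% P) + 1
    (V[, idx(-2), drop = FALSE] - 8 * V[, idx(-1), drop = FALSE] +
       8 * V[, idx(1), drop = FALSE] - V[, idx(2), drop = FALSE]) / (12 * hh)
  } else {
    out <- V * 0
    for (i in seq_len(P)) {
      im <- if (i == 1L) P else i - 1L
      ip <- if (i == P) 1L else i + 1L
      h1 <- h[im]; h2 <- h[i]
      out[, i] <- -h2 / (h1 * (h1 + h2)) * V[, im] +
        (h2 - h1) / (h1 * h2) * V[, i] +
        h1 / (h2 * (h1 + h2)) * V[, ip]
    }
    out
  }
}

#' Terminal airway flows from regional expansion
#'
#' The expansion of the regions supplied by a terminal airway equals the
#' flow through that airway: `Q_terminal(t) = d/dt sum(V_region(t))` over
#' its assigned regions, positive while the regions inflate (flow directed
#' trachea to periphery). The derivative treats the cycle as periodic and
#' uses high-order central differences (local weights on non-uniform phase
#' grids).
#'
#' @param field an [ExpansionField-class] (or a volume matrix with
#'   `times`/`period` supplied).
#' @param map terminal airway id per region, from
#'   [assignRegionsToTerminals()].
#' @param times,period phase times and cycle period, ms (defaulted from
#'   `field`).
#' @return a [FlowSeries-class] over the terminal airway ids (ml/s)
#' @export
computeTerminalFlows <- function(field, map, times = NULL, period = NULL) {
  if (is(field, "ExpansionField")) {
    V <- field@regionVolumes
    if (is.null(times)) times <- field@phaseTimes
    if (is.null(period)) period <- cyclePeriod(field)
  } else V <- field
  if (ncol(V) < 2L) stop("at least 2 phases are required")
  if (nrow(V) != length(map))
    stop("map must assign every region to a terminal airway")
  tids <- sort(unique(map))
  Vterm <- rowsum(V, group = map)          # ordered by sorted unique map
  Q <- .periodicDeriv(Vterm, times, period)
  new("FlowSeries", airwayIds = as.integer(tids), times = times,
      flows = unname(Q), period = period,
      params = list(source = "expansion", nRegions = nrow(V)))
}

#' Propagate terminal flows through the airway tree
#'
#' Applies continuity (negligible compressibility) at every bifurcation in
#' post-order: the flow through a parent equals the sum of the flows
#' through its two daughters, recursively up to the trachea, whose trace
#' is the total tracheal flow.
#'
#' @param tree an [AirwayTree-class].
#' @param terminalFlows a [FlowSeries-class] covering every terminal
#'   airway of `tree`.
#' @return a [FlowSeries-class] covering every segment of the tree
#' @export
propagateFlows <- function(tree, terminalFlows) {
  stopifnot(is(tree, "AirwayTree"), is(terminalFlows, "FlowSeries"))
  tids <- terminalIds(tree)
  missing <- setdiff(tids, airwayIds(terminalFlows))
  if (length(missing))
    stop("no flow trace for terminal airway id(s): ",
         paste(missing, collapse = ", "))
  seg <- segmentTable(tree)
  ids <- seg$id
  Q <- matrix(0, length(ids), length(terminalFlows@times))
  rownames(Q) <- ids
  Q[as.character(tids), ] <-
    flowMatrix(terminalFlows)[match(tids, airwayIds(terminalFlows)), ,
                              drop = FALSE]
  kids <- .childrenMap(tree)
  # children always have larger generation: process deepest first
  for (id in ids[order(seg$generation, decreasing = TRUE)]) {
    ch <- kids[[as.character(id)]]
    if (length(ch))
      Q[as.character(id), ] <- colSums(Q[as.character(ch), , drop = FALSE])
  }
  new("FlowSeries", airwayIds = as.integer(ids),
      times = terminalFlows@times, flows = unname(Q),
      period = terminalFlows@period,
      params = c(terminalFlows@params, list(propagated = TRUE)))
}

#' Lung volume metrics over one cycle
#'
#' Total lung volume per phase (sum of region volumes), tidal volume
#' (maximum minus minimum), minute volume (tidal volume times cycle
#' frequency), per-region fractional tidal volume ((max - min) / initial
#' volume) and, when a per-phase centre track is supplied, the per-region
#' displacement as the path length of the centre translation over the
#' cycle.
#'
#' @param field an [ExpansionField-class], or a volume matrix
#'   (regions x phases, mm^3) with `times` supplied.
#' @param cycleFrequency cycles per minute; defaulted from the field's
#'   composite period.
#' @param times phase times, ms.
#' @param centerTrack optional array (nRegions x 3 x nPhases) of region
#'   centres, mm, for the displacement path length.
#' @return a [VolumeMetrics-class] (volumes in ml, displacement in um)
#' @export
computeVolumeMetrics <- function(field, cycleFrequency = NULL,
                                 times = NULL, centerTrack = NULL) {
  if (is(field, "ExpansionField")) {
    V <- field@regionVolumes
    if (is.null(times)) times <- field@phaseTimes
    if (is.null(cycleFrequency))
      cycleFrequency <- 60000 / cyclePeriod(field)
  } else V <- field
  if (ncol(V) < 2L) stop("at least 2 phases are required")
  if (is.null(cycleFrequency)) stop("cycleFrequency is required")
  lungV <- colSums(V) / 1000               # mm^3 -> ml
  tidal <- max(lungV) - min(lungV)
  minute <- tidal * cycleFrequency
  fracTidal <- (apply(V, 1, max) - apply(V, 1, min)) / V[, 1]
  disp <- rep(NA_real_, nrow(V))
  if (!is.null(centerTrack)) {
    P <- dim(centerTrack)[3]
    disp <- numeric(nrow(V))
    for (p in seq_len(P)) {                # path length with periodic wrap
      pn <- if (p == P) 1L else p + 1L
      d3 <- centerTrack[, , pn, drop = FALSE] -
        centerTrack[, , p, drop = FALSE]
      dim(d3) <- dim(centerTrack)[1:2]
      disp <- disp + sqrt(rowSums(d3^2))
    }
    disp <- disp * 1000                    # mm -> um
  }
  new("VolumeMetrics", times = times, lungVolume = lungV,
      tidalVolume = tidal, minuteVolume = minute,
      regionDisplacement = disp, regionFractionalTidal = fracTidal,
      params = list(cycleFrequency = cycleFrequency))
}

#' Decompose the flow at one bifurcation into bulk and pendelluft
#'
#' With all flows in the tree sign convention (positive = directed from
#' the trachea toward the periphery; `qA` parent, `qB`/`qC` daughters),
#' the total internal flow is `Qtot = |qA| + |qB| + |qC|`, the bulk
#' (trachea-to-alveoli) component is `Qbulk = |qA + qB + qC|` and the
#' pendelluft (sibling-to-sibling redistribution) is
#' `Qpend = Qtot - Qbulk >= 0`. Pure bulk flow `(q, q/2, q/2)` gives
#' `Qpend = 0`; pure pendelluft `(0, q, -q)` gives `Qbulk = 0`.
#' Inputs may be vectors over time.
#'
#' @param qA,qB,qC parent and daughter flows, ml/s.
#' @param tol relative continuity tolerance on `qA = qB + qC` (measured
#'   against the peak total flow); exceeding it is an error.
#' @return list with numeric components `Qtot`, `Qbulk`, `Qpend`
#' @export
decomposeBifurcationFlow <- function(qA, qB, qC, tol = 1e-6) {
  Qtot <- abs(qA) + abs(qB) + abs(qC)
  scale <- max(Qtot, na.rm = TRUE)
  viol <- max(abs(qA - qB - qC))
  if (scale > 0 && viol > tol * scale)
    stop(sprintf(
      "continuity violated at bifurcation: |Qparent - Qb - Qc| = %.3g (tolerance %.3g)",
      viol, tol * scale))
  Qbulk <- abs(qA + qB + qC)
  list(Qtot = Qtot, Qbulk = Qbulk, Qpend = Qtot - Qbulk)
}

# trapezoidal cycle-mean of each row of a periodic series
.periodicMean <- function(M, times, period) {
  tt <- c(times, times[1] + period)
  MM <- cbind(M, M[, 1])
  w <- diff(tt)
  as.vector((MM[, -ncol(MM), drop = FALSE] +
               MM[, -1, drop = FALSE]) %*% w) / (2 * period)
}

#' Aggregate the bulk/pendelluft decomposition over the tree
#'
#' Computes `Qtot`, `Qbulk` and `Qpend` at every bifurcation, averages
#' each over the cycle by trapezoidal integration divided by the cycle
#' duration (ml/s), and sums over all bifurcations for the whole-tree
#' totals. A per-generation breakdown (by parent generation) is included
#' in the result's `params$perGeneration`.
#'
#' @param flows a [FlowSeries-class] covering every segment (from
#'   [propagateFlows()]).
#' @param tree the matching [AirwayTree-class].
#' @param tol continuity tolerance passed to [decomposeBifurcationFlow()].
#' @return a [FlowDecomposition-class]
#' @export
aggregateFlowDecomposition <- function(flows, tree, tol = 1e-6) {
  stopifnot(is(flows, "FlowSeries"), is(tree, "AirwayTree"))
  if (flows@period <= 0) stop("cycle duration must be > 0")
  seg <- segmentTable(tree)
  kids <- .childrenMap(tree)
  parents <- seg$id[seg$id %in% seg$parent_id[!is.na(seg$parent_id)]]
  Q <- flowMatrix(flows)
  rows <- match(parents, airwayIds(flows))
  out <- data.frame(parent_id = parents,
                    generation = seg$generation[match(parents, seg$id)],
                    Qtot = NA_real_, Qbulk = NA_real_, Qpend = NA_real_)
  for (i in seq_along(parents)) {
    ch <- kids[[as.character(parents[i])]]
    dec <- tryCatch(
      decomposeBifurcationFlow(Q[rows[i], ],
                               Q[match(ch[1], airwayIds(flows)), ],
                               Q[match(ch[2], airwayIds(flows)), ],
                               tol = tol),
      error = function(e) stop("bifurcation at parent id ", parents[i],
                               ": ", conditionMessage(e)))
    m <- .periodicMean(rbind(dec$Qtot, dec$Qbulk, dec$Qpend),
                       flows@times, flows@period)
    out$Qtot[i] <- m[1]; out$Qbulk[i] <- m[2]; out$Qpend[i] <- m[3]
  }
  totals <- c(Qtot = sum(out$Qtot), Qbulk = sum(out$Qbulk),
              Qpend = sum(out$Qpend))
  perGen <- aggregate(out[c("Qtot", "Qbulk", "Qpend")],
                      by = list(generation = out$generation), FUN = sum)
  new("FlowDecomposition", perBifurcation = out, totals = totals,
      pendelluftFraction =
        if (totals["Qtot"] > 0) unname(totals["Qpend"] / totals["Qtot"])
        else 0,
      params = list(perGeneration = perGen, tol = tol))
}

#' Read / write a flow table as CSV
#'
#' Long-format columns: `airway_id, time_ms, Q_ml_per_s`.
#'
#' @param x a [FlowSeries-class]
#' @param path file path
#' @param period cycle period, ms (stored as a comment-free extra column
#'   would be lossy; supplied on read).
#' @return `readFlowSeries` returns a [FlowSeries-class]
#' @export
writeFlowSeries <- function(x, path) {
  stopifnot(is(x, "FlowSeries"))
  df <- data.frame(airway_id = rep(airwayIds(x), times = length(x@times)),
                   time_ms = rep(x@times, each = length(airwayIds(x))),
                   Q_ml_per_s = as.vector(flowMatrix(x)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFlowSeries
#' @export
readFlowSeries <- function(path, period) {
  df <- read.csv(path)
  ids <- sort(unique(df$airway_id))
  times <- sort(unique(df$time_ms))
  Q <- matrix(NA_real_, length(ids), length(times))
  Q[cbind(match(df$airway_id, ids), match(df$time_ms, times))] <-
    df$Q_ml_per_s
  new("FlowSeries", airwayIds = as.integer(ids), times = times,
      flows = Q, period = period, params = list(source = path))
}
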