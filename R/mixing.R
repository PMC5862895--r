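#' @include transport.R
NULL

#' Sum two flow series (linear superposition)
#'
#' Combines ventilation-only and cardiac-only flow series sampled on the
#' same time base into the combined-state flows, by adding the traces
#' airway by airway.
#'
#' @param ventFlows,cardFlows [FlowSeries-class] objects on identical
#'   airway ids and times.
#' @return a [FlowSeries-class] tagged as the combined state
#' @export
combineFlows <- function(ventFlows, cardFlows) {
  stopifnot(identical(airwayIds(ventFlows), airwayIds(cardFlows)),
            isTRUE(all.equal(ventFlows@times, cardFlows@times)),
            isTRUE(all.equal(ventFlows@period, cardFlows@period)))
  new("FlowSeries", airwayIds = airwayIds(ventFlows),
      times = ventFlows@times,
      flows = flowMatrix(ventFlows) + flowMatrix(cardFlows),
      period = ventFlows@period,
      params = list(state = "BOTH"))
}

# end-inspiration offset: time of maximum cumulative root inflow over one
# cycle (maximum total lung volume)
.endInspirationOffset <- function(flows, tree) {
  rootId <- segmentTable(tree)$id[is.na(segmentTable(tree)$parent_id)]
  q <- flowMatrix(flows)[match(rootId, airwayIds(flows)), ]
  tt <- c(flows@times, flows@times[1] + flows@period)
  qq <- c(q, q[1])
  vol <- cumsum(c(0, diff(tt) * (head(qq, -1) + tail(qq, -1)) / 2))
  tt[which.max(vol)] %% flows@period
}

#' Run one washout state of the gas-mixing study
#'
#' Runs the full tracer transport simulation for one of the four states —
#' `DIFF` (zero flow, molecular diffusion only), `CARD` (cardiogenic
#' oscillations only), `VENT` (mechanical ventilation only) or `BOTH`
#' (their sum) — and samples the lung-resident Type A (resident gas) and
#' Type B (fresh gas) fractions once per ventilation cycle at end
#' inspiration (the instant of maximum total lung volume; for the
#' flow-free states the same cadence is used for comparability). The
#' declining Type A fraction is analogous to an inert gas washout.
#'
#' @param label `"DIFF"`, `"CARD"`, `"VENT"` or `"BOTH"`.
#' @param geometry a [TransportGeometry-class].
#' @param flows a [FlowSeries-class] for the state (`NULL` for `DIFF`).
#'   When the series carries a `params$state` tag (as those built by
#'   [washoutFlows()] do), a mismatch with `label` is an error.
#' @param config a [TransportConfig-class].
#' @param nCycles number of ventilation cycles to simulate (>= 1).
#' @param tree the [AirwayTree-class] (used to locate the trachea for the
#'   end-inspiration instant).
#' @param samplePeriod sampling cadence, ms; defaults to the flow period
#'   (required for `DIFF`).
#' @param sampleOffset end-inspiration offset within the cycle, ms;
#'   computed from the flows when omitted (0 for `DIFF`).
#' @param seed integer seed.
#' @return a [ConcentrationCurve-class]
#' @export
runWashoutState <- function(label, geometry, flows, config, nCycles,
                            tree = NULL, samplePeriod = NULL,
                            sampleOffset = NULL, seed = 1L) {
  label <- match.arg(label, c("DIFF", "CARD", "VENT", "BOTH"))
  if (nCycles < 1) stop("nCycles must be >= 1")
  if (label == "DIFF") {
    if (!is.null(flows) && any(flowMatrix(flows) != 0))
      stop("DIFF must have identically zero flow")
    flows <- NULL
    if (is.null(samplePeriod))
      stop("samplePeriod is required for the DIFF state")
    if (is.null(sampleOffset)) sampleOffset <- 0
  } else {
    if (is.null(flows)) stop(label, " requires a flow series")
    tag <- flows@params$state
    if (!is.null(tag) && tag != label)
      stop("state/flow mismatch: flows are tagged ", tag,
           " but label is ", label)
    if (is.null(samplePeriod)) samplePeriod <- flows@period
    if (is.null(sampleOffset))
      sampleOffset <- if (!is.null(tree)) .endInspirationOffset(flows, tree)
        else 0
  }
  sampleTimes <- sampleOffset + (seq_len(nCycles) - 1) * samplePeriod
  sampleTimes <- sampleTimes[sampleTimes > 0]
  duration <- (nCycles) * samplePeriod

  set.seed(as.integer(seed))
  state0 <- seedTracers(geometry, config@quantum, seed = as.integer(seed))
  lung0 <- lungTracerCount(state0)
  run <- runTransport(geometry, flows, config, duration, state = state0,
                      sampleTimes = sampleTimes, seed = as.integer(seed))
  sm <- run$samples
  new("ConcentrationCurve", label = label,
      sampleTimes = c(0, sm$time),
      fractionA = c(1, sm$fractionA), fractionB = c(0, sm$fractionB),
      lungCount = c(lung0, as.integer(sm$lung)),
      expiredA = c(0L, as.integer(sm$expiredA)),
      expiredB = c(0L, as.integer(sm$expiredB)),
      injected = c(0L, as.integer(sm$injected)),
      params = list(nCycles = nCycles, samplePeriod = samplePeriod,
                    sampleOffset = sampleOffset, seed = seed,
                    quantum = config@quantum,
                    counts = run$state@counts))
}

#' Terminal flows for each washout state
#'
#' Convenience builder: maps the regions of ventilation-only and
#' cardiac-only expansion fields to their supplying terminal airways,
#' converts expansion into terminal flows, propagates them through the
#' tree, and returns the per-state flow series (`VENT`, `CARD`, and their
#' superposition `BOTH`), each tagged with its state.
#'
#' @param tree an [AirwayTree-class].
#' @param ventField,cardField [ExpansionField-class] objects sharing the
#'   same region centres (generate them with the same seed).
#' @return list with elements `VENT`, `CARD`, `BOTH`
#'   ([FlowSeries-class]) and `map` (region-to-terminal assignment)
#' @export
washoutFlows <- function(tree, ventField, cardField) {
  map <- assignRegionsToTerminals(regionCenters(ventField), tree)
  vent <- propagateFlows(tree, computeTerminalFlows(ventField, map))
  card <- propagateFlows(tree, computeTerminalFlows(cardField, map))
  vent@params$state <- "VENT"
  card@params$state <- "CARD"
  both <- combineFlows(vent, card)
  list(VENT = vent, CARD = card, BOTH = both, map = map)
}

#' Mixing enhancement ratio between two washout curves
#'
#' The ratio of fresh-gas (Type B) concentrations with a flow component
#' present versus without it — `CARD:DIFF` quantifies the mixing added by
#' cardiogenic oscillations during apnea, `BOTH:VENT` the enhancement they
#' add on top of mechanical ventilation. Curves on different time bases
#' are aligned by linear interpolation of the denominator. Samples where
#' both concentrations are zero are undefined (`NA`, flagged, never
#' interpolated); a zero denominator with a positive numerator yields
#' `Inf`, flagged.
#'
#' @param curveWith,curveWithout [ConcentrationCurve-class] objects.
#' @return data.frame with `time`, `ratio`, and a logical `flagged`
#'   column marking undefined/infinite points
#' @export
mixingEnhancementRatio <- function(curveWith, curveWithout) {
  t1 <- curveWith@sampleTimes
  b1 <- curveWith@fractionB
  if (isTRUE(all.equal(t1, curveWithout@sampleTimes))) {
    b0 <- curveWithout@fractionB
  } else {
    b0 <- approx(curveWithout@sampleTimes, curveWithout@fractionB,
                 xout = t1, rule = 2)$y
  }
  ratio <- ifelse(b0 == 0 & b1 == 0, NA_real_, b1 / b0)
  data.frame(time = t1, ratio = ratio,
             flagged = !is.finite(ratio))
}

#' Bundled mouse-like synthetic scenario
#'
#' Builds the complete desk-scale analogue of the in-vivo study: a
#' 5-generation airway tree (16 terminal airways) with trumpet periphery
#' and acinar compartments, ventilation-only and cardiac-only expansion
#' fields sharing one set of tissue regions, the per-state flow series,
#' and a transport configuration. The study conditions follow the
#' ventilator settings (120 ms inspiration, 280 ms expiration, so a
#' 400 ms cycle at 150 breaths/min) with the heart at three times the
#' ventilation rate; the ventilation tidal volume is 0.2 ml against a
#' 0.35 ml end-expiratory volume, and the cardiac regional tidal volume
#' is set to 6.3% of total lung capacity (the middle of the in-vivo
#' 5.5-7.1% band), localized near the heart locus with a wave-like phase
#' lag that produces pendelluft. Tree size, tracer count and cycle count
#' are reduced relative to the in-vivo anatomy so a full four-state
#' mixing study runs on a desktop.
#'
#' @param seed integer seed for every generator.
#' @param nTracers approximate number of tracers seeded.
#' @param nCycles ventilation cycles per washout run.
#' @return list with `tree`, `geometry`, `ventField`, `cardField`,
#'   `flows` (from [washoutFlows()]), `config`, `nCycles`, and scalar
#'   context (`frcVolume`, `tlcVolume`, ms periods)
#' @export
mouseLikeScenario <- function(seed = 1L, nTracers = 2000L, nCycles = 10L) {
  tree <- generateAirwayTree(5, tracheaRadius = 0.6, radiusRatio = 0.7,
                             lengthRatio = 0.72, tracheaLength = 4,
                             seed = seed)
  seg <- segmentTable(tree)
  termGen <- max(seg$generation)
  termRadius <- min(seg$radius_mm)
  table <- makeTrumpetTable(startGeneration = termGen,
                            endGeneration = termGen + 9L,
                            startDiameter = 2 * termRadius,
                            startLength = 0.8)
  geomCyl <- simplifyGeometry(tree)
  frc <- 350                                    # mm^3 end-expiratory volume
  airwayVol <- as.numeric(gasVolume(tree))
  trumpetVol <- sum(table$area_mm2 * table$length_mm) *
    length(terminalIds(tree))
  compVol <- (frc - airwayVol - trumpetVol) / length(terminalIds(tree))
  geometry <- attachTrumpetModel(geomCyl, table,
                                 compartmentVolume = compVol)
  tidalVent <- 200                              # mm^3 (0.2 ml)
  tlc <- frc + tidalVent
  tidalCard <- 0.063 * tlc                      # 6.3% of TLC, regional sum
  ventField <- generateExpansionField(
    tree, ventAmplitude = 0.5, cardiacAmplitude = 0,
    baselineTotal = frc, tidalTarget = tidalVent, seed = seed)
  cardField <- generateExpansionField(
    tree, ventAmplitude = 0, cardiacAmplitude = 0.15,
    decayLength = 2.5, phaseLagRate = 0.8,
    baselineTotal = frc, tidalTarget = tidalCard, seed = seed)
  flows <- washoutFlows(tree, ventField, cardField)
  quantum <- frc / nTracers
  config <- transportConfig(D = 0.23, dt = 2, subSteps = 100L,
                            quantum = quantum)
  list(tree = tree, geometry = geometry, ventField = ventField,
       cardField = cardField, flows = flows, config = config,
       nCycles = nCycles, frcVolume = frc, tlcVolume = tlc,
       ventPeriod = 400, cardPeriod = 400 / 3, seed = seed)
}
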