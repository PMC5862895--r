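#' @include pendelluft-package.R
NULL

#' Rooted bifurcating airway tree
#'
#' An `AirwayTree` stores a rooted network of straight cylindrical airway
#' segments. Each segment is specified by its two end points (proximal,
#' distal; mm) and a single radius (mm), the representation used for flow
#' propagation and gas transport. The root segment is the trachea
#' (generation 0); every other segment has exactly one parent, and every
#' segment has either 0 or 2 children.
#'
#' @slot segments a `data.frame` with one row per segment and columns
#'   `id`, `parent_id` (`NA` for the trachea), `x1,y1,z1` (proximal point),
#'   `x2,y2,z2` (distal point), `radius_mm`, `generation`.
#' @slot metadata list of generation parameters (seed, radius ratio, ...).
#' @seealso [generateAirwayTree()], [AirwayTree()]
#' @export
setClass("AirwayTree",
  representation(segments = "data.frame", metadata = "list"),
  prototype(metadata = list()))

.validAirwayTree <- function(object) {
  seg <- object@segments
  need <- c("id", "parent_id", "x1", "y1", "z1", "x2", "y2", "z2",
            "radius_mm", "generation")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(seg$id)) return("segment ids must be unique")
  root <- is.na(seg$parent_id)
  if (sum(root) != 1L) return("tree must have exactly one root (trachea)")
  if (!all(seg$parent_id[!root] %in% seg$id))
    return("every non-root segment must reference an existing parent")
  nchild <- table(factor(seg$parent_id[!root], levels = seg$id))
  if (!all(nchild %in% c(0L, 2L)))
    return("every segment must have 0 or 2 children")
  if (any(seg$radius_mm <= 0)) return("all radii must be > 0")
  len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 + (seg$z2 - seg$z1)^2)
  if (any(len <= 0)) return("all segment lengths must be > 0")
  if (seg$generation[root] != 0L) return("trachea must be generation 0")
  pgen <- seg$generation[match(seg$parent_id, seg$id)]
  if (!all(seg$generation[!root] == pgen[!root] + 1L))
    return("generation(child) must equal generation(parent) + 1")
  TRUE
}
setValidity("AirwayTree", .validAirwayTree)

#' Regional lung expansion field
#'
#' Per-region tissue volumes over one composite breathing cycle, combining a
#' pressure-controlled ventilation waveform with cardiogenic oscillations
#' localized near a heart locus. Volumes are in mm^3 (microlitres), times in
#' ms. The field is periodic over `cyclePeriod(object)`.
#'
#' @slot regionCenters numeric matrix (nRegions x 3), mm.
#' @slot phaseTimes strictly increasing sample times in ms, covering one
#'   composite cycle `[0, T)`.
#' @slot regionVolumes numeric matrix (nRegions x nPhases), mm^3, all > 0.
#' @slot heartLocus numeric length-3 point (mm) around which the cardiac
#'   component is concentrated.
#' @slot params generation parameters, including `cyclePeriod` (ms),
#'   ventilation and cardiac amplitudes and timings.
#' @seealso [generateExpansionField()]
#' @export
setClass("ExpansionField",
  representation(regionCenters = "matrix", phaseTimes = "numeric",
                 regionVolumes = "matrix", heartLocus = "numeric",
                 params = "list"))

setValidity("ExpansionField", function(object) {
  if (ncol(object@regionCenters) != 3L) return("regionCenters must be n x 3")
  if (any(object@regionVolumes <= 0)) return("volumes must be strictly positive")
  if (is.unsorted(object@phaseTimes, strictly = TRUE))
    return("phaseTimes must be strictly increasing")
  if (nrow(object@regionVolumes) != nrow(object@regionCenters))
    return("regionVolumes rows must match regionCenters")
  if (ncol(object@regionVolumes) != length(object@phaseTimes))
    return("regionVolumes columns must match phaseTimes")
  if (length(object@heartLocus) != 3L) return("heartLocus must be length 3")
  TRUE
})

#' Synthetic acquisition log
#'
#' Frame times, ventilation triggers, ECG R-peaks and the airway pressure
#' trace recorded during an imaging run; the input to retrospective
#' double gating. Times in ms, pressure in cmH2O.
#'
#' @slot frameTimes strictly increasing frame acquisition times (ms).
#' @slot ventTriggerTimes ventilation cycle start times (ms).
#' @slot ecgRpeakTimes ECG R-peak times (ms).
#' @slot airwayPressure pressure at each frame (cmH2O).
#' @slot params generation parameters.
#' @seealso [generateAcquisitionLog()], [doubleGateFrames()]
#' @export
setClass("AcquisitionLog",
  representation(frameTimes = "numeric", ventTriggerTimes = "numeric",
                 ecgRpeakTimes = "numeric", airwayPressure = "numeric",
                 params = "list"))

setValidity("AcquisitionLog", function(object) {
  for (nm in c("frameTimes", "ventTriggerTimes", "ecgRpeakTimes")) {
    v <- slot(object, nm)
    if (length(v) > 1L && is.unsorted(v, strictly = TRUE))
      return(paste(nm, "must be strictly increasing"))
  }
  if (length(object@airwayPressure) != length(object@frameTimes))
    return("airwayPressure must have one value per frame")
  TRUE
})

#' Speckle phantom volume pair
#'
#' A reference 3D speckle volume and the same volume warped through a known
#' displacement field, used to validate cross-correlation velocimetry.
#' The deformed volume satisfies `deformed(x) = reference(x - u(x))`
#' (features move by `+u`, in voxels).
#'
#' @slot reference,deformed 3D numeric arrays of identical shape.
#' @slot voxelSize isotropic voxel size in micrometres (default 15).
#' @slot trueDisplacement 4D array `c(dim(reference), 3)`, voxels.
#' @slot params generation parameters (seed, noise level, blob size).
#' @seealso [generateSpeckleVolumePair()], [crossCorrelateDisplacement()]
#' @export
setClass("SpeckleVolumePair",
  representation(reference = "array", deformed = "array",
                 voxelSize = "numeric", trueDisplacement = "array",
                 params = "list"))

setValidity("SpeckleVolumePair", function(object) {
  if (!identical(dim(object@reference), dim(object@deformed)))
    return("reference and deformed volumes must have the same shape")
  if (!identical(dim(object@trueDisplacement),
                 c(dim(object@reference), 3L)))
    return("trueDisplacement must have shape c(dim(reference), 3)")
  TRUE
})

#' Double-gating result
#'
#' Assignment of acquisition frames to ventilation-phase bins and,
#' independently, to cardiac-phase bins. Frames acquired at airway pressure
#' at or above the pressure threshold are excluded from the cardiac bins
#' (they remain ventilation-binned), so cardiac-phase data are effectively
#' reconstructed at expiratory pressure.
#'
#' @slot ventBins list of frame-index vectors, one per ventilation phase.
#' @slot cardBins list of frame-index vectors, one per cardiac phase.
#' @slot excludedFromCardiac frames removed from cardiac binning by the
#'   pressure filter.
#' @slot unbinnableVent,unbinnableCard frames before the first trigger /
#'   R-peak that cannot be phased.
#' @slot extrapolatedVent,extrapolatedCard frames after the last trigger /
#'   R-peak whose phase used the median cycle length.
#' @slot params binning parameters.
#' @seealso [doubleGateFrames()]
#' @export
setClass("GatingResult",
  representation(ventBins = "list", cardBins = "list",
                 excludedFromCardiac = "integer",
                 unbinnableVent = "integer", unbinnableCard = "integer",
                 extrapolatedVent = "integer", extrapolatedCard = "integer",
                 params = "list"))

#' Velocimetry region grid
#'
#' Lattice of cubic interrogation regions with one modal displacement vector
#' per region (from 3D cross-correlation) and, after
#' [expansionFromDisplacement()], one fractional volume change per region.
#'
#' @slot centersVoxel region centre coordinates in voxels (nRegions x 3).
#' @slot gridDim number of regions along each axis (length 3).
#' @slot window interrogation window edge length, voxels.
#' @slot spacing lattice pitch between region centres, voxels.
#' @slot displacement nRegions x 3 matrix, voxels; `NA` rows are invalid.
#' @slot valid logical per region (flat windows / masked-out are `FALSE`).
#' @slot expansion fractional volume change per region (`NA` until computed
#'   or where undefined).
#' @slot params voxel size etc.
#' @seealso [crossCorrelateDisplacement()], [expansionFromDisplacement()]
#' @export
setClass("RegionGrid",
  representation(centersVoxel = "matrix", gridDim = "integer",
                 window = "integer", spacing = "integer",
                 displacement = "matrix", valid = "logical",
                 expansion = "numeric", params = "list"))

setValidity("RegionGrid", function(object) {
  if (object@spacing > object@window)
    return("spacing must be <= window")
  if (nrow(object@displacement) != nrow(object@centersVoxel))
    return("displacement must have one row per region")
  TRUE
})

#' Signed airflow per airway segment
#'
#' Time-resolved flow through every airway segment over one cycle.
#' Sign convention: positive flow is directed from the trachea toward the
#' periphery. Units: ml/s (identically mm^3/ms). The series is treated as
#' periodic with period `period` (ms).
#'
#' @slot airwayIds segment ids (matching the `AirwayTree`).
#' @slot times sample times in ms.
#' @slot flows matrix (nAirways x nTimes), ml/s.
#' @slot period cycle period in ms.
#' @slot params provenance.
#' @seealso [propagateFlows()], [computeTerminalFlows()]
#' @export
setClass("FlowSeries",
  representation(airwayIds = "integer", times = "numeric",
                 flows = "matrix", period = "numeric", params = "list"))

setValidity("FlowSeries", function(object) {
  if (nrow(object@flows) != length(object@airwayIds))
    return("flows must have one row per airway id")
  if (ncol(object@flows) != length(object@times))
    return("flows must have one column per time")
  if (!all(is.finite(object@flows))) return("flows must be finite")
  if (object@period <= 0) return("period must be > 0")
  TRUE
})

#' Bulk/pendelluft flow decomposition
#'
#' Per-bifurcation and whole-tree decomposition of the flow into total
#' internal flow, bulk flow and pendelluft, time-averaged over one cycle
#' and expressed in ml/s.
#'
#' @slot perBifurcation data.frame with columns `parent_id`, `generation`,
#'   `Qtot`, `Qbulk`, `Qpend` (cycle-averaged, ml/s).
#' @slot totals named numeric: whole-tree `Qtot`, `Qbulk`, `Qpend`.
#' @slot pendelluftFraction whole-tree `Qpend / Qtot`.
#' @slot params provenance.
#' @seealso [aggregateFlowDecomposition()], [decomposeBifurcationFlow()]
#' @export
setClass("FlowDecomposition",
  representation(perBifurcation = "data.frame", totals = "numeric",
                 pendelluftFraction = "numeric", params = "list"))

#' Lung volume metrics
#'
#' Whole-lung and per-region volume metrics over one cycle: total lung
#' volume over time, tidal volume (max - min), minute volume (tidal times
#' cycle frequency), per-region displacement path length and per-region
#' fractional tidal volume.
#'
#' @slot times phase times, ms.
#' @slot lungVolume total lung volume per phase, ml.
#' @slot tidalVolume ml.
#' @slot minuteVolume ml/min.
#' @slot regionDisplacement per-region translation path length over the
#'   cycle, micrometres (`NA` if centers were static).
#' @slot regionFractionalTidal per-region (max - min)/initial volume.
#' @slot params cycle frequency etc.
#' @seealso [computeVolumeMetrics()]
#' @export
setClass("VolumeMetrics",
  representation(times = "numeric", lungVolume = "numeric",
                 tidalVolume = "numeric", minuteVolume = "numeric",
                 regionDisplacement = "numeric",
                 regionFractionalTidal = "numeric", params = "list"))

#' Transport geometry (cylinders + trumpets + acinar compartments)
#'
#' Simplified geometry used by the gas-tracer model: every airway is a
#' straight cylinder; each terminal airway may carry a trumpet section
#' (piecewise-constant total cross-sectional area growing toward the
#' periphery) ending in a well-mixed acinar compartment.
#'
#' @slot elements data.frame, one row per transport element, columns
#'   `elem` (1-based index), `airway_id` (source tree id, `NA` for trumpet
#'   sections), `parent` (elem index, `NA` root), `type`
#'   (`"cylinder"`/`"trumpet"`), `length_mm`, `radius_mm` (cylinders),
#'   `generation`.
#' @slot profiles list indexed by elem: for trumpets a data.frame with
#'   `length_mm`, `area_mm2` per piece (proximal to distal); `NULL` for
#'   cylinders.
#' @slot compartments data.frame: `comp` (1-based), `elem` (owning trumpet),
#'   `volume_mm3`, `area_mm2`.
#' @slot params provenance.
#' @seealso [simplifyGeometry()], [attachTrumpetModel()]
#' @export
setClass("TransportGeometry",
  representation(elements = "data.frame", profiles = "list",
                 compartments = "data.frame", params = "list"))

setValidity("TransportGeometry", function(object) {
  el <- object@elements
  if (any(el$length_mm <= 0)) return("element lengths must be > 0")
  cyl <- el$type == "cylinder"
  if (any(is.na(el$radius_mm[cyl])) || any(el$radius_mm[cyl] <= 0))
    return("cylinder radii must be > 0")
  for (i in which(el$type == "trumpet")) {
    pr <- object@profiles[[i]]
    if (is.null(pr)) return("every trumpet needs an area profile")
    if (any(pr$area_mm2 <= 0) || any(pr$length_mm <= 0))
      return("trumpet profile areas and lengths must be > 0")
    if (is.unsorted(pr$area_mm2))
      return("trumpet area must be non-decreasing toward the periphery")
  }
  cp <- object@compartments
  if (nrow(cp) && (any(cp$volume_mm3 <= 0) || any(cp$area_mm2 <= 0)))
    return("compartment volumes and areas must be > 0")
  TRUE
})

#' Gas-tracer transport configuration
#'
#' @slot D molecular diffusion coefficient, cm^2/s. Default 0.23, the
#'   self-diffusivity of nitrogen at body temperature.
#' @slot dt advection time step, ms.
#' @slot subSteps diffusion sub-steps per time step (default 100).
#' @slot quantum gas volume represented by one tracer, mm^3 (inverse
#'   seeding density).
#' @slot maxWallRetries redraw cap for diffusion wall collisions.
#' @seealso [transportConfig()]
#' @export
setClass("TransportConfig",
  representation(D = "numeric", dt = "numeric", subSteps = "integer",
                 quantum = "numeric", maxWallRetries = "integer"))

setValidity("TransportConfig", function(object) {
  if (object@D < 0) return("D must be >= 0")
  if (object@dt <= 0) return("dt must be > 0")
  if (object@subSteps < 1L) return("subSteps must be >= 1")
  if (object@quantum <= 0) return("quantum must be > 0")
  TRUE
})

#' Tracer population state
#'
#' Massless gas tracers with a gas-type label (1 = Type A, resident;
#' 2 = Type B, fresh) and in-airway cylindrical coordinates: containing
#' element, axial position `z` (mm from the proximal end), relative radius
#' `rrel = r/R(z)` in `[0, 1]`, azimuth `theta`. Compartment-resident
#' tracers are held as per-type tallies and are not advected or diffused.
#'
#' @slot type integer vector (1 = A, 2 = B) for in-airway tracers.
#' @slot elem containing element index per tracer.
#' @slot z,rrel,theta cylindrical coordinates per tracer.
#' @slot tallyA,tallyB per-compartment tracer counts.
#' @slot tracheaAccumulator inward-flux volume accumulator, tracer quanta.
#' @slot compartmentOutflux per-compartment released-volume accumulators,
#'   tracer quanta.
#' @slot counts named integer bookkeeping: `seeded`, `injected`,
#'   `expiredA`, `expiredB`, `heldAtJunction`, `forfeitedSubSteps`,
#'   `emptyReleases`.
#' @seealso [seedTracers()], [runTransport()]
#' @export
setClass("TracerState",
  representation(type = "integer", elem = "integer", z = "numeric",
                 rrel = "numeric", theta = "numeric",
                 tallyA = "numeric", tallyB = "numeric",
                 tracheaAccumulator = "numeric",
                 compartmentOutflux = "numeric", counts = "numeric"))

setValidity("TracerState", function(object) {
  n <- length(object@type)
  if (length(object@elem) != n || length(object@z) != n ||
      length(object@rrel) != n || length(object@theta) != n)
    return("tracer coordinate vectors must have equal length")
  if (n && (any(object@rrel < 0) || any(object@rrel > 1)))
    return("relative radius must lie in [0, 1]")
  if (any(object@tallyA < 0) || any(object@tallyB < 0))
    return("compartment tallies must be >= 0")
  TRUE
})

#' Washout concentration curve
#'
#' Lung-resident Type A / Type B tracer fractions sampled once per
#' ventilation cycle at end inspiration (or at the equivalent cadence for
#' flow-free states), the multi-breath washout readout of the tracer model.
#'
#' @slot label washout state: `"DIFF"`, `"CARD"`, `"VENT"` or `"BOTH"`.
#' @slot sampleTimes ms.
#' @slot fractionA,fractionB lung-resident fractions (airways plus
#'   compartments); they sum to 1 while the lung holds any tracer.
#' @slot lungCount,expiredA,expiredB,injected per-sample bookkeeping.
#' @slot params run configuration.
#' @seealso [runWashoutState()], [mixingEnhancementRatio()]
#' @export
setClass("ConcentrationCurve",
  representation(label = "character", sampleTimes = "numeric",
                 fractionA = "numeric", fractionB = "numeric",
                 lungCount = "integer", expiredA = "integer",
                 expiredB = "integer", injected = "integer",
                 params = "list"))

setValidity("ConcentrationCurve", function(object) {
  ok <- object@lungCount > 0L
  s <- object@fractionA[ok] + object@fractionB[ok]
  if (length(s) && any(abs(s - 1) > 1e-9))
    return("fractionA + fractionB must equal 1 while the lung holds tracers")
  TRUE
})
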