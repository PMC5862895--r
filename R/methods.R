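#' @include AllGenerics.R
NULL

# ---- AirwayTree ----

#' @rdname nSegments
#' @export
setMethod("nSegments", "AirwayTree", function(x) nrow(x@segments))

#' @rdname segmentTable
#' @export
setMethod("segmentTable", "AirwayTree", function(x) x@segments)

#' @rdname terminalIds
#' @export
setMethod("terminalIds", "AirwayTree", function(x) {
  seg <- x@segments
  has_child <- seg$id %in% seg$parent_id[!is.na(seg$parent_id)]
  sort(seg$id[!has_child & !is.na(seg$parent_id)])
})

.segmentLengths <- function(seg) {
  sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 + (seg$z2 - seg$z1)^2)
}

#' @rdname gasVolume
#' @export
setMethod("gasVolume", "AirwayTree", function(x) {
  seg <- x@segments
  sum(pi * seg$radius_mm^2 * .segmentLengths(seg))
})

setMethod("show", "AirwayTree", function(object) {
  seg <- object@segments
  cat("AirwayTree:", nrow(seg), "segments,",
      length(terminalIds(object)), "terminal airways\n")
  cat("  generations 0 -", max(seg$generation), "\n")
  term <- seg$id %in% terminalIds(object)
  if (any(term))
    cat(sprintf("  terminal diameters %.1f - %.1f um\n",
                2000 * min(seg$radius_mm[term]),
                2000 * max(seg$radius_mm[term])))
  cat(sprintf("  airway gas volume %.4g mm^3\n", gasVolume(object)))
})

# ---- ExpansionField ----

#' @rdname phaseTimes
#' @export
setMethod("phaseTimes", "ExpansionField", function(x) x@phaseTimes)

#' @rdname regionCenters
#' @export
setMethod("regionCenters", "ExpansionField", function(x) x@regionCenters)

#' @rdname regionVolumes
#' @export
setMethod("regionVolumes", "ExpansionField", function(x) x@regionVolumes)

#' @rdname cyclePeriod
#' @export
setMethod("cyclePeriod", "ExpansionField", function(x) x@params$cyclePeriod)

setMethod("show", "ExpansionField", function(object) {
  V <- object@regionVolumes
  cat("ExpansionField:", nrow(V), "regions x", ncol(V), "phases\n")
  cat(sprintf("  cycle period %.1f ms; total volume %.4g - %.4g mm^3\n",
              cyclePeriod(object), min(colSums(V)), max(colSums(V))))
})

# ---- AcquisitionLog ----

setMethod("show", "AcquisitionLog", function(object) {
  cat("AcquisitionLog:", length(object@frameTimes), "frames,",
      length(object@ventTriggerTimes), "ventilation triggers,",
      length(object@ecgRpeakTimes), "R-peaks\n")
  cat(sprintf("  pressure %.2f - %.2f cmH2O\n",
              min(object@airwayPressure), max(object@airwayPressure)))
})

# ---- SpeckleVolumePair ----

setMethod("show", "SpeckleVolumePair", function(object) {
  cat("SpeckleVolumePair:", paste(dim(object@reference), collapse = " x "),
      "voxels @", object@voxelSize, "um\n")
  u <- object@trueDisplacement
  cat(sprintf("  max |true displacement| %.3f voxels\n",
              sqrt(max(apply(u^2, 4, max)))))
})

# ---- GatingResult ----

setMethod("show", "GatingResult", function(object) {
  cat("GatingResult:", length(object@ventBins), "ventilation bins,",
      length(object@cardBins), "cardiac bins\n")
  cat("  frames:", sum(lengths(object@ventBins)), "ventilation-binned;",
      sum(lengths(object@cardBins)), "cardiac-binned;",
      length(object@excludedFromCardiac), "pressure-excluded;",
      length(object@unbinnableVent), "unbinnable\n")
})

# ---- RegionGrid ----

setMethod("show", "RegionGrid", function(object) {
  cat("RegionGrid:", paste(object@gridDim, collapse = " x "), "regions",
      sprintf("(window %d, spacing %d voxels)\n",
              object@window, object@spacing))
  cat("  valid:", sum(object@valid), "/", length(object@valid), "\n")
  if (any(is.finite(object@expansion)))
    cat(sprintf("  expansion range %.4g - %.4g\n",
                min(object@expansion, na.rm = TRUE),
                max(object@expansion, na.rm = TRUE)))
})

# ---- FlowSeries ----

#' @rdname phaseTimes
#' @export
setMethod("phaseTimes", "FlowSeries", function(x) x@times)

#' @rdname cyclePeriod
#' @export
setMethod("cyclePeriod", "FlowSeries", function(x) x@period)

#' @rdname flowMatrix
#' @export
setMethod("flowMatrix", "FlowSeries", function(x) x@flows)

#' @rdname airwayIds
#' @export
setMethod("airwayIds", "FlowSeries", function(x) x@airwayIds)

setMethod("show", "FlowSeries", function(object) {
  cat("FlowSeries:", nrow(object@flows), "airways x",
      ncol(object@flows), "times, period", object@period, "ms\n")
  cat(sprintf("  peak |Q| %.4g ml/s\n", max(abs(object@flows))))
})

# ---- FlowDecomposition ----

setMethod("show", "FlowDecomposition", function(object) {
  cat("FlowDecomposition over", nrow(object@perBifurcation),
      "bifurcations (cycle-averaged, ml/s):\n")
  cat(sprintf("  Qtot %.4g, Qbulk %.4g, Qpend %.4g (pendelluft %.1f%%)\n",
              object@totals["Qtot"], object@totals["Qbulk"],
              object@totals["Qpend"], 100 * object@pendelluftFraction))
})

# ---- VolumeMetrics ----

setMethod("show", "VolumeMetrics", function(object) {
  cat(sprintf(
    "VolumeMetrics: lung volume %.4g - %.4g ml, tidal %.4g ml, minute %.4g ml/min\n",
    min(object@lungVolume), max(object@lungVolume),
    object@tidalVolume, object@minuteVolume))
})

# ---- TransportGeometry ----

#' @rdname gasVolume
#' @export
setMethod("gasVolume", "TransportGeometry", function(x) {
  el <- x@elements
  v <- 0
  for (i in seq_len(nrow(el))) {
    v <- v + if (el$type[i] == "cylinder") {
      pi * el$radius_mm[i]^2 * el$length_mm[i]
    } else {
      pr <- x@profiles[[i]]
      sum(pr$area_mm2 * pr$length_mm)
    }
  }
  structure(v, compartments = sum(x@compartments$volume_mm3))
})

setMethod("show", "TransportGeometry", function(object) {
  el <- object@elements
  v <- gasVolume(object)
  cat("TransportGeometry:", sum(el$type == "cylinder"), "cylinders,",
      sum(el$type == "trumpet"), "trumpets,",
      nrow(object@compartments), "acinar compartments\n")
  cat(sprintf("  airway volume %.4g mm^3 + compartment volume %.4g mm^3\n",
              as.numeric(v), attr(v, "compartments")))
})

# ---- TracerState ----

#' @rdname lungTracerCount
#' @export
setMethod("lungTracerCount", "TracerState", function(x) {
  length(x@type) + as.integer(round(sum(x@tallyA) + sum(x@tallyB)))
})

setMethod("show", "TracerState", function(object) {
  cat("TracerState:", length(object@type), "tracers in airways,",
      round(sum(object@tallyA) + sum(object@tallyB)), "in compartments\n")
  cat("  Type A:", sum(object@type == 1L) + round(sum(object@tallyA)),
      " Type B:", sum(object@type == 2L) + round(sum(object@tallyB)), "\n")
  cat("  expired A/B:", object@counts[["expiredA"]], "/",
      object@counts[["expiredB"]],
      " injected:", object@counts[["injected"]], "\n")
})

# ---- ConcentrationCurve ----

#' @rdname phaseTimes
#' @export
setMethod("phaseTimes", "ConcentrationCurve", function(x) x@sampleTimes)

setMethod("show", "ConcentrationCurve", function(object) {
  cat("ConcentrationCurve [", object@label, "]: ",
      length(object@sampleTimes), " samples\n", sep = "")
  cat(sprintf("  fraction A %.3f -> %.3f\n",
              object@fractionA[1], tail(object@fractionA, 1)))
})
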