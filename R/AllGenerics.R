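#' @include AllClasses.R
NULL

#' Number of airway segments in a tree
#' @param x an [AirwayTree-class]
#' @return integer
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' Segment table of an airway tree
#' @param x an [AirwayTree-class]
#' @return the segment `data.frame` (see [AirwayTree-class])
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' Ids of terminal (distal-most) airway segments
#'
#' Terminal airways are the segments with a parent but no daughters; they
#' are the supplying airways to which tissue regions are assigned.
#' @param x an [AirwayTree-class]
#' @return integer vector of segment ids
#' @export
setGeneric("terminalIds", function(x) standardGeneric("terminalIds"))

#' Phase sample times
#' @param x an object with a time axis
#' @return numeric vector, ms
#' @export
setGeneric("phaseTimes", function(x) standardGeneric("phaseTimes"))

#' Region centre coordinates
#' @param x an [ExpansionField-class]
#' @return numeric matrix (nRegions x 3), mm
#' @export
setGeneric("regionCenters", function(x) standardGeneric("regionCenters"))

#' Per-region volumes over the cycle
#' @param x an [ExpansionField-class]
#' @return numeric matrix (nRegions x nPhases), mm^3
#' @export
setGeneric("regionVolumes", function(x) standardGeneric("regionVolumes"))

#' Composite cycle period
#' @param x an [ExpansionField-class] or [FlowSeries-class]
#' @return period in ms
#' @export
setGeneric("cyclePeriod", function(x) standardGeneric("cyclePeriod"))

#' Flow matrix of a flow series
#' @param x a [FlowSeries-class]
#' @return numeric matrix (nAirways x nTimes), ml/s; positive flow is
#'   directed from the trachea toward the periphery
#' @export
setGeneric("flowMatrix", function(x) standardGeneric("flowMatrix"))

#' Airway ids covered by an object
#' @param x a [FlowSeries-class]
#' @return integer vector
#' @export
setGeneric("airwayIds", function(x) standardGeneric("airwayIds"))

#' Total gas volume of a geometry
#' @param x an [AirwayTree-class] or [TransportGeometry-class]
#' @return volume in mm^3 (airways; for transport geometries including
#'   trumpets and, as attribute `"compartments"`, the compartment volume)
#' @export
setGeneric("gasVolume", function(x) standardGeneric("gasVolume"))

#' Number of tracers currently in the airways plus compartments
#' @param x a [TracerState-class]
#' @return integer
#' @export
setGeneric("lungTracerCount", function(x) standardGeneric("lungTracerCount"))
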