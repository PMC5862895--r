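#' @include tree.R
NULL

#' Simplify an airway tree into transport cylinders
#'
#' Each airway becomes a straight cylinder between its end points with its
#' single radius; connectivity (and hence child counts) is preserved. This
#' is the substrate of the gas-tracer model.
#'
#' @param tree an [AirwayTree-class].
#' @return a [TransportGeometry-class] with cylinder elements only
#' @export
simplifyGeometry <- function(tree) {
  stopifnot(is(tree, "AirwayTree"))
  seg <- segmentTable(tree)
  len <- .segmentLengths(seg)
  if (any(len <= 0)) stop("zero-length segment in tree")
  el <- data.frame(
    elem = seq_len(nrow(seg)),
    airway_id = seg$id,
    parent = match(seg$parent_id, seg$id),
    type = "cylinder",
    length_mm = len,
    radius_mm = seg$radius_mm,
    generation = seg$generation)
  new("TransportGeometry", elements = el,
      profiles = vector("list", nrow(el)),
      compartments = data.frame(comp = integer(), elem = integer(),
                                volume_mm3 = numeric(),
                                area_mm2 = numeric()),
      params = list())
}

#' Self-similar trumpet geometry table
#'
#' Per-generation total cross-sectional area and length for the peripheral
#' airway generations beyond the segmented terminals, built from a
#' self-similar branching rule: at each generation the airway count
#' multiplies by `countFactor` while diameters and lengths contract by
#' `diameterRatio` and `lengthRatio`. With the defaults
#' (`2 x 0.85^2 = 1.445 > 1`) the total cross-sectional area grows toward
#' the periphery, the defining trumpet property. This synthetic table
#' stands in for published morphometric tables of the distal mouse airways
#' (which are not bundled); all parameters are configurable.
#'
#' @param startGeneration generation of the terminal (segmented) airway
#'   the trumpet attaches to (default 14).
#' @param endGeneration last generation of the trumpet (default 23).
#' @param startDiameter diameter of the terminal airway, mm
#'   (default 0.095, the 85-100 um band midpoint).
#' @param startLength length of the terminal airway, mm.
#' @param countFactor,diameterRatio,lengthRatio per-generation scaling.
#' @return data.frame with columns `generation`, `area_mm2` (total area of
#'   the generation), `length_mm`, covering generations
#'   `startGeneration + 1` to `endGeneration`
#' @export
makeTrumpetTable <- function(startGeneration = 14L, endGeneration = 23L,
                             startDiameter = 0.095, startLength = 0.4,
                             countFactor = 2, diameterRatio = 0.85,
                             lengthRatio = 0.8) {
  if (endGeneration <= startGeneration)
    stop("endGeneration must exceed startGeneration")
  g <- seq(startGeneration + 1L, endGeneration)
  k <- g - startGeneration
  data.frame(
    generation = g,
    area_mm2 = countFactor^k * pi / 4 * (startDiameter * diameterRatio^k)^2,
    length_mm = startLength * lengthRatio^k)
}

#' Attach trumpet sections and acinar compartments
#'
#' Replaces the (unsegmented) periphery beyond each terminal airway with a
#' one-dimensional trumpet: a piecewise-constant total cross-sectional
#' area profile `A(z)` spanning the generations of `table`, ending in a
#' well-mixed acinar compartment whose cross-sectional area equals the
#' last (most peripheral) generation's area.
#'
#' @param geometry a [TransportGeometry-class] from [simplifyGeometry()].
#' @param table data.frame with columns `generation` (contiguous,
#'   ascending), `area_mm2`, `length_mm` — one row per trumpet piece,
#'   proximal to distal (see [makeTrumpetTable()]).
#' @param compartmentVolume acinar compartment volume, mm^3: a scalar, a
#'   vector (one per terminal, in `terminalIds` order), or `NULL` for the
#'   default `last area x total trumpet length`.
#' @return the geometry with one trumpet element and one compartment per
#'   terminal airway
#' @export
attachTrumpetModel <- function(geometry, table, compartmentVolume = NULL) {
  stopifnot(is(geometry, "TransportGeometry"))
  need <- c("generation", "area_mm2", "length_mm")
  if (!all(need %in% names(table)) || nrow(table) < 1L)
    stop("trumpet table must have columns generation, area_mm2, length_mm")
  if (nrow(table) > 1L && any(diff(table$generation) != 1L))
    stop("trumpet table generations must be contiguous and ascending")
  if (any(table$area_mm2 <= 0) || any(table$length_mm <= 0))
    stop("trumpet areas and lengths must be > 0")

  el <- geometry@elements
  if (any(el$type == "trumpet")) stop("geometry already carries trumpets")
  isParent <- el$elem %in% el$parent
  termElems <- el$elem[!isParent]
  nT <- length(termElems)
  trumpetLen <- sum(table$length_mm)
  if (is.null(compartmentVolume))
    compartmentVolume <- table$area_mm2[nrow(table)] * trumpetLen
  compartmentVolume <- rep_len(compartmentVolume, nT)

  newElems <- data.frame(
    elem = nrow(el) + seq_len(nT),
    airway_id = NA_integer_,
    parent = termElems,
    type = "trumpet",
    length_mm = trumpetLen,
    radius_mm = NA_real_,
    generation = el$generation[match(termElems, el$elem)] + 1L)
  profiles <- c(geometry@profiles,
                rep(list(table[c("length_mm", "area_mm2", "generation")]),
                    nT))
  comps <- data.frame(
    comp = seq_len(nT),
    elem = newElems$elem,
    volume_mm3 = compartmentVolume,
    area_mm2 = table$area_mm2[nrow(table)])

  new("TransportGeometry",
      elements = rbind(el, newElems), profiles = profiles,
      compartments = comps,
      params = c(geometry@params, list(trumpetTable = table)))
}

#' Womersley numbers of a transport geometry
#'
#' `alpha = R * sqrt(2 * pi * f / nu)` per element (largest radius for
#' trumpets). The quasi-steady parabolic (Poiseuille) velocity profile
#' assumed by the tracer model is justified when `alpha < 1` everywhere;
#' [runTransport()] warns when the oscillation frequency violates this.
#'
#' @param geometry a [TransportGeometry-class].
#' @param frequencyHz dominant oscillation frequency, Hz.
#' @param nu kinematic viscosity of air, mm^2/s (default 15600 mm^2/s x
#'   1e-3 = 15.6 mm^2/s at body temperature).
#' @return numeric vector of Womersley numbers, one per element
#' @export
womersleyNumbers <- function(geometry, frequencyHz, nu = 15.6) {
  el <- geometry@elements
  R <- el$radius_mm
  tr <- el$type == "trumpet"
  if (any(tr))
    R[tr] <- vapply(which(tr), function(i)
      sqrt(max(geometry@profiles[[i]]$area_mm2) / pi), numeric(1))
  R * sqrt(2 * pi * frequencyHz / nu)
}
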