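#' @include AllClasses.R
NULL

#' Construct an airway tree from a segment table
#'
#' @param segments data.frame with columns `id`, `parent_id` (`NA` for the
#'   trachea), `x1,y1,z1`, `x2,y2,z2` (mm), `radius_mm`, `generation`.
#' @param metadata optional list of provenance/parameters.
#' @return a validated [AirwayTree-class]
#' @export
AirwayTree <- function(segments, metadata = list()) {
  segments$id <- as.integer(segments$id)
  segments$parent_id <- as.integer(segments$parent_id)
  segments$generation <- as.integer(segments$generation)
  new("AirwayTree", segments = as.data.frame(segments), metadata = metadata)
}

# orthonormal basis perpendicular to a unit vector
.perpBasis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Generate a synthetic bifurcating airway tree
#'
#' Builds a full binary tree of straight cylindrical segments. The trachea
#' (generation 0) starts at the origin pointing along +z; each generation
#' branches symmetrically at `branchAngle` with the branching plane rotated
#' per generation (golden-angle advance plus seeded jitter), which keeps the
#' tree loosely space-filling. Radii and lengths contract geometrically:
#' a segment at generation g has radius `tracheaRadius * radiusRatio^g` and
#' length `tracheaLength * lengthRatio^g`, so with `radiusRatio = 0.83` a
#' generation-14 terminal has diameter `2 * 0.6 * 0.83^14` mm, i.e. about
#' 88 micrometres, within the 85-100 um band typical of the distal limit of
#' mouse airway segmentations.
#'
#' @param nGenerations number of generation levels; `1` yields a single
#'   trachea segment (generations run 0 to `nGenerations - 1`).
#' @param tracheaRadius trachea radius, mm.
#' @param radiusRatio per-generation radius contraction, in (0, 1).
#' @param branchAngle half-angle between daughters and parent axis, degrees.
#' @param lengthRatio per-generation length contraction, in (0, 1).
#' @param tracheaLength trachea length, mm.
#' @param angleJitter s.d. of the seeded azimuthal jitter, degrees.
#' @param seed integer seed; identical seeds give identical trees.
#' @return an [AirwayTree-class]
#' @examples
#' tr <- generateAirwayTree(5, seed = 1)
#' tr
#' @export
generateAirwayTree <- function(nGenerations, tracheaRadius = 0.6,
                               radiusRatio = 0.83, branchAngle = 35,
                               lengthRatio = 0.78, tracheaLength = 4,
                               angleJitter = 6, seed = 1L) {
  if (nGenerations < 1) stop("nGenerations must be >= 1")
  if (tracheaRadius <= 0) stop("tracheaRadius must be > 0")
  if (radiusRatio <= 0 || radiusRatio >= 1)
    stop("radiusRatio must lie strictly between 0 and 1")
  if (lengthRatio <= 0 || lengthRatio >= 1)
    stop("lengthRatio must lie strictly between 0 and 1")

  set.seed(as.integer(seed))
  nSeg <- 2L^nGenerations - 1L
  id <- seq_len(nSeg)
  gen <- as.integer(floor(log2(id)))
  parent <- ifelse(id == 1L, NA_integer_, id %/% 2L)

  p1 <- matrix(0, nSeg, 3)   # proximal points
  p2 <- matrix(0, nSeg, 3)   # distal points
  dirs <- matrix(0, nSeg, 3)
  dirs[1, ] <- c(0, 0, 1)
  p2[1, ] <- tracheaLength * dirs[1, ]
  golden <- pi * (3 - sqrt(5))
  a <- branchAngle * pi / 180
  jit <- angleJitter * pi / 180

  for (i in id[-1]) {
    pa <- parent[i]
    d <- dirs[pa, ]
    b <- .perpBasis(d)
    phi <- golden * gen[i] + rnorm(1, 0, jit) +
      if (i %% 2L == 0L) 0 else pi
    nd <- cos(a) * d + sin(a) * (cos(phi) * b$e1 + sin(phi) * b$e2)
    nd <- nd / sqrt(sum(nd^2))
    dirs[i, ] <- nd
    p1[i, ] <- p2[pa, ]
    p2[i, ] <- p1[i, ] + tracheaLength * lengthRatio^gen[i] * nd
  }

  seg <- data.frame(
    id = id, parent_id = parent,
    x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
    x2 = p2[, 1], y2 = p2[, 2], z2 = p2[, 3],
    radius_mm = tracheaRadius * radiusRatio^gen,
    generation = gen)
  AirwayTree(seg, metadata = list(
    seed = seed, nGenerations = nGenerations, tracheaRadius = tracheaRadius,
    radiusRatio = radiusRatio, branchAngle = branchAngle,
    lengthRatio = lengthRatio, tracheaLength = tracheaLength,
    angleJitter = angleJitter))
}

#' Read / write an airway tree as a CSV edge list
#'
#' Columns: `id, parent_id, x1, y1, z1, x2, y2, z2, radius_mm, generation`.
#'
#' @param x an [AirwayTree-class]
#' @param path file path
#' @return `readAirwayTree` returns an [AirwayTree-class];
#'   `writeAirwayTree` returns `path` invisibly.
#' @export
writeAirwayTree <- function(x, path) {
  stopifnot(is(x, "AirwayTree"))
  write.csv(segmentTable(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAirwayTree
#' @export
readAirwayTree <- function(path) {
  AirwayTree(read.csv(path), metadata = list(source = path))
}

# children of each segment id, as a named list (internal)
.childrenMap <- function(tree) {
  seg <- segmentTable(tree)
  kid <- seg[!is.na(seg$parent_id), c("id", "parent_id")]
  split(kid$id, factor(kid$parent_id, levels = seg$id))
}
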