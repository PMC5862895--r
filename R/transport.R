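#' @include transport-geometry.R airflow.R
NULL

#' Gas-tracer transport configuration
#'
#' @param D molecular diffusion coefficient, cm^2/s; the default 0.23 is
#'   the self-diffusivity of nitrogen at body temperature, modelling the
#'   intrinsic mixing of air.
#' @param dt advection time step, ms.
#' @param subSteps diffusion sub-steps per time step (default 100); each
#'   sub-step displaces a tracer by `|N(0, sigma)|` with
#'   `sigma^2 = 6 D dt/subSteps` in a uniformly random 3D direction, so
#'   the simulated mean squared displacement obeys the Einstein relation.
#' @param quantum gas volume represented by one tracer, mm^3.
#' @param maxWallRetries redraw cap for diffusion wall collisions; beyond
#'   it the remainder of the sub-step is forfeited (and counted).
#' @return a [TransportConfig-class]
#' @export
transportConfig <- function(D = 0.23, dt = 2, subSteps = 100L,
                            quantum = 0.1, maxWallRetries = 20L) {
  new("TransportConfig", D = D, dt = dt, subSteps = as.integer(subSteps),
      quantum = quantum, maxWallRetries = as.integer(maxWallRetries))
}

# pack a TransportGeometry into the flat vectors the C++ engine expects
.packGeometry <- function(geometry) {
  el <- geometry@elements
  n <- nrow(el)
  child1 <- child2 <- rep(-1L, n)
  for (i in seq_len(n)) {
    kids <- el$elem[!is.na(el$parent) & el$parent == el$elem[i]]
    if (length(kids) >= 1L) child1[i] <- kids[1] - 1L
    if (length(kids) >= 2L) child2[i] <- kids[2] - 1L
  }
  profEnd <- profR <- profA <- numeric(0)
  profOff <- profN <- integer(n)
  for (i in seq_len(n)) {
    profOff[i] <- length(profEnd)
    if (el$type[i] == "cylinder") {
      profEnd <- c(profEnd, el$length_mm[i])
      profR <- c(profR, el$radius_mm[i])
      profA <- c(profA, pi * el$radius_mm[i]^2)
      profN[i] <- 1L
    } else {
      pr <- geometry@profiles[[i]]
      profEnd <- c(profEnd, cumsum(pr$length_mm))
      profR <- c(profR, sqrt(pr$area_mm2 / pi))
      profA <- c(profA, pr$area_mm2)
      profN[i] <- nrow(pr)
    }
  }
  compOf <- rep(-1L, n)
  cp <- geometry@compartments
  if (nrow(cp)) compOf[cp$elem] <- cp$comp - 1L
  list(parent = ifelse(is.na(el$parent), -1L, el$parent - 1L),
       child1 = child1, child2 = child2, compOf = compOf,
       isTrumpet = as.integer(el$type == "trumpet"),
       len = el$length_mm, profOff = profOff, profN = profN,
       profEnd = profEnd, profR = profR, profA = profA)
}

# per-element volumes (cylinder or trumpet)
.elementVolumes <- function(geometry) {
  el <- geometry@elements
  vapply(seq_len(nrow(el)), function(i) {
    if (el$type[i] == "cylinder")
      pi * el$radius_mm[i]^2 * el$length_mm[i]
    else sum(geometry@profiles[[i]]$area_mm2 *
               geometry@profiles[[i]]$length_mm)
  }, numeric(1))
}

# expand a FlowSeries over tree airway ids to a per-element flow matrix
# (trumpets inherit their terminal airway's flow; NULL gives zero flow)
.elementFlows <- function(geometry, flows) {
  el <- geometry@elements
  if (is.null(flows)) {
    return(list(Q = matrix(0, nrow(el), 1L), times = 0, period = 1))
  }
  stopifnot(is(flows, "FlowSeries"))
  Q <- matrix(0, nrow(el), length(flows@times))
  m <- match(el$airway_id, airwayIds(flows))
  ok <- !is.na(m)
  Q[ok, ] <- flowMatrix(flows)[m[ok], , drop = FALSE]
  tr <- which(el$type == "trumpet")
  Q[tr, ] <- Q[el$parent[tr], , drop = FALSE]
  list(Q = Q, times = flows@times, period = flows@period)
}

# periodic linear interpolation of one element's flow at times t
.flowAtTime <- function(ef, e, t) {
  tt <- t %% ef$period
  times <- ef$times
  if (length(times) == 1L) return(rep(ef$Q[e, 1], length(t)))
  xt <- c(times, times[1] + ef$period)
  yq <- c(ef$Q[e, ], ef$Q[e, 1])
  approx(xt, yq, xout = tt, rule = 2)$y
}

#' Seed tracers uniformly over a transport geometry
#'
#' Every airway element and every compartment receives
#' `round(volume / quantum)` tracers so the tracer density is constant
#' throughout the domain. In-airway positions are uniform over each
#' element's gas volume (axially proportional to the local
#' cross-sectional area; radially with `r/R = sqrt(U)` so the
#' cross-section is covered uniformly). All seeded tracers are Type A
#' (resident gas); compartment tracers are held as tallies.
#'
#' @param geometry a [TransportGeometry-class].
#' @param quantum gas volume per tracer, mm^3 (> 0). A quantum larger
#'   than the smallest element volume triggers a warning (that element
#'   may receive no tracer).
#' @param seed integer seed.
#' @return a [TracerState-class]
#' @export
seedTracers <- function(geometry, quantum, seed = 1L) {
  if (quantum <= 0) stop("quantum must be > 0")
  set.seed(as.integer(seed))
  vols <- .elementVolumes(geometry)
  if (quantum > min(vols))
    warning("quantum exceeds the smallest element volume; ",
            "some elements may receive no tracers")
  counts <- round(vols / quantum)
  el <- geometry@elements
  elemIdx <- rep(seq_along(counts), counts)
  n <- length(elemIdx)
  z <- numeric(n); start <- 0L
  for (i in seq_along(counts)) {
    k <- counts[i]
    if (k == 0) next
    sel <- start + seq_len(k)
    if (el$type[i] == "cylinder") {
      z[sel] <- runif(k, 0, el$length_mm[i])
    } else {
      pr <- geometry@profiles[[i]]
      pv <- pr$area_mm2 * pr$length_mm
      piece <- sample.int(nrow(pr), k, replace = TRUE, prob = pv)
      ends <- cumsum(pr$length_mm)
      starts <- ends - pr$length_mm
      z[sel] <- runif(k, starts[piece], ends[piece])
    }
    start <- start + k
  }
  tallies <- round(geometry@compartments$volume_mm3 / quantum)
  st <- new("TracerState",
            type = rep(1L, n), elem = as.integer(elemIdx), z = z,
            rrel = sqrt(runif(n)), theta = runif(n, 0, 2 * pi),
            tallyA = as.numeric(tallies),
            tallyB = numeric(length(tallies)),
            tracheaAccumulator = 0,
            compartmentOutflux = numeric(length(tallies)),
            counts = c(seeded = n + sum(tallies), injected = 0,
                       expiredA = 0, expiredB = 0, heldAtJunction = 0,
                       forfeitedSubSteps = 0, emptyReleases = 0,
                       diffusiveExchanges = 0))
  st
}

# fold engine step results (advection or diffusion) back into the state
.applyEngineResult <- function(state, res) {
  state@elem <- res$elem; state@z <- res$z
  state@rrel <- res$rrel; state@theta <- res$theta
  if (!is.null(res$type)) state@type <- res$type
  if (!is.null(res$relabel) && any(res$relabel == 1L)) {
    rel <- res$relabel == 1L & res$status == 0L
    oldA <- sum(state@type[rel] == 1L)
    state@counts["expiredA"] <- state@counts[["expiredA"]] + oldA
    state@counts["expiredB"] <- state@counts[["expiredB"]] + sum(rel) - oldA
    state@counts["injected"] <- state@counts[["injected"]] + sum(rel)
    state@type[rel] <- 2L
  }
  if (any(res$status == 2L)) {
    ab <- res$status == 2L
    for (tp in 1:2) {
      addc <- tabulate(res$comp[ab & state@type == tp] + 1L,
                       nbins = length(state@tallyA))
      if (tp == 1L) state@tallyA <- state@tallyA + addc
      else state@tallyB <- state@tallyB + addc
    }
  }
  if (any(res$status == 1L)) {
    ex <- res$status == 1L
    state@counts["expiredA"] <- state@counts[["expiredA"]] +
      sum(state@type[ex] == 1L)
    state@counts["expiredB"] <- state@counts[["expiredB"]] +
      sum(state@type[ex] == 2L)
  }
  keep <- res$status == 0L
  state@type <- state@type[keep]; state@elem <- state@elem[keep]
  state@z <- state@z[keep]; state@rrel <- state@rrel[keep]
  state@theta <- state@theta[keep]
  state
}

#' Advect tracers for one time step
#'
#' Each in-airway tracer moves axially with the local gas velocity
#' `u(r, z, t) = 2 Q(t) / A(z) * (1 - (r/R)^2)` (parabolic Poiseuille
#' profile on the quasi-1D mean velocity `Q/A`), integrated with 4th-order
#' Runge-Kutta; flows are linearly interpolated in time (periodic over the
#' cycle). Advection changes only `z`: the radial coordinate and gas type
#' are untouched. Tracers crossing a bifurcation are routed to a candidate
#' airway with probability proportional to its outgoing flow, preserving
#' relative radius `r/R` (azimuth randomized); if no candidate carries
#' flow away from the junction (transient continuity violation) the
#' tracer is held there for the remainder of the step and the event is
#' counted. Tracers leaving through the trachea opening are removed and
#' counted by type; tracers reaching a trumpet's distal end are absorbed
#' into its compartment tally.
#'
#' @param state a [TracerState-class].
#' @param geometry a [TransportGeometry-class].
#' @param flows a [FlowSeries-class] (or `NULL` for zero flow).
#' @param dt step length, ms.
#' @param t0 step start time, ms (flows are evaluated over `[t0, t0+dt]`).
#' @return the updated [TracerState-class]
#' @export
advectTracers <- function(state, geometry, flows, dt, t0 = 0) {
  ef <- .elementFlows(geometry, flows)
  gp <- .packGeometry(geometry)
  res <- cpp_advect(state@elem, state@z, state@rrel, state@theta,
                    gp, ef$Q, ef$times, ef$period, t0, dt)
  state@counts["heldAtJunction"] <-
    state@counts[["heldAtJunction"]] + res$held
  .applyEngineResult(state, res)
}

#' Diffuse tracers for one time step
#'
#' Random-walk molecular diffusion: the step is divided into `subSteps`
#' sub-steps; in each, a tracer moves a distance `|N(0, sigma)|` with
#' `sigma^2 = 6 D tau` (`tau` the sub-step duration) in a uniformly random
#' 3D direction, so the mean squared displacement grows as `6 D t` (the
#' 3D Einstein relation). A tracer crossing the airway wall has its
#' direction randomly reset into the interior half-space at the collision
#' point and continues with its remaining length (up to
#' `maxWallRetries`, after which the sub-step remainder is forfeited and
#' counted). A tracer reaching a bifurcation is routed to one of the
#' three adjoining airways with probability proportional to their
#' cross-sectional areas. Crossing the trachea opening exchanges the
#' tracer for a fresh Type B tracer at the mirrored position (the
#' atmosphere is a fresh-gas reservoir; one expiration and one injection
#' are counted). Crossing the acinar mouth exchanges the tracer with one
#' drawn from the compartment tally in proportion to its contents
#' (bidirectional diffusive flux, zero net volume); net advective
#' absorption and release remain governed by the terminal flux.
#'
#' @param state a [TracerState-class].
#' @param geometry a [TransportGeometry-class].
#' @param D diffusion coefficient, cm^2/s.
#' @param dt step length, ms.
#' @param subSteps number of sub-steps (default 100).
#' @param maxWallRetries wall-collision redraw cap.
#' @return the updated [TracerState-class]
#' @export
diffuseTracers <- function(state, geometry, D, dt, subSteps = 100L,
                           maxWallRetries = 20L) {
  if (D < 0) stop("D must be >= 0")
  if (D == 0 || length(state@type) == 0L) return(state)
  gp <- .packGeometry(geometry)
  res <- cpp_diffuse(state@elem, state@z, state@rrel, state@theta,
                     state@type, state@tallyA, state@tallyB,
                     gp, D * 0.1, dt, as.integer(subSteps),
                     as.integer(maxWallRetries))   # cm^2/s -> mm^2/ms
  state@tallyA <- res$tallyA
  state@tallyB <- res$tallyB
  state@counts["forfeitedSubSteps"] <-
    state@counts[["forfeitedSubSteps"]] + res$forfeited
  state@counts["diffusiveExchanges"] <-
    state@counts[["diffusiveExchanges"]] + res$exchanged
  .applyEngineResult(state, res)
}

#' Route a tracer crossing a bifurcation
#'
#' A tracer exiting an airway into a junction is assigned to one of the
#' candidate airways with probability proportional to the magnitude of
#' the flow carrying gas away from the junction; candidates whose flow
#' is directed toward the junction are ineligible. Returns `NA` when no
#' candidate carries flow away (the caller holds the tracer at the
#' junction for the remainder of the step).
#'
#' @param outgoingFlows numeric vector of candidate flows, each signed
#'   positive when directed away from the junction.
#' @return the chosen candidate index, or `NA`
#' @export
routeAtBifurcation <- function(outgoingFlows) {
  w <- pmax(outgoingFlows, 0)
  if (sum(w) <= 0) return(NA_integer_)
  sample.int(length(w), 1L, prob = w)
}

#' Trachea boundary accumulator update
#'
#' The volume flux into the trachea is integrated in units of tracer
#' quanta; at each step the integer part of the accumulator is the number
#' of fresh (Type B) tracers to insert at the trachea opening, with the
#' remaining decimal part carried forward. Negative inflow reduces the
#' accumulator (which may go negative during expiration); no tracers are
#' injected while it is below one.
#'
#' @param accumulator current accumulator value, tracer quanta.
#' @param inflowVolume gas volume entering over the step, mm^3 (signed).
#' @param quantum tracer volume quantum, mm^3.
#' @return list with `nInject` (integer >= 0) and the updated
#'   `accumulator`
#' @export
tracheaBoundaryUpdate <- function(accumulator, inflowVolume, quantum) {
  if (quantum <= 0) stop("quantum must be > 0")
  acc <- accumulator + inflowVolume / quantum
  n <- floor(acc + 1e-9)                 # guard against 0.3/0.1 = 2.999...
  if (n > 0) acc <- acc - n else n <- 0
  list(nInject = as.integer(n), accumulator = acc)
}

#' Compartment release bookkeeping
#'
#' Volume flowing out of a terminal compartment into its trumpet airway
#' accumulates in tracer quanta; each whole quantum releases one tracer
#' whose type is sampled in proportion to the compartment's current
#' Type A / Type B tallies (decrementing the tally). A release requested
#' from an empty compartment releases nothing and is counted.
#'
#' @param tallyA,tallyB current compartment tallies.
#' @param accumulator current outflux accumulator, tracer quanta.
#' @param outfluxVolume gas volume leaving the compartment this step,
#'   mm^3 (>= 0).
#' @param quantum tracer volume quantum, mm^3.
#' @return list with `releasedA`, `releasedB`, updated `tallyA`,
#'   `tallyB`, `accumulator`, and `emptyReleases`
#' @export
compartmentExchange <- function(tallyA, tallyB, accumulator,
                                outfluxVolume, quantum) {
  if (quantum <= 0) stop("quantum must be > 0")
  acc <- accumulator + outfluxVolume / quantum
  n <- max(floor(acc + 1e-9), 0)         # tolerate binary round-off
  acc <- acc - n
  relA <- relB <- 0L
  empty <- 0L
  for (k in seq_len(n)) {
    tot <- tallyA + tallyB
    if (tot <= 0) { empty <- empty + (n - k + 1L); break }
    if (runif(1) < tallyA / tot) {
      tallyA <- tallyA - 1; relA <- relA + 1L
    } else {
      tallyB <- tallyB - 1; relB <- relB + 1L
    }
  }
  list(releasedA = relA, releasedB = relB, tallyA = tallyA,
       tallyB = tallyB, accumulator = acc, emptyReleases = empty)
}

#' Run the gas-tracer transport simulation
#'
#' Drives the full tracer model over `duration` ms in steps of
#' `config@dt`: Poiseuille advection (with bifurcation routing, trachea
#' removal and compartment absorption), fresh-gas injection at the
#' trachea opening from the integrated inward volume flux, compartment
#' release from the integrated outward terminal flux, then random-walk
#' diffusion. Tracer accounting is exact at every step:
#' `in-airway + in-compartment + expired = seeded + injected`.
#'
#' @param geometry a [TransportGeometry-class].
#' @param flows a [FlowSeries-class] over the tree's airway ids, or
#'   `NULL` for zero flow (diffusion only).
#' @param config a [TransportConfig-class].
#' @param duration total simulated time, ms.
#' @param state optional initial [TracerState-class]; defaults to
#'   [seedTracers()] with `config@quantum`.
#' @param sampleTimes times (ms) at which to record lung-resident
#'   fractions; defaults to the end of the run.
#' @param recordAccounting record per-step conservation bookkeeping
#'   (slower; used by conservation tests).
#' @param seed integer seed for all stochastic draws.
#' @param checkWomersley warn when the Womersley number at
#'   `oscillationHz` reaches 1 anywhere (parabolic-profile validity).
#' @param oscillationHz dominant oscillation frequency for the Womersley
#'   check, Hz.
#' @return list with `state` (final [TracerState-class]), `samples`
#'   (data.frame: time, in-airway and compartment counts by type,
#'   fractions, cumulative expirations/injections) and, when requested,
#'   `accounting` (per-step data.frame with the conservation balance)
#' @export
runTransport <- function(geometry, flows, config, duration,
                         state = NULL, sampleTimes = NULL,
                         recordAccounting = FALSE, seed = 1L,
                         checkWomersley = TRUE, oscillationHz = NULL) {
  stopifnot(is(geometry, "TransportGeometry"), is(config, "TransportConfig"))
  set.seed(as.integer(seed))
  if (is.null(state))
    state <- seedTracers(geometry, config@quantum,
                         seed = as.integer(seed) + 1L)
  if (checkWomersley && !is.null(flows)) {
    if (is.null(oscillationHz)) oscillationHz <- 1000 / flows@period
    wo <- womersleyNumbers(geometry, oscillationHz)
    if (any(wo >= 1))
      warning(sprintf(
        "Womersley number reaches %.2f (>= 1) at %.3g Hz; the parabolic velocity profile assumption weakens",
        max(wo), oscillationHz))
  }
  ef <- .elementFlows(geometry, flows)
  rootElem <- which(is.na(geometry@elements$parent))[1]
  rootArea <- pi * geometry@elements$radius_mm[rootElem]^2
  cp <- geometry@compartments
  trumpetElem <- cp$elem
  dt <- config@dt
  nSteps <- ceiling(duration / dt)
  if (is.null(sampleTimes)) sampleTimes <- nSteps * dt
  sampleTimes <- sort(sampleTimes)
  nextSample <- 1L

  samp <- list()
  acct <- if (recordAccounting) vector("list", nSteps) else NULL
  recordSample <- function(state, t) {
    nAair <- sum(state@type == 1L); nBair <- sum(state@type == 2L)
    tA <- sum(state@tallyA); tB <- sum(state@tallyB)
    lung <- nAair + nBair + tA + tB
    data.frame(time = t, airwayA = nAair, airwayB = nBair,
               compA = tA, compB = tB, lung = lung,
               fractionA = if (lung > 0) (nAair + tA) / lung else NA_real_,
               fractionB = if (lung > 0) (nBair + tB) / lung else NA_real_,
               expiredA = state@counts[["expiredA"]],
               expiredB = state@counts[["expiredB"]],
               injected = state@counts[["injected"]])
  }

  t <- 0
  for (s in seq_len(nSteps)) {
    if (!is.null(flows)) {
      state <- advectTracers(state, geometry, flows, dt, t0 = t)
      # fresh gas injection from the inward volume flux at the opening
      qr <- .flowAtTime(ef, rootElem, c(t, t + dt))
      inflow <- dt * mean(pmax(qr, 0))
      upd <- tracheaBoundaryUpdate(state@tracheaAccumulator, inflow,
                                   config@quantum)
      state@tracheaAccumulator <- upd$accumulator
      if (upd$nInject > 0) {
        k <- upd$nInject
        slug <- max(inflow / rootArea, 1e-6)
        state@type <- c(state@type, rep(2L, k))
        state@elem <- c(state@elem, rep(rootElem, k))
        state@z <- c(state@z, runif(k, 0, min(slug,
                       geometry@elements$length_mm[rootElem])))
        state@rrel <- c(state@rrel, sqrt(runif(k)))
        state@theta <- c(state@theta, runif(k, 0, 2 * pi))
        state@counts["injected"] <- state@counts[["injected"]] + k
      }
      # compartment release from the outward terminal flux
      for (ci in seq_along(trumpetElem)) {
        qtm <- .flowAtTime(ef, trumpetElem[ci], c(t, t + dt))
        outflux <- dt * mean(pmax(-qtm, 0))
        if (outflux <= 0 && state@compartmentOutflux[ci] < 1) next
        ex <- compartmentExchange(state@tallyA[ci], state@tallyB[ci],
                                  state@compartmentOutflux[ci],
                                  outflux, config@quantum)
        state@tallyA[ci] <- ex$tallyA
        state@tallyB[ci] <- ex$tallyB
        state@compartmentOutflux[ci] <- ex$accumulator
        state@counts["emptyReleases"] <-
          state@counts[["emptyReleases"]] + ex$emptyReleases
        k <- ex$releasedA + ex$releasedB
        if (k > 0) {
          Ltr <- geometry@elements$length_mm[trumpetElem[ci]]
          state@type <- c(state@type,
                          rep(c(1L, 2L), c(ex$releasedA, ex$releasedB)))
          state@elem <- c(state@elem, rep(trumpetElem[ci], k))
          state@z <- c(state@z, rep(Ltr * (1 - 1e-9), k))
          state@rrel <- c(state@rrel, sqrt(runif(k)))
          state@theta <- c(state@theta, runif(k, 0, 2 * pi))
        }
      }
    }
    if (config@D > 0)
      state <- diffuseTracers(state, geometry, config@D, dt,
                              config@subSteps, config@maxWallRetries)
    t <- s * dt
    if (recordAccounting) {
      acct[[s]] <- data.frame(
        step = s, time = t,
        inAirways = length(state@type),
        inCompartments = sum(state@tallyA) + sum(state@tallyB),
        expired = state@counts[["expiredA"]] + state@counts[["expiredB"]],
        seeded = state@counts[["seeded"]],
        injected = state@counts[["injected"]])
    }
    while (nextSample <= length(sampleTimes) &&
           sampleTimes[nextSample] <= t + 1e-9) {
      samp[[length(samp) + 1L]] <- recordSample(state,
                                                sampleTimes[nextSample])
      nextSample <- nextSample + 1L
    }
  }
  out <- list(state = state, samples = do.call(rbind, samp))
  if (recordAccounting) out$accounting <- do.call(rbind, acct)
  out
}
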