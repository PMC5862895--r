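#' @include acquisition-log.R
NULL

# phase fraction in [0, 1) of each time relative to a trigger train;
# after the last trigger the median cycle length extrapolates the phase.
.phaseFraction <- function(times, triggers) {
  n <- length(times)
  frac <- rep(NA_real_, n)
  extrapolated <- logical(n)
  idx <- findInterval(times, triggers)
  inside <- idx >= 1L & idx < length(triggers)
  frac[inside] <- (times[inside] - triggers[idx[inside]]) /
    (triggers[idx[inside] + 1L] - triggers[idx[inside]])
  last <- idx == length(triggers)
  if (any(last)) {
    med <- if (length(triggers) > 1L) median(diff(triggers)) else NA_real_
    if (!is.na(med)) {
      frac[last] <- ((times[last] - triggers[length(triggers)]) / med) %% 1
      extrapolated[last] <- TRUE
    }
  }
  list(fraction = frac, extrapolated = extrapolated)
}

#' Retrospective cardiorespiratory double gating
#'
#' Assigns each acquisition frame to one of `nVentBins` ventilation-phase
#' bins (phase = elapsed fraction of its ventilation cycle, bin =
#' `floor(phase * nVentBins)`) and, independently, to one of `nCardBins`
#' cardiac-phase bins from the R-R interval fraction. Frames acquired at
#' airway pressure at or above `pressureThreshold` are excluded from
#' cardiac binning only (the `< threshold` filter suppresses
#' ventilation-induced motion blur in the cardiac-phase data, which is
#' thereby reconstructed at approximately expiratory pressure). Phase
#' fractions use the half-open convention: a frame exactly at a trigger
#' starts the next cycle at phase 0. Frames before the first trigger or
#' R-peak are reported as unbinnable, not silently dropped; frames after
#' the last one are phased with the median cycle length and flagged.
#'
#' @param log an [AcquisitionLog-class]
#' @param nVentBins number of ventilation phase bins (default 19).
#' @param nCardBins number of cardiac phase bins (default 8).
#' @param pressureThreshold cmH2O; frames with pressure strictly below it
#'   are eligible for cardiac binning (default 4).
#' @return a [GatingResult-class]
#' @export
doubleGateFrames <- function(log, nVentBins = 19L, nCardBins = 8L,
                             pressureThreshold = 4) {
  stopifnot(is(log, "AcquisitionLog"))
  if (length(log@ventTriggerTimes) < 1L)
    stop("log must contain at least one ventilation trigger")
  if (length(log@ecgRpeakTimes) < 2L)
    stop("log must contain at least two R-peaks")
  nVentBins <- as.integer(nVentBins)
  nCardBins <- as.integer(nCardBins)
  t <- log@frameTimes
  n <- length(t)
  frames <- seq_len(n)

  vph <- .phaseFraction(t, log@ventTriggerTimes)
  ventBin <- ifelse(is.na(vph$fraction), NA_integer_,
                    pmin(as.integer(floor(vph$fraction * nVentBins)),
                         nVentBins - 1L))
  cph <- .phaseFraction(t, log@ecgRpeakTimes)
  cardBin <- ifelse(is.na(cph$fraction), NA_integer_,
                    pmin(as.integer(floor(cph$fraction * nCardBins)),
                         nCardBins - 1L))

  highP <- log@airwayPressure >= pressureThreshold
  cardEligible <- !is.na(cardBin) & !highP

  ventBins <- lapply(seq_len(nVentBins) - 1L,
                     function(b) frames[!is.na(ventBin) & ventBin == b])
  cardBins <- lapply(seq_len(nCardBins) - 1L,
                     function(b) frames[cardEligible & cardBin == b])

  new("GatingResult",
      ventBins = ventBins, cardBins = cardBins,
      excludedFromCardiac = frames[highP & !is.na(cardBin)],
      unbinnableVent = frames[is.na(ventBin)],
      unbinnableCard = frames[is.na(cardBin)],
      extrapolatedVent = frames[vph$extrapolated],
      extrapolatedCard = frames[cph$extrapolated],
      params = list(nVentBins = nVentBins, nCardBins = nCardBins,
                    pressureThreshold = pressureThreshold))
}
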