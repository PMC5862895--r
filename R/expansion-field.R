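#' @include tree.R
NULL

#' Pressure-controlled ventilation waveform
#'
#' Normalized lung-inflation waveform for pressure-controlled ventilation:
#' exponential rise toward the inflation plateau during the inspiration
#' time, exponential decay toward PEEP during the expiration time. The
#' waveform is exactly periodic with period `tInsp + tExp` and scaled to
#' `[0, 1]` (0 = end expiration, 1 = end inspiration).
#'
#' @param t times, ms (any real values; the waveform is periodic).
#' @param tInsp inspiration time, ms (default 120).
#' @param tExp expiration time, ms (default 280).
#' @param tauInsp,tauExp exponential time constants, ms.
#' @return numeric vector in `[0, 1]`
#' @export
ventilationWaveform <- function(t, tInsp = 120, tExp = 280,
                                tauInsp = tInsp / 4, tauExp = tExp / 4) {
  period <- tInsp + tExp
  tt <- t %% period
  a <- tInsp / tauInsp
  b <- tExp / tauExp
  # periodic fixed point of the rise/decay pair
  w0 <- exp(-b) * (1 - exp(-a)) / (1 - exp(-a - b))
  wpk <- 1 - (1 - w0) * exp(-a)
  w <- ifelse(tt < tInsp,
              1 - (1 - w0) * exp(-tt / tauInsp),
              wpk * exp(-(tt - tInsp) / tauExp))
  (w - w0) / (wpk - w0)
}

# smallest k <= kmax with k * ratio integral (composite cycle multiplier)
.compositeMultiplier <- function(ratio, kmax = 1000L, tol = 1e-9) {
  for (k in seq_len(kmax)) {
    if (abs(k * ratio - round(k * ratio)) < tol) return(k)
  }
  stop("heart/ventilation frequency ratio admits no composite cycle <= ",
       kmax, " ventilation cycles; use a rational ratio")
}

#' Generate a synthetic regional expansion field
#'
#' Places tissue interrogation regions around the terminal airways of a
#' tree and builds per-region volume traces over one composite cycle:
#' `V_i(t) = V0_i * (1 + s * [vent_i(t) + card_i(t)])` where `vent_i` is
#' the (optionally per-region time-jittered) pressure-controlled
#' ventilation waveform and `card_i` is a cardiogenic sinusoid at
#' `frequencyRatio` times the ventilation frequency whose amplitude decays
#' as `exp(-d/decayLength)` with distance `d` from the heart locus and
#' whose phase lags by `phaseLagRate * d`, emulating the wave-like
#' displacement of tissue away from the beating heart that redistributes
#' gas between regions (pendelluft). The common scale `s` is set so the
#' total regional tidal volume matches `tidalTarget` when requested.
#'
#' @param tree an [AirwayTree-class]; regions are scattered around its
#'   terminal airway end points.
#' @param ventAmplitude fractional volume excursion of the ventilation
#'   component (>= 0; 0 gives a cardiac-only field).
#' @param cardiacAmplitude fractional cardiac excursion at the heart locus
#'   (>= 0; 0 gives a ventilation-only field).
#' @param tInsp,tExp inspiration/expiration times, ms.
#' @param frequencyRatio heart rate over ventilation rate (default 3;
#'   rational values such as 3.07 decorrelate the two cycles at the cost
#'   of a longer composite period).
#' @param decayLength cardiac amplitude decay length from the heart, mm.
#' @param phaseLagRate cardiac phase lag per mm from the heart, rad/mm.
#' @param heartLocus length-3 point (mm); default places it off-centre
#'   among the terminal airways, emulating the left-lobe heart vicinity.
#' @param regionsPerTerminal regions scattered around each terminal.
#' @param regionScatter s.d. of the scatter, mm.
#' @param baselineTotal total baseline (end-expiratory) lung volume, mm^3.
#' @param ventHeterogeneity s.d. of per-region fractional spread of the
#'   ventilation amplitude.
#' @param ventTimeJitter s.d. of per-region ventilation time shifts, ms
#'   (compliance/resistance time-constant heterogeneity; the source of the
#'   small pendelluft seen under pure mechanical ventilation).
#' @param tidalTarget optional total regional tidal volume, mm^3; the
#'   field is rescaled so `sum(max V_i - min V_i)` matches it within 1%.
#' @param nPhases phase samples over one composite cycle.
#' @param seed integer seed.
#' @return an [ExpansionField-class]
#' @export
generateExpansionField <- function(tree, ventAmplitude = 0.3,
                                   cardiacAmplitude = 0.15,
                                   tInsp = 120, tExp = 280,
                                   frequencyRatio = 3,
                                   decayLength = 2, phaseLagRate = 0.8,
                                   heartLocus = NULL,
                                   regionsPerTerminal = 4L,
                                   regionScatter = 0.4,
                                   baselineTotal = 500,
                                   ventHeterogeneity = 0.1,
                                   ventTimeJitter = 4,
                                   tidalTarget = NULL,
                                   nPhases = 60L, seed = 1L) {
  if (ventAmplitude < 0 || cardiacAmplitude < 0)
    stop("amplitudes must be >= 0")
  if (frequencyRatio <= 0) stop("frequencyRatio must be > 0")
  set.seed(as.integer(seed))

  seg <- segmentTable(tree)
  term <- seg[seg$id %in% terminalIds(tree), ]
  nReg <- nrow(term) * regionsPerTerminal
  centers <- term[rep(seq_len(nrow(term)), each = regionsPerTerminal),
                  c("x2", "y2", "z2")]
  centers <- as.matrix(centers) + matrix(rnorm(3 * nReg, 0, regionScatter),
                                         nReg, 3)
  dimnames(centers) <- NULL

  if (is.null(heartLocus)) {
    heartLocus <- c(quantile(term$x2, 0.15), mean(term$y2),
                    quantile(term$z2, 0.55))
    names(heartLocus) <- NULL
  }
  d <- sqrt(rowSums((centers - matrix(heartLocus, nReg, 3, byrow = TRUE))^2))

  ventPeriod <- tInsp + tExp
  k <- .compositeMultiplier(frequencyRatio)
  period <- k * ventPeriod
  tt <- (seq_len(nPhases) - 1) / nPhases * period

  V0 <- rep(baselineTotal / nReg, nReg)
  hvent <- pmax(1 + rnorm(nReg, 0, ventHeterogeneity), 0.2)
  dvent <- rnorm(nReg, 0, ventTimeJitter)
  cardAmp <- cardiacAmplitude * exp(-d / decayLength)
  cardPhase <- phaseLagRate * d
  fCard <- frequencyRatio / ventPeriod     # cycles per ms

  Fmat <- matrix(0, nReg, nPhases)
  for (i in seq_len(nReg)) {
    Fmat[i, ] <- ventAmplitude * hvent[i] *
      ventilationWaveform(tt - dvent[i], tInsp, tExp) +
      cardAmp[i] * sin(2 * pi * fCard * tt - cardPhase[i])
  }

  s <- 1
  if (!is.null(tidalTarget)) {
    excursion <- sum(V0 * (apply(Fmat, 1, max) - apply(Fmat, 1, min)))
    if (excursion <= 0)
      stop("cannot scale a constant field to a tidal volume target")
    s <- tidalTarget / excursion
  }
  V <- V0 * (1 + s * Fmat)
  if (any(V <= 0))
    stop("amplitudes produce non-positive region volumes; reduce them")

  new("ExpansionField",
      regionCenters = centers, phaseTimes = tt, regionVolumes = V,
      heartLocus = as.numeric(heartLocus),
      params = list(cyclePeriod = period, ventPeriod = ventPeriod,
                    tInsp = tInsp, tExp = tExp,
                    frequencyRatio = frequencyRatio,
                    ventAmplitude = ventAmplitude,
                    cardiacAmplitude = cardiacAmplitude,
                    decayLength = decayLength, phaseLagRate = phaseLagRate,
                    scale = s, seed = seed, regionBaseline = V0,
                    distanceToHeart = d, terminalIds = term$id,
                    regionsPerTerminal = regionsPerTerminal))
}
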