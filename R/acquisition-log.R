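#' @include expansion-field.R
NULL

#' Generate a synthetic acquisition log
#'
#' Emulates the timing/telemetry side-channel of a dynamic lung imaging
#' run: frame times at a fixed frame rate, ventilation trigger times at the
#' ventilator period, quasi-periodic ECG R-peaks, and the airway pressure
#' trace cycling between PEEP and the inflation pressure.
#'
#' @param duration total duration, ms (must cover at least 2 ventilation
#'   cycles).
#' @param frameRate frames per second (default 50).
#' @param ventPeriod ventilation cycle period, ms (default 400 =
#'   120 ms inspiration + 280 ms expiration).
#' @param heartPeriod mean R-R interval, ms; default `ventPeriod / 3`
#'   (heart rate about three times the ventilation rate).
#' @param tInsp,tExp inspiration/expiration times for the pressure trace.
#' @param inflationPressure,peep pressure plateau and PEEP, cmH2O.
#' @param jitter s.d. of R-R interval jitter, ms (0 gives exactly periodic
#'   R-peaks).
#' @param pressureNoise s.d. of measurement noise on the pressure, cmH2O.
#' @param heartOffset time of the first R-peak, ms.
#' @param seed integer seed.
#' @return an [AcquisitionLog-class]
#' @export
generateAcquisitionLog <- function(duration, frameRate = 50,
                                   ventPeriod = 400, heartPeriod = NULL,
                                   tInsp = 120, tExp = 280,
                                   inflationPressure = 10, peep = 2,
                                   jitter = 2, pressureNoise = 0,
                                   heartOffset = 15, seed = 1L) {
  if (duration < 2 * ventPeriod)
    stop("duration must cover at least 2 ventilation cycles")
  if (is.null(heartPeriod)) heartPeriod <- ventPeriod / 3
  if (heartPeriod <= 0) stop("heartPeriod must be > 0")
  set.seed(as.integer(seed))

  nFrames <- floor(duration * frameRate / 1000)
  frameTimes <- (seq_len(nFrames) - 1) * 1000 / frameRate
  ventTriggerTimes <- seq(0, duration, by = ventPeriod)

  nBeats <- ceiling((duration - heartOffset) / heartPeriod) + 1L
  intervals <- heartPeriod + rnorm(nBeats, 0, jitter)
  if (any(intervals <= 0))
    stop("jitter too large relative to heartPeriod")
  rpeaks <- heartOffset + c(0, cumsum(intervals))
  rpeaks <- rpeaks[rpeaks <= duration]

  # pressure-controlled trace: fast rise to the plateau, decay to PEEP
  w <- ventilationWaveform(frameTimes %% ventPeriod, tInsp, tExp,
                           tauInsp = tInsp / 6, tauExp = tExp / 6)
  pressure <- peep + (inflationPressure - peep) * w +
    rnorm(nFrames, 0, pressureNoise)

  new("AcquisitionLog",
      frameTimes = frameTimes, ventTriggerTimes = ventTriggerTimes,
      ecgRpeakTimes = rpeaks, airwayPressure = pressure,
      params = list(duration = duration, frameRate = frameRate,
                    ventPeriod = ventPeriod, heartPeriod = heartPeriod,
                    inflationPressure = inflationPressure, peep = peep,
                    jitter = jitter, pressureNoise = pressureNoise,
                    seed = seed))
}
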