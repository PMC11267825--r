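.defaultOrientation <- "rows: 1 = ventral -> dorsal; cols: 1 = right -> left"

## Healthy-sheep baseline feature values and the 120-s edema endpoints the
## default trajectory is tuned to.  Band fractions are renormalized to sum
## to exactly 100 by simConfig().
.defaultBaseline <- c(cov_vd = 52.8, cov_rl = 50, tiv = 1460, eeli = 2445,
                      nss = 7.04, dss = 8.42,
                      dz_v = 7.64, dz_cv = 36.9, dz_cd = 41.8, dz_d = 13.7)
.defaultPlateau  <- c(cov_vd = 58.0, cov_rl = 50, tiv = 1309, eeli = 732,
                      nss = 4.09, dss = 12.4,
                      dz_v = 4.81, dz_cv = 29.3, dz_cd = 45.0, dz_d = 20.8)

.defaultNoise <- c(cov_vd = 0.01, cov_rl = 0.01, tiv = 0.03, eeli = 0.03,
                   nss = 0.10, dss = 0.10,
                   dz_v = 0.03, dz_cv = 0.03, dz_cd = 0.03, dz_d = 0.03,
                   raw = 0.03, cdyn = 0.03,
                   etco2 = 0.02, vdaw = 0.02, siii = 0.05)

.defaultSubjectSd <- c(cov_vd = 0.08, cov_rl = 0.02, tiv = 0.14, eeli = 0.28,
                       nss = 0.50, dss = 0.50,
                       dz_v = 0.25, dz_cv = 0.10, dz_cd = 0.05, dz_d = 0.25,
                       raw = 0.20, cdyn = 0.20,
                       etco2 = 0.05, vdaw = 0.10, siii = 0.20)

.renormBands <- function(f, what) {
  s <- sum(f[.bandNames])
  if (abs(s - 100) > 0.5)
    stop(what, " band fractions sum to ", signif(s, 6),
         "; must be within 0.5 of 100", call. = FALSE)
  f[.bandNames] <- f[.bandNames] * 100 / s
  f
}

#' Build a simulation configuration
#'
#' Returns a [SimConfig] describing the virtual edema experiment.  The
#' defaults reproduce the study conditions: 15 subjects under
#' volume-controlled ventilation at 10 mL/kg and 10 breaths/min with zero
#' PEEP, EIT at 47 frames/s on a 32 x 32 grid, airway signals at 100 Hz,
#' a 10-s apnea at \[-70, -60) s, a 60-s baseline, a 60-s injection
#' starting at t = 0 and recording to +360 s.  Baseline EIT feature
#' values default to the published healthy-sheep baselines and the
#' trajectory plateau to the published 120-s values.  Band-fraction
#' vectors are renormalized to sum to exactly 100 (printed values may
#' carry rounding).
#'
#' @param nSubjects number of subjects (default 15).
#' @param bodyMass body mass in kg (default 50, an adult Merino ewe).
#' @param tidalVolumePerKg tidal volume in mL/kg (default 10).
#' @param respRate breaths per minute (default 10).
#' @param peep PEEP in cmH2O (default 0).
#' @param eitFrameRate EIT frame rate in Hz (default 47).
#' @param airwaySampleRate airway sampling rate in Hz (default 100).
#' @param gridHeight,gridWidth EIT grid size in pixels (default 32 x 32).
#' @param maskGeometry lung-mask geometry, see [makeLungMask()].
#' @param baselineFeatures,plateauFeatures named feature vectors; partial
#'   vectors override the defaults element-wise.
#' @param mechBaseline,mechPlateau,capnoBaseline,capnoPlateau named
#'   mechanics/capnography parameters, overriding defaults element-wise.
#' @param noiseSd,interSubjectSd named relative SDs, overriding defaults
#'   element-wise.  Set `noiseSd = 0` to zero all per-breath noise.
#' @param onsetT0,onsetTau,plateauTime edema-trajectory timing in s
#'   (defaults 30, 20, 120).
#' @param inspFraction,pauseFraction breath timing as fractions of the
#'   cycle (defaults 1/3 inspiratory time, 0.1 end-inspiratory pause).
#' @param spontEffortProb,spontEffortDepth optional spontaneous-effort
#'   contamination (probability per breath, cmH2O below PEEP).
#' @param timeline named vector of segment times in s.
#' @param seed integer root seed; per-subject streams are derived from it
#'   by fixed offsets.
#' @return a validated [SimConfig].
#' @examples
#' cfg <- simConfig(nSubjects = 1, noiseSd = 0)
#' cfg
#' @export
simConfig <- function(nSubjects = 15, bodyMass = 50, tidalVolumePerKg = 10,
                      respRate = 10, peep = 0, eitFrameRate = 47,
                      airwaySampleRate = 100, gridHeight = 32, gridWidth = 32,
                      maskGeometry = list(),
                      baselineFeatures = numeric(), plateauFeatures = numeric(),
                      mechBaseline = numeric(), mechPlateau = numeric(),
                      capnoBaseline = numeric(), capnoPlateau = numeric(),
                      noiseSd = numeric(), interSubjectSd = numeric(),
                      onsetT0 = 30, onsetTau = 20, plateauTime = 120,
                      inspFraction = 1 / 3, pauseFraction = 0.1,
                      spontEffortProb = 0, spontEffortDepth = 3,
                      timeline = c(apneaStart = -70, apneaEnd = -60,
                                   baselineStart = -60, injectionStart = 0,
                                   injectionEnd = 60, recordEnd = 360),
                      seed = 1L) {
  merge <- function(default, user) {
    if (length(user) == 1 && is.null(names(user)))
      return(setNames(rep(user, length(default)), names(default)))
    default[names(user)] <- user
    default
  }
  geom <- list(rowCenter = 0.5, rowRadius = 0.34, colRadius = 0.18,
               lobeOffset = 0.22, bridgeHalfWidth = 1)
  geom[names(maskGeometry)] <- maskGeometry
  base <- .renormBands(merge(.defaultBaseline, baselineFeatures), "baseline")
  plat <- .renormBands(merge(.defaultPlateau, plateauFeatures), "plateau")
  new("SimConfig",
      nSubjects = as.integer(nSubjects), bodyMass = bodyMass,
      tidalVolumePerKg = tidalVolumePerKg, respRate = respRate, peep = peep,
      eitFrameRate = eitFrameRate, airwaySampleRate = airwaySampleRate,
      gridHeight = as.integer(gridHeight), gridWidth = as.integer(gridWidth),
      maskGeometry = geom,
      baselineFeatures = base, plateauFeatures = plat,
      mechBaseline = merge(c(raw = 8, crs = 25), mechBaseline),
      mechPlateau = merge(c(rawScale = 1.5, cdynScale = 0.7), mechPlateau),
      capnoBaseline = merge(c(etco2 = 40, vdawFrac = 0.30, siii = 6,
                              phase2Width = 10), capnoBaseline),
      capnoPlateau = merge(c(etco2Scale = 0.85, vdawScale = 1.15,
                             siiiScale = 1.2), capnoPlateau),
      noiseSd = merge(.defaultNoise, noiseSd),
      interSubjectSd = merge(.defaultSubjectSd, interSubjectSd),
      onsetT0 = onsetT0, onsetTau = onsetTau, plateauTime = plateauTime,
      inspFraction = inspFraction, pauseFraction = pauseFraction,
      spontEffortProb = spontEffortProb, spontEffortDepth = spontEffortDepth,
      timeline = timeline, seed = as.integer(seed))
}

#' Construct an EITSequence
#'
#' @param frames numeric 3-D array (time x height x width, AU).
#' @param frameRate frames per second.
#' @param lungMask logical matrix matching the frame dimensions.
#' @param orientation orientation tag (default: row 1 ventral, col 1 right).
#' @return an [EITSequence].
#' @export
eitSequence <- function(frames, frameRate, lungMask,
                        orientation = .defaultOrientation) {
  new("EITSequence", frames = frames, frameRate = frameRate,
      lungMask = lungMask, orientation = orientation)
}

#' Construct an AirwaySignals object
#'
#' @param time time in s (strictly increasing, uniform).
#' @param flow airway flow in L/s (positive = inspiration).
#' @param paw airway pressure in cmH2O.
#' @param pco2 CO2 tension in mmHg.
#' @param sampleRate samples per second; inferred from `time` if missing.
#' @return an [AirwaySignals].
#' @export
airwaySignals <- function(time, flow, paw, pco2,
                          sampleRate = 1 / median(diff(time))) {
  new("AirwaySignals", time = time, flow = flow, paw = paw, pco2 = pco2,
      sampleRate = sampleRate)
}

#' Construct an EventLog
#'
#' @param apneaStart,apneaEnd,injectionStart,injectionEnd times in s.
#' @return an [EventLog].
#' @export
eventLog <- function(apneaStart, apneaEnd, injectionStart, injectionEnd) {
  new("EventLog", apneaStart = apneaStart, apneaEnd = apneaEnd,
      injectionStart = injectionStart, injectionEnd = injectionEnd)
}
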