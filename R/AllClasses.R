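#' @import methods
#' @importFrom stats aggregate approx coef lm median plogis qt quantile
#'   rnorm runif sd setNames t.test uniroot
#' @importFrom utils read.csv write.csv
NULL

## Feature names used throughout the EIT side of the pipeline.  Band
## fractions (dz_*) are % of total tidal impedance change; cov_* are % of
## the lung-region extent; nss/dss are % of lung pixels; tiv/eeli are AU.
.eitFeatureNames <- c("cov_vd", "cov_rl", "tiv", "eeli", "nss", "dss",
                      "dz_v", "dz_cv", "dz_cd", "dz_d")
.bandNames <- c("dz_v", "dz_cv", "dz_cd", "dz_d")

#' SimConfig: parameters of the virtual edema experiment
#'
#' Holds everything the cohort simulator needs: ventilator settings,
#' acquisition rates, the EIT grid and lung-mask geometry, per-variable
#' baseline values (defaults are the published healthy-sheep baselines),
#' the 120-s edema endpoints the trajectory is tuned to, noise levels and
#' the experiment timeline.  Construct with [simConfig()].
#'
#' @slot nSubjects number of virtual subjects.
#' @slot bodyMass body mass per subject (kg).
#' @slot tidalVolumePerKg set tidal volume (mL/kg).
#' @slot respRate ventilator rate (breaths/min).
#' @slot peep positive end-expiratory pressure (cmH2O).
#' @slot eitFrameRate EIT frame rate (Hz).
#' @slot airwaySampleRate airway signal sample rate (Hz).
#' @slot gridHeight,gridWidth EIT reconstruction grid size (pixels).
#' @slot maskGeometry named list of lung-mask geometry parameters
#'   (see [makeLungMask()]).
#' @slot baselineFeatures named numeric vector of baseline EIT feature
#'   values (`cov_vd`, `cov_rl`, `tiv`, `eeli`, `nss`, `dss`, `dz_v`,
#'   `dz_cv`, `dz_cd`, `dz_d`).
#' @slot plateauFeatures same names; the values the edema trajectory
#'   reaches at `plateauTime`.
#' @slot mechBaseline named vector: `raw` (cmH2O/(L/s)) and `crs`
#'   (single-compartment compliance, mL/cmH2O).
#' @slot mechPlateau named vector: `rawScale`, `cdynScale` multipliers at
#'   the trajectory plateau.
#' @slot capnoBaseline named vector: `etco2` (mmHg), `vdawFrac`
#'   (airway dead space as a fraction of VT), `siii` (mmHg/L),
#'   `phase2Width` (mL, logistic width of the phase II transition).
#' @slot capnoPlateau named vector: `etco2Scale`, `vdawScale`,
#'   `siiiScale` plateau multipliers.
#' @slot noiseSd named relative per-breath noise SD per feature.
#' @slot interSubjectSd named relative between-subject SD of baselines.
#' @slot onsetT0,onsetTau logistic onset midpoint and timescale (s).
#' @slot plateauTime time (s) by which the trajectory reaches the
#'   configured plateau values.
#' @slot inspFraction fraction of the breath cycle spent in inspiration
#'   (flow delivery plus pause).
#' @slot pauseFraction fraction of the breath cycle spent in the
#'   end-inspiratory pause.
#' @slot spontEffortProb probability that a breath carries a simulated
#'   spontaneous-effort deflection (0 by default).
#' @slot spontEffortDepth depth of that deflection below PEEP (cmH2O).
#' @slot timeline named vector `apneaStart`, `apneaEnd`, `baselineStart`,
#'   `injectionStart`, `injectionEnd`, `recordEnd` (s, injection start = 0).
#' @slot seed integer root seed.
#' @name SimConfig-class
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nSubjects        = "integer",
  bodyMass         = "numeric",
  tidalVolumePerKg = "numeric",
  respRate         = "numeric",
  peep             = "numeric",
  eitFrameRate     = "numeric",
  airwaySampleRate = "numeric",
  gridHeight       = "integer",
  gridWidth        = "integer",
  maskGeometry     = "list",
  baselineFeatures = "numeric",
  plateauFeatures  = "numeric",
  mechBaseline     = "numeric",
  mechPlateau      = "numeric",
  capnoBaseline    = "numeric",
  capnoPlateau     = "numeric",
  noiseSd          = "numeric",
  interSubjectSd   = "numeric",
  onsetT0          = "numeric",
  onsetTau         = "numeric",
  plateauTime      = "numeric",
  inspFraction     = "numeric",
  pauseFraction    = "numeric",
  spontEffortProb  = "numeric",
  spontEffortDepth = "numeric",
  timeline         = "numeric",
  seed             = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c(respRate = object@respRate, eitFrameRate = object@eitFrameRate,
           airwaySampleRate = object@airwaySampleRate,
           bodyMass = object@bodyMass,
           tidalVolumePerKg = object@tidalVolumePerKg)
  if (any(pos <= 0))
    msg <- c(msg, paste0("rates and ventilator settings must be > 0: ",
                         paste(names(pos)[pos <= 0], collapse = ", ")))
  for (nm in c("baselineFeatures", "plateauFeatures")) {
    f <- slot(object, nm)
    miss <- setdiff(.eitFeatureNames, names(f))
    if (length(miss))
      msg <- c(msg, paste0(nm, " missing: ", paste(miss, collapse = ", ")))
    else if (abs(sum(f[.bandNames]) - 100) > 0.01)
      msg <- c(msg, paste0(nm, " band fractions must sum to 100 +/- 0.01"))
  }
  tl <- object@timeline
  need <- c("apneaStart", "apneaEnd", "baselineStart", "injectionStart",
            "injectionEnd", "recordEnd")
  if (!all(need %in% names(tl)))
    msg <- c(msg, "timeline must name apneaStart, apneaEnd, baselineStart, injectionStart, injectionEnd, recordEnd")
  else if (is.unsorted(tl[need], strictly = FALSE))
    msg <- c(msg, "timeline segments must be ordered and non-overlapping")
  if (length(msg)) msg else TRUE
})

#' EdemaState: the edema trajectory evaluated at one time point
#'
#' Dimensionless multipliers describing how far edema has progressed at
#' time `t` (seconds relative to injection start).  `progress` is the
#' normalized logistic time course in `[0, ~1]`; the remaining slots are
#' derived per-variable scales: `eeliScale`/`tivScale`/`cdynScale`/
#' `etco2Scale` fall from 1, `rawScale`/`siiiScale`/`vdawScale` rise from
#' 1, `ventralLoss`/`cvLoss` are the fractions of ventral and
#' centro-ventral band ventilation reassigned dorsally and `dorsalShare`
#' is the fraction of that freed ventilation going to the dorsal (rest to
#' the centro-dorsal) band.
#'
#' @name EdemaState-class
#' @aliases EdemaState
#' @exportClass EdemaState
setClass("EdemaState", representation(
  t = "numeric", progress = "numeric",
  eeliScale = "numeric", tivScale = "numeric",
  ventralLoss = "numeric", cvLoss = "numeric", dorsalShare = "numeric",
  rawScale = "numeric", cdynScale = "numeric",
  siiiScale = "numeric", etco2Scale = "numeric", vdawScale = "numeric"
))

setValidity("EdemaState", function(object) {
  msg <- character()
  if (object@eeliScale <= 0 || object@eeliScale > 1 + 1e-9)
    msg <- c(msg, "eeliScale must lie in (0, 1]")
  if (object@ventralLoss < 0 || object@ventralLoss >= 1)
    msg <- c(msg, "ventralLoss must lie in [0, 1)")
  if (object@rawScale < 1) msg <- c(msg, "rawScale must be >= 1")
  if (object@cdynScale <= 0 || object@cdynScale > 1 + 1e-9)
    msg <- c(msg, "cdynScale must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' EITSequence: a reconstructed pixel-impedance frame sequence
#'
#' Time-ordered EIT frames with the lung-region mask and the orientation
#' convention used throughout the package: row 1 is the most ventral
#' pixel row and rows increase dorsally; column 1 is the subject's right
#' side and columns increase leftward.
#'
#' @slot frames numeric array, time x height x width, arbitrary units.
#' @slot frameRate frames per second.
#' @slot lungMask logical matrix, height x width.
#' @slot orientation character tag recording the convention above.
#' @name EITSequence-class
#' @aliases EITSequence
#' @exportClass EITSequence
setClass("EITSequence", representation(
  frames = "array", frameRate = "numeric",
  lungMask = "matrix", orientation = "character"
))

setValidity("EITSequence", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3) msg <- c(msg, "frames must be a 3-D array (time x height x width)")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(d) == 3 && !identical(dim(object@lungMask), d[2:3]))
    msg <- c(msg, "lung_mask dimensions must equal the frame dimensions")
  if (!any(object@lungMask)) msg <- c(msg, "lung_mask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' AirwaySignals: synchronized airway-opening signals
#'
#' Uniformly sampled flow (L/s, positive = inspiration), airway pressure
#' (cmH2O) and CO2 tension (mmHg) on a common time grid (s).
#'
#' @name AirwaySignals-class
#' @aliases AirwaySignals
#' @exportClass AirwaySignals
setClass("AirwaySignals", representation(
  time = "numeric", flow = "numeric", paw = "numeric", pco2 = "numeric",
  sampleRate = "numeric"
))

setValidity("AirwaySignals", function(object) {
  msg <- character()
  n <- length(object@time)
  if (!all(lengths(list(object@flow, object@paw, object@pco2)) == n))
    msg <- c(msg, "time, flow, paw and pco2 must have equal lengths")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  if (n > 1) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msg <- c(msg, "time must be strictly increasing")
    else if (max(dt) - min(dt) > 1e-6 * mean(dt) + 1e-9)
      msg <- c(msg, "time must be uniformly sampled")
  }
  if (length(msg)) msg else TRUE
})

#' EventLog: experiment event times
#'
#' Times (s, relative to injection start) of the synchronization apnea
#' and of the start and end of the edemagenic injection.
#'
#' @name EventLog-class
#' @aliases EventLog
#' @exportClass EventLog
setClass("EventLog", representation(
  apneaStart = "numeric", apneaEnd = "numeric",
  injectionStart = "numeric", injectionEnd = "numeric"
))

setValidity("EventLog", function(object) {
  msg <- character()
  if (object@apneaEnd < object@apneaStart)
    msg <- c(msg, "apneaEnd must be >= apneaStart")
  if (object@apneaEnd > object@injectionStart)
    msg <- c(msg, "apnea must precede the injection")
  if (object@injectionEnd < object@injectionStart)
    msg <- c(msg, "injectionEnd must be >= injectionStart")
  if (length(msg)) msg else TRUE
})

#' TidalImage: per-pixel impedance change over one inspiration
#'
#' The pixel-wise difference between the end-inspiratory and
#' start-inspiratory frames, restricted to the lung mask, together with
#' the bounding extent of the mask (ventral/dorsal rows, right/left
#' columns) on which regional variables are normalized.
#'
#' @name TidalImage-class
#' @aliases TidalImage
#' @exportClass TidalImage
setClass("TidalImage", representation(
  dz = "matrix", mask = "matrix",
  ventralEdge = "integer", dorsalEdge = "integer",
  rightEdge = "integer", leftEdge = "integer"
))

setValidity("TidalImage", function(object) {
  msg <- character()
  if (!identical(dim(object@dz), dim(object@mask)))
    msg <- c(msg, "dz and mask dimensions must agree")
  rr <- range(which(rowSums(object@mask) > 0))
  cc <- range(which(colSums(object@mask) > 0))
  if (object@ventralEdge > rr[1] || object@dorsalEdge < rr[2] ||
      object@rightEdge > cc[1] || object@leftEdge < cc[2])
    msg <- c(msg, "extent must enclose all mask pixels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  tl <- object@timeline
  cat("SimConfig:", object@nSubjects, "subjects,",
      object@tidalVolumePerKg, "mL/kg at", object@respRate,
      "breaths/min, PEEP", object@peep, "cmH2O\n")
  cat("  EIT", object@eitFrameRate, "Hz on a", object@gridHeight, "x",
      object@gridWidth, "grid; airway", object@airwaySampleRate, "Hz\n")
  cat(sprintf("  timeline: apnea [%g, %g) s, baseline [%g, %g) s, injection [%g, %g] s, record to %g s\n",
              tl["apneaStart"], tl["apneaEnd"], tl["baselineStart"],
              tl["injectionStart"], tl["injectionStart"], tl["injectionEnd"],
              tl["recordEnd"]))
  cat("  baseline:", paste(sprintf("%s=%.4g", names(object@baselineFeatures),
                                   object@baselineFeatures), collapse = " "), "\n")
})

setMethod("show", "EITSequence", function(object) {
  d <- dim(object@frames)
  cat("EITSequence:", d[1], "frames of", d[2], "x", d[3], "pixels at",
      object@frameRate, "Hz;", sum(object@lungMask), "lung pixels\n")
  cat("  orientation:", object@orientation, "\n")
})

setMethod("show", "AirwaySignals", function(object) {
  cat("AirwaySignals:", length(object@time), "samples at",
      object@sampleRate, "Hz, t in [",
      round(min(object@time), 3), ",", round(max(object@time), 3), "] s\n")
})

setMethod("show", "EventLog", function(object) {
  cat(sprintf("EventLog: apnea [%g, %g] s, injection [%g, %g] s\n",
              object@apneaStart, object@apneaEnd,
              object@injectionStart, object@injectionEnd))
})

setMethod("show", "EdemaState", function(object) {
  cat(sprintf("EdemaState at t = %g s (progress %.3f): eeli x%.3f, tiv x%.3f, ventral loss %.3f, Raw x%.2f, Cdyn x%.2f\n",
              object@t, object@progress, object@eeliScale, object@tivScale,
              object@ventralLoss, object@rawScale, object@cdynScale))
})

setMethod("show", "TidalImage", function(object) {
  cat("TidalImage:", paste(dim(object@dz), collapse = " x "),
      "grid;", sum(object@mask), "lung pixels; extent rows",
      object@ventralEdge, "-", object@dorsalEdge, ", cols",
      object@rightEdge, "-", object@leftEdge, "\n")
})
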