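## Synthetic cohort generator: a full virtual edema experiment (EIT pixel
## frames + airway signals + events) with known per-breath ground truth.

## Normalized logistic progress curve: 0 at t <= 0, -> 1 as t -> Inf.
.logisticG <- function(t, t0, tau) {
  s0 <- plogis(-t0 / tau)
  g <- (plogis((t - t0) / tau) - s0) / (1 - s0)
  ifelse(t <= 0, 0, g)
}

#' Construct an edema state by hand
#'
#' Low-level constructor, mainly for testing single stages; in normal use
#' states come from [edemaTrajectory()].  All arguments default to the
#' baseline (no-edema) state.
#'
#' @param t time in s relative to injection start.
#' @param progress trajectory progress in `[0, 1]`.
#' @param eeliScale,tivScale,cdynScale,etco2Scale multipliers falling
#'   from 1 as edema progresses.
#' @param ventralLoss,cvLoss fractions of ventral / centro-ventral band
#'   ventilation reassigned dorsally.
#' @param dorsalShare fraction of the freed ventilation assigned to the
#'   dorsal band (rest goes centro-dorsal).
#' @param rawScale,siiiScale,vdawScale multipliers rising from 1.
#' @return an [EdemaState].
#' @export
edemaState <- function(t = 0, progress = 0, eeliScale = 1, tivScale = 1,
                       ventralLoss = 0, cvLoss = 0, dorsalShare = 0.5,
                       rawScale = 1, cdynScale = 1, siiiScale = 1,
                       etco2Scale = 1, vdawScale = 1) {
  new("EdemaState", t = t, progress = progress, eeliScale = eeliScale,
      tivScale = tivScale, ventralLoss = ventralLoss, cvLoss = cvLoss,
      dorsalShare = dorsalShare, rawScale = rawScale, cdynScale = cdynScale,
      siiiScale = siiiScale, etco2Scale = etco2Scale, vdawScale = vdawScale)
}

#' Evaluate the edema trajectory at a time point
#'
#' Each affected quantity follows `s(t) = 1 - A * g(t)` (falling) or
#' `1 + A * g(t)` (rising), where `g` is a logistic time course in `t`
#' anchored so that `g(t) = 0` exactly for `t <= 0` and `g -> 1` as
#' `t -> Inf`.  Default amplitudes are derived from the configured
#' baseline and plateau feature values so that the trajectory passes
#' exactly through the plateau values at `plateauTime`.
#'
#' @param t time in s relative to injection start.
#' @param config a [SimConfig].
#' @param amplitudes optional named overrides of the derived amplitudes
#'   (names among `eeli`, `tiv`; amplitude `A` gives limit `1 - A`).
#' @return an [EdemaState].
#' @examples
#' cfg <- simConfig()
#' edemaTrajectory(-10, cfg)  # baseline
#' edemaTrajectory(120, cfg)  # at the configured plateau
#' @export
edemaTrajectory <- function(t, config, amplitudes = numeric()) {
  stopifnot(is(config, "SimConfig"), length(t) == 1)
  g <- .logisticG(t, config@onsetT0, config@onsetTau)
  gP <- .logisticG(config@plateauTime, config@onsetT0, config@onsetTau)
  base <- config@baselineFeatures
  plat <- config@plateauFeatures
  ampFall <- function(nm) {
    if (nm %in% names(amplitudes)) amplitudes[[nm]]
    else (1 - plat[[nm]] / base[[nm]]) / gP
  }
  vlMax <- (1 - plat[["dz_v"]] / base[["dz_v"]]) / gP
  cvMax <- (1 - plat[["dz_cv"]] / base[["dz_cv"]]) / gP
  freedP <- (base[["dz_v"]] - plat[["dz_v"]]) +
            (base[["dz_cv"]] - plat[["dz_cv"]])
  share <- if (freedP > 0) (plat[["dz_d"]] - base[["dz_d"]]) / freedP else 0.5
  gn <- g / gP
  mp <- config@mechPlateau
  cp <- config@capnoPlateau
  edemaState(
    t = t, progress = g,
    eeliScale = 1 - ampFall("eeli") * g,
    tivScale  = 1 - ampFall("tiv") * g,
    ventralLoss = min(vlMax * g, 0.999),
    cvLoss      = min(cvMax * g, 0.999),
    dorsalShare = share,
    rawScale  = 1 + (mp[["rawScale"]] - 1) * gn,
    cdynScale = 1 - (1 - mp[["cdynScale"]]) * gn,
    siiiScale  = 1 + (cp[["siiiScale"]] - 1) * gn,
    etco2Scale = 1 - (1 - cp[["etco2Scale"]]) * gn,
    vdawScale  = 1 + (cp[["vdawScale"]] - 1) * gn)
}

#' Per-breath ground-truth EIT feature targets
#'
#' Maps an [EdemaState] (plus an optional subject-level baseline feature
#' vector) to the feature values one breath of synthetic frames is built
#' to carry.  Band fractions are reduced by `ventralLoss`/`cvLoss`, the
#' freed ventilation is reassigned to the dorsal bands by `dorsalShare`,
#' and the result is renormalized to sum to 100.  Centroid and
#' silent-space targets are interpolated between the configured baseline
#' and plateau values by the trajectory progress.
#'
#' @param config a [SimConfig].
#' @param state an [EdemaState].
#' @param subjectBase named feature vector for this subject (defaults to
#'   the configured population baseline).
#' @return named numeric vector over the EIT feature names.
#' @export
breathTargets <- function(config, state, subjectBase = NULL) {
  base <- config@baselineFeatures
  plat <- config@plateauFeatures
  if (is.null(subjectBase)) subjectBase <- base
  gP <- .logisticG(config@plateauTime, config@onsetT0, config@onsetTau)
  gn <- state@progress / gP
  bands <- subjectBase[.bandNames]
  freed <- bands[["dz_v"]] * state@ventralLoss +
           bands[["dz_cv"]] * state@cvLoss
  bands[["dz_v"]]  <- bands[["dz_v"]] * (1 - state@ventralLoss)
  bands[["dz_cv"]] <- bands[["dz_cv"]] * (1 - state@cvLoss)
  bands[["dz_d"]]  <- bands[["dz_d"]] + state@dorsalShare * freed
  bands[["dz_cd"]] <- bands[["dz_cd"]] + (1 - state@dorsalShare) * freed
  bands <- bands * 100 / sum(bands)
  interp <- function(nm) {
    ratio <- if (base[[nm]] > 0) plat[[nm]] / base[[nm]] - 1 else 0
    subjectBase[[nm]] * (1 + ratio * gn)
  }
  c(cov_vd = interp("cov_vd"), cov_rl = interp("cov_rl"),
    tiv = subjectBase[["tiv"]] * state@tivScale,
    eeli = subjectBase[["eeli"]] * state@eeliScale,
    nss = interp("nss"), dss = interp("dss"), bands)
}

#' Build a two-lobe lung mask
#'
#' Deterministic, left-right symmetric mask of two elliptical lobes
#' joined by a thin central bridge (so the lung region is connected), on
#' an EIT grid with row 1 most ventral.
#'
#' @param height,width grid size in pixels (each >= 8).
#' @param geometry named list: `rowCenter` (fraction of height),
#'   `rowRadius`, `colRadius` (ellipse semi-axes as fractions),
#'   `lobeOffset` (lobe center offset from midline as fraction of width)
#'   and `bridgeHalfWidth` (half-height of the connecting bridge in
#'   pixels).
#' @return logical matrix height x width.
#' @examples
#' m <- makeLungMask(32, 32)
#' mean(m)  # fraction of grid covered
#' @export
makeLungMask <- function(height, width,
                         geometry = list(rowCenter = 0.5, rowRadius = 0.34,
                                         colRadius = 0.18, lobeOffset = 0.22,
                                         bridgeHalfWidth = 1)) {
  if (height < 8 || width < 8)
    stop("grid must be at least 8 x 8 pixels")
  g <- list(rowCenter = 0.5, rowRadius = 0.34, colRadius = 0.18,
            lobeOffset = 0.22, bridgeHalfWidth = 1)
  g[names(geometry)] <- geometry
  fr <- (seq_len(height) - 0.5) / height
  fc <- (seq_len(width) - 0.5) / width
  inEllipse <- function(cc) {
    outer(((fr - g$rowCenter) / g$rowRadius)^2,
          ((fc - cc) / g$colRadius)^2, "+") <= 1
  }
  mask <- inEllipse(0.5 - g$lobeOffset) | inEllipse(0.5 + g$lobeOffset)
  bridgeRows <- abs(seq_len(height) - g$rowCenter * height) <=
    g$bridgeHalfWidth
  bridgeCols <- fc >= 0.5 - g$lobeOffset & fc <= 0.5 + g$lobeOffset
  mask[bridgeRows, bridgeCols] <- TRUE
  if (!any(mask))
    stop("degenerate lung-mask geometry: empty mask")
  if (!.isConnected(mask))
    stop("degenerate lung-mask geometry: mask is not connected")
  mask
}

## 4-neighbour connectivity by flood fill (validity check only).
.isConnected <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  lab <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- idx[1, , drop = FALSE]
  lab[queue] <- TRUE
  while (nrow(queue) > 0) {
    p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
          mask[q[1], q[2]] && !lab[q[1], q[2]]) {
        lab[q[1], q[2]] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  all(lab[mask])
}

## Construct the per-pixel tidal impedance-change field carrying the
## requested feature targets exactly (noise-free):
##   - band sums match `bands` (% of total, sum 100)
##   - dz-weighted centroid sits at (cov_vd, cov_rl) on the mask extent
##   - round(nss% / dss% of mask pixels) dorsal/ventral of the CoV plane
##     get dz = 0 (silent-space ground truth)
##   - total dz sums to `tiv`
## The centroid is met by an exponential ventro-dorsal tilt of within-band
## pixel weights (band sums renormalized, so they stay exact), and the
## right-left centroid by a per-row column tilt (row sums preserved).
.buildTidalField <- function(mask, tiv, cov_vd, cov_rl, nss, dss, bands) {
  stopifnot(abs(sum(bands) - 100) < 0.02)
  nMask <- sum(mask)
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  nR <- r1 - r0 + 1; nC <- c1 - c0 + 1
  idx <- which(mask, arr.ind = TRUE)
  posVD <- if (nR == 1) rep(50, nrow(idx)) else
    (idx[, 1] - r0 + 0.5) / nR * 100
  posRL <- if (nC == 1) rep(50, nrow(idx)) else
    (idx[, 2] - c0 + 0.5) / nC * 100
  band <- pmin(floor((idx[, 1] - r0 + 0.5) / nR * 4) + 1, 4)

  ## silent-space ground truth: zero-dz pixels farthest from the CoV plane
  nN <- round(nss / 100 * nMask); nD <- round(dss / 100 * nMask)
  dorsal <- which(posVD > cov_vd); ventral <- which(posVD <= cov_vd)
  if (length(dorsal) < nN || length(ventral) < nD)
    stop("infeasible feature combination: requested silent-space fractions",
         " exceed the pixels available on one side of the CoV plane")
  spread <- function(cand, k) {  # evenly spaced picks, extremes first
    if (k == 0) return(integer())
    cand[unique(round(seq(1, length(cand), length.out = k)))]
  }
  silent <- c(spread(dorsal[order(-posVD[dorsal], posRL[dorsal])], nN),
              spread(ventral[order(posVD[ventral], posRL[ventral])], nD))
  act <- setdiff(seq_len(nrow(idx)), silent)
  if (any(tabulate(band[act], 4) == 0 & bands > 0))
    stop("infeasible feature combination: a band with nonzero ventilation",
         " share contains no non-silent lung pixels")

  bandWeights <- function(tilt) {
    w <- exp(tilt * (posVD[act] - 50) / 50)
    for (b in 1:4) {
      inb <- band[act] == b
      if (any(inb)) w[inb] <- w[inb] * bands[b] / sum(w[inb])
    }
    w
  }
  covOf <- function(w, pos) sum(w * pos) / sum(w)
  fvd <- function(tilt) covOf(bandWeights(tilt), posVD[act]) - cov_vd
  tilt <- .solveTilt(fvd, lo = -40, hi = 40)
  w <- bandWeights(tilt)

  ## per-row column tilt toward the requested right-left centroid
  colTilt <- function(u) {
    wc <- w * exp(u * (posRL[act] - 50) / 50)
    for (r in unique(idx[act, 1])) {
      inr <- idx[act, 1] == r
      sw <- sum(w[inr])
      wc[inr] <- if (sw > 0) wc[inr] * sw / sum(wc[inr]) else 0
    }
    wc
  }
  frl <- function(u) covOf(colTilt(u), posRL[act]) - cov_rl
  u <- .solveTilt(frl, lo = -40, hi = 40)
  wc <- colTilt(u)

  dz <- matrix(0, nrow(mask), ncol(mask))
  dz[idx[act, , drop = FALSE]] <- wc * tiv / sum(wc)

  ## realized feature values of the built field, by direct counting /
  ## summing (independent of the feature-extraction code paths): under
  ## extreme band draws the tilt can push further pixels below the 10%
  ## silent threshold, and a clamped tilt leaves the centroid at the
  ## attainable extreme -- the truth tables carry what the field does.
  v <- dz[idx]
  covVD <- sum(v * posVD) / sum(v)
  covRL <- sum(v * posRL) / sum(v)
  sil <- v < 0.1 * max(v)
  bandSums <- vapply(1:4, function(b) sum(v[band == b]), numeric(1))
  realized <- c(cov_vd = covVD, cov_rl = covRL,
                tiv = sum(v), eeli = NA_real_,
                nss = 100 * sum(sil & posVD > covVD) / nMask,
                dss = 100 * sum(sil & posVD <= covVD) / nMask,
                setNames(100 * bandSums / sum(v), .bandNames))
  list(dz = dz, realized = realized)
}

## Monotone root with clamping at the bounds: targets beyond the
## attainable centroid range concentrate mass at the matching extreme.
.solveTilt <- function(f, lo, hi) {
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi)) stop("degenerate ventilation field")
  if (flo > 0 && fhi > 0) return(lo)
  if (flo < 0 && fhi < 0) return(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate EIT frames for one breath
#'
#' Per-pixel impedance is an end-expiratory baseline field (the EELI
#' target spread uniformly over the lung mask) plus a tidal
#' impedance-change field modulated by the intrapulmonary volume
#' waveform of the volume-controlled breath (linear rise over the
#' constant-flow phase, hold over the end-inspiratory pause, exponential
#' passive decay in expiration).  The tidal field is constructed so the
#' feature-extraction pipeline recovers the configured TIV, EELI,
#' centroid, band-fraction and silent-space values exactly on noise-free
#' runs.
#'
#' @param config a [SimConfig].
#' @param state an [EdemaState].
#' @param phase time grid for the breath in s from inspiration onset
#'   (default: one full cycle at the EIT frame rate).
#' @param mask lung mask (default built from `config`).
#' @param targets feature targets (default [breathTargets()] of `state`).
#' @return an [EITSequence] covering the breath.
#' @examples
#' cfg <- simConfig(noiseSd = 0)
#' br <- simulateBreathFrames(cfg, edemaTrajectory(-10, cfg))
#' range(globalSignal(br))
#' @export
simulateBreathFrames <- function(config, state, phase = NULL, mask = NULL,
                                 targets = NULL) {
  if (is.null(mask))
    mask <- makeLungMask(config@gridHeight, config@gridWidth,
                         config@maskGeometry)
  if (is.null(targets)) targets <- breathTargets(config, state)
  period <- 60 / config@respRate
  if (is.null(phase))
    phase <- seq(0, period - 1 / config@eitFrameRate,
                 by = 1 / config@eitFrameRate)
  fld <- .buildTidalField(mask, tiv = targets[["tiv"]],
                          cov_vd = targets[["cov_vd"]],
                          cov_rl = targets[["cov_rl"]],
                          nss = targets[["nss"]], dss = targets[["dss"]],
                          bands = targets[.bandNames])
  dz <- fld$dz
  w <- .volumeFraction(phase, config, state)
  base <- matrix(0, nrow(mask), ncol(mask))
  base[mask] <- targets[["eeli"]] / sum(mask)
  fr <- array(0, dim = c(length(phase), nrow(mask), ncol(mask)))
  for (k in seq_along(phase)) fr[k, , ] <- base + dz * w[k]
  eitSequence(fr, config@eitFrameRate, mask)
}

## Breath timing (s): constant-flow time, pause time, inspiratory time.
.breathTiming <- function(config) {
  period <- 60 / config@respRate
  ti <- config@inspFraction * period
  tp <- config@pauseFraction * period
  list(period = period, tFlow = ti - tp, tPause = tp, tInsp = ti)
}

## Intrapulmonary volume as a fraction of VT at times `tt` (s from
## inspiration onset), shared by the EIT and airway generators.
.volumeFraction <- function(tt, config, state) {
  tm <- .breathTiming(config)
  mech <- config@mechBaseline
  tau <- mech[["raw"]] * state@rawScale *
    mech[["crs"]] * state@cdynScale / 1000
  ifelse(tt < tm$tFlow, tt / tm$tFlow,
         ifelse(tt < tm$tInsp, 1, exp(-(tt - tm$tInsp) / tau)))
}

#' Simulate airway signals for one breath
#'
#' Volume-controlled breath from a single-compartment lung: constant
#' inspiratory flow delivering the set tidal volume, an end-inspiratory
#' pause, and passive exponential expiration with time constant
#' `Raw * Crs`.  Airway pressure follows the equation of motion
#' `Paw = Raw * flow + V / Crs + PEEP`.  Expired CO2 follows a
#' three-phase expirogram against expired volume: zero over the airway
#' dead space, a sigmoidal transition centered on it, and a linear
#' alveolar phase III.
#'
#' @param config a [SimConfig].
#' @param state an [EdemaState].
#' @param tStart breath start time in s (defines the output time grid).
#' @param mech optional named overrides `raw`, `crs` (subject level).
#' @param capno optional named overrides `etco2`, `vdawFrac`, `siii`.
#' @param spontEffort if `TRUE`, a negative airway-pressure deflection is
#'   added during early expiration (simulated spontaneous effort).
#' @return a data.frame with `time_s`, `flow_lps`, `paw_cmh2o`,
#'   `pco2_mmhg` covering one breath cycle.
#' @examples
#' cfg <- simConfig(noiseSd = 0)
#' b <- simulateAirwaySignals(cfg, edemaTrajectory(-10, cfg))
#' max(b$flow_lps)
#' @export
simulateAirwaySignals <- function(config, state, tStart = 0,
                                  mech = numeric(), capno = numeric(),
                                  spontEffort = FALSE) {
  m <- config@mechBaseline; m[names(mech)] <- mech
  cp <- config@capnoBaseline; cp[names(capno)] <- capno
  if (any(c(m, cp[["etco2"]]) <= 0))
    stop("mechanical and capnographic parameters must be positive")
  tm <- .breathTiming(config)
  vt <- config@tidalVolumePerKg * config@bodyMass / 1000  # L
  raw <- m[["raw"]] * state@rawScale
  crs <- m[["crs"]] * state@cdynScale / 1000              # L/cmH2O
  tau <- raw * crs
  dt <- 1 / config@airwaySampleRate
  tt <- seq(0, tm$period - dt, by = dt)
  fi <- vt / tm$tFlow
  ## the delivery phase is closed at tFlow so a grid-aligned sample sees
  ## the true end-inspiratory peak (flow fi with the full VT delivered)
  flow <- ifelse(tt <= tm$tFlow + 1e-9, fi,
                 ifelse(tt < tm$tInsp, 0,
                        -vt / tau * exp(-(tt - tm$tInsp) / tau)))
  vol <- vt * .volumeFraction(tt, config, state)
  paw <- raw * flow + vol / crs + config@peep
  if (spontEffort) {
    dip <- config@spontEffortDepth + 1
    paw <- paw - dip * exp(-((tt - (tm$tInsp + 0.5)) / 0.2)^2)
  }
  ve <- pmax(0, vt - vol)  # expired volume so far, L
  vdaw <- cp[["vdawFrac"]] * vt * state@vdawScale             # L
  etco2 <- cp[["etco2"]] * state@etco2Scale
  s3 <- cp[["siii"]] * state@siiiScale                        # mmHg/L
  pco2 <- ifelse(tt < tm$tInsp, 0,
                 pmax(0, (etco2 + s3 * (ve - vt)) *
                        plogis((ve - vdaw) / (cp[["phase2Width"]] / 1000))))
  data.frame(time_s = tStart + tt, flow_lps = flow, paw_cmh2o = paw,
             pco2_mmhg = pco2)
}

## Subject-level parameter draws around the configured means.
.drawSubject <- function(config) {
  isd <- config@interSubjectSd
  base <- config@baselineFeatures
  jit <- function(mu, s) {
    v <- mu * (1 + rnorm(1) * s)
    max(v, 0.05 * mu)
  }
  feat <- base
  for (nm in names(feat)) feat[nm] <- jit(base[nm], isd[[nm]])
  feat["cov_vd"] <- min(max(feat["cov_vd"], 10), 90)
  feat["cov_rl"] <- min(max(feat["cov_rl"], 10), 90)
  feat[.bandNames] <- feat[.bandNames] * 100 / sum(feat[.bandNames])
  mech <- c(raw = jit(config@mechBaseline[["raw"]], isd[["raw"]]),
            crs = jit(config@mechBaseline[["crs"]], isd[["cdyn"]]))
  capno <- c(etco2 = jit(config@capnoBaseline[["etco2"]], isd[["etco2"]]),
             vdawFrac = jit(config@capnoBaseline[["vdawFrac"]],
                            isd[["vdaw"]]),
             siii = jit(config@capnoBaseline[["siii"]], isd[["siii"]]))
  list(features = feat, mech = mech, capno = capno)
}

## Per-breath multiplicative jitter of the EIT feature targets.
.jitterTargets <- function(targets, noise) {
  for (nm in names(targets))
    targets[nm] <- targets[nm] * (1 + rnorm(1) * noise[[nm]])
  targets["cov_vd"] <- min(max(targets["cov_vd"], 1), 99)
  targets["cov_rl"] <- min(max(targets["cov_rl"], 1), 99)
  targets["nss"] <- max(targets["nss"], 0)
  targets["dss"] <- max(targets["dss"], 0)
  targets[.bandNames] <- abs(targets[.bandNames]) * 100 /
    sum(abs(targets[.bandNames]))
  targets
}

.subjectSeed <- function(config, subjectIndex) {
  (config@seed + 7919L * as.integer(subjectIndex)) %% 2147483647L
}

#' Simulate one subject of the virtual experiment
#'
#' Generates the full synchronized recording for one subject: EIT frames
#' from the 10-s apnea through the baseline, injection and post-injection
#' periods, airway signals on the same clock, the event log, and a
#' ground-truth table with the feature targets of every breath.
#' Subject-level baselines are drawn around the configured means with the
#' configured between-subject spread; per-breath targets are jittered
#' with the configured noise.  The random stream is derived from the root
#' seed by a fixed per-subject offset, so cohort-size changes do not
#' reshuffle earlier subjects.
#'
#' @param config a [SimConfig].
#' @param subjectIndex 1-based subject number.
#' @return a list with elements `eit` ([EITSequence]), `airway`
#'   ([AirwaySignals]), `events` ([EventLog]), `truth` (data.frame of
#'   per-breath ground truth) and `baselines` (subject-level parameters).
#' @export
simulateSubject <- function(config, subjectIndex = 1) {
  set.seed(.subjectSeed(config, subjectIndex))
  subj <- .drawSubject(config)
  tl <- config@timeline
  tm <- .breathTiming(config)
  fs <- config@airwaySampleRate
  fr <- config@eitFrameRate
  t0 <- tl[["apneaStart"]]
  tEnd <- tl[["recordEnd"]]
  nS <- round((tEnd - t0) * fs)
  nF <- round((tEnd - t0) * fr)
  timeA <- t0 + (seq_len(nS) - 1) / fs
  timeF <- t0 + (seq_len(nF) - 1) / fr

  mask <- makeLungMask(config@gridHeight, config@gridWidth,
                       config@maskGeometry)
  flow <- numeric(nS); paw <- rep(config@peep, nS); pco2 <- numeric(nS)

  starts <- seq(tl[["baselineStart"]], tEnd - 1e-9, by = tm$period)
  starts <- starts[starts < tEnd]
  vtml <- config@tidalVolumePerKg * config@bodyMass
  truth <- vector("list", length(starts))
  dzFields <- vector("list", length(starts))
  states <- vector("list", length(starts))
  eelis <- numeric(length(starts))
  for (b in seq_along(starts)) {
    ts <- starts[b]
    state <- edemaTrajectory(ts, config)
    targets <- .jitterTargets(breathTargets(config, state, subj$features),
                              config@noiseSd)
    mJit <- c(raw = subj$mech[["raw"]] *
                (1 + rnorm(1) * config@noiseSd[["raw"]]),
              crs = subj$mech[["crs"]] *
                (1 + rnorm(1) * config@noiseSd[["cdyn"]]))
    cJit <- subj$capno[c("etco2", "vdawFrac", "siii")] *
      (1 + rnorm(3) * config@noiseSd[c("etco2", "vdaw", "siii")])
    cJit["phase2Width"] <- config@capnoBaseline[["phase2Width"]]
    spont <- runif(1) < config@spontEffortProb
    seg <- simulateAirwaySignals(config, state, tStart = ts, mech = mJit,
                                 capno = cJit, spontEffort = spont)
    i0 <- round((ts - t0) * fs) + 1
    ii <- i0:min(i0 + nrow(seg) - 1, nS)
    flow[ii] <- seg$flow_lps[seq_along(ii)]
    paw[ii] <- seg$paw_cmh2o[seq_along(ii)]
    pco2[ii] <- seg$pco2_mmhg[seq_along(ii)]

    fld <- .buildTidalField(mask, tiv = targets[["tiv"]],
                            cov_vd = targets[["cov_vd"]],
                            cov_rl = targets[["cov_rl"]],
                            nss = targets[["nss"]], dss = targets[["dss"]],
                            bands = targets[.bandNames])
    targets[names(fld$realized)[!is.na(fld$realized)]] <-
      fld$realized[!is.na(fld$realized)]
    dzFields[[b]] <- fld$dz
    states[[b]] <- state
    eelis[b] <- targets[["eeli"]]

    raw2 <- mJit[["raw"]] * state@rawScale
    crs2 <- mJit[["crs"]] * state@cdynScale / 1000
    fi <- vtml / 1000 / tm$tFlow
    pip <- raw2 * fi + vtml / 1000 / crs2 + config@peep
    truth[[b]] <- data.frame(
      subject = subjectIndex, breath = b, t_start_s = ts,
      as.list(targets),
      vt_ml = vtml, pip_cmh2o = pip,
      p_plat_cmh2o = vtml / 1000 / crs2 + config@peep,
      pef_lps = vtml / 1000 / (raw2 * crs2),
      raw_cmh2o_per_lps = raw2,
      cdyn_ml_per_cmh2o = vtml / (pip - config@peep),
      vdaw_ml = cJit[["vdawFrac"]] * vtml * state@vdawScale,
      siii_mmhg_per_l = cJit[["siii"]] * state@siiiScale,
      etco2_mmhg = cJit[["etco2"]] * state@etco2Scale,
      spont_effort = spont)
  }

  ## frame rendering: the end-expiratory baseline field is held constant
  ## through each breath's landmark neighborhood and stepped to the next
  ## breath's level mid-expiration, where the tidal component has decayed
  ## -- EELI steps between breaths never fall inside a landmark window
  framesArr <- array(0, dim = c(nF, nrow(mask), ncol(mask)))
  nPix <- sum(mask)
  bFieldOf <- function(eeli) {
    f <- matrix(0, nrow(mask), ncol(mask)); f[mask] <- eeli / nPix; f
  }
  if (length(starts)) {
    apneaField <- bFieldOf(eelis[1])
    for (k in seq_len(max(0, round((starts[1] - t0) * fr))))
      framesArr[k, , ] <- apneaField
    switchT <- tm$tInsp + (tm$period - tm$tInsp) / 2
    for (b in seq_along(starts)) {
      ts <- starts[b]
      k0 <- round((ts - t0) * fr) + 1
      kk <- k0:min(k0 + round(tm$period * fr) - 1, nF)
      tt <- timeF[kk] - ts
      wv <- .volumeFraction(tt, config, states[[b]])
      bNow <- bFieldOf(eelis[b])
      bNext <- bFieldOf(eelis[min(b + 1, length(starts))])
      for (j in seq_along(kk))
        framesArr[kk[j], , ] <- (if (tt[j] < switchT) bNow else bNext) +
          dzFields[[b]] * wv[j]
    }
  } else {
    apneaField <- bFieldOf(subj$features[["eeli"]])
    for (k in seq_len(nF)) framesArr[k, , ] <- apneaField
  }
  list(eit = eitSequence(framesArr, fr, mask),
       airway = airwaySignals(timeA, flow, paw, pco2, fs),
       events = eventLog(tl[["apneaStart"]], tl[["apneaEnd"]],
                         tl[["injectionStart"]], tl[["injectionEnd"]]),
       truth = do.call(rbind, truth),
       baselines = subj)
}

#' Simulate and write a full virtual cohort
#'
#' Runs [simulateSubject()] for each subject and writes the on-disk
#' dataset layout (see [writeSubject()]) under `dir/subject_XX/`.
#' Fully reproducible from the configured seed.
#'
#' @param config a [SimConfig].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of subject directories.
#' @export
simulateCohort <- function(config, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- character(config@nSubjects)
  for (s in seq_len(config@nSubjects)) {
    sub <- simulateSubject(config, s)
    paths[s] <- file.path(dir, sprintf("subject_%02d", s))
    writeSubject(sub, paths[s])
  }
  invisible(paths)
}

#' Simulate a per-breath feature table directly
#'
#' Generates the long-format breath table (subject x variable x breath)
#' from the same subject-level draws, edema trajectory and per-breath
#' noise model as the frame-level simulator, without synthesizing pixel
#' frames or waveforms.  This is the generator entry point for
#' statistical studies (power, family-wise error) where thousands of
#' cohort realizations are needed.
#'
#' @param config a [SimConfig].
#' @param variables which feature variables to emit (default: all EIT
#'   features).
#' @param nullEffect if `TRUE`, the edema effect is switched off and all
#'   breaths are drawn from the subject baseline (pure noise) -- the null
#'   cohorts used to check type-I error control.
#' @return data.frame `subject`, `variable`, `breath_ordinal`, `t_s`,
#'   `value`.
#' @examples
#' tab <- simulateFeatureTable(simConfig(nSubjects = 2), variables = "eeli")
#' head(tab)
#' @export
simulateFeatureTable <- function(config, variables = .eitFeatureNames,
                                 nullEffect = FALSE) {
  tl <- config@timeline
  tm <- .breathTiming(config)
  starts <- seq(tl[["baselineStart"]], tl[["recordEnd"]] - 1e-9,
                by = tm$period)
  out <- vector("list", config@nSubjects)
  baselineState <- edemaState()
  for (s in seq_len(config@nSubjects)) {
    set.seed(.subjectSeed(config, s))
    subj <- .drawSubject(config)
    rows <- vector("list", length(starts))
    for (b in seq_along(starts)) {
      state <- if (nullEffect) baselineState
               else edemaTrajectory(starts[b], config)
      targets <- .jitterTargets(breathTargets(config, state, subj$features),
                                config@noiseSd)
      rows[[b]] <- data.frame(subject = s, variable = variables,
                              breath_ordinal = b, t_s = starts[b],
                              value = unname(targets[variables]))
    }
    out[[s]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}
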