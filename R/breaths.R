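## Breath segmentation from airway flow, apnea-based synchronization of
## the EIT and airway timebases, and per-breath quality control.

#' Detect mechanical breaths from the flow signal
#'
#' Inspiration starts at a positive flow-threshold crossing sustained for
#' the hysteresis time; inspiration ends at the last positive-flow sample
#' before sustained non-positive flow (so the end-inspiratory pause and
#' expiration together form the remainder of the breath); expiration ends
#' at the next inspiration start (or the record end).  Breaths whose
#' inspiratory flow phase is shorter than `minInspS` are discarded.
#' Ordinals are assigned in time order.
#'
#' @param signals an [AirwaySignals].
#' @param minInspS minimum inspiratory (flow) duration in s.
#' @param flowThreshold inspiration threshold in L/s.
#' @param hysteresisS time the threshold must be held, in s.
#' @return data.frame with one row per breath: `ordinal`, sample indices
#'   `insp_start`, `insp_end`, `exp_end`, and times `t_start_s`,
#'   `t_mid_insp_s`, `t_mid_exp_s`.  Zero rows if no breaths are found.
#' @examples
#' cfg <- simConfig(noiseSd = 0)
#' b <- simulateAirwaySignals(cfg, edemaTrajectory(-10, cfg))
#' sig <- airwaySignals(b$time_s, b$flow_lps, b$paw_cmh2o, b$pco2_mmhg)
#' detectBreaths(sig)
#' @export
detectBreaths <- function(signals, minInspS = 0.3, flowThreshold = 0.02,
                          hysteresisS = 0.05) {
  flow <- signals@flow
  n <- length(flow)
  nh <- max(1L, round(hysteresisS * signals@sampleRate))
  above <- flow > flowThreshold
  ## sustained run-length of `above` starting at each sample
  runLen <- integer(n)
  r <- 0L
  for (i in n:1) {
    r <- if (above[i]) r + 1L else 0L
    runLen[i] <- r
  }
  starts <- which(above & !c(FALSE, above[-n]) & runLen >= nh)
  if (length(starts) == 0) return(.emptyBreaths())
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    iEnd <- if (k < length(starts)) starts[k + 1] - 1L else n
    seg <- i0:iEnd
    nonpos <- flow[seg] <= 0
    rl <- integer(length(seg)); r <- 0L
    for (i in length(seg):1) {
      r <- if (nonpos[i]) r + 1L else 0L
      rl[i] <- r
    }
    j <- which(nonpos & rl >= nh)
    j <- j[j > 1]
    inspEnd <- if (length(j)) {
      pos <- which(flow[seg[1:(j[1] - 1)]] > 0)
      if (length(pos)) seg[max(pos)] else i0
    } else iEnd
    out[[k]] <- data.frame(insp_start = i0, insp_end = inspEnd,
                           exp_end = iEnd)
  }
  br <- do.call(rbind, out)
  keep <- (br$insp_end - br$insp_start + 1) / signals@sampleRate >= minInspS &
    br$insp_end < br$exp_end
  br <- br[keep, , drop = FALSE]
  if (nrow(br) == 0) return(.emptyBreaths())
  br$ordinal <- seq_len(nrow(br))
  tm <- signals@time
  br$t_start_s <- tm[br$insp_start]
  br$t_end_s <- tm[br$exp_end]
  br$t_mid_insp_s <- (tm[br$insp_start] + tm[br$insp_end]) / 2
  br$t_mid_exp_s <- (tm[br$insp_end] + tm[br$exp_end]) / 2
  rownames(br) <- NULL
  br[, c("ordinal", "insp_start", "insp_end", "exp_end", "t_start_s",
         "t_end_s", "t_mid_insp_s", "t_mid_exp_s")]
}

.emptyBreaths <- function() {
  data.frame(ordinal = integer(), insp_start = integer(),
             insp_end = integer(), exp_end = integer(),
             t_start_s = numeric(), t_end_s = numeric(),
             t_mid_insp_s = numeric(), t_mid_exp_s = numeric())
}

#' Synchronize the EIT and airway timebases via the apnea
#'
#' Finds the longest quiescent window in each modality (airway: |flow|
#' below threshold; EIT: frame-to-frame change of the global lung signal
#' below a small fraction of its overall range) and returns the end of
#' each window.  Downstream, airway time `t` maps to frame index
#' `frameSync + round((t - tSyncAirway) * frameRate)`.
#'
#' @param signals an [AirwaySignals].
#' @param eit an [EITSequence].
#' @param minApneaS minimum apnea duration in s; shorter quiescent
#'   windows raise an error.
#' @param flowThreshold airway quiescence threshold in L/s.
#' @param flatFraction EIT flatness threshold as a fraction of the
#'   global-signal range.
#' @return list with `tSyncAirway` (s), `frameSync` (frame index) and
#'   `frameRate` (Hz).
#' @export
detectApneaSync <- function(signals, eit, minApneaS = 5,
                            flowThreshold = 0.02, flatFraction = 1e-3) {
  quiet <- abs(signals@flow) < flowThreshold
  ra <- rle(quiet)
  ends <- cumsum(ra$lengths)
  ok <- ra$values & ra$lengths >= minApneaS * signals@sampleRate
  if (!any(ok))
    stop("no apnea found in the airway signal (no |flow| < ",
         flowThreshold, " L/s window of at least ", minApneaS,
         " s); align the timebases manually")
  iA <- which(ok)[which.max(ra$lengths[ok])]
  tSync <- signals@time[ends[iA]]

  g <- globalSignal(eit)
  tol <- flatFraction * diff(range(g))
  flat <- c(abs(diff(g)) <= tol, FALSE)
  rf <- rle(flat)
  endsF <- cumsum(rf$lengths)
  okF <- rf$values & rf$lengths >= minApneaS * frameRate(eit)
  if (!any(okF))
    stop("no apnea found in the EIT global signal (no flat window of at",
         " least ", minApneaS, " s); align the timebases manually")
  iF <- which(okF)[which.max(rf$lengths[okF])]
  list(tSyncAirway = tSync, frameSync = endsF[iF], frameRate = frameRate(eit))
}

#' Map airway time to EIT frame index
#'
#' @param t time in s on the airway clock.
#' @param sync result of [detectApneaSync()].
#' @return frame index (integer, clamped at 1).
#' @export
frameIndexAt <- function(t, sync) {
  pmax(1L, sync$frameSync +
         as.integer(round((t - sync$tSyncAirway) * sync$frameRate)))
}

#' Flag breaths failing quality control
#'
#' Applies the leak rule (inspired/expired tidal volume difference above
#' a fraction of the first breath's expired volume) and the
#' spontaneous-effort rule (airway pressure dropping below PEEP by more
#' than a threshold anywhere in the breath).  Flagged breaths are meant
#' to be excluded from statistics.
#'
#' @param breaths data.frame from [detectBreaths()].
#' @param signals the matching [AirwaySignals].
#' @param vtInsp,vtExp per-breath inspired and expired volumes in mL
#'   (from [mechVolumes()]).
#' @param vtExpFirst reference expired volume in mL (default: first
#'   breath).
#' @param peep set PEEP in cmH2O.
#' @param leakFraction leak tolerance as a fraction of `vtExpFirst`.
#' @param spontThreshold cmH2O below PEEP that flags an effort.
#' @return `breaths` with logical columns `flag_leak`,
#'   `flag_spontaneous_effort` and `flag_incomplete` added (the latter
#'   initialized to `FALSE`; feature extractors may set it).
#' @export
qcBreaths <- function(breaths, signals, vtInsp, vtExp,
                      vtExpFirst = vtExp[1], peep = 0,
                      leakFraction = 0.10, spontThreshold = 2) {
  stopifnot(nrow(breaths) == length(vtInsp), length(vtInsp) == length(vtExp))
  breaths$flag_leak <- abs(vtInsp - vtExp) > leakFraction * vtExpFirst
  minPaw <- vapply(seq_len(nrow(breaths)), function(i) {
    min(signals@paw[breaths$insp_start[i]:breaths$exp_end[i]])
  }, numeric(1))
  breaths$flag_spontaneous_effort <- minPaw < peep - spontThreshold
  if (is.null(breaths$flag_incomplete))
    breaths$flag_incomplete <- rep(FALSE, nrow(breaths))
  breaths
}
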