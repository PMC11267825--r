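## Spirometry / respiratory-mechanics variables per breath from flow and
## airway pressure.

#' Inspired and expired tidal volumes
#'
#' Trapezoidal time integrals of flow over the inspiration and of
#' negated flow over the expiration, in mL.
#'
#' @param signals an [AirwaySignals].
#' @param breath one row of the [detectBreaths()] table.
#' @return list with `vt_insp` and `vt_exp` in mL.
#' @export
mechVolumes <- function(signals, breath) {
  tt <- signals@time
  n <- length(tt)
  ## pad the inspiration by one sample on each side so the trapezoid
  ## closes the threshold crossings of a (near-)rectangular flow wave
  insp <- max(1, breath$insp_start - 1):min(n, breath$insp_end + 1)
  rest <- breath$insp_end:breath$exp_end
  negs <- rest[signals@flow[rest] < 0]
  vtExp <- if (length(negs) < 2) 0 else
    1000 * pracma::trapz(tt[negs[1]:breath$exp_end],
                         pmax(-signals@flow[negs[1]:breath$exp_end], 0))
  list(vt_insp = 1000 * pracma::trapz(tt[insp],
                                      pmax(signals@flow[insp], 0)),
       vt_exp = vtExp)
}

#' Breath pressures and peak expiratory flow
#'
#' PIP is the maximum airway pressure up to the start of expiratory
#' flow; plateau pressure is the mean over the zero-flow
#' end-inspiratory pause (missing when no pause exists); PEEP is the
#' mean pressure over the final 10% of the expiration; PEF is the
#' maximum expiratory flow.
#'
#' @param signals an [AirwaySignals].
#' @param breath one row of the [detectBreaths()] table.
#' @param flowThreshold |flow| below this counts as zero flow (L/s).
#' @return list with `pip`, `p_plat`, `peep` (cmH2O) and `pef` (L/s);
#'   `p_plat` is `NA` when no pause is present.
#' @export
mechPressures <- function(signals, breath, flowThreshold = 0.02) {
  seg <- breath$insp_start:breath$exp_end
  flow <- signals@flow[seg]
  paw <- signals@paw[seg]
  negs <- which(flow < -flowThreshold)
  expStart <- if (length(negs)) negs[1] else length(seg)
  pip <- max(paw[1:max(1, expStart - 1)])
  iInspEnd <- breath$insp_end - breath$insp_start + 1
  pause <- seq_len(length(seg)) > iInspEnd &
    seq_len(length(seg)) < expStart & abs(flow) < flowThreshold
  pPlat <- if (any(pause)) mean(paw[pause]) else NA_real_
  expIdx <- expStart:length(seg)
  tail10 <- expIdx[expIdx >= expStart + 0.9 * (length(seg) - expStart)]
  list(pip = pip, p_plat = pPlat, peep = mean(paw[tail10]),
       pef = max(-flow[expIdx]))
}

#' Airway resistance and dynamic compliance
#'
#' Resistance is the resistive pressure drop over the mean inspiratory
#' flow, `(PIP - Pplat) / flow` -- the only dimensionally consistent
#' reading of the classic bedside formula (some texts print the inverted
#' quotient; `literal = TRUE` reproduces that wording for comparison).
#' Dynamic compliance is `VT / (PIP - PEEP)`, reading the "peak
#' expiratory pressure" of the bedside formula as the measured
#' end-expiratory pressure -- the only reading that makes the quotient a
#' compliance.
#'
#' @param pip,pPlat,peep pressures in cmH2O.
#' @param vtExp expired tidal volume in mL.
#' @param meanInspFlow mean inspiratory flow in L/s.
#' @param literal reproduce the literal (dimensionally inverted)
#'   resistance wording.
#' @return list with `raw` (cmH2O/(L/s)) and `cdyn` (mL/cmH2O); `NA`
#'   where undefined.
#' @export
resistanceCompliance <- function(pip, pPlat, peep, vtExp, meanInspFlow,
                                 literal = FALSE) {
  raw <- if (is.na(pPlat) || meanInspFlow <= 0) NA_real_
         else if (literal) meanInspFlow / (pip - pPlat)
         else (pip - pPlat) / meanInspFlow
  cdyn <- if (pip > peep) vtExp / (pip - peep) else NA_real_
  list(raw = raw, cdyn = cdyn)
}

## Mean flow over the central 5-95% of the constant-flow segment.
.meanInspFlow <- function(signals, breath, flowThreshold = 0.02) {
  insp <- breath$insp_start:breath$insp_end
  flowing <- insp[signals@flow[insp] > flowThreshold]
  if (length(flowing) < 3) return(NA_real_)
  lo <- quantile(seq_along(flowing), 0.05, type = 1)
  hi <- quantile(seq_along(flowing), 0.95, type = 1)
  mean(signals@flow[flowing[lo:hi]])
}

#' Per-breath respiratory-mechanics feature table
#'
#' @param signals an [AirwaySignals].
#' @param breaths data.frame from [detectBreaths()].
#' @param subject subject identifier for the output table.
#' @param tRef time subtracted to express `t_mid_s` relative to
#'   injection start (breaths matched on mid-inspiration).
#' @param literalRaw see [resistanceCompliance()].
#' @return data.frame with columns `subject`, `breath_ordinal`,
#'   `t_mid_s`, `vt_insp_ml`, `vt_exp_ml`, `pip_cmh2o`, `p_plat_cmh2o`,
#'   `peep_cmh2o`, `pef_lps`, `raw_cmh2o_per_lps`, `cdyn_ml_per_cmh2o`,
#'   `f_r_bpm`.
#' @export
mechFeatures <- function(signals, breaths, subject = 1L, tRef = 0,
                         literalRaw = FALSE) {
  out <- vector("list", nrow(breaths))
  for (i in seq_len(nrow(breaths))) {
    b <- breaths[i, ]
    vols <- mechVolumes(signals, b)
    pr <- mechPressures(signals, b)
    rc <- resistanceCompliance(pr$pip, pr$p_plat, pr$peep, vols$vt_exp,
                               .meanInspFlow(signals, b),
                               literal = literalRaw)
    out[[i]] <- data.frame(
      subject = subject, breath_ordinal = b$ordinal,
      t_mid_s = b$t_mid_insp_s - tRef,
      vt_insp_ml = vols$vt_insp, vt_exp_ml = vols$vt_exp,
      pip_cmh2o = pr$pip, p_plat_cmh2o = pr$p_plat,
      peep_cmh2o = pr$peep, pef_lps = pr$pef,
      raw_cmh2o_per_lps = rc$raw, cdyn_ml_per_cmh2o = rc$cdyn,
      f_r_bpm = 60 / (b$t_end_s - b$t_start_s +
                        1 / signals@sampleRate))
  }
  do.call(rbind, out)
}
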