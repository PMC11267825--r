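## End-to-end drivers: subject-level feature extraction and cohort
## assembly into the long-format breath table used by the statistics.

.eitVarMap <- c(tiv_au = "tiv", eeli_au = "eeli", cov_vd_pct = "cov_vd",
                cov_rl_pct = "cov_rl", nss_pct = "nss", dss_pct = "dss",
                dz_v_pct = "dz_v", dz_cv_pct = "dz_cv",
                dz_cd_pct = "dz_cd", dz_d_pct = "dz_d")
.mechVarMap <- c(vt_exp_ml = "vt", pip_cmh2o = "pip",
                 p_plat_cmh2o = "p_plat", pef_lps = "pef",
                 raw_cmh2o_per_lps = "raw", cdyn_ml_per_cmh2o = "cdyn")
.vcapVarMap <- c(vd_aw_ml = "vd_aw", vt_alv_ml = "vt_alv",
                 s2_mmhg_per_l = "s2", s3_mmhg_per_l = "s3",
                 alpha_deg = "alpha", y_int_mmhg = "y_int",
                 x_int_ml = "x_int", vco2_br_ml = "vco2_br",
                 pe_co2_mmhg = "pe_co2", vd_bohr = "vd_bohr",
                 vd_alv_ml = "vd_alv")

#' Analyze one subject end to end
#'
#' Synchronizes the modalities via the apnea, segments breaths from
#' flow, applies quality control and extracts the EIT, capnography and
#' mechanics feature tables (one row per breath, times relative to
#' injection start).
#'
#' @param subject list with `eit`, `airway`, `events` (from
#'   [readSubject()] or [simulateSubject()]).
#' @param subjectId identifier used in the output tables.
#' @param literalRaw see [resistanceCompliance()].
#' @return list with `breaths` (QC-flagged segmentation), `eit`, `vcap`,
#'   `mech` feature tables and the `sync` result.
#' @examples
#' cfg <- simConfig(nSubjects = 1, noiseSd = 0,
#'                  timeline = c(apneaStart = -70, apneaEnd = -60,
#'                               baselineStart = -60, injectionStart = 0,
#'                               injectionEnd = 0, recordEnd = 0))
#' a <- analyzeSubject(simulateSubject(cfg, 1))
#' head(a$eit)
#' @export
analyzeSubject <- function(subject, subjectId = 1L, literalRaw = FALSE) {
  sync <- detectApneaSync(subject$airway, subject$eit)
  breaths <- detectBreaths(subject$airway)
  if (nrow(breaths) == 0)
    stop("no breaths detected for subject ", subjectId)
  tRef <- subject$events@injectionStart
  mech <- mechFeatures(subject$airway, breaths, subject = subjectId,
                       tRef = tRef, literalRaw = literalRaw)
  vcap <- vcapFeatures(subject$airway, breaths, subject = subjectId,
                       tRef = tRef)
  eitF <- eitFeatures(subject$eit, breaths, sync, subject = subjectId,
                      tRef = tRef)
  peep <- median(mech$peep_cmh2o)
  breaths <- qcBreaths(breaths, subject$airway, mech$vt_insp_ml,
                       mech$vt_exp_ml, peep = peep)
  breaths$flag_incomplete <- breaths$flag_incomplete | eitF$incomplete |
    vcap$incomplete
  list(breaths = breaths, eit = eitF, vcap = vcap, mech = mech,
       sync = sync)
}

#' Long-format breath table for the cohort statistics
#'
#' Stacks the per-breath feature tables of one analyzed subject into
#' records of (subject, variable, breath_ordinal, t_s, value), dropping
#' breaths flagged by quality control.
#'
#' @param analysis result of [analyzeSubject()].
#' @return long-format data.frame.
#' @export
breathTable <- function(analysis) {
  keep <- !(analysis$breaths$flag_leak |
              analysis$breaths$flag_spontaneous_effort |
              analysis$breaths$flag_incomplete)
  stack1 <- function(tab, map) {
    tab <- tab[keep, , drop = FALSE]
    do.call(rbind, lapply(names(map), function(col) {
      data.frame(subject = tab$subject,
                 variable = rep(map[[col]], nrow(tab)),
                 breath_ordinal = tab$breath_ordinal, t_s = tab$t_mid_s,
                 value = tab[[col]])
    }))
  }
  out <- rbind(stack1(analysis$eit, .eitVarMap),
               stack1(analysis$mech, .mechVarMap),
               stack1(analysis$vcap, .vcapVarMap))
  out[!is.na(out$value), ]
}

#' Analyze a cohort of subject datasets
#'
#' Reads and analyzes each subject directory and assembles the combined
#' long-format breath table.
#'
#' @param dirs subject directories (as written by [simulateCohort()]).
#' @param literalRaw see [resistanceCompliance()].
#' @return list with per-subject `analyses` and the combined long
#'   `table`.
#' @export
analyzeCohort <- function(dirs, literalRaw = FALSE) {
  analyses <- vector("list", length(dirs))
  tabs <- vector("list", length(dirs))
  for (i in seq_along(dirs)) {
    subj <- readSubject(dirs[i])
    analyses[[i]] <- analyzeSubject(subj, subjectId = i,
                                    literalRaw = literalRaw)
    tabs[[i]] <- breathTable(analyses[[i]])
  }
  list(analyses = analyses, table = do.call(rbind, tabs))
}
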