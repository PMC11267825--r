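## Volumetric capnography: the per-breath expirogram (CO2 tension vs
## expired volume) and the variables derived from its three phases.

#' Build the expirogram of one breath
#'
#' Expired volume is the cumulative trapezoidal integral of the negated
#' flow over the expiration; CO2 tension is taken on the same samples
#' and the curve is resampled onto a uniform 1-mL expired-volume grid.
#'
#' @param signals an [AirwaySignals].
#' @param breath one row of the [detectBreaths()] table.
#' @param minVt minimum expired volume in mL; smaller breaths are
#'   returned with `incomplete = TRUE`.
#' @return list with `volume` (mL grid from 0 to `vt`), `pco2` (mmHg),
#'   `vt` (mL) and logical `incomplete`.
#' @export
buildExpirogram <- function(signals, breath, minVt = 50) {
  seg <- breath$insp_end:breath$exp_end
  expi <- seg[which(signals@flow[seg] < 0)]
  if (length(expi) < 2)
    return(list(volume = numeric(), pco2 = numeric(), vt = 0,
                incomplete = TRUE))
  tt <- signals@time[expi]
  vol <- 1000 * pracma::cumtrapz(tt, -signals@flow[expi])[, 1]  # mL
  vt <- vol[length(vol)]
  if (vt < minVt)
    return(list(volume = vol, pco2 = signals@pco2[expi], vt = vt,
                rawSpacing = NA_real_, incomplete = TRUE))
  grid <- seq(0, vt, by = 1)
  p <- approx(vol, signals@pco2[expi], xout = grid, ties = "ordered",
              rule = 2)$y
  ## coarsest raw volume step (early expiration moves fastest); the
  ## phase fits widen their smoothing to this so the inflection is not
  ## pinned to an interpolation segment boundary
  list(volume = grid, pco2 = p, vt = vt, rawSpacing = max(diff(vol)),
       incomplete = FALSE)
}

## centered moving average over a window of `w` grid points
.movavg <- function(x, w) {
  if (w < 2) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y[is.na(y)] <- x[is.na(y)]
  as.numeric(y)
}

#' Fit the expirogram phases
#'
#' Phase III slope is the least-squares slope of CO2 vs expired volume
#' over the 60-90% expired-volume window.  Phase II slope is the tangent
#' at the point of maximum dCO2/dV, estimated on a 5-mL smoothed
#' derivative and capped at `s2Cap` for near-vertical (square-wave)
#' transitions.  The alpha angle between the two lines is computed on
#' normalized axes (volume scaled by VT, CO2 by the end-tidal value) as
#' 180 degrees minus the angle between the lines; identical lines give
#' 180 degrees.
#'
#' @param e expirogram from [buildExpirogram()].
#' @param window phase III fit window as fractions of VT (default
#'   `c(0.6, 0.9)`).
#' @param smoothMl minimum smoothing window for the derivative, in mL;
#'   automatically widened to the coarsest raw volume step of the
#'   expirogram so that fast early expiration (sparse volume samples)
#'   does not pin the inflection to an interpolation segment.
#' @param s2Cap cap for the phase II slope, mmHg/L.
#' @return list with `s2`, `s3` (mmHg/L), `alpha_deg`, `y_int` (mmHg,
#'   phase III intercept at volume 0), `x_int` (mL, phase II zero
#'   crossing), `inflection_ml` and `etco2` (mmHg).
#' @export
fitPhases <- function(e, window = c(0.6, 0.9), smoothMl = 5, s2Cap = 1e4) {
  if (e$incomplete || max(e$pco2) <= 0)
    stop("no phase II detected: flat or incomplete expirogram")
  ## smoothing window: configured floor, widened to the coarsest raw
  ## volume step so sparsely sampled (fast) expirations stay localized
  w <- max(smoothMl, ceiling(if (is.null(e$rawSpacing) ||
                                 is.na(e$rawSpacing)) 0 else e$rawSpacing))
  if (w %% 2 == 0) w <- w + 1
  p <- .movavg(e$pco2, w)
  d <- .movavg(c(diff(p), 0), w)                # mmHg per mL
  interior <- seq(2, length(d) - 2)
  iMax <- interior[which.max(d[interior])]
  if (d[iMax] <= 0) stop("no phase II detected: derivative never positive")
  vStar <- e$volume[iMax]
  s2mL <- min(d[iMax], s2Cap / 1000)
  inWin <- e$volume >= window[1] * e$vt & e$volume <= window[2] * e$vt
  fit <- lm(pco2 ~ volume, data.frame(volume = e$volume[inWin],
                                      pco2 = e$pco2[inWin]))
  s3mL <- coef(fit)[["volume"]]
  yInt <- coef(fit)[["(Intercept)"]]
  etco2 <- e$pco2[length(e$pco2)]
  s2n <- s2mL * e$vt / etco2
  s3n <- s3mL * e$vt / etco2
  list(s2 = 1000 * s2mL, s3 = 1000 * s3mL,
       alpha_deg = 180 - (atan(s2n) - atan(s3n)) * 180 / pi,
       y_int = yInt, x_int = vStar - p[iMax] / s2mL,
       inflection_ml = vStar, etco2 = etco2)
}

#' Airway dead space and alveolar tidal volume
#'
#' The airway (Fowler-type) dead space is the expired volume at the
#' inflection point of the smoothed expirogram (maximum of dCO2/dV);
#' the alveolar tidal volume is the remainder of the breath.
#'
#' @param e expirogram from [buildExpirogram()].
#' @param fits from [fitPhases()].
#' @return list with `vd_aw` and `vt_alv` in mL.
#' @export
deadSpaces <- function(e, fits) {
  if (is.null(fits$inflection_ml) || is.na(fits$inflection_ml))
    stop("inflection point not found")
  list(vd_aw = fits$inflection_ml, vt_alv = e$vt - fits$inflection_ml)
}

#' CO2 exchange and Bohr dead space
#'
#' Per-breath CO2 elimination is the integral of the CO2 fraction
#' (dry-gas barometric conversion, `pco2 / (pb - ph2o)`) over expired
#' volume; the mixed-expired CO2 tension is the volume-weighted mean;
#' the mean alveolar CO2 tension is the fitted phase III line evaluated
#' at the midpoint of the phase III window; and the Bohr dead-space
#' ratio is `(pa - pe) / pa`, with the alveolar dead space following as
#' `vd_bohr * vt - vd_aw`.
#'
#' @param e expirogram from [buildExpirogram()].
#' @param fits from [fitPhases()].
#' @param vdAw airway dead space in mL from [deadSpaces()].
#' @param pb,ph2o barometric and water-vapor pressure, mmHg.
#' @param window phase III window used for the alveolar midpoint.
#' @return list with `vco2_br` (mL, at measurement conditions),
#'   `pe_co2`, `pa_co2` (mmHg), `vd_bohr` (ratio) and `vd_alv` (mL);
#'   all `NA` when the alveolar tension is non-positive.
#' @export
gasExchange <- function(e, fits, vdAw, pb = 760, ph2o = 47,
                        window = c(0.6, 0.9)) {
  vco2 <- pracma::trapz(e$volume, e$pco2) / (pb - ph2o)
  pe <- pracma::trapz(e$volume, e$pco2) / e$vt
  pa <- fits$y_int + fits$s3 / 1000 * mean(window) * e$vt
  if (is.na(pa) || pa <= 0)
    return(list(vco2_br = NA_real_, pe_co2 = NA_real_, pa_co2 = NA_real_,
                vd_bohr = NA_real_, vd_alv = NA_real_))
  bohr <- (pa - pe) / pa
  list(vco2_br = vco2, pe_co2 = pe, pa_co2 = pa, vd_bohr = bohr,
       vd_alv = bohr * e$vt - vdAw)
}

#' Per-breath volumetric capnography feature table
#'
#' @param signals an [AirwaySignals].
#' @param breaths data.frame from [detectBreaths()].
#' @param subject subject identifier for the output table.
#' @param tRef time subtracted to express `t_mid_s` relative to
#'   injection start (breath times are matched on mid-expiration).
#' @param minVt minimum expired volume in mL.
#' @return data.frame with columns `subject`, `breath_ordinal`,
#'   `t_mid_s`, `vt_ml`, `vd_aw_ml`, `vt_alv_ml`, `s2_mmhg_per_l`,
#'   `s3_mmhg_per_l`, `alpha_deg`, `y_int_mmhg`, `x_int_ml`,
#'   `vco2_br_ml`, `pe_co2_mmhg`, `pa_co2_mmhg`, `vd_bohr`, `vd_alv_ml`,
#'   `incomplete`.
#' @export
vcapFeatures <- function(signals, breaths, subject = 1L, tRef = 0,
                         minVt = 50) {
  out <- vector("list", nrow(breaths))
  for (i in seq_len(nrow(breaths))) {
    e <- buildExpirogram(signals, breaths[i, ], minVt = minVt)
    row <- data.frame(subject = subject,
                      breath_ordinal = breaths$ordinal[i],
                      t_mid_s = breaths$t_mid_exp_s[i] - tRef,
                      vt_ml = e$vt, vd_aw_ml = NA_real_,
                      vt_alv_ml = NA_real_, s2_mmhg_per_l = NA_real_,
                      s3_mmhg_per_l = NA_real_, alpha_deg = NA_real_,
                      y_int_mmhg = NA_real_, x_int_ml = NA_real_,
                      vco2_br_ml = NA_real_, pe_co2_mmhg = NA_real_,
                      pa_co2_mmhg = NA_real_, vd_bohr = NA_real_,
                      vd_alv_ml = NA_real_, incomplete = e$incomplete)
    if (!e$incomplete) {
      fits <- tryCatch(fitPhases(e), error = function(err) NULL)
      if (!is.null(fits)) {
        ds <- deadSpaces(e, fits)
        gx <- gasExchange(e, fits, ds$vd_aw)
        row$vd_aw_ml <- ds$vd_aw; row$vt_alv_ml <- ds$vt_alv
        row$s2_mmhg_per_l <- fits$s2; row$s3_mmhg_per_l <- fits$s3
        row$alpha_deg <- fits$alpha_deg
        row$y_int_mmhg <- fits$y_int; row$x_int_ml <- fits$x_int
        row$vco2_br_ml <- gx$vco2_br; row$pe_co2_mmhg <- gx$pe_co2
        row$pa_co2_mmhg <- gx$pa_co2; row$vd_bohr <- gx$vd_bohr
        row$vd_alv_ml <- gx$vd_alv
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}
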