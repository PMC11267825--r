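## Global and regional EIT variables, computed per breath from the pixel
## frames: TIV, EELI, center of ventilation, silent spaces and the four
## ventro-dorsal band fractions.

#' Global lung impedance signal
#'
#' Per-frame sum of pixel impedance inside the lung mask (the curve on
#' which TIV and EELI are read).
#'
#' @param x an [EITSequence].
#' @return numeric vector, one value per frame (AU).
#' @export
setGeneric("globalSignal", function(x) standardGeneric("globalSignal"))

#' @rdname globalSignal
#' @export
setMethod("globalSignal", "EITSequence", function(x) {
  if (!any(x@lungMask)) stop("empty lung mask")
  m <- matrix(x@frames, nrow = dim(x@frames)[1])
  rowSums(m[, as.vector(x@lungMask), drop = FALSE])
})

#' EIT breath landmarks from the global signal
#'
#' The start-of-inspiration frame is the minimum of the global signal in
#' a window around the flow-derived inspiration start; the
#' end-of-inspiration frame is the maximum within the breath.  Ties take
#' the earliest frame.
#'
#' @param signal global impedance signal from [globalSignal()].
#' @param tInspStart,tExpEnd flow-derived breath boundary times (s, on
#'   the airway clock).
#' @param sync synchronization from [detectApneaSync()].
#' @param window half-width (s) of the search window around the
#'   inspiration start.
#' @return list with `inspStartFrame` and `inspEndFrame`.
#' @export
breathLandmarksEIT <- function(signal, tInspStart, tExpEnd, sync,
                               window = 0.5) {
  f0 <- max(1L, frameIndexAt(tInspStart - window, sync))
  f1 <- min(length(signal), frameIndexAt(tInspStart + window, sync))
  if (f1 < f0) stop("empty EIT landmark window for breath at t = ",
                    tInspStart, " s")
  inspStart <- f0 - 1L + which.min(signal[f0:f1])
  fEnd <- min(length(signal), frameIndexAt(tExpEnd, sync))
  if (fEnd < inspStart) stop("empty EIT breath window at t = ",
                             tInspStart, " s")
  inspEnd <- inspStart - 1L + which.max(signal[inspStart:fEnd])
  list(inspStartFrame = inspStart, inspEndFrame = inspEnd)
}

#' Tidal impedance variation and end-expiratory lung impedance
#'
#' `eeli` is the global signal at the start-of-inspiration frame (the
#' impedance in the chest before the breath, a surrogate for functional
#' residual capacity); `tiv` is the rise of the global signal from the
#' start to the end of inspiration (a surrogate for tidal volume).  A
#' negative `tiv` marks the breath incomplete rather than dropping it.
#'
#' @param signal global impedance signal.
#' @param landmarks from [breathLandmarksEIT()].
#' @return list with `tiv` (AU), `eeli` (AU) and logical `incomplete`.
#' @export
tivEeli <- function(signal, landmarks) {
  eeli <- signal[landmarks$inspStartFrame]
  tiv <- signal[landmarks$inspEndFrame] - eeli
  list(tiv = tiv, eeli = eeli, incomplete = tiv < 0)
}

#' Per-pixel tidal image of one breath
#'
#' Pixel-wise difference between the end-inspiratory and
#' start-inspiratory frames inside the lung mask.  The raw (unclipped)
#' difference is stored -- its sum over the mask equals the global TIV --
#' and downstream ventilation measures clip negative pixels to zero.
#'
#' @param eit an [EITSequence].
#' @param landmarks from [breathLandmarksEIT()].
#' @return a [TidalImage].
#' @export
tidalImage <- function(eit, landmarks) {
  dz <- eit@frames[landmarks$inspEndFrame, , ] -
    eit@frames[landmarks$inspStartFrame, , ]
  dz[!eit@lungMask] <- 0
  rows <- which(rowSums(eit@lungMask) > 0)
  cols <- which(colSums(eit@lungMask) > 0)
  new("TidalImage", dz = dz, mask = eit@lungMask,
      ventralEdge = min(rows), dorsalEdge = max(rows),
      rightEdge = min(cols), leftEdge = max(cols))
}

## Clipped dz values and extent coordinates (%) of all mask pixels.
## Row/column centers are mapped onto the lung-region bounding extent so
## that 0% is the most ventral (rightmost) edge and 100% the most dorsal
## (leftmost); a single-row or single-column extent maps to 50%.
.pixelGeometry <- function(img) {
  idx <- which(img@mask, arr.ind = TRUE)
  nR <- img@dorsalEdge - img@ventralEdge + 1L
  nC <- img@leftEdge - img@rightEdge + 1L
  posVD <- if (nR == 1) rep(50, nrow(idx)) else
    (idx[, 1] - img@ventralEdge + 0.5) / nR * 100
  posRL <- if (nC == 1) rep(50, nrow(idx)) else
    (idx[, 2] - img@rightEdge + 0.5) / nC * 100
  list(dz = pmax(img@dz[idx], 0), posVD = posVD, posRL = posRL,
       band = pmin(floor((idx[, 1] - img@ventralEdge + 0.5) / nR * 4) + 1, 4))
}

#' Center of ventilation
#'
#' dz-weighted centroid of the (negative-clipped) tidal image, expressed
#' as a percentage of the lung-region ventro-dorsal extent (0% most
#' ventral, 100% most dorsal) and right-left extent (0% subject's right,
#' 100% left).
#'
#' @param img a [TidalImage].
#' @return list with `cov_vd` and `cov_rl` in %; both `NA` when the
#'   total clipped dz is zero.
#' @export
centerOfVentilation <- function(img) {
  p <- .pixelGeometry(img)
  tot <- sum(p$dz)
  if (tot <= 0) return(list(cov_vd = NA_real_, cov_rl = NA_real_))
  list(cov_vd = sum(p$dz * p$posVD) / tot,
       cov_rl = sum(p$dz * p$posRL) / tot)
}

#' Silent spaces
#'
#' Lung pixels whose tidal impedance change is strictly below 10% of the
#' maximum over the mask, split at the horizontal plane through the
#' center-of-ventilation height: pixels dorsal to the plane count as
#' non-dependent silent space (NSS), pixels ventral to or exactly on it
#' as dependent silent space (DSS -- the animal is prone, so ventral is
#' dependent).  Both are percentages of the total lung pixel count.
#'
#' @param img a [TidalImage].
#' @param covVd the ventro-dorsal center of ventilation in %.
#' @param threshold silent-space threshold as a fraction of the maximum
#'   pixel dz (default 0.10).
#' @return list with `nss` and `dss` in % of lung pixels.
#' @export
silentSpaces <- function(img, covVd, threshold = 0.10) {
  p <- .pixelGeometry(img)
  n <- length(p$dz)
  silent <- p$dz < threshold * max(p$dz)
  list(nss = 100 * sum(silent & p$posVD > covVd) / n,
       dss = 100 * sum(silent & p$posVD <= covVd) / n)
}

#' Ventro-dorsal band fractions of ventilation
#'
#' The lung-region ventro-dorsal extent is split into four bands of
#' equal width (ventral, centro-ventral, centro-dorsal, dorsal); each
#' pixel belongs to the band containing its center.  Values are each
#' band's share of the total clipped tidal impedance change, in %.
#'
#' @param img a [TidalImage].
#' @return list with `dz_v`, `dz_cv`, `dz_cd`, `dz_d` in % (summing to
#'   100); all `NA` when total clipped dz is zero.
#' @export
regionalBands <- function(img) {
  p <- .pixelGeometry(img)
  tot <- sum(p$dz)
  if (tot <= 0)
    return(list(dz_v = NA_real_, dz_cv = NA_real_, dz_cd = NA_real_,
                dz_d = NA_real_))
  s <- vapply(1:4, function(b) sum(p$dz[p$band == b]), numeric(1))
  s <- 100 * s / tot
  list(dz_v = s[1], dz_cv = s[2], dz_cd = s[3], dz_d = s[4])
}

#' Per-breath EIT feature table
#'
#' Runs the full EIT chain (landmarks, TIV/EELI, tidal image, centroid,
#' silent spaces, bands) for every breath.
#'
#' @param eit an [EITSequence].
#' @param breaths data.frame from [detectBreaths()].
#' @param sync from [detectApneaSync()].
#' @param subject subject identifier for the output table.
#' @param tRef time subtracted from breath times to express `t_mid_s`
#'   relative to injection start (default 0: times already relative).
#' @return data.frame with columns `subject`, `breath_ordinal`,
#'   `t_mid_s`, `tiv_au`, `eeli_au`, `cov_vd_pct`, `cov_rl_pct`,
#'   `nss_pct`, `dss_pct`, `dz_v_pct`, `dz_cv_pct`, `dz_cd_pct`,
#'   `dz_d_pct`, `incomplete`.
#' @export
eitFeatures <- function(eit, breaths, sync, subject = 1L, tRef = 0) {
  signal <- globalSignal(eit)
  out <- vector("list", nrow(breaths))
  for (i in seq_len(nrow(breaths))) {
    lm <- breathLandmarksEIT(signal, breaths$t_start_s[i],
                             breaths$t_end_s[i], sync)
    ge <- tivEeli(signal, lm)
    img <- tidalImage(eit, lm)
    cov <- centerOfVentilation(img)
    ss <- if (is.na(cov$cov_vd)) list(nss = NA_real_, dss = NA_real_)
          else silentSpaces(img, cov$cov_vd)
    bands <- regionalBands(img)
    out[[i]] <- data.frame(
      subject = subject, breath_ordinal = breaths$ordinal[i],
      t_mid_s = breaths$t_mid_insp_s[i] - tRef,
      tiv_au = ge$tiv, eeli_au = ge$eeli,
      cov_vd_pct = cov$cov_vd, cov_rl_pct = cov$cov_rl,
      nss_pct = ss$nss, dss_pct = ss$dss,
      dz_v_pct = bands$dz_v, dz_cv_pct = bands$dz_cv,
      dz_cd_pct = bands$dz_cd, dz_d_pct = bands$dz_d,
      incomplete = ge$incomplete)
  }
  do.call(rbind, out)
}
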