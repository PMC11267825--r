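# Shared fixtures: short experiment timelines and quick configs so the
# frame-level simulations stay small.

shortTimeline <- function(recordEnd = 6) {
  c(apneaStart = -70, apneaEnd = -60, baselineStart = -60,
    injectionStart = 0, injectionEnd = min(60, max(0, recordEnd)),
    recordEnd = recordEnd)
}

# full statistics window: baseline plus post-start breaths 0..120 s
statsTimeline <- function() shortTimeline(126)

quietConfig <- function(...) {
  simConfig(nSubjects = 1, noiseSd = 0, interSubjectSd = 0, ...)
}

signalsFromBreath <- function(df) {
  airwaySignals(df$time_s, df$flow_lps, df$paw_cmh2o, df$pco2_mmhg)
}

# one noise-free baseline breath of airway signals
baselineBreathSignals <- function(cfg = quietConfig()) {
  signalsFromBreath(simulateAirwaySignals(cfg, edemaState(), tStart = 0))
}

# brute-force centroid oracle: explicit double loop over pixels
bruteForceCov <- function(img) {
  r0 <- img@ventralEdge; r1 <- img@dorsalEdge
  c0 <- img@rightEdge; c1 <- img@leftEdge
  nR <- r1 - r0 + 1; nC <- c1 - c0 + 1
  num_vd <- num_rl <- den <- 0
  for (i in seq_len(nrow(img@mask))) {
    for (j in seq_len(ncol(img@mask))) {
      if (!img@mask[i, j]) next
      dz <- max(img@dz[i, j], 0)
      pvd <- if (nR == 1) 50 else (i - r0 + 0.5) / nR * 100
      prl <- if (nC == 1) 50 else (j - c0 + 0.5) / nC * 100
      num_vd <- num_vd + dz * pvd
      num_rl <- num_rl + dz * prl
      den <- den + dz
    }
  }
  list(cov_vd = num_vd / den, cov_rl = num_rl / den)
}

# random tidal image on a random connected-ish mask (for property tests)
randomTidalImage <- function() {
  h <- sample(6:16, 1); w <- sample(6:16, 1)
  mask <- matrix(runif(h * w) < 0.6, h, w)
  if (!any(mask)) mask[sample(h * w, 3)] <- TRUE
  dz <- matrix(0, h, w)
  dz[mask] <- runif(sum(mask))
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  new("TidalImage", dz = dz, mask = mask,
      ventralEdge = min(rows), dorsalEdge = max(rows),
      rightEdge = min(cols), leftEdge = max(cols))
}

# tidal image from explicit matrices
tidalImageOf <- function(dz, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dz), ncol(dz))
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  new("TidalImage", dz = dz, mask = mask,
      ventralEdge = min(rows), dorsalEdge = max(rows),
      rightEdge = min(cols), leftEdge = max(cols))
}

# analytic expirogram constructed directly on a 1-mL grid
expirogramOf <- function(pco2, vt = length(pco2) - 1) {
  list(volume = seq(0, vt, by = 1), pco2 = pco2, vt = vt, rawSpacing = 1,
       incomplete = FALSE)
}
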