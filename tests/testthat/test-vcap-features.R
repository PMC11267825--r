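test_that("constant expiratory flow integrates to the expired volume", {
  fs <- 100
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  flow <- ifelse(tt < 1, 0.5, ifelse(tt < 1.99, -0.5, 0))
  sig <- airwaySignals(tt, flow, rep(0, length(tt)), rep(0, length(tt)))
  br <- data.frame(ordinal = 1, insp_start = 1, insp_end = 100,
                   exp_end = 300)
  e <- buildExpirogram(sig, br)
  expect_equal(e$vt, 500, tolerance = 2.5)  # 0.5% trapezoid tolerance
  expect_true(all(e$pco2 == 0))
})

test_that("a sub-minimum expired volume flags the breath incomplete", {
  fs <- 100
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  flow <- ifelse(tt < 0.5, 0.1, -0.05)
  sig <- airwaySignals(tt, flow, rep(0, length(tt)), rep(0, length(tt)))
  br <- data.frame(ordinal = 1, insp_start = 1, insp_end = 50, exp_end = 100)
  expect_true(buildExpirogram(sig, br, minVt = 50)$incomplete)
})

test_that("the synthetic breath expirogram carries the configured VT", {
  cfg <- quietConfig()
  sig <- baselineBreathSignals(cfg)
  br <- detectBreaths(sig)
  e <- buildExpirogram(sig, br[1, ])
  expect_equal(e$vt, 500, tolerance = 0.005 * 500)
})

test_that("least squares recovers an exactly linear phase III", {
  v <- 0:500
  p <- pmax(0, 20 + 10 / 1000 * v) * plogis((v - 150) / 10)
  f <- fitPhases(expirogramOf(p))
  expect_equal(f$s3, 10, tolerance = 0.1)
  expect_equal(f$y_int, 20, tolerance = 0.2)
})

test_that("identical phase II and III lines give a 180-degree alpha angle", {
  v <- 0:500
  p <- 10 + 0.02 * v  # a single straight line: zero angle between fits
  f <- fitPhases(expirogramOf(p))
  expect_equal(f$alpha_deg, 180, tolerance = 1)
})

test_that("a square-wave expirogram caps phase II and puts x_int at the rise", {
  v <- 0:500
  p <- ifelse(v < 150, 0, ifelse(v == 150, 20, 40))
  f <- fitPhases(expirogramOf(p))
  expect_lte(f$s2, 1e4)        # capped at the configured maximum
  expect_gt(f$s2, 1000)        # near-vertical transition
  expect_equal(f$x_int, 150, tolerance = 5)
  ds <- deadSpaces(expirogramOf(p), f)
  expect_equal(ds$vd_aw, 150, tolerance = 3)
  expect_equal(ds$vd_aw + ds$vt_alv, 500)
})

test_that("a symmetric sigmoid transition puts the dead space at its center", {
  v <- 0:500
  p <- 40 * plogis((v - 150) / 10)
  f <- fitPhases(expirogramOf(p))
  expect_equal(deadSpaces(expirogramOf(p), f)$vd_aw, 150, tolerance = 1)
})

test_that("flat curves are rejected as having no phase II", {
  expect_error(fitPhases(expirogramOf(rep(0, 501))), "no phase II")
})

test_that("Bohr arithmetic on the analytic square wave is exact", {
  v <- 0:500
  p <- ifelse(v < 150, 0, ifelse(v == 150, 20, 40))
  e <- expirogramOf(p)
  f <- fitPhases(e)
  gx <- gasExchange(e, f, vdAw = 150)
  expect_equal(gx$pe_co2, 28, tolerance = 1e-9)       # 40 * 350 / 500
  expect_equal(gx$pa_co2, 40, tolerance = 1e-6)
  expect_equal(gx$vd_bohr, 0.30, tolerance = 1e-7)    # (40 - 28) / 40
  expect_equal(gx$vd_alv, 0, tolerance = 1e-4)
})

test_that("zero CO2 eliminates zero volume", {
  e <- expirogramOf(c(0, rep(0, 500)))
  expect_equal(pracma::trapz(e$volume, e$pco2) / (760 - 47), 0)
})

test_that("CO2 formulas are homogeneous; Bohr ratio is scale free", {
  v <- 0:500
  p <- 40 * plogis((v - 150) / 15)
  e1 <- expirogramOf(p); e2 <- expirogramOf(2 * p)
  f1 <- fitPhases(e1); f2 <- fitPhases(e2)
  g1 <- gasExchange(e1, f1, 150); g2 <- gasExchange(e2, f2, 150)
  expect_equal(g2$vco2_br, 2 * g1$vco2_br, tolerance = 1e-9)
  expect_equal(g2$pe_co2, 2 * g1$pe_co2, tolerance = 1e-9)
  expect_equal(g2$vd_bohr, g1$vd_bohr, tolerance = 1e-9)
})

test_that("alpha angle follows the fitted-line geometry in s2 and s3", {
  v <- 0:500
  mkAlpha <- function(s3) {
    p <- pmax(0, (30 + s3 / 1000 * v)) * plogis((v - 150) / 25)
    fitPhases(expirogramOf(p))$alpha_deg
  }
  alphas <- vapply(c(4, 8, 16, 30), mkAlpha, numeric(1))
  # steeper phase III closes the gap to phase II: alpha rises toward 180
  expect_true(all(diff(alphas) > 0))
  expect_true(all(alphas > 90 & alphas < 180))
})

test_that("mixed-expired CO2 never exceeds end-tidal on monotone curves", {
  set.seed(5)
  for (rep in 1:10) {
    vd <- runif(1, 80, 250); w <- runif(1, 8, 40); et <- runif(1, 25, 60)
    v <- 0:500
    p <- et * plogis((v - vd) / w) / plogis((500 - vd) / w)
    e <- expirogramOf(p)
    f <- fitPhases(e)
    gx <- gasExchange(e, f, vd)
    expect_lte(gx$pe_co2, p[length(p)] + 1e-9)
  }
})

test_that("noise-free synthetic breaths recover VDaw and SIII within 2%", {
  cfg <- quietConfig()
  sig <- baselineBreathSignals(cfg)
  br <- detectBreaths(sig)
  vc <- vcapFeatures(sig, br)
  expect_equal(vc$vd_aw_ml, 150, tolerance = 0.02 * 150)
  expect_equal(vc$s3_mmhg_per_l, 6, tolerance = 0.02 * 6)
  expect_equal(vc$vt_ml, 500, tolerance = 0.005 * 500)
  expect_equal(vc$vd_aw_ml + vc$vt_alv_ml, vc$vt_ml)
})
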