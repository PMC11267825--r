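rectBreathSignals <- function(fs = 100) {
  # 0.5 L/s for 1 s in, 1 s pause, passive out; paw from a single
  # compartment with Raw 10, Crs 25 mL/cmH2O, PEEP 0
  tt <- seq(0, 6 - 1 / fs, by = 1 / fs)
  tau <- 10 * 0.025
  flow <- ifelse(tt <= 1, 0.5, ifelse(tt < 2, 0,
                                      -0.5 / tau * exp(-(tt - 2) / tau)))
  vol <- ifelse(tt <= 1, 0.5 * tt, ifelse(tt < 2, 0.5,
                                          0.5 * exp(-(tt - 2) / tau)))
  paw <- 10 * flow + vol / 0.025
  airwaySignals(tt, flow, paw, rep(0, length(tt)), fs)
}

test_that("tidal volumes are the trapezoidal flow integrals", {
  sig <- rectBreathSignals()
  br <- detectBreaths(sig)
  vols <- mechVolumes(sig, br[1, ])
  expect_equal(vols$vt_insp, 500, tolerance = 0.005 * 500)
  expect_equal(vols$vt_exp, 500, tolerance = 0.005 * 500)
  expect_equal(vols$vt_insp, vols$vt_exp, tolerance = 0.005 * 500)
})

test_that("pressures read PIP, plateau, PEEP and PEF off the waveform", {
  sig <- rectBreathSignals()
  br <- detectBreaths(sig)
  pr <- mechPressures(sig, br[1, ])
  expect_equal(pr$pip, 10 * 0.5 + 500 / 25, tolerance = 1e-6)
  expect_equal(pr$p_plat, 20, tolerance = 1e-6)
  expect_equal(pr$peep, 0, tolerance = 1e-3)
  expect_equal(pr$pef, 2, tolerance = 1e-6)  # 0.5 / 0.25
})

test_that("constant pressure collapses PIP, plateau and PEEP", {
  fs <- 100
  tt <- seq(0, 6 - 1 / fs, by = 1 / fs)
  flow <- ifelse(tt <= 1, 0.5, ifelse(tt < 2, 0, -0.2 * (tt < 4.5)))
  sig <- airwaySignals(tt, flow, rep(5, length(tt)), rep(0, length(tt)))
  br <- detectBreaths(sig)
  pr <- mechPressures(sig, br[1, ])
  expect_equal(pr$pip, 5)
  expect_equal(pr$p_plat, 5)
  expect_equal(pr$peep, 5)
})

test_that("resistance and compliance follow the bedside formulas", {
  rc <- resistanceCompliance(pip = 20, pPlat = 15, peep = 0, vtExp = 500,
                             meanInspFlow = 0.5)
  expect_equal(rc$raw, 10)          # (20 - 15) / 0.5
  expect_equal(rc$cdyn, 25)         # 500 / (20 - 0)
  lit <- resistanceCompliance(20, 15, 0, 500, 0.5, literal = TRUE)
  expect_equal(lit$raw, 0.1)        # the literal inverted wording
  expect_true(is.na(resistanceCompliance(5, 4, 5, 500, 0.5)$cdyn))
})

test_that("breaths without a pause report resistance as missing", {
  fs <- 100
  tt <- seq(0, 6 - 1 / fs, by = 1 / fs)
  tau <- 0.25
  flow <- ifelse(tt <= 2, 0.25, -0.5 / tau * exp(-(tt - 2) / tau))
  paw <- 10 * flow + ifelse(tt <= 2, 0.25 * tt, 0.5 * exp(-(tt - 2) / tau)) / 0.025
  sig <- airwaySignals(tt, flow, paw, rep(0, length(tt)))
  br <- detectBreaths(sig)
  m <- mechFeatures(sig, br)
  expect_true(is.na(m$p_plat_cmh2o[1]))
  expect_true(is.na(m$raw_cmh2o_per_lps[1]))
})

test_that("synthetic breaths recover the generator mechanics within 2%", {
  cfg <- quietConfig()
  sig <- baselineBreathSignals(cfg)
  br <- detectBreaths(sig)
  m <- mechFeatures(sig, br)
  fi <- 0.5 / breathEIT:::.breathTiming(cfg)$tFlow
  pipTrue <- 8 * fi + 500 / 25
  expect_equal(m$p_plat_cmh2o, 500 / 25, tolerance = 0.02 * 20)
  expect_equal(m$pip_cmh2o, pipTrue, tolerance = 0.02 * pipTrue)
  expect_equal(m$raw_cmh2o_per_lps, 8, tolerance = 0.02 * 8)
  expect_equal(m$cdyn_ml_per_cmh2o, 500 / pipTrue,
               tolerance = 0.02 * 500 / pipTrue)
  expect_equal(m$pef_lps, 0.5 / (8 * 0.025), tolerance = 0.02 * 2.5)
})

test_that("doubling simulated resistance doubles the recovered value", {
  cfg <- quietConfig()
  getRaw <- function(state) {
    sig <- signalsFromBreath(simulateAirwaySignals(cfg, state))
    mechFeatures(sig, detectBreaths(sig))$raw_cmh2o_per_lps
  }
  r1 <- getRaw(edemaState())
  r2 <- getRaw(edemaState(rawScale = 2))
  expect_equal(r2 / r1, 2, tolerance = 0.02)
})

test_that("resistance and compliance are stable across sampling rates", {
  vals <- sapply(c(50, 100, 200, 500), function(fs) {
    cfg <- quietConfig(airwaySampleRate = fs)
    sig <- baselineBreathSignals(cfg)
    m <- mechFeatures(sig, detectBreaths(sig))
    c(m$raw_cmh2o_per_lps, m$cdyn_ml_per_cmh2o)
  })
  expect_lt(diff(range(vals[1, ])) / mean(vals[1, ]), 0.01)
  expect_lt(diff(range(vals[2, ])) / mean(vals[2, ]), 0.01)
})
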