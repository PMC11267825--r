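squareWaveSignals <- function(nCycles = 10, period = 6, fs = 100) {
  tt <- seq(0, nCycles * period - 1 / fs, by = 1 / fs)
  phase <- tt %% period
  flow <- ifelse(phase < 1, 0.5, ifelse(phase < 2, 0, -0.25))
  airwaySignals(tt, flow, paw = rep(5, length(tt)),
                pco2 = rep(0, length(tt)), sampleRate = fs)
}

test_that("a square-wave flow of 10 cycles yields 10 breaths", {
  sig <- squareWaveSignals(10)
  br <- detectBreaths(sig)
  expect_equal(nrow(br), 10)
  expect_equal(br$ordinal, 1:10)
})

test_that("all-zero flow yields zero breaths, not an error", {
  tt <- seq(0, 60, by = 0.01)
  sig <- airwaySignals(tt, rep(0, length(tt)), rep(0, length(tt)),
                       rep(0, length(tt)))
  expect_equal(nrow(detectBreaths(sig)), 0)
})

test_that("breath period on the synthetic default run is 6 s", {
  cfg <- quietConfig(timeline = shortTimeline(0))
  sub <- simulateSubject(cfg, 1)
  br <- detectBreaths(sub$airway)
  expect_equal(nrow(br), 10)
  expect_true(all(abs(diff(br$t_start_s) - 6.0) < 0.1))
})

test_that("apnea sync points land inside the configured apnea window", {
  cfg <- quietConfig(timeline = shortTimeline(0))
  sub <- simulateSubject(cfg, 1)
  sync <- detectApneaSync(sub$airway, sub$eit)
  expect_gte(sync$tSyncAirway, -70)
  expect_lt(sync$tSyncAirway, -59.9)
  tFrame <- -70 + (sync$frameSync - 1) / frameRate(sub$eit)
  expect_gte(tFrame, -70)
  expect_lt(tFrame, -59.9)
})

test_that("a recording without an apnea raises an alignment error", {
  cfg <- quietConfig(timeline = shortTimeline(0))
  sub <- simulateSubject(cfg, 1)
  cut <- sub$airway@time >= -60
  sig <- airwaySignals(sub$airway@time[cut], sub$airway@flow[cut],
                       sub$airway@paw[cut], sub$airway@pco2[cut])
  expect_error(detectApneaSync(sig, sub$eit), "no apnea")
})

test_that("EIT landmarks align with flow landmarks within one frame", {
  cfg <- quietConfig(timeline = shortTimeline(0))
  sub <- simulateSubject(cfg, 1)
  sync <- detectApneaSync(sub$airway, sub$eit)
  br <- detectBreaths(sub$airway)
  sig <- globalSignal(sub$eit)
  for (i in c(2, 5, 9)) {
    lm <- breathLandmarksEIT(sig, br$t_start_s[i], br$t_end_s[i], sync)
    trueFrame <- round((br$t_start_s[i] + 70) * frameRate(sub$eit)) + 1
    expect_lte(abs(lm$inspStartFrame - trueFrame), 1)
  }
})

test_that("the leak rule follows the 10%-of-first-breath arithmetic", {
  sig <- squareWaveSignals(3)
  br <- detectBreaths(sig)
  flags <- qcBreaths(br, sig, vtInsp = c(500, 500, 500),
                     vtExp = c(500, 430, 460), vtExpFirst = 500)
  expect_equal(flags$flag_leak, c(FALSE, TRUE, FALSE))  # 70 > 50 > 40
})

test_that("identical volumes never flag a leak", {
  sig <- squareWaveSignals(2)
  br <- detectBreaths(sig)
  flags <- qcBreaths(br, sig, vtInsp = c(480, 520), vtExp = c(480, 520))
  expect_false(any(flags$flag_leak))
})

test_that("leak flagging is monotone in the simulated leak", {
  sig <- squareWaveSignals(1)
  br <- detectBreaths(sig)
  leaks <- seq(0, 200, by = 10)
  flagged <- vapply(leaks, function(L) {
    qcBreaths(br, sig, vtInsp = 500, vtExp = 500 - L,
              vtExpFirst = 500)$flag_leak
  }, logical(1))
  expect_true(all(diff(as.integer(flagged)) >= 0))
})

test_that("airway pressure below PEEP flags a spontaneous effort", {
  sig <- squareWaveSignals(1)
  sig@paw[300] <- -3  # dip to -3 cmH2O with PEEP 0
  br <- detectBreaths(sig)
  flags <- qcBreaths(br, sig, vtInsp = 500, vtExp = 500, peep = 0)
  expect_true(flags$flag_spontaneous_effort)
  sig@paw[300] <- -1  # within the 2 cmH2O tolerance
  flags <- qcBreaths(br, sig, vtInsp = 500, vtExp = 500, peep = 0)
  expect_false(flags$flag_spontaneous_effort)
})
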