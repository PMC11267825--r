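# build a long table by hand: 15 subjects, breaths every 6 s from -60 to
# 120, unit-SD noise around 100, with an optional injected step
makeNullTable <- function(nSubj = 15, effect = 0, effectAt = numeric(),
                          seed = 1) {
  set.seed(seed)
  ts <- seq(-60, 120, by = 6)
  do.call(rbind, lapply(seq_len(nSubj), function(s) {
    val <- 100 + rnorm(length(ts))
    val[ts %in% effectAt] <- val[ts %in% effectAt] + effect
    data.frame(subject = s, variable = "x",
               breath_ordinal = seq_along(ts), t_s = ts, value = val)
  }))
}

test_that("baseline means are plain arithmetic means over the window", {
  tab <- data.frame(subject = 1, variable = "x", breath_ordinal = 1:13,
                    t_s = seq(-60, 12, by = 6),
                    value = c(rep(100, 10), 900, 900, 900))
  bl <- baselineMeans(tab)
  expect_equal(bl$baseline, 100)
  tab$value[1:3] <- c(90, 100, 110)
  tab$value[4:10] <- 100
  expect_equal(baselineMeans(tab)$baseline, 100)
})

test_that("subjects with too few baseline breaths are dropped", {
  tab <- makeNullTable(3)
  tab <- tab[!(tab$subject == 2 & tab$t_s < -6), ]
  expect_message(bl <- baselineMeans(tab), "fewer than")
  expect_false(2 %in% bl$subject)
})

test_that("normalization is a percentage and round-trips", {
  tab <- makeNullTable(4)
  bl <- baselineMeans(tab)
  nt <- normalizeToBaseline(tab, bl)
  m <- merge(nt, bl, by = c("subject", "variable"))
  expect_equal(m$value_pct_baseline, 100 * m$value / m$baseline.x)
  back <- m$value_pct_baseline / 100 * m$baseline.x
  expect_equal(back, m$value, tolerance = 1e-12)
  half <- tab
  half$value <- 0.3 * bl$baseline[match(half$subject, bl$subject)]
  nt2 <- normalizeToBaseline(half, bl)
  expect_true(all(abs(nt2$value_pct_baseline - 30) < 1e-9))
})

test_that("identical values over time yield no significant comparisons", {
  tab <- makeNullTable(6)
  tab$value <- 100
  nt <- normalizeToBaseline(tab, baselineMeans(tab))
  res <- suppressWarnings(perBreathTests(nt))
  expect_false(any(res$significant))
  expect_equal(unique(res$m), 21)  # breaths 0..120 at 6-s spacing
  # CI of identical values collapses to the value
  expect_equal(res$ci95_lo, res$mean_pct)
  expect_equal(res$ci95_hi, res$mean_pct)
})

test_that("Bonferroni adjustment multiplies by the comparison count", {
  tab <- makeNullTable(6)
  nt <- normalizeToBaseline(tab, baselineMeans(tab))
  res <- perBreathTests(nt)
  expect_equal(res$p_adj, pmin(1, res$m * res$p_raw))
  expect_equal(min(1, 21 * 0.001), 0.021)
  expect_true(all(res$significant == (res$p_adj < 0.05)))
})

test_that("an injected 10-SD step is first detected at its own breath", {
  tab <- makeNullTable(15, effect = 10,
                       effectAt = seq(42, 120, by = 6), seed = 4)
  nt <- normalizeToBaseline(tab, baselineMeans(tab))
  res <- perBreathTests(nt)
  fc <- firstChange(res)
  expect_equal(fc$first_t_s, 42)
  expect_equal(fc$direction, "increase")
})

test_that("first change is missing when nothing is significant", {
  tab <- makeNullTable(8, seed = 6)
  nt <- normalizeToBaseline(tab, baselineMeans(tab))
  fc <- firstChange(perBreathTests(nt))
  expect_true(is.na(fc$first_t_s))
  expect_true(is.na(fc$direction))
})

test_that("persistence rule postpones isolated significance", {
  res <- data.frame(variable = "x", t_s = seq(0, 24, by = 6),
                    breath_ordinal = 1:5, n_subjects = 15,
                    mean_pct = c(100, 120, 100, 120, 120),
                    ci95_lo = 0, ci95_hi = 0, p_raw = 0, p_adj = 0,
                    significant = c(FALSE, TRUE, FALSE, TRUE, TRUE), m = 5)
  expect_equal(firstChange(res)$first_t_s, 6)
  expect_equal(firstChange(res, requirePersistence = TRUE)$first_t_s, 18)
})

test_that("the summary table formats cells and stars significance", {
  tab <- makeNullTable(6, effect = 30, effectAt = 60, seed = 9)
  nt <- normalizeToBaseline(tab, baselineMeans(tab))
  res <- perBreathTests(nt)
  st <- summaryTable(res)
  expect_equal(nrow(st), 21)
  expect_true(all(grepl("\\[.*-.*\\]", st$x)))
  expect_true(grepl("\\*$", st$x[st$t_s == 60]))
})

test_that("t-based confidence intervals match a bootstrap oracle", {
  set.seed(13)
  x <- 100 + rnorm(15, sd = 4)
  tab <- makeNullTable(15)
  tab$value[tab$t_s == 0] <- x
  nt <- normalizeToBaseline(tab, baselineMeans(tab))
  res <- perBreathTests(nt)
  row <- res[res$t_s == 0, ]
  bootMeans <- replicate(2000, mean(sample(
    nt$value_pct_baseline[nt$t_s == 0], 15, replace = TRUE)))
  bootHw <- diff(unname(quantile(bootMeans, c(0.025, 0.975)))) / 2
  tHw <- (row$ci95_hi - row$ci95_lo) / 2
  expect_equal(tHw, bootHw, tolerance = 0.25 * tHw)
})

test_that("fewer than two subjects is an error", {
  tab <- makeNullTable(1)
  nt <- normalizeToBaseline(tab, baselineMeans(tab))
  expect_error(perBreathTests(nt), "2 subjects")
})
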