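## Cohort statistics: baseline averaging, %-of-baseline normalization,
## per-breath mixed-effects comparison to baseline with Bonferroni
## correction, and the first significant breath per variable.

#' Per-subject per-variable baseline means
#'
#' Arithmetic mean of each variable over the unflagged baseline breaths
#' (those with `t_s` in the baseline window).  Subjects with too few
#' baseline breaths are dropped for that variable (with a message).
#'
#' @param table long-format breath table with columns `subject`,
#'   `variable`, `breath_ordinal`, `t_s`, `value`.
#' @param window baseline window in s (default `[-60, 0)`).
#' @param minBreaths minimum baseline breaths required per subject.
#' @return data.frame `subject`, `variable`, `baseline`.
#' @export
baselineMeans <- function(table, window = c(-60, 0), minBreaths = 3) {
  base <- table[table$t_s >= window[1] & table$t_s < window[2], ]
  agg <- aggregate(value ~ subject + variable, base,
                   function(v) c(mean(v), length(v)))
  out <- data.frame(subject = agg$subject, variable = agg$variable,
                    baseline = agg$value[, 1], n = agg$value[, 2])
  few <- out$n < minBreaths
  if (any(few))
    message("dropping ", sum(few), " subject x variable combinations with ",
            "fewer than ", minBreaths, " baseline breaths")
  out <- out[!few, c("subject", "variable", "baseline")]
  rownames(out) <- NULL
  out
}

#' Express values as a percentage of the subject baseline
#'
#' @param table long-format breath table (see [baselineMeans()]).
#' @param baselines data.frame from [baselineMeans()].
#' @return `table` with a `value_pct_baseline` column added; records
#'   with a zero or missing baseline get `NA` (with a message).
#' @export
normalizeToBaseline <- function(table, baselines) {
  m <- merge(table, baselines, by = c("subject", "variable"), all.x = TRUE)
  bad <- is.na(m$baseline) | m$baseline == 0
  if (any(bad))
    message(sum(bad), " records have no usable baseline; set to NA")
  m$value_pct_baseline <- ifelse(bad, NA_real_, 100 * m$value / m$baseline)
  m
}

## one-sample t fallback (paired against the per-subject baseline of 100)
.tTestLevel <- function(x) {
  if (length(x) < 2 || sd(x) == 0)
    return(c(p = if (all(x == 100)) 1 else NA_real_))
  c(p = t.test(x, mu = 100)$p.value)
}

#' Per-breath mixed-effects comparison to baseline
#'
#' For each variable, fits one linear mixed-effects model (REML) on the
#' %-of-baseline values with subject as random intercept and breath time
#' as a categorical fixed effect (all baseline breaths pooled as the
#' reference level, plus one level per post-start breath in the test
#' window).  Each post-start level is tested against baseline (Wald
#' contrast, Satterthwaite degrees of freedom) and Bonferroni-corrected
#' by the number of comparisons `m` -- the actual count of post-start
#' breaths in the window.  If the model cannot be fit, the procedure
#' falls back to per-breath one-sample t-tests against 100% with a
#' warning.
#'
#' @param table normalized table from [normalizeToBaseline()].
#' @param alpha familywise significance level (default 0.05).
#' @param window test window in s (default `[0, 120]`).
#' @param baselineWindow baseline window in s (default `[-60, 0)`).
#' @return data.frame with one row per variable x post-start breath:
#'   `variable`, `t_s`, `breath_ordinal`, `n_subjects`, `mean_pct`,
#'   `ci95_lo`, `ci95_hi`, `p_raw`, `p_adj`, `significant`, `m`.
#' @export
perBreathTests <- function(table, alpha = 0.05, window = c(0, 120),
                           baselineWindow = c(-60, 0)) {
  stopifnot(!is.null(table$value_pct_baseline))
  out <- list()
  for (v in unique(table$variable)) {
    tv <- table[table$variable == v & !is.na(table$value_pct_baseline), ]
    isBase <- tv$t_s >= baselineWindow[1] & tv$t_s < baselineWindow[2]
    isPost <- tv$t_s >= window[1] & tv$t_s <= window[2]
    tv <- tv[isBase | isPost, ]
    if (length(unique(tv$subject)) < 2)
      stop("per-breath tests need at least 2 subjects")
    postT <- sort(unique(tv$t_s[tv$t_s >= window[1] & tv$t_s <= window[2]]))
    m <- length(postT)
    tv$level <- factor(ifelse(tv$t_s < window[1], "baseline",
                              sprintf("t%07.1f", tv$t_s)),
                       levels = c("baseline", sprintf("t%07.1f", postT)))
    pRaw <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(value_pct_baseline ~ level + (1 | subject),
                       data = tv, REML = TRUE)))
      cf <- coef(summary(fit))
      setNames(cf[-1, "Pr(>|t|)"], rownames(cf)[-1])
    }, error = function(err) {
      warning("mixed model failed for '", v, "' (", conditionMessage(err),
              "); falling back to per-breath t-tests", call. = FALSE)
      vals <- setNames(vapply(postT, function(tt) {
        .tTestLevel(tv$value_pct_baseline[tv$t_s == tt])
      }, numeric(1)), paste0("level", sprintf("t%07.1f", postT)))
      vals
    })
    rows <- lapply(postT, function(tt) {
      x <- tv$value_pct_baseline[tv$t_s == tt]
      n <- length(x)
      ci <- if (n > 1 && sd(x) > 0)
        mean(x) + c(-1, 1) * qt(0.975, n - 1) * sd(x) / sqrt(n)
      else rep(mean(x), 2)
      p <- unname(pRaw[paste0("level", sprintf("t%07.1f", tt))])
      if (length(p) == 0) p <- NA_real_
      pAdj <- min(1, m * p)
      data.frame(variable = v, t_s = tt,
                 breath_ordinal = tv$breath_ordinal[tv$t_s == tt][1],
                 n_subjects = n, mean_pct = mean(x),
                 ci95_lo = ci[1], ci95_hi = ci[2], p_raw = p,
                 p_adj = pAdj,
                 significant = !is.na(pAdj) && pAdj < alpha, m = m)
    })
    out[[v]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' First significant change per variable
#'
#' The earliest post-start breath at which the Bonferroni-adjusted
#' comparison to baseline is significant, with the direction of change.
#'
#' @param results data.frame from [perBreathTests()].
#' @param requirePersistence if `TRUE`, significance must hold for two
#'   consecutive breaths (sensitivity rule); the first breath of the
#'   pair is reported.
#' @return data.frame `variable`, `first_t_s`, `first_breath_ordinal`,
#'   `direction` (`"increase"`/`"decrease"`); `NA`s when a variable
#'   never reaches significance.
#' @export
firstChange <- function(results, requirePersistence = FALSE) {
  out <- lapply(split(results, results$variable), function(rv) {
    rv <- rv[order(rv$t_s), ]
    sig <- rv$significant & !is.na(rv$significant)
    if (requirePersistence)
      sig <- sig & c(sig[-1], FALSE)
    i <- which(sig)[1]
    if (is.na(i))
      data.frame(variable = rv$variable[1], first_t_s = NA_real_,
                 first_breath_ordinal = NA_integer_,
                 direction = NA_character_)
    else
      data.frame(variable = rv$variable[1], first_t_s = rv$t_s[i],
                 first_breath_ordinal = rv$breath_ordinal[i],
                 direction = if (rv$mean_pct[i] >= 100) "increase"
                             else "decrease")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-breath mean \[95% CI\] summary table
#'
#' One row per breath time, one column per variable, each cell
#' `"mean [lo-hi]"` with significant changes starred.
#'
#' @param results data.frame from [perBreathTests()].
#' @param digits significant digits in the cells.
#' @return data.frame with a `t_s` column and one character column per
#'   variable.
#' @export
summaryTable <- function(results, digits = 3) {
  vars <- unique(results$variable)
  ts <- sort(unique(results$t_s))
  out <- data.frame(t_s = ts)
  for (v in vars) {
    rv <- results[results$variable == v, ]
    rv <- rv[match(ts, rv$t_s), ]
    out[[v]] <- sprintf("%s [%s-%s]%s",
                        signif(rv$mean_pct, digits),
                        signif(rv$ci95_lo, digits),
                        signif(rv$ci95_hi, digits),
                        ifelse(!is.na(rv$significant) & rv$significant,
                               "*", ""))
  }
  out
}
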