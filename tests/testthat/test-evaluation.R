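# Validation statistics: rate ratios, AUROC, proportion tests, event
# yield, Poisson rate comparison, and distribution summaries.

test_that("rate_ratio reproduces the closed form and flags degenerate input", {
  est <- rate_ratio(10, 100, 1, 100)
  expect_equal(est$rr, 10)
  expect_equal(est$log_rr, log(10))
  se <- sqrt(1 / 10 + 1 / 1)
  expect_equal(est$ci_low, exp(log(10) - 1.96 * se), tolerance = 1e-4)
  expect_equal(est$ci_high, exp(log(10) + 1.96 * se), tolerance = 1e-4)

  eq <- rate_ratio(5, 100, 5, 100)
  expect_equal(eq$rr, 1)
  expect_true(eq$ci_low < 1 && eq$ci_high > 1)

  z <- rate_ratio(0, 100, 5, 100)
  expect_equal(z$rr, 0)
  expect_true(z$one_sided)
  expect_error(rate_ratio(5, 100, 0, 100), "reference events")
})

test_that("day-level AUROC equals the rank statistic with Hanley-McNeil CI", {
  expect_equal(day_level_auroc(rep(1, 50), rep(c(TRUE, FALSE), 25))$auc, 0.5)
  lab <- c(rep(TRUE, 20), rep(FALSE, 80))
  expect_equal(day_level_auroc(as.numeric(lab), lab)$auc, 1.0)

  # binary marker with sensitivity 0.4, specificity 0.9: AUROC 0.65
  labels <- c(rep(TRUE, 100), rep(FALSE, 100))
  scores <- c(rep(1, 40), rep(0, 60), rep(1, 10), rep(0, 90))
  expect_equal(day_level_auroc(scores, labels)$auc, 0.65)

  # cross-check estimate and rough CI behaviour against pROC
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- rnorm(400); lb <- runif(400) < plogis(sc)
  ours <- day_level_auroc(sc, lb)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE)))
  expect_equal(ours$auc, ref, tolerance = 1e-12)
  expect_error(day_level_auroc(sc, rep(TRUE, 400)), "both classes")
})

test_that("two-proportion test matches the pooled-z formula and prop.test", {
  # identical proportions: p = 1
  expect_equal(two_proportion_test(5, 50, 10, 100)$p_value, 1)
  expect_equal(two_proportion_test(0, 10, 0, 10)$p_value, 1)

  out <- two_proportion_test(50, 100, 10, 100)
  pp <- 60 / 200
  z_ref <- (0.5 - 0.1) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(out$z, z_ref)
  ref <- prop.test(c(50, 10), c(100, 100), correct = FALSE)
  expect_equal(out$z^2, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
})

test_that("Poisson rate comparison recovers the closed-form contrast", {
  out <- poisson_rate_comparison(c("duration", "quantity"),
                                 events = c(20, 10), days = c(1000, 1000))
  expect_equal(unname(out$coefficients["duration"]), log(20 / 1000))
  expect_equal(unname(out$pairwise$diff), log(2))
  expect_equal(unname(out$pairwise$z), log(2) / sqrt(1 / 20 + 1 / 10))
  expect_true(out$converged)

  eqc <- poisson_rate_comparison(c("a", "b"), c(15, 15), c(500, 500))
  expect_equal(unname(eqc$pairwise$diff), 0)
  expect_equal(unname(eqc$pairwise$p_value), 1)

  # type-I error of the equality test stays near its nominal level
  set.seed(77)
  rej <- mean(replicate(200, {
    ev <- rpois(2, 30)
    if (any(ev == 0)) return(FALSE)
    poisson_rate_comparison(c("a", "b"), ev, c(1e4, 1e4))$pairwise$p_value <
      0.05
  }))
  expect_lt(rej, 0.12)
})

test_that("printed-ratio helpers do their arithmetic", {
  expect_equal(yield_increase_pct(137, 644), 100 * 137 / 644)
  expect_equal(exclusivity_pct(5114, 10017), 100 * 5114 / 10017)
  expect_equal(relative_change_pct(0.55, 0.66), 20, tolerance = 1e-9)
  expect_equal(days_per_year(0.159), 58.035)
  expect_error(yield_increase_pct(1, 0), "clinical_events")
})

# A handcrafted cohort whose day table is fully known: one event patient
# whose pre-event window meets chosen criteria, one censored patient.
toy_day_table <- function() {
  b1 <- c(numeric(21), rep(100, 19))   # high burden from day 22
  b2 <- numeric(45)
  co <- make_cohort(list(b1, b2), cvh = c(41L, NA))
  risk_day_table(co, config = trend_config())
}

test_that("risk day table wires events, labels and flags together", {
  dt <- toy_day_table()
  expect_equal(sum(dt$event), 1)
  expect_equal(dt$day_offset[dt$event], 40)        # terminal record day
  expect_equal(sum(dt$label), 5)                   # days 36..40
  expect_setequal(dt$day_offset[dt$label], 36:40)
  expect_true(all(dt$quantity_met[dt$patient_id == "T001"]))
  expect_true(all(!dt$quantity_met[dt$patient_id == "T002"]))
})

test_that("incidence rate attributes events through the pre-event window", {
  dt <- toy_day_table()
  ir <- incidence_rate(dt, "quantity_met")
  expect_equal(ir$events, 1)
  expect_equal(ir$days, sum(dt$quantity_met))
  expect_equal(ir$rate, 1 / sum(dt$quantity_met))
  expect_error(incidence_rate(dt, "trend_d"), "zero days")
  dt0 <- dt; dt0$label[] <- FALSE
  expect_equal(incidence_rate(dt0, "quantity_met")$events, 0)
})

test_that("venn event yield partitions captured events", {
  dt <- toy_day_table()
  y <- venn_event_yield(dt)
  expect_equal(sum(y$regions), 1)  # the one event, in one region
  expect_equal(y$captured_events, 1)
  # the event meets duration+quantity but not trend D
  expect_equal(unname(y$regions[["duration+quantity"]]), 1)
  expect_equal(y$trend_exclusive_events, 0)
  expect_equal(y$pct_increase, 0)

  # simulated cohort: regions always partition the captured events
  sim <- small_sim()
  filled <- forward_fill(apply_inclusion(sim$cohort, 365)$cohort)
  dts <- risk_day_table(filled)
  ys <- venn_event_yield(dts)
  expect_equal(sum(ys$regions[setdiff(names(ys$regions), "none")]),
               ys$captured_events)
  expect_lte(ys$trend_exclusive_days, ys$trend_days)
})

test_that("time-in-AF distribution matches a brute-force quantile oracle", {
  sim <- small_sim()
  filled <- forward_fill(apply_inclusion(sim$cohort, 365)$cohort)
  dt <- risk_day_table(filled)
  taf <- time_in_af_distribution(dt, classify_af_phenotype(filled))
  hours <- dt$af_burden_min[dt$quantity_met] / 60
  expect_equal(taf$median[taf$criterion == "quantity"],
               unname(quantile(hours, 0.5)))
  expect_equal(taf$q75[taf$criterion == "quantity"],
               unname(quantile(hours, 0.75)))
  # saturated days: degenerate quartiles
  co <- make_cohort(list(rep(1440, 40)))
  dts <- risk_day_table(co)
  t2 <- time_in_af_distribution(dts)
  expect_equal(t2$median[t2$criterion == "quantity"], 24)
  expect_equal(t2$q25[t2$criterion == "quantity"], 24)
})

test_that("state rate ratios recover planted multipliers on a simulated cohort", {
  cfg <- simulation_config(n_patients = 800, seed = 420,
                           state_multipliers = c(A = 1, B = 3, C = 6, D = 12))
  sim <- simulate_cohort(cfg)
  filled <- forward_fill(apply_inclusion(sim$cohort)$cohort)
  dt <- risk_day_table(filled)
  est <- estimate_state_rate_ratios(dt)
  expect_equal(est$state, c("A", "B", "C", "D"))
  expect_equal(est$rr[1], 1)
  # generating values inside the 95% CIs, and the ordering is monotone
  expect_true(est$ci_low[2] < 3 && 3 < est$ci_high[2])
  expect_true(est$ci_low[3] < 6 && 6 < est$ci_high[3])
  expect_true(est$ci_low[4] < 12 && 12 < est$ci_high[4])
  expect_true(all(diff(est$rr) > 0))
})

test_that("holdout report is coherent and degenerates gracefully", {
  sim <- small_sim()
  filled <- forward_fill(apply_inclusion(sim$cohort, 365)$cohort)
  rep <- evaluate_holdout(filled)
  expect_s3_class(rep, "holdout_report")
  expect_false(rep$degenerate)
  expect_equal(rep$n_events, sum(!is.na(filled$patients$cvh_day)))
  # report totals cross-check the follow-up summary
  expect_equal(rep$follow_up$patient_days, nrow(filled$records))
  expect_equal(rep$follow_up$n_events, rep$n_events)
  expect_true(!is.null(rep$aurocs))
  expect_true(rep$aurocs$clinical$auc >= 0 && rep$aurocs$clinical$auc <= 1)

  # no events: everything flagged degenerate
  co <- make_cohort(list(c(numeric(21), rep(30, 30))))
  r0 <- evaluate_holdout(co)
  expect_true(r0$degenerate)
  expect_null(r0$state_rate_ratios)
})

test_that("adding the trend criterion raises day-level AUROC under planted D hazard", {
  hits <- 0L
  for (s in 1:8) {
    cfg <- simulation_config(n_patients = 250, max_follow_up_days = 365,
                             seed = 5000 + s,
                             state_multipliers = c(A = 1, B = 1, C = 1,
                                                   D = 10))
    sim <- simulate_cohort(cfg)
    filled <- forward_fill(apply_inclusion(sim$cohort, 365)$cohort)
    dt <- risk_day_table(filled)
    if (!any(dt$label) || all(dt$label)) next
    a2 <- day_level_auroc(dt$duration_met + dt$quantity_met, dt$label)
    a3 <- day_level_auroc(dt$duration_met + dt$quantity_met + dt$trend_d,
                          dt$label)
    hits <- hits + (a3$auc > a2$auc)
  }
  expect_gte(hits, 7)
})
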