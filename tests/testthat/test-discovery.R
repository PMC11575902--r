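# Rule mining: labels, patient splits, feature construction, tree path
# extraction, scoring, and comparator matching.

test_that("pre-event labeling marks exactly the preceding horizon days", {
  co <- make_cohort(list(rep(10, 99), rep(10, 50)), cvh = c(100L, NA))
  lab <- label_risk_days(co)
  pos <- lab[lab$label, ]
  expect_equal(pos$day_offset, 95:99)
  expect_true(all(pos$patient_id == "T001"))
  # censored patient contributes no positives
  expect_equal(sum(lab$label[lab$patient_id == "T002"]), 0)
  # an event just after index: only the existing days are positive
  co2 <- make_cohort(list(rep(10, 23)), cvh = 24L)
  expect_equal(sum(label_risk_days(co2)$label), 5)
  co3 <- make_cohort(list(rep(10, 2)), cvh = 3L)
  expect_equal(sum(label_risk_days(co3)$label), 2)
  expect_error(label_risk_days(co, horizon = 0), "horizon")
})

test_that("patient split is disjoint, sized, and reproducible", {
  co <- make_cohort(rep(list(rep(5, 30)), 10))
  sp <- split_patients(co, 0.7, seed = 3)
  expect_equal(n_patients(sp$train), 7)
  expect_equal(n_patients(sp$holdout), 3)
  expect_length(intersect(sp$train$patients$patient_id,
                          sp$holdout$patients$patient_id), 0)
  sp2 <- split_patients(co, 0.7, seed = 3)
  expect_identical(sp$train$patients$patient_id,
                   sp2$train$patients$patient_id)
  expect_warning(split_patients(co, 1, seed = 1), "empty holdout")
  # no patient-day leakage
  expect_length(intersect(unique(sp$train$records$patient_id),
                          unique(sp$holdout$records$patient_id)), 0)
})

test_that("feature matrix carries 8 averages and 28 indicators per parameter", {
  sim <- small_sim()
  filled <- forward_fill(apply_inclusion(sim$cohort, 365)$cohort)
  f <- build_feature_matrix(filled, parameters = c("burden", "activity"))
  burden_cols <- grep("^burden_", names(f), value = TRUE)
  expect_length(burden_cols, 8 + choose(8, 2))
  expect_length(grep("^burden_.*_ge_", names(f)), 28)
  expect_true(all(f$day_offset >= index_day()))
  # indicator semantics: sma21 >= cma matches the direct comparison
  expect_identical(f$burden_sma21_ge_cma,
                   as.integer(f$burden_sma21 >= f$burden_cma))
  # sma1 is the raw daily value
  rec <- filled$records
  key <- paste(rec$patient_id, rec$day_offset)
  expect_equal(f$burden_sma1,
               rec$af_burden_min[match(paste(f$patient_id, f$day_offset),
                                       key)])
})

test_that("trees find a separating column and rules match path enumeration", {
  # perfectly separable toy data spread over many 'patients'
  set.seed(10)
  n <- 600
  feats <- data.frame(patient_id = rep(sprintf("Q%02d", 1:20), each = 30),
                      day_offset = rep(22:51, 20),
                      x_noise = runif(n), x_split = runif(n))
  labels <- feats$x_split >= 0.5
  forest <- train_bootstrap_forest(feats, labels, n_replicates = 5,
                                   seed = 2, min_leaf = 10)
  rules <- extract_rules(forest)
  expect_true(all(vapply(rules$conditions, function(cc)
    any(cc$var == "x_split" & cc$op == ">="), logical(1))))
  top <- rules$conditions[[1]]
  expect_equal(top$var, "x_split")
  expect_equal(top$threshold, 0.5, tolerance = 0.02)
  expect_equal(rules$selection_frequency[1], 1)

  # depth-2 tree: extracted rules equal manual enumeration via path.rpart
  set.seed(11)
  f2 <- data.frame(patient_id = rep(sprintf("Q%02d", 1:20), each = 30),
                   day_offset = rep(22:51, 20),
                   a = runif(n), b = runif(n))
  lab2 <- (f2$a >= 0.6 & f2$b >= 0.3) | (f2$a < 0.6 & runif(n) < 0.05)
  forest2 <- train_bootstrap_forest(f2, lab2, n_replicates = 1, seed = 4,
                                    max_depth = 2, min_leaf = 20,
                                    train_fraction = 1)
  tree <- forest2$trees[[1]]
  rules2 <- extract_rules(forest2)
  frame <- tree$frame
  pos_leaves <- as.integer(rownames(frame))[frame$var == "<leaf>" &
                                              frame$yval == 2]
  manual <- rpart::path.rpart(tree, pos_leaves, print.it = FALSE)
  expect_equal(nrow(rules2), length(pos_leaves))
  for (i in seq_along(manual)) {
    clauses <- setdiff(trimws(manual[[i]]), "root")
    for (cl in clauses) {
      var <- sub("[<>=].*$", "", cl)
      thr <- as.numeric(sub("^[^<>=]*[<>=]+", "", cl))
      op <- if (grepl(">=", cl)) ">=" else "<"
      hit <- vapply(rules2$conditions, function(cc)
        any(cc$var == var & cc$op == op &
              abs(cc$threshold - thr) < 1e-3 * (abs(thr) + 1)),
        logical(1))
      expect_true(any(hit))
    }
  }

  # duplicated trees double the frequency, not the rule count
  twice <- extract_rules(list(tree, tree))
  once <- extract_rules(list(tree))
  expect_equal(nrow(twice), nrow(once))
  expect_equal(twice$n_trees_selected, 2L * once$n_trees_selected)

  # extraction is exhaustive: leaf-day totals match the tree's positive leaves
  expect_equal(sum(once$leaf_days), sum(frame$n[frame$var == "<leaf>" &
                                                  frame$yval == 2]))
  # degenerate labels are refused
  expect_error(train_bootstrap_forest(f2, rep(TRUE, n), 1, 1),
               "positive and negative")
})

test_that("rule scoring computes log RR against trend-A days", {
  # synthetic day table with known counts: rule days 100 with 10 events,
  # A days 100 with 1 event
  dt <- data.frame(
    patient_id = rep(sprintf("R%03d", 1:20), each = 10),
    day_offset = rep(22:31, 20),
    trend_state = factor(rep(c("A", "C"), each = 100),
                         levels = c("A", "B", "C", "D")),
    duration_met = FALSE, quantity_met = FALSE)
  dt$trend_d <- FALSE
  dt$event <- FALSE
  dt$event[dt$trend_state == "A"][1] <- TRUE
  dt$event[dt$trend_state == "C"][1:10] <- TRUE
  dt$label <- dt$event
  feats <- data.frame(patient_id = dt$patient_id,
                      day_offset = dt$day_offset,
                      marker = as.integer(dt$trend_state == "C"))
  rules <- structure(data.frame(rule_id = 1L, key = "marker>=0.5",
                                selection_frequency = 1,
                                n_trees_selected = 1L, leaf_days = 100),
                     class = c("rule_set", "data.frame"))
  rules$conditions <- I(list(data.frame(var = "marker", op = ">=",
                                        threshold = 0.5)))
  scored <- score_rules(rules, feats, dt)
  expect_equal(scored$log_rr, log(10))
  expect_equal(scored$rule_days, 100)
  expect_equal(scored$day_pct, 0.5)
  expect_equal(scored$patient_pct, 0.5)

  # a rule matching no days is dropped
  rules$conditions <- I(list(data.frame(var = "marker", op = ">=",
                                        threshold = 2)))
  expect_equal(nrow(score_rules(rules, feats, dt)), 0)
})

test_that("comparator matching enforces strict floors in frequency order", {
  mk_rules <- function(freq, lrr, dpct, ppct) {
    r <- data.frame(rule_id = seq_along(freq), key = sprintf("r%d",
                                                             seq_along(freq)),
                    selection_frequency = freq, n_trees_selected = 1L,
                    leaf_days = 10, log_rr = lrr, rr = exp(lrr),
                    day_pct = dpct, patient_pct = ppct)
    r$conditions <- I(rep(list(data.frame(var = "x", op = ">=",
                                          threshold = 1)), nrow(r)))
    structure(r, class = c("rule_set", "data.frame"))
  }
  comps <- data.frame(days = c(100, 100), events = c(5, 6),
                      log_rr = c(0.386, 0.369),
                      patient_pct = c(0.076, 0.129),
                      day_pct = c(0.076, 0.129),
                      row.names = c("duration", "quantity"))

  # the top-frequency rule ties the floor on prevalence: strict inequality
  # fails, the next rule qualifies
  rules <- mk_rules(freq = c(0.9, 0.5),
                    lrr = c(0.50, 0.40),
                    dpct = c(0.129, 0.20), ppct = c(0.129, 0.20))
  got <- match_to_comparators(rules, comps)
  expect_equal(got$rule_id, 2L)

  # single qualifying rule is returned
  rules1 <- mk_rules(0.3, 0.4, 0.2, 0.2)
  expect_equal(nrow(match_to_comparators(rules1, comps)), 1)

  # no rule qualifies: explicit empty result
  none <- mk_rules(c(0.9, 0.8), c(0.1, 0.5), c(0.05, 0.129), c(0.05, 0.129))
  expect_message(out <- match_to_comparators(none, comps), "no rule")
  expect_equal(nrow(out), 0)

  # patient-share matching is available
  rules_p <- mk_rules(0.9, 0.5, 0.05, 0.2)
  expect_equal(nrow(match_to_comparators(rules_p, comps,
                                         prevalence = "patients")), 1)
  expect_equal(nrow(match_to_comparators(rules_p, comps)), 0)
})

test_that("a planted D-state hazard is rediscovered as a burden-trend rule", {
  cfg <- simulation_config(n_patients = 600, max_follow_up_days = 365,
                           seed = 990427,
                           state_multipliers = c(A = 1, B = 1, C = 1,
                                                 D = 10))
  sim <- simulate_cohort(cfg)
  filled <- forward_fill(apply_inclusion(sim$cohort, 365)$cohort)
  parts <- split_patients(filled, 0.7, seed = 990428)
  feats <- build_feature_matrix(parts$train,
                                parameters = c("burden", "activity"))
  lab <- label_risk_days(parts$train)
  lab <- lab$label[match(paste(feats$patient_id, feats$day_offset),
                         paste(lab$patient_id, lab$day_offset))]
  forest <- train_bootstrap_forest(feats, lab, n_replicates = 12,
                                   seed = 990429, max_depth = 4)
  dt <- risk_day_table(parts$train)
  dt <- dt[match(paste(feats$patient_id, feats$day_offset),
                 paste(dt$patient_id, dt$day_offset)), ]
  rules <- score_rules(extract_rules(forest), feats, dt)
  matched <- match_to_comparators(rules, comparator_stats(dt))
  expect_equal(nrow(matched), 1)
  conds <- matched$conditions[[1]]
  expect_true(any(conds$var == "burden_sma21_ge_cma" & conds$op == ">="))
  # freezing the rule yields a usable trend configuration
  frozen <- rule_to_trend_config(matched)
  expect_s3_class(frozen, "trend_config")
})
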