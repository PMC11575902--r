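# Day-level risk-rule mining: pre-event labeling, patient-level splitting,
# moving-average features with pairwise trend indicators, a bootstrap tree
# ensemble, rule extraction, scoring, and matching against the clinical
# comparator thresholds.

.PARAM_SHORT <- c(burden = "af_burden_min", activity = "activity_min",
                  vrate_day = "vrate_day_bpm", vrate_night = "vrate_night_bpm",
                  hrv = "hrv_sd_ms")

#' Label the days preceding a hospitalization
#'
#' Marks the `horizon` days immediately preceding each patient's CVH (those
#' that exist in the records) as positive; all other days, and all days of
#' censored patients, are negative.
#'
#' @param cohort A post-inclusion [icm_cohort()].
#' @param horizon Days before the event to label positive (default 5).
#' @return Data frame `patient_id`, `day_offset`, `label` (logical), one
#'   row per record day.
#' @export
label_risk_days <- function(cohort, horizon = 5) {
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1)
    stop("'horizon' must be a single count >= 1", call. = FALSE)
  rec <- cohort$records[, c("patient_id", "day_offset")]
  cvh <- cohort$patients$cvh_day[match(rec$patient_id,
                                       cohort$patients$patient_id)]
  rec$label <- !is.na(cvh) & rec$day_offset >= cvh - horizon &
    rec$day_offset <= cvh - 1
  rec
}

#' Split a cohort at the patient level
#'
#' @param cohort An [icm_cohort()].
#' @param train_fraction Fraction of patients assigned to the training
#'   partition (default 0.7).
#' @param seed Integer seed making the split reproducible.
#' @return A list of two cohorts, `train` and `holdout`, with disjoint
#'   patient sets.
#' @export
split_patients <- function(cohort, train_fraction = 0.7, seed = 1L) {
  ids <- cohort$patients$patient_id
  if (length(ids) < 2) stop("need at least 2 patients to split", call. = FALSE)
  set.seed(seed)
  n_train <- round(train_fraction * length(ids))
  train_ids <- sample(ids, n_train)
  if (n_train == length(ids))
    warning("train_fraction leaves an empty holdout partition")
  list(train = .subset_cohort(cohort, train_ids),
       holdout = .subset_cohort(cohort, setdiff(ids, train_ids)))
}

#' Moving-average feature matrix for rule mining
#'
#' For each diagnostic parameter, the feature row of a day carries the CMA,
#' the SMA over every configured window, and all pairwise trend indicators:
#' for each pair of averages the binary flag "shorter window at or above the
#' longer one" (the CMA acting as the longest window), i.e. choose(8, 2) =
#' 28 indicators per parameter for the default 7 windows. Rows cover days
#' at or after the index day, where every window is defined.
#'
#' @param cohort A forward-filled [icm_cohort()].
#' @param config A [trend_config()].
#' @param parameters Which diagnostic parameters to include (default all
#'   five).
#' @return Data frame with `patient_id`, `day_offset`, and the feature
#'   columns.
#' @export
build_feature_matrix <- function(cohort, config = trend_config(),
                                 parameters = names(.PARAM_SHORT)) {
  parameters <- match.arg(parameters, names(.PARAM_SHORT), several.ok = TRUE)
  records <- .assert_contiguous(cohort$records)
  day <- records$day_offset
  wins <- config$sma_windows
  keep <- day >= max(.INDEX_DAY, max(wins))
  out <- records[keep, c("patient_id", "day_offset")]
  for (nm in parameters) {
    x <- records[[.PARAM_SHORT[[nm]]]]
    series <- c(lapply(wins, function(p) .sma_grouped(x, day, p)[keep]),
                list(.cma_grouped(x, day)[keep]))
    labels <- c(paste0("sma", wins), "cma")
    for (i in seq_along(series))
      out[[paste0(nm, "_", labels[i])]] <- series[[i]]
    for (i in seq_len(length(series) - 1))
      for (j in (i + 1):length(series))
        out[[paste0(nm, "_", labels[i], "_ge_", labels[j])]] <-
          as.integer(series[[i]] >= series[[j]])
  }
  rownames(out) <- NULL
  out
}

#' Train a bootstrapped ensemble of classification trees
#'
#' Each replicate draws a random 70% patient partition, fits a CART-style
#' tree (via `rpart`) classifying pre-event days from the feature columns,
#' and reserves the out-of-partition days for rule scoring. Positive days
#' are weighted inversely to their prevalence so the trees are not swamped
#' by the class imbalance.
#'
#' @param features Feature data frame from [build_feature_matrix()].
#' @param labels Logical vector, one per feature row (pre-event day or not).
#' @param n_replicates Number of bootstrap replicates (trees).
#' @param seed Integer seed.
#' @param train_fraction Fraction of patients in each learning partition.
#' @param max_depth Maximum tree depth.
#' @param min_leaf Minimum days per leaf.
#' @param cp `rpart` complexity parameter; splits that do not improve the
#'   fit by this factor are not made.
#' @param balance_weights Weight positives inversely to prevalence?
#' @param value_split_cost Split cost applied to raw moving-average value
#'   columns relative to the binary trend-indicator columns (whose cost is
#'   1). With a cost above 1 a split on an absolute level must improve the
#'   fit by that factor more than a within-patient relative comparison to
#'   be chosen: the method's premise is change-from-baseline risk, and
#'   rules built from relative comparisons transfer across patients whose
#'   absolute burden scales differ. The default of 2 keeps "almost
#'   crossed" absolute cuts from displacing the crossover conditions the
#'   rules are meant to surface; set to 1 to disable the preference.
#' @return An object of class `bootstrap_forest`: the fitted trees and the
#'   per-replicate partitions.
#' @export
train_bootstrap_forest <- function(features, labels, n_replicates = 200,
                                   seed = 1L, train_fraction = 0.7,
                                   max_depth = 4, min_leaf = 50, cp = 0.005,
                                   balance_weights = TRUE,
                                   value_split_cost = 2) {
  if (length(labels) != nrow(features))
    stop("'labels' must have one entry per feature row", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("training data must contain both positive and negative days",
         call. = FALSE)
  set.seed(seed)
  ids <- unique(features$patient_id)
  fcols <- setdiff(names(features), c("patient_id", "day_offset"))
  y <- factor(ifelse(labels, "risk", "no"), levels = c("no", "risk"))
  ctrl <- rpart::rpart.control(maxdepth = max_depth, minbucket = min_leaf,
                               cp = cp, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  split_costs <- ifelse(grepl("_ge_", fcols), 1, value_split_cost)
  trees <- vector("list", n_replicates)
  partitions <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    in_ids <- sample(ids, round(train_fraction * length(ids)))
    take <- features$patient_id %in% in_ids
    if (!any(labels[take]) || all(labels[take])) {
      trees[r] <- list(NULL)  # degenerate partition: skip, keep indexing
      partitions[[r]] <- list(learn = in_ids, test = setdiff(ids, in_ids))
      next
    }
    dat <- features[take, fcols, drop = FALSE]
    dat$.y <- y[take]
    w <- if (balance_weights) {
      np <- sum(labels[take]); nn <- sum(!labels[take])
      ifelse(labels[take], nn / np, 1)
    } else rep(1, sum(take))
    trees[[r]] <- rpart::rpart(.y ~ ., data = dat, weights = w,
                               method = "class", control = ctrl,
                               cost = split_costs)
    partitions[[r]] <- list(learn = in_ids, test = setdiff(ids, in_ids))
  }
  structure(list(trees = trees, partitions = partitions,
                 n_replicates = n_replicates, feature_cols = fcols),
            class = "bootstrap_forest")
}

#' @export
print.bootstrap_forest <- function(x, ...) {
  fitted <- sum(!vapply(x$trees, is.null, logical(1)))
  cat(sprintf("Bootstrap tree ensemble: %d replicates (%d fitted)\n",
              x$n_replicates, fitted))
  invisible(x)
}

# Root-to-leaf conditions of an rpart tree. Returns a list, one element per
# leaf: list(node, positive, n, conditions = data.frame(var, op, threshold)).
# Requires trees fitted with maxcompete = 0 and maxsurrogate = 0 so the
# splits matrix holds exactly one row per internal node, in frame order.
.tree_paths <- function(tree) {
  frame <- tree$frame
  nodes <- as.integer(rownames(frame))
  internal <- frame$var != "<leaf>"
  split_row <- integer(nrow(frame))
  split_row[internal] <- seq_len(sum(internal))
  leaf_idx <- which(!internal)
  lapply(leaf_idx, function(li) {
    conds <- list()
    node <- nodes[li]
    while (node > 1) {
      parent <- node %/% 2L
      pi <- match(parent, nodes)
      s <- tree$splits[split_row[pi], , drop = FALSE]
      thr <- unname(s[1, "index"])
      left <- node %% 2L == 0L
      # ncat == -1: left child takes x < threshold; +1: left takes x >= thr
      lt_goes_left <- s[1, "ncat"] == -1
      op <- if (left == lt_goes_left) "<" else ">="
      conds[[length(conds) + 1L]] <-
        data.frame(var = as.character(frame$var[pi]), op = op,
                   threshold = thr, stringsAsFactors = FALSE)
      node <- parent
    }
    list(node = nodes[li], positive = frame$yval[li] == 2L,
         n = frame$n[li],
         conditions = if (length(conds)) do.call(rbind, rev(conds)) else
           data.frame(var = character(0), op = character(0),
                      threshold = numeric(0)))
  })
}

# Canonicalize a conjunction: per variable keep the tightest lower (>=) and
# upper (<) bound, sorted by variable and direction.
.canonical_conditions <- function(conds) {
  if (nrow(conds) == 0) return(conds)
  lower <- tapply(conds$threshold[conds$op == ">="],
                  conds$var[conds$op == ">="], max)
  upper <- tapply(conds$threshold[conds$op == "<"],
                  conds$var[conds$op == "<"], min)
  out <- rbind(
    if (length(lower)) data.frame(var = names(lower), op = ">=",
                                  threshold = unname(lower)),
    if (length(upper)) data.frame(var = names(upper), op = "<",
                                  threshold = unname(upper)))
  out[order(out$var, out$op), , drop = FALSE]
}

# Structural identity of a rule: which columns it bounds and in which
# direction. Split thresholds drift across bootstrap replicates, so
# frequency counting keys on the structure; thresholds of merged instances
# are aggregated by their median.
.rule_structure <- function(conds) {
  paste(paste0(conds$var, conds$op), collapse = " & ")
}

.rule_key <- function(conds) {
  paste(sprintf("%s%s%g", conds$var, conds$op, signif(conds$threshold, 3)),
        collapse = " & ")
}

#' Extract candidate rules from a tree ensemble
#'
#' Every root-to-leaf path ending in a positive-majority leaf becomes a
#' conjunction of threshold conditions, canonicalized to the tightest
#' per-variable bounds. Conjunctions with the same structure -- the same
#' bounded columns and directions -- are merged across trees, accumulating
#' their selection frequency; the merged rule's thresholds are the medians
#' over its instances (split points drift between bootstrap replicates, so
#' frequency is counted on the structure, not the raw cut points).
#'
#' @param forest A [train_bootstrap_forest()] result, or a list of `rpart`
#'   trees.
#' @return An object of class `rule_set`: a data frame with `rule_id`,
#'   `key` (the conjunction with median thresholds), `selection_frequency`,
#'   `n_trees_selected`, `leaf_days`, and a list-column `conditions` of
#'   per-rule condition tables.
#' @export
extract_rules <- function(forest) {
  trees <- if (inherits(forest, "bootstrap_forest")) forest$trees else forest
  n_rep <- length(trees)
  acc <- new.env(parent = emptyenv())
  for (tree in trees) {
    if (is.null(tree)) next
    for (path in .tree_paths(tree)) {
      if (!path$positive) next
      conds <- .canonical_conditions(path$conditions)
      key <- .rule_structure(conds)
      if (is.null(acc[[key]]))
        assign(key, list(conditions = conds, count = 1L, days = path$n,
                         thresholds = list(conds$threshold)), envir = acc)
      else {
        cur <- acc[[key]]
        cur$count <- cur$count + 1L
        cur$days <- cur$days + path$n
        cur$thresholds <- c(cur$thresholds, list(conds$threshold))
        assign(key, cur, envir = acc)
      }
    }
  }
  keys <- ls(acc)
  counts <- vapply(keys, function(k) acc[[k]]$count, integer(1))
  ord <- order(counts, decreasing = TRUE)
  conditions <- lapply(keys[ord], function(k) {
    cur <- acc[[k]]
    conds <- cur$conditions
    conds$threshold <- apply(do.call(rbind, cur$thresholds), 2,
                             stats::median)
    conds
  })
  out <- data.frame(
    rule_id = seq_along(keys),
    key = vapply(conditions, .rule_key, character(1)),
    selection_frequency = unname(counts[ord]) / n_rep,
    n_trees_selected = unname(counts[ord]),
    leaf_days = vapply(keys[ord], function(k) acc[[k]]$days, numeric(1)),
    stringsAsFactors = FALSE)
  out$conditions <- I(conditions)
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"))
}

#' Evaluate a rule's conjunction on a feature table
#'
#' @param conditions A condition table (`var`, `op`, `threshold`) as stored
#'   in a `rule_set`.
#' @param features Feature data frame.
#' @return Logical vector: rows satisfying every condition.
#' @export
apply_rule <- function(conditions, features) {
  hit <- rep(TRUE, nrow(features))
  for (i in seq_len(nrow(conditions))) {
    x <- features[[conditions$var[i]]]
    if (is.null(x))
      stop("feature column not found: ", conditions$var[i], call. = FALSE)
    hit <- hit & if (conditions$op[i] == ">=") x >= conditions$threshold[i]
    else x < conditions$threshold[i]
  }
  hit
}

#' Score rules by incidence-rate ratio and prevalence
#'
#' Computes, for every rule, the natural-log incidence-rate ratio of CVH on
#' rule days versus trend-A reference days, the fraction of patients ever
#' satisfying the rule, and the fraction of days selected. Events are
#' attributed to their terminal record day (follow-up ends the day before
#' the event). Rules matching no days are dropped.
#'
#' @param rules A `rule_set` from [extract_rules()].
#' @param features Feature table aligned with `day_table` rows.
#' @param day_table A [risk_day_table()] for the same patient-days.
#' @return The `rule_set` with columns `rule_days`, `rule_events`, `log_rr`,
#'   `rr`, `patient_pct`, `day_pct` added (rules with zero days removed).
#' @export
score_rules <- function(rules, features, day_table) {
  if (nrow(features) != nrow(day_table) ||
      any(features$patient_id != day_table$patient_id) ||
      any(features$day_offset != day_table$day_offset))
    stop("'features' and 'day_table' must cover the same patient-days ",
         "in the same order", call. = FALSE)
  ref_days <- sum(day_table$trend_state == "A")
  ref_events <- sum(day_table$event[day_table$trend_state == "A"])
  if (ref_days == 0) stop("no trend-A reference days present", call. = FALSE)
  if (ref_events == 0)
    stop("zero events on trend-A reference days: rate ratios undefined",
         call. = FALSE)
  n_pat <- length(unique(day_table$patient_id))
  n_days <- nrow(day_table)
  stats <- lapply(rules$conditions, function(conds) {
    hit <- apply_rule(conds, features)
    rd <- sum(hit)
    if (rd == 0) return(NULL)
    ev <- sum(day_table$event[hit])
    data.frame(
      rule_days = rd, rule_events = ev,
      log_rr = log((ev / rd) / (ref_events / ref_days)),
      patient_pct = length(unique(day_table$patient_id[hit])) / n_pat,
      day_pct = rd / n_days)
  })
  keep <- !vapply(stats, is.null, logical(1))
  out <- rules[keep, , drop = FALSE]
  if (!any(keep)) {
    out$rule_days <- integer(0); out$rule_events <- integer(0)
    out$log_rr <- numeric(0); out$rr <- numeric(0)
    out$patient_pct <- numeric(0); out$day_pct <- numeric(0)
    return(out)
  }
  add <- do.call(rbind, stats[keep])
  out$rule_days <- add$rule_days
  out$rule_events <- add$rule_events
  out$log_rr <- add$log_rr
  out$rr <- exp(add$log_rr)
  out$patient_pct <- add$patient_pct
  out$day_pct <- add$day_pct
  rownames(out) <- NULL
  out
}

#' Comparator statistics for the clinical burden thresholds
#'
#' The same statistics computed for rules by [score_rules()], evaluated for
#' the prespecified duration and quantity thresholds on the same training
#' days.
#'
#' @param day_table A [risk_day_table()].
#' @return Data frame with rows `duration` and `quantity`: `log_rr`,
#'   `patient_pct`, `day_pct`, day and event counts.
#' @export
comparator_stats <- function(day_table) {
  ref_days <- sum(day_table$trend_state == "A")
  ref_events <- sum(day_table$event[day_table$trend_state == "A"])
  if (ref_days == 0 || ref_events == 0)
    stop("trend-A reference days/events required", call. = FALSE)
  n_pat <- length(unique(day_table$patient_id))
  n_days <- nrow(day_table)
  one <- function(flag) {
    d <- sum(flag); ev <- sum(day_table$event[flag])
    data.frame(days = d, events = ev,
               log_rr = log((ev / d) / (ref_events / ref_days)),
               patient_pct = length(unique(day_table$patient_id[flag])) / n_pat,
               day_pct = d / n_days)
  }
  out <- rbind(duration = one(day_table$duration_met),
               quantity = one(day_table$quantity_met))
  out$criterion <- rownames(out)
  out
}

#' Match mined rules to the clinical comparators
#'
#' Reproduces how the high-risk trend was fixed: candidate rules are walked
#' in order of selection frequency and the first whose log incidence-rate
#' ratio strictly exceeds the comparator floor and whose prevalence strictly
#' exceeds the comparator prevalence floor is returned. Floors are taken
#' from the quantity threshold. The prevalence statistic defaults to the
#' share of selected days; the share of patients is available via
#' `prevalence = "patients"` (both are reported by [score_rules()]).
#'
#' @param rules A scored `rule_set` ([score_rules()]).
#' @param comparators Output of [comparator_stats()] on the same training
#'   days.
#' @param prevalence `"days"` or `"patients"`.
#' @param floor_source Row of `comparators` supplying the floors
#'   (default `"quantity"`).
#' @return The matched rule (single-row `rule_set`), or an empty rule set
#'   (zero rows) when no rule qualifies.
#' @export
match_to_comparators <- function(rules, comparators, prevalence = c("days",
                                                                    "patients"),
                                 floor_source = "quantity") {
  prevalence <- match.arg(prevalence)
  pct_col <- if (prevalence == "days") "day_pct" else "patient_pct"
  fl <- comparators[floor_source, ]
  if (nrow(fl) != 1 || anyNA(fl$log_rr))
    stop("comparator floors not available for: ", floor_source, call. = FALSE)
  ord <- order(rules$selection_frequency, decreasing = TRUE)
  for (i in ord) {
    if (rules$log_rr[i] > fl$log_rr && rules[[pct_col]][i] > fl[[pct_col]]) {
      return(rules[i, , drop = FALSE])
    }
  }
  message("no rule exceeded the comparator floors (log RR > ",
          signif(fl$log_rr, 3), ", ", prevalence, " share > ",
          signif(100 * fl[[pct_col]], 3), "%)")
  rules[0, , drop = FALSE]
}

#' Freeze a matched rule into trend-engine thresholds
#'
#' Translates a matched rule's conditions into a [trend_config()]: a lower
#' bound on the burden CMA becomes `trend_d_burden_cma_min`, an upper bound
#' on the activity CMA becomes `trend_d_activity_cma_max`. The rule should
#' contain the above-average burden condition (`burden_sma21_ge_cma`); a
#' rule without it is returned unfrozen with a warning.
#'
#' @param rule A single-row scored `rule_set`.
#' @param base_config The [trend_config()] to update.
#' @return A `trend_config` with the rule's thresholds frozen in.
#' @export
rule_to_trend_config <- function(rule, base_config = trend_config()) {
  if (nrow(rule) != 1) stop("'rule' must be a single matched rule",
                            call. = FALSE)
  conds <- rule$conditions[[1]]
  crossover <- any(grepl("_sma21_ge_cma$", conds$var) & conds$op == ">=" &
                     conds$threshold <= 1)
  if (!crossover) {
    warning("matched rule lacks an above-average burden (SMA21 vs CMA) ",
            "condition; trend thresholds left unchanged")
    return(base_config)
  }
  b_lo <- conds$threshold[conds$var == "burden_cma" & conds$op == ">="]
  a_hi <- conds$threshold[conds$var == "activity_cma" & conds$op == "<"]
  trend_config(
    sma_windows = base_config$sma_windows,
    sinus_cma_threshold = base_config$sinus_cma_threshold,
    trend_d_burden_cma_min = if (length(b_lo)) max(b_lo) else
      base_config$trend_d_burden_cma_min,
    trend_d_activity_cma_max = if (length(a_hi)) min(a_hi) else
      base_config$trend_d_activity_cma_max,
    duration_threshold_min = base_config$duration_threshold_min,
    quantity_threshold_min = base_config$quantity_threshold_min)
}

#' Serialize / read mined rules as structured text
#'
#' One line per rule: tab-separated `rule_id`, `selection_frequency`,
#' `log_rr`, `patient_pct`, `day_pct`, and the conjunction as
#' `column op threshold` clauses joined by " & ".
#'
#' @param rules A scored `rule_set`.
#' @param path File path.
#' @return `write_rules()` invisibly returns the path.
#' @export
write_rules <- function(rules, path) {
  lines <- c("rule_id\tselection_frequency\tlog_rr\tpatient_pct\tday_pct\trule")
  for (i in seq_len(nrow(rules))) {
    lines <- c(lines, sprintf(
      "%d\t%.6g\t%.6g\t%.6g\t%.6g\t%s", rules$rule_id[i],
      rules$selection_frequency[i],
      if ("log_rr" %in% names(rules)) rules$log_rr[i] else NA,
      if ("patient_pct" %in% names(rules)) rules$patient_pct[i] else NA,
      if ("day_pct" %in% names(rules)) rules$day_pct[i] else NA,
      rules$key[i]))
  }
  writeLines(lines, path)
  invisible(path)
}
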