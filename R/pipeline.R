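# End-to-end orchestration: simulate -> preprocess -> trends -> discover
# (train split) -> evaluate (holdout), with per-stage seeds, config
# hashing, and text artifacts.

#' Derive a per-stage seed from the global seed
#'
#' Deterministic mixing of the global seed with the stage name so stages
#' can be re-run independently; the result stays within the 32-bit integer
#' range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
derive_stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 131 + h * 7919) %% 2147483647)
}

.config_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(lapply(list(...), unclass), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full burden-trend pipeline
#'
#' Simulates a cohort, preprocesses it (forward-fill and inclusion rules),
#' computes day flags, mines and matches risk rules on a 70% patient
#' partition, freezes the matched rule into the trend configuration, and
#' validates on the 30% holdout. Every artifact is written as delimited or
#' structured text under `out_dir`, and a manifest records the seed and a
#' hash of the configuration.
#'
#' @param out_dir Output directory (created if missing).
#' @param sim_config A [simulation_config()].
#' @param trend_cfg A [trend_config()].
#' @param seed Global seed; per-stage seeds are derived from it. Defaults
#'   to the generator seed.
#' @param n_trees Bootstrap replicates for the forest.
#' @param horizon Pre-event labeling window, days.
#' @param train_fraction Patient fraction for the training partition.
#' @param max_depth,min_leaf,cp Tree-growing controls, see
#'   [train_bootstrap_forest()].
#' @param discovery_parameters Diagnostic parameters fed to the feature
#'   matrix.
#' @param verbose Log stage progress to stderr?
#' @return Invisibly, a list with the matched rule, the frozen trend
#'   config, the holdout report, and the artifact paths.
#' @export
run_pipeline <- function(out_dir, sim_config, trend_cfg = trend_config(),
                         seed = sim_config$seed, n_trees = 50, horizon = 5,
                         train_fraction = 0.7, max_depth = 4, min_leaf = 50,
                         cp = 0.005,
                         discovery_parameters = names(.PARAM_SHORT),
                         verbose = TRUE) {
  stopifnot(inherits(sim_config, "sim_config"),
            inherits(trend_cfg, "trend_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[afburden] ", sprintf(...))
  hash <- .config_hash(sim_config, trend_cfg, seed, n_trees, horizon,
                       train_fraction, max_depth, min_leaf, cp,
                       discovery_parameters)
  stage_status <- character(0)
  artifact <- function(...) file.path(out_dir, ...)
  run_stage <- function(name, fun) {
    say("stage %s", name)
    res <- tryCatch(fun(), error = function(e) {
      stage_status <<- c(stage_status, setNames("failed", name))
      .write_manifest(artifact("run_manifest.json"), seed, hash, out_dir,
                      stage_status)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stage_status <<- c(stage_status, setNames("ok", name))
    res
  }

  sim <- run_stage("simulate", function() {
    cfg <- sim_config
    cfg$seed <- derive_stage_seed(seed, "simulate")
    out <- simulate_cohort(cfg, trend_cfg)
    write_daily_diagnostics(out$cohort, artifact("cohort_records.csv"),
                            artifact("cohort_patients.csv"))
    write_simulation_config(cfg, artifact("simulation_config.yaml"))
    out
  })

  prep <- run_stage("preprocess", function() {
    if (n_patients(sim$cohort) == 0)
      stop("cohort is empty: nothing to preprocess")
    inc <- apply_inclusion(sim$cohort,
                           max_follow_up_days = sim_config$max_follow_up_days)
    filled <- forward_fill(inc$cohort)
    write_daily_diagnostics(filled, artifact("processed_records.csv"),
                            artifact("processed_patients.csv"))
    write.csv(inc$exclusions, artifact("exclusions.csv"), row.names = FALSE)
    list(cohort = filled, exclusions = inc$exclusions)
  })

  flags <- run_stage("trends", function() {
    fl <- flag_days(prep$cohort, trend_cfg)
    write.csv(fl, artifact("day_flags.csv"), row.names = FALSE)
    fl
  })

  disc <- run_stage("discover", function() {
    parts <- split_patients(prep$cohort, train_fraction,
                            derive_stage_seed(seed, "split"))
    feats <- build_feature_matrix(parts$train, trend_cfg,
                                  discovery_parameters)
    labels <- label_risk_days(parts$train, horizon)
    key_f <- paste(feats$patient_id, feats$day_offset)
    lab <- labels$label[match(key_f, paste(labels$patient_id,
                                           labels$day_offset))]
    forest <- train_bootstrap_forest(feats, lab, n_replicates = n_trees,
                                     seed = derive_stage_seed(seed, "forest"),
                                     train_fraction = train_fraction,
                                     max_depth = max_depth,
                                     min_leaf = min_leaf, cp = cp)
    train_dt <- risk_day_table(parts$train, config = trend_cfg,
                               horizon = horizon)
    key_dt <- paste(train_dt$patient_id, train_dt$day_offset)
    train_dt <- train_dt[match(key_f, key_dt), ]
    rules <- score_rules(extract_rules(forest), feats, train_dt)
    comp <- comparator_stats(train_dt)
    matched <- match_to_comparators(rules, comp)
    write_rules(rules, artifact("rules.txt"))
    frozen <- if (nrow(matched) == 1)
      rule_to_trend_config(matched, trend_cfg) else trend_cfg
    yaml::write_yaml(unclass(frozen), artifact("frozen_trend_config.yaml"))
    if (nrow(matched) == 1) write_rules(matched, artifact("matched_rule.txt"))
    list(parts = parts, rules = rules, comparators = comp,
         matched = matched, frozen = frozen)
  })

  report <- run_stage("evaluate", function() {
    rep <- evaluate_holdout(disc$parts$holdout, disc$frozen, horizon)
    json <- .report_to_json(rep)
    jsonlite::write_json(json, artifact("holdout_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    if (!is.null(rep$state_rate_ratios))
      write.csv(rep$state_rate_ratios, artifact("state_rate_ratios.csv"),
                row.names = FALSE)
    rep
  })

  .write_manifest(artifact("run_manifest.json"), seed, hash, out_dir,
                  stage_status)
  say("done; artifacts in %s", out_dir)
  invisible(list(matched_rule = disc$matched, frozen_config = disc$frozen,
                 report = report, exclusions = prep$exclusions,
                 out_dir = out_dir, config_hash = hash))
}

.report_to_json <- function(rep) {
  list(
    follow_up = rep$follow_up,
    degenerate = rep$degenerate,
    state_rate_ratios = rep$state_rate_ratios,
    criterion_rate_ratios = rep$criterion_rate_ratios,
    aurocs = if (!is.null(rep$aurocs)) list(
      clinical = rep$aurocs$clinical, with_trend = rep$aurocs$with_trend,
      relative_increase_pct = rep$aurocs$relative_increase_pct) else NULL,
    yield = if (!is.null(rep$yield)) list(
      regions = as.list(rep$yield$regions),
      captured_events = rep$yield$captured_events,
      clinical_events = rep$yield$clinical_events,
      trend_exclusive_events = rep$yield$trend_exclusive_events,
      pct_increase = rep$yield$pct_increase,
      day_exclusivity_pct = rep$yield$day_exclusivity_pct) else NULL,
    trend_day_fraction = rep$trend_day_fraction,
    trend_patient_fraction = rep$trend_patient_fraction,
    n_days = rep$n_days, n_events = rep$n_events)
}

.write_manifest <- function(path, seed, hash, out_dir, stage_status) {
  jsonlite::write_json(list(
    package = "afburden",
    version = as.character(utils::packageVersion("afburden")),
    seed = seed, config_hash = hash,
    stages = as.list(stage_status),
    files = list.files(out_dir)), path, auto_unbox = TRUE, pretty = TRUE)
}
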