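# Configuration objects: generator settings and trend-engine thresholds.

.chk_num <- function(x, field, lo = -Inf, hi = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    stop(sprintf("'%s' must be a numeric value of length %d", field, len),
         call. = FALSE)
  if (any(x < lo) || any(x > hi))
    stop(sprintf("'%s' must lie in [%s, %s]", field, format(lo), format(hi)),
         call. = FALSE)
  invisible(x)
}

.chk_prob <- function(x, field) .chk_num(x, field, 0, 1)

#' Settings for the synthetic ICM cohort generator
#'
#' Bundles every knob of the generator into a validated object. The defaults
#' describe a cohort of elderly patients monitored for up to two years:
#' a 6% persistent-AF phenotype mix, a 2-minute device detection floor,
#' paroxysmal AF driven by a slowly varying episode propensity, a subset of
#' patients with linearly declining activity, sparse follow-up gaps
#' averaging 7.4 days, and a per-day cardiovascular-hospitalization (CVH)
#' hazard that is multiplied by the patient's current burden trend state.
#'
#' @param n_patients Number of patients to simulate.
#' @param max_follow_up_days Maximum follow-up, days since implant (730 =
#'   two years).
#' @param phenotype_mix Fraction of patients with the persistent-AF
#'   phenotype (at least 23.5 h of AF on 7 or more consecutive days).
#' @param episode_rate Baseline per-day probability that a paroxysmal
#'   patient has at least one AF episode.
#' @param episode_duration_log_mean,episode_duration_log_sd Log-scale mean
#'   and SD (log-minutes) of the total AF amount on an episode day.
#' @param amount_scale_log_sd Optional patient-level SD (log scale) of the
#'   episode amount. Real cohorts mix patients whose daily AF is minutes
#'   with patients whose daily AF is hours; values near 1 reproduce that
#'   overdispersion. The default (0) keeps episode amounts on a common
#'   scale, which makes planted trend-state signals cleanly recoverable by
#'   the discovery module.
#' @param fragmentation_prob Probability that an episode day's AF is split
#'   across several episodes, so the longest continuous episode is shorter
#'   than the daily total.
#' @param propensity_sd SD of the patient-level intercept on the logit
#'   episode propensity (between-patient heterogeneity).
#' @param propensity_ar_rho,propensity_ar_sd Autocorrelation and stationary
#'   SD of the AR(1) day-level component of the logit episode propensity;
#'   this is what makes moving-average crossovers informative.
#' @param activity_mean_min,activity_sd_min Mean and SD of daily activity,
#'   minutes/day.
#' @param activity_decline_fraction Fraction of patients whose activity
#'   declines linearly over follow-up.
#' @param activity_decline_min_per_day Slope of that decline,
#'   minutes/day per day.
#' @param baseline_hazard Per-day CVH probability while in trend state A.
#' @param state_multipliers Named vector `c(A = 1, B, C, D)` of hazard rate
#'   ratios applied per trend state; A is fixed at 1.
#' @param gap_probability Per-day probability that a follow-up gap starts.
#' @param gap_length_mean Mean gap length in days (positive integer
#'   distribution, 1 + Poisson).
#' @param detection_floor_min Minimum AF amount (minutes) the device can
#'   register on a day; smaller amounts are recorded as zero.
#' @param seed Integer seed; together with the config it fully determines
#'   the generated cohort.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @examples
#' cfg <- simulation_config(n_patients = 50, seed = 7)
#' cfg$state_multipliers
#' @export
simulation_config <- function(n_patients,
                              max_follow_up_days = 730,
                              phenotype_mix = 0.06,
                              episode_rate = 0.3,
                              episode_duration_log_mean = log(40),
                              episode_duration_log_sd = 0.9,
                              amount_scale_log_sd = 0,
                              fragmentation_prob = 0.5,
                              propensity_sd = 1.5,
                              propensity_ar_rho = 0.95,
                              propensity_ar_sd = 1.0,
                              activity_mean_min = 95,
                              activity_sd_min = 30,
                              activity_decline_fraction = 0.55,
                              activity_decline_min_per_day = 0.8,
                              baseline_hazard = 4.5e-4,
                              state_multipliers = c(A = 1, B = 4.49,
                                                    C = 8.41, D = 11.15),
                              gap_probability = 3e-4,
                              gap_length_mean = 7.4,
                              detection_floor_min = 2,
                              seed = 1L) {
  .chk_num(n_patients, "n_patients", 0)
  .chk_num(max_follow_up_days, "max_follow_up_days", 22)
  .chk_prob(phenotype_mix, "phenotype_mix")
  .chk_prob(episode_rate, "episode_rate")
  .chk_num(episode_duration_log_mean, "episode_duration_log_mean")
  .chk_num(episode_duration_log_sd, "episode_duration_log_sd", 0)
  .chk_num(amount_scale_log_sd, "amount_scale_log_sd", 0)
  .chk_prob(fragmentation_prob, "fragmentation_prob")
  .chk_num(propensity_sd, "propensity_sd", 0)
  .chk_num(propensity_ar_rho, "propensity_ar_rho", 0, 0.9999)
  .chk_num(propensity_ar_sd, "propensity_ar_sd", 0)
  .chk_num(activity_mean_min, "activity_mean_min", 0, 1440)
  .chk_num(activity_sd_min, "activity_sd_min", 0)
  .chk_prob(activity_decline_fraction, "activity_decline_fraction")
  .chk_num(activity_decline_min_per_day, "activity_decline_min_per_day", 0)
  .chk_prob(baseline_hazard, "baseline_hazard")
  if (!is.numeric(state_multipliers) ||
      !setequal(names(state_multipliers), c("A", "B", "C", "D")))
    stop("'state_multipliers' must be a numeric vector named A, B, C, D",
         call. = FALSE)
  state_multipliers <- state_multipliers[c("A", "B", "C", "D")]
  if (any(state_multipliers <= 0))
    stop("'state_multipliers' must all be > 0", call. = FALSE)
  if (state_multipliers[["A"]] != 1)
    stop("'state_multipliers' must fix the A (reference) multiplier at 1",
         call. = FALSE)
  if (baseline_hazard * max(state_multipliers) > 1)
    stop("'baseline_hazard' times the largest of 'state_multipliers' ",
         "exceeds 1: not a valid per-day probability", call. = FALSE)
  .chk_prob(gap_probability, "gap_probability")
  .chk_num(gap_length_mean, "gap_length_mean", 1)
  .chk_num(detection_floor_min, "detection_floor_min", 0, 1440)
  .chk_num(seed, "seed")
  structure(list(
    n_patients = as.integer(n_patients),
    max_follow_up_days = as.integer(max_follow_up_days),
    phenotype_mix = phenotype_mix,
    episode_rate = episode_rate,
    episode_duration_log_mean = episode_duration_log_mean,
    episode_duration_log_sd = episode_duration_log_sd,
    amount_scale_log_sd = amount_scale_log_sd,
    fragmentation_prob = fragmentation_prob,
    propensity_sd = propensity_sd,
    propensity_ar_rho = propensity_ar_rho,
    propensity_ar_sd = propensity_ar_sd,
    activity_mean_min = activity_mean_min,
    activity_sd_min = activity_sd_min,
    activity_decline_fraction = activity_decline_fraction,
    activity_decline_min_per_day = activity_decline_min_per_day,
    baseline_hazard = baseline_hazard,
    state_multipliers = state_multipliers,
    gap_probability = gap_probability,
    gap_length_mean = gap_length_mean,
    detection_floor_min = detection_floor_min,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ICM cohort settings\n")
  cat(sprintf("  patients: %d, follow-up <= %d days, persistent mix %.1f%%\n",
              x$n_patients, x$max_follow_up_days, 100 * x$phenotype_mix))
  cat(sprintf("  baseline hazard %.4g/day; state multipliers A=%.3g B=%.3g C=%.3g D=%.3g\n",
              x$baseline_hazard, x$state_multipliers[["A"]],
              x$state_multipliers[["B"]], x$state_multipliers[["C"]],
              x$state_multipliers[["D"]]))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Write / read generator settings as structured text
#'
#' Serializes a [simulation_config()] to YAML with keys exactly matching the
#' field names, and reads it back through the validating constructor.
#'
#' @param config A `sim_config` object.
#' @param path File path.
#' @return `read_simulation_config()` returns a validated `sim_config`.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$state_multipliers <- as.list(config$state_multipliers)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$state_multipliers <- unlist(x$state_multipliers)
  do.call(simulation_config, x)
}

#' Thresholds and windows for the burden trend engine
#'
#' @param sma_windows Strictly increasing simple-moving-average windows in
#'   days; the largest window drives the crossover comparison.
#' @param sinus_cma_threshold Trend A cutoff on the burden CMA, minutes/day.
#'   14.4 min is 1% of a 1440-minute day.
#' @param trend_d_burden_cma_min Trend D lower cutoff on the burden CMA,
#'   minutes/day.
#' @param trend_d_activity_cma_max Trend D upper cutoff on the activity CMA,
#'   minutes/day.
#' @param duration_threshold_min Clinical duration threshold: longest
#'   continuous AF episode of the day, minutes.
#' @param quantity_threshold_min Clinical quantity threshold: total AF
#'   amount of the day, minutes (72 = 5% of the day).
#' @return An object of class `trend_config`.
#' @examples
#' trend_config()$quantity_threshold_min  # 72 = 5% of 1440
#' @export
trend_config <- function(sma_windows = c(1, 2, 3, 5, 8, 13, 21),
                         sinus_cma_threshold = 14.4,
                         trend_d_burden_cma_min = 8.5,
                         trend_d_activity_cma_max = 87,
                         duration_threshold_min = 60,
                         quantity_threshold_min = 72) {
  if (!is.numeric(sma_windows) || length(sma_windows) < 1 ||
      any(sma_windows < 1) || is.unsorted(sma_windows, strictly = TRUE))
    stop("'sma_windows' must be positive and strictly increasing",
         call. = FALSE)
  .chk_num(sinus_cma_threshold, "sinus_cma_threshold", 1e-12)
  .chk_num(trend_d_burden_cma_min, "trend_d_burden_cma_min", 1e-12)
  .chk_num(trend_d_activity_cma_max, "trend_d_activity_cma_max", 1e-12)
  .chk_num(duration_threshold_min, "duration_threshold_min", 1e-12)
  .chk_num(quantity_threshold_min, "quantity_threshold_min", 1e-12)
  structure(list(
    sma_windows = as.integer(sma_windows),
    sinus_cma_threshold = sinus_cma_threshold,
    trend_d_burden_cma_min = trend_d_burden_cma_min,
    trend_d_activity_cma_max = trend_d_activity_cma_max,
    duration_threshold_min = duration_threshold_min,
    quantity_threshold_min = quantity_threshold_min
  ), class = "trend_config")
}

#' @export
print.trend_config <- function(x, ...) {
  cat("Burden trend engine settings\n")
  cat("  SMA windows:", paste(x$sma_windows, collapse = ", "), "days\n")
  cat(sprintf("  trend A: burden CMA < %.3g min/day\n", x$sinus_cma_threshold))
  cat(sprintf("  trend D: burden CMA > %.3g and activity CMA < %.3g min/day\n",
              x$trend_d_burden_cma_min, x$trend_d_activity_cma_max))
  cat(sprintf("  thresholds: duration >= %.3g min, quantity >= %.3g min\n",
              x$duration_threshold_min, x$quantity_threshold_min))
  invisible(x)
}
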