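# Synthetic ICM cohort generator: AF burden series, activity, vital
# channels, trend-state-linked hospitalization hazards, and follow-up gaps.

# Column-wise cumulative sums via one pass over the stacked vector.
.col_cumsum <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  full <- cumsum(as.vector(mat))
  if (m > 1) {
    base <- rep(c(0, full[n * seq_len(m - 1)]), each = n)
    full <- full - base
  }
  matrix(full, n, m)
}

# Paroxysmal daily burden for m patients over n days, as n x m matrices.
# A patient-level intercept plus an AR(1) component on the logit episode
# propensity makes burden drift slowly, so SMA/CMA crossovers carry signal.
.sim_burden_matrix <- function(n, m, config) {
  b0 <- rnorm(m, qlogis(config$episode_rate), config$propensity_sd)
  rho <- config$propensity_ar_rho
  z <- matrix(0, n, m)
  z[1, ] <- rnorm(m, 0, config$propensity_ar_sd)
  if (n > 1) {
    innov_sd <- config$propensity_ar_sd * sqrt(1 - rho^2)
    eps <- matrix(rnorm((n - 1) * m, 0, innov_sd), n - 1, m)
    for (t in 2:n) z[t, ] <- rho * z[t - 1, ] + eps[t - 1, ]
  }
  p <- plogis(sweep(z, 2, b0, "+"))
  ep <- matrix(runif(n * m), n, m) < p
  burden <- matrix(0, n, m)
  idx <- which(ep)
  # patient-level episode scale: daily AF amounts differ by orders of
  # magnitude between patients (minutes for some, hours for others)
  scale_j <- rnorm(m, config$episode_duration_log_mean,
                   config$amount_scale_log_sd)
  burden[idx] <- pmin(rlnorm(length(idx), scale_j[(idx - 1L) %/% n + 1L],
                             config$episode_duration_log_sd), 1440)
  burden[burden < config$detection_floor_min] <- 0
  longest <- burden
  nz <- which(burden > 0)
  frag <- nz[runif(length(nz)) < config$fragmentation_prob]
  longest[frag] <- burden[frag] * runif(length(frag), 0.45, 0.9)
  longest[nz] <- pmin(pmax(longest[nz], config$detection_floor_min),
                      burden[nz])
  list(burden = burden, longest = longest)
}

# Overlay a persistent phase: from `onset` to the end of the series the
# daily burden stays at or above 23.5 h, so the phenotype classifier labels
# the patient persistent by construction.
.overlay_persistent <- function(burden, longest, onset) {
  n <- length(burden)
  idx <- onset:n
  burden[idx] <- runif(length(idx), 1410, 1440)
  longest[idx] <- burden[idx] * runif(length(idx), 0.8, 1)
  list(burden = burden, longest = longest)
}

.persistent_onset <- function(n_days, rng_n = 1L) {
  onset_max <- n_days - 6L
  if (onset_max < 1L)
    stop("persistent series needs at least 7 days", call. = FALSE)
  onset_min <- min(.INDEX_DAY, onset_max)
  if (onset_min == onset_max) rep(onset_min, rng_n)
  else onset_min + floor(runif(rng_n) * (onset_max - onset_min + 1L))
}

#' Simulate a daily AF burden series for one patient
#'
#' Paroxysmal series follow a daily Bernoulli episode process whose logit
#' propensity carries a patient-level intercept and an AR(1) drift, with a
#' log-normal AF amount on episode days; amounts under the device detection
#' floor are recorded as zero. Persistent series add an onset day after
#' which every day holds at least 23.5 hours of AF, so the series always
#' contains a run of 7 or more such consecutive days. Uses the current RNG
#' stream; call `set.seed()` upstream for reproducibility.
#'
#' @param phenotype `"paroxysmal"` or `"persistent"`.
#' @param n_days Number of days to simulate (>= 1; persistent needs >= 7).
#' @param config A [simulation_config()].
#' @return A list with numeric vectors `burden` and `longest` (daily total
#'   and longest continuous AF, minutes), both in `[0, 1440]` with
#'   `longest <= burden`.
#' @export
simulate_af_series <- function(phenotype, n_days,
                               config = simulation_config(n_patients = 1)) {
  phenotype <- match.arg(phenotype, c("paroxysmal", "persistent"))
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 1)
    stop("'n_days' must be a single count >= 1", call. = FALSE)
  n_days <- as.integer(n_days)
  sim <- .sim_burden_matrix(n_days, 1L, config)
  out <- list(burden = sim$burden[, 1], longest = sim$longest[, 1])
  if (phenotype == "persistent") {
    onset <- .persistent_onset(n_days)
    out <- .overlay_persistent(out$burden, out$longest, onset)
  }
  out
}

#' Simulate daily patient activity for one patient
#'
#' Gaussian daily activity, optionally with a linear decline of
#' `activity_decline_min_per_day`, clipped to `[0, 1440]` minutes.
#'
#' @param n_days Number of days (>= 1).
#' @param decline Logical: is this a declining-activity patient?
#' @param config A [simulation_config()].
#' @return Numeric vector of daily activity minutes.
#' @export
simulate_activity <- function(n_days, decline = FALSE,
                              config = simulation_config(n_patients = 1)) {
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 1)
    stop("'n_days' must be a single count >= 1", call. = FALSE)
  n_days <- as.integer(n_days)
  mu <- config$activity_mean_min -
    (if (decline) config$activity_decline_min_per_day * (seq_len(n_days) - 1)
     else 0)
  pmin(pmax(rnorm(n_days, mu, config$activity_sd_min), 0), 1440)
}

# Ventricular rates and HRV: weakly linked to same-day burden (higher rates,
# lower variability on heavy AF days). Not used by the trend states.
.sim_vitals <- function(burden) {
  n <- length(burden)
  f <- burden / 1440
  list(
    vrate_day = pmax(rnorm(n, 78, 8) + 14 * f, 30),
    vrate_night = pmax(rnorm(n, 64, 6) + 10 * f, 25),
    hrv = pmax(rnorm(n, 95, 25) - 35 * f, 0)
  )
}

#' Assign a hazard-linked hospitalization event to one patient
#'
#' Scans follow-up from the index day onward. The probability that a CVH
#' occurs on day `t` is `baseline_hazard * state_multipliers[state(t - 1)]`
#' — the hazard of the event is driven by the trend state of the last
#' record day, since diagnostic follow-up ends the day before the event.
#' An event landing beyond `max_follow_up_days` is treated as censoring.
#'
#' @param states Character (or factor) vector of per-day trend states
#'   (`NA` allowed before the index day).
#' @param config A [simulation_config()].
#' @return A list: `cvh_day` (integer or `NA`) and `censor_day` (last
#'   diagnostic record day).
#' @export
assign_events <- function(states, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(states)
  if (n < 1) stop("'states' must contain at least one day", call. = FALSE)
  mult <- config$state_multipliers
  h <- config$baseline_hazard * unname(mult[as.character(states)])
  h[is.na(h)] <- 0  # pre-index days carry no event risk
  u <- runif(n)
  hit <- which(u < h)
  if (length(hit)) {
    d <- hit[1]  # state day; the event lands the next day
    if (d + 1L <= config$max_follow_up_days)
      return(list(cvh_day = d + 1L, censor_day = d))
  }
  list(cvh_day = NA_integer_, censor_day = min(n, config$max_follow_up_days))
}

#' Inject follow-up gaps into a cohort
#'
#' Each day after the first can start a gap with probability
#' `gap_probability`; gap lengths follow `1 + Poisson(gap_length_mean - 1)`,
#' a positive integer distribution with the configured mean. Days inside a
#' gap keep their row but lose their diagnostic values and are flagged
#' `observed = FALSE`.
#'
#' @param cohort An [icm_cohort()].
#' @param config A [simulation_config()].
#' @return The cohort with unobserved days blanked.
#' @export
inject_gaps <- function(cohort, config) {
  stopifnot(inherits(cohort, "icm_cohort"), inherits(config, "sim_config"))
  rec <- cohort$records
  if (nrow(rec) == 0 || config$gap_probability == 0) return(cohort)
  eligible <- rec$day_offset >= 2L
  starts <- which(eligible & runif(nrow(rec)) < config$gap_probability)
  if (length(starts)) {
    lens <- .gap_length_draw(length(starts), config)
    idx <- rep(starts, lens) + sequence(lens) - 1L
    src <- rep(starts, lens)
    ok <- idx <= nrow(rec) & rec$patient_id[pmin(idx, nrow(rec))] ==
      rec$patient_id[src]
    idx <- unique(idx[ok])
    rec$observed[idx] <- FALSE
    rec[idx, .VALUE_COLS] <- NA_real_
  }
  .new_cohort(rec, cohort$patients)
}

.gap_length_draw <- function(n, config) {
  1L + rpois(n, config$gap_length_mean - 1)
}

#' Simulate a synthetic ICM cohort with ground truth
#'
#' Draws phenotypes, burden/activity/vital series, computes the true per-day
#' trend state from the generated series (making parameter recovery
#' self-consistent), assigns hazard-linked CVH events, truncates records to
#' the day before each event, and injects follow-up gaps. The seed in the
#' config fully determines the output.
#'
#' @param config A [simulation_config()].
#' @param trend_cfg The [trend_config()] defining the true states used by
#'   the hazard.
#' @return A list: `cohort` (an [icm_cohort()]) and `truth` (per-patient
#'   phenotype and decline flags, per-record-day true states, and the
#'   generating `state_multipliers`).
#' @export
simulate_cohort <- function(config, trend_cfg = trend_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_patients
  n <- config$max_follow_up_days
  ids <- sprintf("P%05d", seq_len(m))
  if (m == 0) {
    empty_rec <- data.frame(patient_id = character(0), day_offset = integer(0),
                            af_burden_min = numeric(0),
                            max_continuous_af_min = numeric(0),
                            activity_min = numeric(0),
                            vrate_day_bpm = numeric(0),
                            vrate_night_bpm = numeric(0),
                            hrv_sd_ms = numeric(0), observed = logical(0))
    empty_pat <- data.frame(patient_id = character(0), indication = character(0),
                            cvh_day = integer(0), censor_day = integer(0))
    return(list(cohort = icm_cohort(empty_rec, empty_pat),
                truth = list(patients = empty_pat[, "patient_id", drop = FALSE],
                             states = NULL,
                             state_multipliers = config$state_multipliers)))
  }
  persistent <- runif(m) < config$phenotype_mix
  sim <- .sim_burden_matrix(n, m, config)
  burden <- sim$burden; longest <- sim$longest
  onset <- rep(NA_integer_, m)
  if (any(persistent)) {
    onset[persistent] <- as.integer(.persistent_onset(n, sum(persistent)))
    for (j in which(persistent)) {
      o <- .overlay_persistent(burden[, j], longest[, j], onset[j])
      burden[, j] <- o$burden; longest[, j] <- o$longest
    }
  }
  decline <- runif(m) < config$activity_decline_fraction
  mu <- matrix(config$activity_mean_min, n, m)
  mu[, decline] <- mu[, decline] -
    config$activity_decline_min_per_day * (seq_len(n) - 1)
  activity <- pmin(pmax(matrix(rnorm(n * m), n, m) * config$activity_sd_min +
                          mu, 0), 1440)

  # true trend states from the generated series, days >= index
  day <- seq_len(n)
  cma_b <- .col_cumsum(burden) / day
  sma_b <- stats::filter(burden, rep(1 / 21, 21), sides = 1)
  sma_b <- matrix(as.numeric(sma_b), n, m)
  cma_a <- .col_cumsum(activity) / day
  state <- matrix(NA_character_, n, m)
  rows <- .INDEX_DAY:n
  st <- rep("C", length(rows) * m)
  cb <- cma_b[rows, ]; sb <- sma_b[rows, ]; ca <- cma_a[rows, ]
  st[sb < cb] <- "B"
  st[st == "C" & cb > trend_cfg$trend_d_burden_cma_min &
       ca < trend_cfg$trend_d_activity_cma_max] <- "D"
  st[cb < trend_cfg$sinus_cma_threshold] <- "A"
  state[rows, ] <- st

  # hazard-linked events: the state of day t drives an event on day t + 1
  mult <- config$state_multipliers
  h <- matrix(0, n, m)
  h[rows, ] <- config$baseline_hazard * unname(mult[state[rows, ]])
  succ <- matrix(runif(n * m), n, m) < h
  first_hit <- apply(succ, 2, function(cl) match(TRUE, cl))
  cvh <- ifelse(!is.na(first_hit) & first_hit + 1L <= n,
                first_hit + 1L, NA_integer_)
  end <- ifelse(!is.na(cvh), cvh - 1L, n)

  # assemble stacked record tables (column-major linear indexing)
  len <- as.integer(end)
  pid <- rep(ids, len)
  d <- sequence(len)
  lin <- d + (rep(seq_len(m), len) - 1L) * n
  vit <- .sim_vitals(burden[lin])
  records <- data.frame(
    patient_id = pid, day_offset = d,
    af_burden_min = burden[lin], max_continuous_af_min = longest[lin],
    activity_min = activity[lin],
    vrate_day_bpm = vit$vrate_day, vrate_night_bpm = vit$vrate_night,
    hrv_sd_ms = vit$hrv, observed = TRUE, stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = ids,
    indication = sample(.INDICATIONS, m, replace = TRUE,
                        prob = c(0.45, 0.3, 0.25)),
    cvh_day = as.integer(cvh), censor_day = as.integer(end),
    stringsAsFactors = FALSE)
  cohort <- inject_gaps(.new_cohort(records, patients), config)
  truth <- list(
    patients = data.frame(patient_id = ids,
                          phenotype = ifelse(persistent, "persistent",
                                             "paroxysmal"),
                          persistent_onset = onset,
                          activity_decline = decline,
                          stringsAsFactors = FALSE),
    states = data.frame(patient_id = pid, day_offset = d,
                        true_state = state[lin], stringsAsFactors = FALSE),
    state_multipliers = config$state_multipliers
  )
  list(cohort = cohort, truth = truth)
}
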