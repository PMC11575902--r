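# Moving-average trend engine: CMA/SMA, crossover states A-D, and the
# prespecified clinical burden thresholds.

# First eligible follow-up day: the day after the 21-day initialization
# window that starts the day after implant (day_offset is 1-based).
.INDEX_DAY <- 22L

#' Index day of follow-up
#'
#' Follow-up eligibility starts the day after the 21-day series
#' initialization window, i.e. day 22 on the 1-based days-since-implant
#' scale used throughout the package.
#' @return Integer day offset (22).
#' @export
index_day <- function() .INDEX_DAY

#' Cumulative moving average at a given day
#'
#' The CMA at day `t` is the mean of the daily values from day 1 (the day
#' after implant) through `t`: the patient's historical baseline.
#'
#' @param series Numeric vector of daily values, day 1 first.
#' @param t Day at which to evaluate (1-based); `length(series) >= t`.
#' @return The mean of `series[1:t]`.
#' @examples
#' x <- numeric(30); x[12] <- 255
#' cumulative_moving_average(x, 30)  # 8.5 min/day
#' @export
cumulative_moving_average <- function(series, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 1)
    stop("'t' must be a single day >= 1", call. = FALSE)
  t <- as.integer(t)
  if (length(series) < t)
    stop("'series' has fewer than 't' entries", call. = FALSE)
  mean(series[seq_len(t)])
}

#' Simple moving average at a given day
#'
#' The SMA with window `p` at day `t` is the mean of the last `p` daily
#' values ending at `t`. It is undefined for `t < p`.
#'
#' @inheritParams cumulative_moving_average
#' @param p Window length in days, `1 <= p <= t`.
#' @return The mean of `series[(t - p + 1):t]`.
#' @export
simple_moving_average <- function(series, t, p) {
  if (!is.numeric(p) || length(p) != 1 || p < 1)
    stop("'p' must be a single window >= 1", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1 || t < p)
    stop("SMA undefined: 't' must be at least the window length 'p'",
         call. = FALSE)
  t <- as.integer(t); p <- as.integer(p)
  if (length(series) < t)
    stop("'series' has fewer than 't' entries", call. = FALSE)
  mean(series[(t - p + 1L):t])
}

# Whole-series helpers (one value per day; SMA is NA while t < p).
.cma_series <- function(x) cumsum(x) / seq_along(x)
.sma_series <- function(x, p) {
  if (p == 1L) return(as.numeric(x))
  as.numeric(stats::filter(x, rep(1 / p, p), sides = 1))
}

# Grouped versions for a stacked cohort vector: `day` must be the 1-based,
# contiguous within-patient day offset (records sorted by patient then day).
.cma_grouped <- function(x, day) {
  cs <- cumsum(x)
  first <- which(day == 1L)
  base <- rep(c(0, cs[first[-1L] - 1L]), diff(c(first, length(x) + 1L)))
  (cs - base) / day
}
.sma_grouped <- function(x, day, p) {
  out <- .sma_series(x, as.integer(p))
  out[day < p] <- NA_real_  # window not yet filled for this patient
  out
}

.assert_contiguous <- function(records) {
  n <- nrow(records)
  if (n == 0) return(records)
  if (is.unsorted(records$patient_id))
    records <- records[order(records$patient_id, records$day_offset), ,
                       drop = FALSE]
  first <- c(TRUE, records$patient_id[-1] != records$patient_id[-n])
  if (any(records$day_offset[first] != 1L))
    stop("records must start at day_offset 1 for every patient ",
         "(the day after implant)", call. = FALSE)
  if (any(records$day_offset[!first] !=
            c(0L, records$day_offset[-n])[!first] + 1L))
    stop("records must be contiguous per patient; run forward_fill() first",
         call. = FALSE)
  records
}

#' Per-day moving-average snapshots for all diagnostic parameters
#'
#' Computes, for every patient-day, the cumulative moving average and the
#' simple moving averages over every configured window, for each of the five
#' diagnostic parameters (AF burden, activity, day/night ventricular rate,
#' heart-rate-variability SD). Requires a forward-filled, contiguous cohort.
#'
#' @param cohort An [icm_cohort()].
#' @param config A [trend_config()].
#' @return A data frame with `patient_id`, `day_offset`, and one column per
#'   parameter/average combination (e.g. `burden_cma`, `burden_sma21`).
#'   SMA columns are `NA` on days before their window is filled.
#' @export
compute_trend_snapshots <- function(cohort, config = trend_config()) {
  records <- .assert_contiguous(cohort$records)
  params <- c(burden = "af_burden_min", activity = "activity_min",
              vrate_day = "vrate_day_bpm", vrate_night = "vrate_night_bpm",
              hrv = "hrv_sd_ms")
  out <- records[, c("patient_id", "day_offset")]
  day <- records$day_offset
  for (nm in names(params)) {
    x <- records[[params[[nm]]]]
    out[[paste0(nm, "_cma")]] <- .cma_grouped(x, day)
    for (p in config$sma_windows)
      out[[paste0(nm, "_sma", p)]] <- .sma_grouped(x, day, p)
  }
  out
}

#' Classify the burden trend state of a day
#'
#' A day is in state A when the historical (CMA) AF burden is below the
#' sinus threshold (1% of the day by default); otherwise B when the 21-day
#' SMA is trending strictly below the CMA, and C when it is at or above.
#' A C day is upgraded to D when the burden CMA exceeds
#' `trend_d_burden_cma_min` and the activity CMA is below
#' `trend_d_activity_cma_max` (above-average burden with declining patient
#' activity).
#'
#' @param burden_cma,burden_sma21,activity_cma Numeric vectors of equal
#'   length: the day's burden CMA, burden SMA over the largest window, and
#'   activity CMA (minutes/day).
#' @param config A [trend_config()].
#' @return A factor with levels `A`, `B`, `C`, `D`.
#' @examples
#' classify_trend_state(20, 25, 80)   # D
#' classify_trend_state(10, 25, 100)  # A: historical burden under 1%
#' @export
classify_trend_state <- function(burden_cma, burden_sma21, activity_cma,
                                 config = trend_config()) {
  n <- length(burden_cma)
  if (length(burden_sma21) != n || length(activity_cma) != n)
    stop("inputs must have equal length", call. = FALSE)
  if (anyNA(burden_cma) || anyNA(burden_sma21) || anyNA(activity_cma))
    stop("classification refused: undefined moving average ",
         "(day precedes the largest SMA window)", call. = FALSE)
  state <- rep("C", n)
  state[burden_sma21 < burden_cma] <- "B"
  state[state == "C" &
          burden_cma > config$trend_d_burden_cma_min &
          activity_cma < config$trend_d_activity_cma_max] <- "D"
  state[burden_cma < config$sinus_cma_threshold] <- "A"
  factor(state, levels = c("A", "B", "C", "D"))
}

#' Clinical burden threshold indicators
#'
#' `duration_threshold_met()` flags days whose longest continuous AF episode
#' lasted at least one hour (regardless of when the episode started);
#' `quantity_threshold_met()` flags days whose total AF amount reached 72
#' minutes (5% of the day).
#'
#' @param x A numeric vector (`max_continuous_af_min` for duration,
#'   `af_burden_min` for quantity) or a daily-records data frame holding
#'   those columns.
#' @param config A [trend_config()].
#' @return Logical vector.
#' @examples
#' duration_threshold_met(c(59, 60, 1440))  # FALSE TRUE TRUE
#' quantity_threshold_met(c(71, 72))        # FALSE TRUE
#' @export
duration_threshold_met <- function(x, config = trend_config()) {
  if (is.data.frame(x)) x <- x$max_continuous_af_min
  x >= config$duration_threshold_min
}

#' @rdname duration_threshold_met
#' @export
quantity_threshold_met <- function(x, config = trend_config()) {
  if (is.data.frame(x)) x <- x$af_burden_min
  x >= config$quantity_threshold_min
}

#' Per-day trend states and threshold flags for a cohort
#'
#' Classifies every follow-up day on or after the index day (when all SMA
#' windows are filled) into trend state A/B/C/D and evaluates the duration
#' and quantity thresholds. Crossover days are identifiable as changes in
#' `trend_state` between consecutive rows of a patient.
#'
#' @param cohort A forward-filled [icm_cohort()].
#' @param config A [trend_config()].
#' @return A data frame: `patient_id`, `day_offset`, `trend_state` (factor
#'   A-D), `duration_met`, `quantity_met`.
#' @export
flag_days <- function(cohort, config = trend_config()) {
  records <- .assert_contiguous(cohort$records)
  day <- records$day_offset
  pmax_w <- max(config$sma_windows)
  burden_cma <- .cma_grouped(records$af_burden_min, day)
  burden_sma <- .sma_grouped(records$af_burden_min, day, pmax_w)
  activity_cma <- .cma_grouped(records$activity_min, day)
  keep <- day >= max(.INDEX_DAY, pmax_w)
  out <- records[keep, c("patient_id", "day_offset")]
  out$trend_state <- classify_trend_state(burden_cma[keep], burden_sma[keep],
                                          activity_cma[keep], config)
  out$duration_met <- duration_threshold_met(records$max_continuous_af_min[keep],
                                             config)
  out$quantity_met <- quantity_threshold_met(records$af_burden_min[keep],
                                             config)
  rownames(out) <- NULL
  out
}
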