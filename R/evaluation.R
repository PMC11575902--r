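# Holdout validation statistics: the canonical risk day table, incidence
# rates, rate ratios with log-Wald CIs, day-level AUROC (Hanley-McNeil),
# equal-proportion tests, Venn event yield, Poisson rate comparison, and
# time-in-AF distribution summaries.

#' Canonical day-level risk table
#'
#' Joins per-day trend states and threshold flags with event accounting:
#' `event` marks the terminal record day of a patient with a CVH (the day
#' whose diagnostics immediately precede the event), `label` marks the
#' `horizon` days preceding the event (the prediction target).
#'
#' @param cohort A post-inclusion, forward-filled [icm_cohort()].
#' @param flags Day flags from [flag_days()]; computed if omitted.
#' @param config A [trend_config()] (used when computing flags).
#' @param horizon Pre-event labeling window in days.
#' @return Data frame: `patient_id`, `day_offset`, `trend_state`,
#'   `duration_met`, `quantity_met`, `trend_d`, `af_burden_min`, `event`,
#'   `label`.
#' @export
risk_day_table <- function(cohort, flags = NULL, config = trend_config(),
                           horizon = 5) {
  if (is.null(flags)) flags <- flag_days(cohort, config)
  rec <- cohort$records
  key_rec <- paste(rec$patient_id, rec$day_offset)
  key_flag <- paste(flags$patient_id, flags$day_offset)
  ri <- match(key_flag, key_rec)
  if (anyNA(ri)) stop("flags contain days absent from the cohort records",
                      call. = FALSE)
  pat <- cohort$patients
  pi <- match(flags$patient_id, pat$patient_id)
  last_day <- tapply(rec$day_offset, rec$patient_id, max)
  out <- flags
  out$trend_d <- flags$trend_state == "D"
  out$af_burden_min <- rec$af_burden_min[ri]
  out$event <- !is.na(pat$cvh_day[pi]) &
    flags$day_offset == unname(last_day[flags$patient_id])
  cvh <- pat$cvh_day[pi]
  out$label <- !is.na(cvh) & flags$day_offset >= cvh - horizon &
    flags$day_offset <= cvh - 1
  rownames(out) <- NULL
  out
}

#' Incidence rate of events on criterion days
#'
#' An event is attributed to a criterion when any of its `horizon` pre-event
#' days (the `label` days) meets the criterion; the rate divides attributed
#' events by criterion days.
#'
#' @param day_table A [risk_day_table()].
#' @param criterion Name of a logical column of `day_table` (e.g.
#'   `"duration_met"`).
#' @param horizon Unused directly (attribution uses the table's `label`
#'   column); kept for interface symmetry.
#' @return List: `rate`, `events`, `days`.
#' @export
incidence_rate <- function(day_table, criterion, horizon = 5) {
  flag <- day_table[[criterion]]
  if (is.null(flag)) stop("unknown criterion column: ", criterion,
                          call. = FALSE)
  days <- sum(flag)
  if (days == 0)
    stop("criterion flags zero days: incidence rate undefined", call. = FALSE)
  hit <- day_table$label & flag
  events <- length(unique(day_table$patient_id[hit]))
  list(rate = events / days, events = events, days = days)
}

#' Incidence-rate ratio with a log-Wald confidence interval
#'
#' `rr = (a / PT1) / (c / PT0)` with
#' `CI = exp(log rr +/- z * sqrt(1/a + 1/c))`, the standard log-Wald
#' interval for a ratio of Poisson rates with person-time denominators.
#'
#' @param exposed_events,exposed_days Events and person-days in the exposed
#'   stratum.
#' @param reference_events,reference_days Events and person-days in the
#'   reference stratum (reference events must be positive).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `rate_ratio_estimate`: `rr`, `log_rr`,
#'   `ci_low`, `ci_high`, the four counts, and `one_sided` (`TRUE` when the
#'   exposed stratum had zero events and only an upper bound is available).
#' @export
rate_ratio <- function(exposed_events, exposed_days, reference_events,
                       reference_days, conf_level = 0.95) {
  if (reference_events <= 0) stop("reference events must be > 0",
                                  call. = FALSE)
  if (exposed_days <= 0 || reference_days <= 0)
    stop("person-day denominators must be > 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (exposed_events == 0) {
    # zero exposed events: rr 0 with a one-sided upper bound (rule of 3-ish
    # via a 0.5 continuity correction on the exposed count)
    lr <- log((0.5 / exposed_days) / (reference_events / reference_days))
    hi <- exp(lr + z * sqrt(1 / 0.5 + 1 / reference_events))
    est <- list(rr = 0, log_rr = -Inf, ci_low = 0, ci_high = hi,
                exposed_events = exposed_events, exposed_days = exposed_days,
                reference_events = reference_events,
                reference_days = reference_days, one_sided = TRUE)
    return(structure(est, class = "rate_ratio_estimate"))
  }
  lr <- log((exposed_events / exposed_days) /
              (reference_events / reference_days))
  se <- sqrt(1 / exposed_events + 1 / reference_events)
  structure(list(rr = exp(lr), log_rr = lr,
                 ci_low = exp(lr - z * se), ci_high = exp(lr + z * se),
                 exposed_events = exposed_events, exposed_days = exposed_days,
                 reference_events = reference_events,
                 reference_days = reference_days, one_sided = FALSE),
            class = "rate_ratio_estimate")
}

#' @export
print.rate_ratio_estimate <- function(x, ...) {
  cat(sprintf("RR %.3g [95%% CI %.3g-%.3g] (%d/%d vs %d/%d events/days)\n",
              x$rr, x$ci_low, x$ci_high, x$exposed_events, x$exposed_days,
              x$reference_events, x$reference_days))
  invisible(x)
}

#' Per-state incidence-rate ratios versus trend A
#'
#' Day-level exposure accounting: every classified day contributes one day
#' at risk to its state, and an event is counted on its terminal record day
#' (the day whose state carried the hazard). A window-attributed tally
#' (event counted in every state seen during its pre-event `label` window)
#' is reported alongside.
#'
#' @param day_table A [risk_day_table()].
#' @param conf_level Confidence level for the rate-ratio intervals.
#' @return Data frame, one row per state A-D: `days`, `events`, `rate`,
#'   `rr`, `ci_low`, `ci_high` (A is the reference with rr 1), and
#'   `window_events`.
#' @export
estimate_state_rate_ratios <- function(day_table, conf_level = 0.95) {
  states <- levels(day_table$trend_state)
  days <- as.numeric(table(day_table$trend_state))
  events <- vapply(states, function(s)
    sum(day_table$event[day_table$trend_state == s]), numeric(1))
  win <- vapply(states, function(s) {
    hit <- day_table$label & day_table$trend_state == s
    length(unique(day_table$patient_id[hit]))
  }, numeric(1))
  out <- data.frame(state = states, days = days, events = unname(events),
                    rate = unname(events) / days,
                    rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    window_events = unname(win),
                    stringsAsFactors = FALSE)
  a <- out[out$state == "A", ]
  if (a$events > 0) {
    for (s in states) {
      if (s == "A") {
        out[out$state == "A", c("rr", "ci_low", "ci_high")] <- c(1, NA, NA)
        next
      }
      row <- out$state == s
      if (out$days[row] == 0) next
      est <- rate_ratio(out$events[row], out$days[row], a$events, a$days,
                        conf_level)
      out[row, c("rr", "ci_low", "ci_high")] <-
        c(est$rr, est$ci_low, est$ci_high)
    }
  }
  out
}

#' Day-level AUROC with a Hanley-McNeil confidence interval
#'
#' The area under the ROC curve computed as the rank (Mann-Whitney)
#' statistic -- the probability that a positive day outscores a negative
#' day, ties counted one-half -- with the Hanley-McNeil variance for the
#' interval.
#'
#' @param scores Numeric day scores (e.g. the number of criteria met).
#' @param labels Logical pre-event labels.
#' @param conf_level Confidence level.
#' @return List: `auc`, `ci_low`, `ci_high`, `se`, `n_pos`, `n_neg`.
#' @export
day_level_auroc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc, ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se), se = se, n_pos = n1, n_neg = n0)
}

#' Pooled two-sided test for equal proportions
#'
#' Plain pooled z-test (the square of `z` equals the uncorrected chi-square
#' statistic). Degenerate pooled proportions (0 or 1) give `z = 0`,
#' `p = 1`.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List: `z`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("'n1' and 'n2' must be > 0", call. = FALSE)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  denom <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  if (denom == 0) return(list(z = 0, p_value = 1, p1 = p1, p2 = p2))
  z <- (p1 - p2) / sqrt(denom)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

# Printed-ratio helpers used across reports.

#' Event-yield and share arithmetic
#'
#' Small helpers shared by the yield and AUROC reports:
#' `yield_increase_pct()` is the percent increase in detected events that a
#' criterion's exclusive captures add over the events captured by the
#' clinical criteria; `exclusivity_pct()` is the percent of a criterion's
#' days (or events) that no other criterion shares; `relative_change_pct()`
#' is the percent change from one value to another; `days_per_year()` turns
#' a fraction of follow-up days into days per year.
#'
#' @param exclusive_events,clinical_events Event counts.
#' @param exclusive,total Counts for the exclusivity share.
#' @param from,to Values for the relative change.
#' @param fraction Fraction of follow-up days.
#' @return A single number (percent, or days for `days_per_year()`).
#' @export
yield_increase_pct <- function(exclusive_events, clinical_events) {
  if (clinical_events <= 0) stop("'clinical_events' must be > 0",
                                 call. = FALSE)
  100 * exclusive_events / clinical_events
}

#' @rdname yield_increase_pct
#' @export
exclusivity_pct <- function(exclusive, total) {
  if (total <= 0) stop("'total' must be > 0", call. = FALSE)
  100 * exclusive / total
}

#' @rdname yield_increase_pct
#' @export
relative_change_pct <- function(from, to) {
  if (from == 0) stop("'from' must be nonzero", call. = FALSE)
  100 * (to - from) / from
}

#' @rdname yield_increase_pct
#' @export
days_per_year <- function(fraction) 365 * fraction

#' Venn event yield across burden criteria
#'
#' Assigns every captured event to the set of criteria met during its
#' pre-event window and tabulates all exclusive and intersection regions.
#' The percent increase in detection divides the trend-exclusive events by
#' the events captured by the clinical (duration or quantity) criteria.
#' Day-level exclusivity of the trend criterion is reported alongside.
#'
#' @param day_table A [risk_day_table()].
#' @param criteria Named character vector mapping region names to logical
#'   columns; the name `trend` identifies the trend criterion.
#' @return An object of class `yield_report`: `regions` (counts per
#'   criterion combination), `captured_events`, `clinical_events`,
#'   `trend_exclusive_events`, `pct_increase`, `trend_days`,
#'   `trend_exclusive_days`, `day_exclusivity_pct`.
#' @export
venn_event_yield <- function(day_table,
                             criteria = c(duration = "duration_met",
                                          quantity = "quantity_met",
                                          trend = "trend_d")) {
  if (length(criteria) < 1) stop("need at least one criterion", call. = FALSE)
  ev_pat <- unique(day_table$patient_id[day_table$event])
  met <- vapply(criteria, function(col) {
    hit <- day_table$label & day_table[[col]]
    ev_pat %in% unique(day_table$patient_id[hit])
  }, logical(length(ev_pat)))
  met <- matrix(met, nrow = length(ev_pat),
                dimnames = list(NULL, names(criteria)))
  combo <- apply(met, 1, function(r)
    if (any(r)) paste(names(criteria)[r], collapse = "+") else "none")
  regions <- table(factor(combo, levels = c(
    unlist(lapply(seq_along(criteria), function(k)
      apply(utils::combn(names(criteria), k), 2, paste, collapse = "+"))),
    "none")))
  captured <- sum(regions[names(regions) != "none"])
  clin <- setdiff(names(criteria), "trend")
  clinical_events <- if (length(clin))
    sum(rowSums(met[, clin, drop = FALSE]) > 0) else 0
  trend_excl <- if ("trend" %in% names(criteria))
    sum(met[, "trend"] & rowSums(met[, clin, drop = FALSE]) == 0) else 0
  pct <- if (clinical_events > 0) yield_increase_pct(trend_excl,
                                                     clinical_events) else
    NA_real_
  trend_days <- if ("trend" %in% names(criteria))
    sum(day_table[[criteria[["trend"]]]]) else NA_integer_
  trend_excl_days <- if ("trend" %in% names(criteria) && length(clin))
    sum(day_table[[criteria[["trend"]]]] &
          !Reduce(`|`, lapply(clin, function(cn) day_table[[criteria[[cn]]]])))
  else NA_integer_
  structure(list(
    regions = regions, captured_events = captured,
    clinical_events = clinical_events,
    trend_exclusive_events = trend_excl, pct_increase = pct,
    trend_days = trend_days, trend_exclusive_days = trend_excl_days,
    day_exclusivity_pct = if (!is.na(trend_days) && trend_days > 0)
      exclusivity_pct(trend_excl_days, trend_days) else NA_real_),
    class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  cat("Event yield by burden criteria\n")
  print(x$regions)
  cat(sprintf("captured %d events; trend-exclusive %d; +%.1f%% over %d clinical\n",
              x$captured_events, x$trend_exclusive_events, x$pct_increase,
              x$clinical_events))
  if (!is.na(x$day_exclusivity_pct))
    cat(sprintf("trend days mutually exclusive to clinical thresholds: %.1f%% (%d/%d)\n",
                x$day_exclusivity_pct, x$trend_exclusive_days, x$trend_days))
  invisible(x)
}

#' Poisson comparison of criterion event rates
#'
#' Fits a log-linear rate model with one indicator per criterion and a log
#' person-days offset (IRLS via `glm`), then Wald-tests every pairwise
#' coefficient difference for equality.
#'
#' @param criteria Character vector of criterion names.
#' @param events,days Event and person-day counts per criterion.
#' @return List: `coefficients` (log rates), `se`, `pairwise` (data frame
#'   with `diff`, `z`, `p_value` per pair), `converged`, `iterations`.
#' @export
poisson_rate_comparison <- function(criteria, events, days) {
  if (length(criteria) < 2 || any(days <= 0))
    stop("need >= 2 criteria with positive person-days", call. = FALSE)
  dat <- data.frame(criterion = factor(criteria, levels = criteria),
                    events = events, days = days)
  fit <- glm(events ~ 0 + criterion + offset(log(days)),
             family = poisson(), data = dat)
  if (!fit$converged)
    warning("Poisson rate model did not converge after ", fit$iter,
            " IRLS iterations")
  cf <- coef(fit)
  names(cf) <- criteria
  vc <- diag(vcov(fit))
  pairs <- utils::combn(criteria, 2)
  pw <- data.frame(
    a = pairs[1, ], b = pairs[2, ],
    diff = cf[pairs[1, ]] - cf[pairs[2, ]],
    stringsAsFactors = FALSE)
  pw$z <- pw$diff / sqrt(vc[match(pw$a, criteria)] + vc[match(pw$b, criteria)])
  pw$p_value <- 2 * stats::pnorm(-abs(pw$z))
  rownames(pw) <- NULL
  list(coefficients = cf, se = sqrt(vc), pairwise = pw,
       converged = fit$converged, iterations = fit$iter)
}

#' Time-in-AF distribution by burden criterion
#'
#' Quartiles of the daily AF amount (hours) over each criterion's days, and
#' the fraction of those days belonging to persistent-phenotype patients.
#'
#' @param day_table A [risk_day_table()].
#' @param phenotypes Data frame `patient_id`, `phenotype` (from
#'   [classify_af_phenotype()]); omit to skip the persistent fraction.
#' @param criteria Named character vector of logical columns.
#' @return Data frame: one row per criterion with `days`, `q25`, `median`,
#'   `q75` (hours), `persistent_day_pct`.
#' @export
time_in_af_distribution <- function(day_table, phenotypes = NULL,
                                    criteria = c(duration = "duration_met",
                                                 quantity = "quantity_met",
                                                 trend = "trend_d")) {
  pers <- if (!is.null(phenotypes))
    day_table$patient_id %in%
      phenotypes$patient_id[phenotypes$phenotype == "persistent"] else NULL
  rows <- lapply(names(criteria), function(nm) {
    flag <- day_table[[criteria[[nm]]]]
    if (sum(flag) == 0)
      return(data.frame(criterion = nm, days = 0, q25 = NA_real_,
                        median = NA_real_, q75 = NA_real_,
                        persistent_day_pct = NA_real_))
    h <- day_table$af_burden_min[flag] / 60
    q <- quantile(h, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(criterion = nm, days = sum(flag), q25 = q[1], median = q[2],
               q75 = q[3],
               persistent_day_pct = if (is.null(pers)) NA_real_ else
                 100 * mean(pers[flag]))
  })
  do.call(rbind, rows)
}

#' Full holdout validation report
#'
#' Computes, on a holdout cohort with frozen trend thresholds: follow-up
#' totals, per-state incidence-rate ratios versus trend A, rate ratios for
#' the duration/quantity thresholds and the triple intersection with the
#' trend criterion, day-level AUROC of the 2-criterion (duration +
#' quantity) and 3-criterion (adding the trend) day scores, the Venn event
#' yield, the Poisson rate comparison, incidence rates per criterion, and
#' time-in-AF distributions.
#'
#' @param cohort A post-inclusion, forward-filled holdout [icm_cohort()].
#' @param config The frozen [trend_config()].
#' @param horizon Pre-event window in days.
#' @return An object of class `holdout_report`.
#' @export
evaluate_holdout <- function(cohort, config = trend_config(), horizon = 5) {
  flags <- flag_days(cohort, config)
  dt <- risk_day_table(cohort, flags, config, horizon)
  fu <- follow_up_summary(cohort)
  degenerate <- sum(dt$event) == 0
  states <- if (!degenerate) estimate_state_rate_ratios(dt) else NULL

  crit_rr <- NULL
  if (!degenerate) {
    a_days <- sum(dt$trend_state == "A")
    a_events <- sum(dt$event[dt$trend_state == "A"])
    one <- function(flag, nm) {
      d <- sum(flag)
      if (d == 0 || a_events == 0)
        return(data.frame(criterion = nm, days = d, events = NA, rr = NA,
                          ci_low = NA, ci_high = NA))
      est <- rate_ratio(sum(dt$event[flag]), d, a_events, a_days)
      data.frame(criterion = nm, days = d, events = est$exposed_events,
                 rr = est$rr, ci_low = est$ci_low, ci_high = est$ci_high)
    }
    crit_rr <- rbind(
      one(dt$duration_met, "duration"),
      one(dt$quantity_met, "quantity"),
      one(dt$trend_d, "trend"),
      one(dt$duration_met & dt$quantity_met, "duration+quantity"),
      one(dt$duration_met & dt$quantity_met & dt$trend_d,
          "duration+quantity+trend"))
  }

  score2 <- dt$duration_met + dt$quantity_met
  score3 <- score2 + dt$trend_d
  aurocs <- if (any(dt$label) && !all(dt$label)) {
    a2 <- day_level_auroc(score2, dt$label)
    a3 <- day_level_auroc(score3, dt$label)
    list(clinical = a2, with_trend = a3,
         relative_increase_pct = relative_change_pct(a2$auc, a3$auc))
  } else NULL

  yield <- if (!degenerate) venn_event_yield(dt) else NULL
  inc <- if (!degenerate) {
    lapply(c(duration = "duration_met", quantity = "quantity_met",
             trend = "trend_d"), function(col)
               if (sum(dt[[col]]) > 0) incidence_rate(dt, col) else NULL)
  } else NULL
  pois <- if (!degenerate && !is.null(crit_rr)) {
    sub <- crit_rr[crit_rr$criterion %in% c("duration", "quantity", "trend") &
                     !is.na(crit_rr$events) & crit_rr$days > 0, ]
    if (nrow(sub) >= 2)
      poisson_rate_comparison(sub$criterion, sub$events, sub$days) else NULL
  } else NULL
  phen <- tryCatch(classify_af_phenotype(cohort), error = function(e) NULL)
  taf <- if (!degenerate) time_in_af_distribution(dt, phen) else NULL
  prop_test <- if (!is.null(inc) && !is.null(inc$trend) &&
                   !is.null(inc$quantity))
    two_proportion_test(inc$trend$events, inc$trend$days,
                        inc$quantity$events, inc$quantity$days) else NULL

  structure(list(
    follow_up = fu, degenerate = degenerate, state_rate_ratios = states,
    criterion_rate_ratios = crit_rr, aurocs = aurocs, yield = yield,
    incidence = inc, poisson = pois, time_in_af = taf,
    trend_vs_quantity_rate_test = prop_test,
    n_days = nrow(dt), n_events = sum(dt$event),
    trend_day_fraction = mean(dt$trend_d),
    trend_patient_fraction =
      length(unique(dt$patient_id[dt$trend_d])) /
      length(unique(dt$patient_id))),
    class = "holdout_report")
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf("Holdout validation: %d patients, %d classified days, %d events\n",
              x$follow_up$n_patients, x$n_days, x$n_events))
  if (x$degenerate) {
    cat("  degenerate: no events in holdout\n")
    return(invisible(x))
  }
  s <- x$state_rate_ratios
  for (i in seq_len(nrow(s)))
    cat(sprintf("  trend %s: %6d days, %4d events, RR %s\n", s$state[i],
                s$days[i], s$events[i],
                if (s$state[i] == "A") "1 (reference)" else
                  sprintf("%.2f [%.2f-%.2f]", s$rr[i], s$ci_low[i],
                          s$ci_high[i])))
  if (!is.null(x$aurocs))
    cat(sprintf("  AUROC %.3f -> %.3f with trend criterion (+%.1f%% relative)\n",
                x$aurocs$clinical$auc, x$aurocs$with_trend$auc,
                x$aurocs$relative_increase_pct))
  if (!is.null(x$yield))
    cat(sprintf("  trend-exclusive events: %d (+%.1f%% over clinical criteria)\n",
                x$yield$trend_exclusive_events, x$yield$pct_increase))
  invisible(x)
}
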