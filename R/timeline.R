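# Cohort data model, delimited-text I/O, forward-fill, inclusion rules,
# phenotype classification, and follow-up accounting.

.RECORD_COLS <- c("patient_id", "day_offset", "af_burden_min",
                  "max_continuous_af_min", "activity_min", "vrate_day_bpm",
                  "vrate_night_bpm", "hrv_sd_ms", "observed")
.PATIENT_COLS <- c("patient_id", "indication", "cvh_day", "censor_day")
.VALUE_COLS <- setdiff(.RECORD_COLS, c("patient_id", "day_offset", "observed"))
.INDICATIONS <- c("AF management", "suspected AF", "cryptogenic stroke")

#' Construct an ICM cohort
#'
#' A cohort bundles two tables: one row per patient-day of device
#' diagnostics (`records`) and one row per patient (`patients`). Day
#' offsets are 1-based days since implant; the index day (start of
#' follow-up eligibility) is day 22, the day after the 21-day series
#' initialization window. When a cardiovascular hospitalization (CVH)
#' occurred, `cvh_day` holds its day offset and diagnostic records end the
#' day before it.
#'
#' @param records Data frame with columns `patient_id`, `day_offset`,
#'   `af_burden_min`, `max_continuous_af_min`, `activity_min`,
#'   `vrate_day_bpm`, `vrate_night_bpm`, `hrv_sd_ms`, `observed`.
#'   Unobserved (gap) days may be missing entirely or present with
#'   `observed = FALSE` and `NA` diagnostics.
#' @param patients Data frame with columns `patient_id`, `indication`
#'   (one of "AF management", "suspected AF", "cryptogenic stroke"),
#'   `cvh_day` (`NA` if none), `censor_day`.
#' @return An object of class `icm_cohort`.
#' @export
icm_cohort <- function(records, patients) {
  miss <- setdiff(.RECORD_COLS, names(records))
  if (length(miss))
    stop("records: missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(.PATIENT_COLS, names(patients))
  if (length(miss))
    stop("patients: missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  records <- records[, .RECORD_COLS, drop = FALSE]
  records$day_offset <- as.integer(records$day_offset)
  records$observed <- as.logical(records$observed)
  n <- nrow(records)
  sorted <- !is.unsorted(records$patient_id)
  if (sorted && n > 1) {
    same <- records$patient_id[-1] == records$patient_id[-n]
    sorted <- all(records$day_offset[-1][same] > records$day_offset[-n][same])
    if (sorted && any(records$day_offset[-1][same] ==
                        records$day_offset[-n][same]))
      stop("records: duplicate (patient_id, day_offset) rows", call. = FALSE)
  }
  if (!sorted) {
    records <- records[order(records$patient_id, records$day_offset), ,
                       drop = FALSE]
    if (n > 1) {
      same <- records$patient_id[-1] == records$patient_id[-n]
      if (any(same & records$day_offset[-1] == records$day_offset[-n]))
        stop("records: duplicate (patient_id, day_offset) rows", call. = FALSE)
    }
  }
  if (is.unsorted(patients$patient_id))
    patients <- patients[order(patients$patient_id), , drop = FALSE]
  .validate_record_ranges(records)
  if (anyDuplicated(patients$patient_id))
    stop("patients: duplicate patient_id rows", call. = FALSE)
  extra <- setdiff(unique(records$patient_id), patients$patient_id)
  if (length(extra))
    stop("records contain patients absent from the patient table: ",
         paste(head(extra, 5), collapse = ", "), call. = FALSE)
  rownames(records) <- rownames(patients) <- NULL
  structure(list(records = records, patients = patients),
            class = "icm_cohort")
}

# Trusted fast-path constructor for internal callers that already hold
# sorted, validated tables.
.new_cohort <- function(records, patients) {
  rownames(records) <- rownames(patients) <- NULL
  structure(list(records = records, patients = patients),
            class = "icm_cohort")
}

.validate_record_ranges <- function(records) {
  obs <- which(records$observed)
  bad <- function(cond, what) {
    rows <- obs[which(cond[obs])]
    if (length(rows))
      stop(sprintf("records: %s (row%s %s)", what,
                   if (length(rows) > 1) "s" else "",
                   paste(head(rows, 10), collapse = ", ")), call. = FALSE)
  }
  bad(records$day_offset < 1, "day_offset must be >= 1")
  for (col in c("af_burden_min", "max_continuous_af_min", "activity_min"))
    bad(is.na(records[[col]]) | records[[col]] < 0 | records[[col]] > 1440,
        sprintf("%s out of range [0, 1440] (minutes/day)", col))
  bad(records$max_continuous_af_min > records$af_burden_min,
      "max_continuous_af_min exceeds af_burden_min")
  for (col in c("vrate_day_bpm", "vrate_night_bpm"))
    bad(is.na(records[[col]]) | records[[col]] <= 0,
        sprintf("%s must be > 0", col))
  bad(is.na(records$hrv_sd_ms) | records$hrv_sd_ms < 0,
      "hrv_sd_ms must be >= 0")
  invisible(records)
}

#' @export
print.icm_cohort <- function(x, ...) {
  n_ev <- sum(!is.na(x$patients$cvh_day))
  cat(sprintf("ICM cohort: %d patients, %d patient-days, %d CVH events\n",
              nrow(x$patients), nrow(x$records), n_ev))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An [icm_cohort()].
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

.subset_cohort <- function(cohort, ids) {
  icm_cohort(cohort$records[cohort$records$patient_id %in% ids, , drop = FALSE],
             cohort$patients[cohort$patients$patient_id %in% ids, , drop = FALSE])
}

#' Read / write daily ICM diagnostics
#'
#' Comma-separated UTF-8 text with a header row. The daily table carries the
#' nine record columns, the patient table the four patient columns
#' (`cvh_day` empty when no event occurred). Malformed rows are reported
#' with their row numbers.
#'
#' @param records_path,patients_path File paths for the two tables.
#' @param cohort An [icm_cohort()] (for writing).
#' @return `read_daily_diagnostics()` returns an [icm_cohort()].
#' @export
read_daily_diagnostics <- function(records_path, patients_path) {
  records <- read.csv(records_path, stringsAsFactors = FALSE)
  patients <- read.csv(patients_path, stringsAsFactors = FALSE)
  if (nrow(patients)) {
    patients$cvh_day <- suppressWarnings(as.integer(patients$cvh_day))
    patients$censor_day <- as.integer(patients$censor_day)
  }
  icm_cohort(records, patients)
}

#' @rdname read_daily_diagnostics
#' @export
write_daily_diagnostics <- function(cohort, records_path, patients_path) {
  stopifnot(inherits(cohort, "icm_cohort"))
  write.csv(cohort$records, records_path, row.names = FALSE, na = "")
  write.csv(cohort$patients, patients_path, row.names = FALSE, na = "")
  invisible(c(records_path, patients_path))
}

.locf <- function(x) {
  idx <- cummax(seq_along(x) * !is.na(x))
  if (length(idx) && idx[1] == 0)
    stop("gap precedes any observation: no value to carry forward",
         call. = FALSE)
  x[idx]
}

#' Forward-fill unobserved follow-up days
#'
#' Gaps in daily follow-up are interpolated by carrying the last known value
#' of each diagnostic parameter forward. Days absent from the records are
#' inserted with `observed = FALSE`; observed values are never changed, so
#' the operation is idempotent.
#'
#' @param cohort An [icm_cohort()].
#' @return The cohort with contiguous per-patient records.
#' @export
forward_fill <- function(cohort) {
  stopifnot(inherits(cohort, "icm_cohort"))
  rec <- cohort$records
  n <- nrow(rec)
  if (n == 0) return(cohort)
  # patients needing work: a missing day row or an NA diagnostic value
  new_pat <- c(TRUE, rec$patient_id[-1] != rec$patient_id[-n])
  broken_grid <- !new_pat & rec$day_offset != c(0L, rec$day_offset[-n]) + 1L
  has_na <- rowSums(is.na(rec[, .VALUE_COLS])) > 0
  todo <- unique(rec$patient_id[broken_grid | has_na])
  if (length(todo) == 0) return(cohort)
  keep <- !(rec$patient_id %in% todo)
  pieces <- lapply(split(rec[!keep, , drop = FALSE],
                         rec$patient_id[!keep], drop = TRUE), function(r) {
    days <- seq(min(r$day_offset), max(r$day_offset))
    if (length(days) != nrow(r)) {
      full <- data.frame(patient_id = r$patient_id[1], day_offset = days)
      r <- merge(full, r, by = c("patient_id", "day_offset"), all.x = TRUE)
      r$observed[is.na(r$observed)] <- FALSE
    }
    r <- r[order(r$day_offset), ]
    for (col in .VALUE_COLS) {
      if (anyNA(r[[col]]))
        r[[col]] <- tryCatch(.locf(r[[col]]), error = function(e)
          stop(sprintf("patient %s, %s: %s", r$patient_id[1], col,
                       conditionMessage(e)), call. = FALSE))
    }
    r[, .RECORD_COLS]
  })
  out <- rbind(rec[keep, , drop = FALSE], do.call(rbind, pieces))
  out <- out[order(out$patient_id, out$day_offset), , drop = FALSE]
  .new_cohort(out, cohort$patients)
}

# Maximal runs of unobserved days (missing rows or observed == FALSE),
# evaluated before forward-fill. Returns an integer vector of run lengths.
.gap_runs <- function(r) {
  days <- seq(min(r$day_offset), max(r$day_offset))
  obs <- days %in% r$day_offset[r$observed]
  rl <- rle(!obs)
  rl$lengths[rl$values]
}

#' Apply the cohort inclusion and exclusion rules
#'
#' Retains patients with at least one observed follow-up day of AF burden
#' greater than zero on or after the index day, excludes patients with a gap
#' in daily follow-up of 30 days or more (measured before forward-fill),
#' truncates follow-up at two years (730 days), and — when a CVH is present
#' — truncates the records to the day before the event. Events after day
#' 730 are treated as censoring at day 730 and flagged.
#'
#' @param cohort An [icm_cohort()] (pre-fill: gaps still visible).
#' @param max_follow_up_days Truncation horizon in days (730).
#' @param max_gap_days Exclusion threshold for gaps in daily follow-up.
#' @return A list: `cohort` (the filtered, truncated cohort) and
#'   `exclusions`, a data frame with the single primary `reason` each
#'   dropped patient violated.
#' @export
apply_inclusion <- function(cohort, max_follow_up_days = 730,
                            max_gap_days = 30) {
  stopifnot(inherits(cohort, "icm_cohort"))
  rec <- cohort$records
  pat <- cohort$patients
  pat$post_truncation_event <- rep(FALSE, nrow(pat))
  n <- nrow(rec)
  pid_f <- factor(rec$patient_id, levels = pat$patient_id)

  af_day <- rec$observed & rec$day_offset >= .INDEX_DAY &
    !is.na(rec$af_burden_min) & rec$af_burden_min > 0
  af_ok <- tabulate(pid_f[af_day], nbins = nrow(pat)) > 0

  # gap screen: patients whose observed-day count falls short of their day
  # span, or with explicit unobserved rows, get an exact maximal-run check
  span <- tapply(rec$day_offset, pid_f, function(d) max(d) - min(d) + 1L)
  span[is.na(span)] <- 0L
  n_obs <- tabulate(pid_f[rec$observed], nbins = nrow(pat))
  suspicious <- which(span - n_obs >= max_gap_days)
  gap_bad <- logical(nrow(pat))
  if (length(suspicious)) {
    sub <- rec[as.integer(pid_f) %in% suspicious, , drop = FALSE]
    runs <- vapply(split(sub, factor(sub$patient_id)), function(r)
      max(c(.gap_runs(r), 0L)), numeric(1))
    gap_bad[suspicious] <- runs[pat$patient_id[suspicious]] >= max_gap_days
  }

  reason <- rep(NA_character_, nrow(pat))
  reason[!af_ok] <- "no AT/AF day on or after index"
  reason[af_ok & gap_bad] <- sprintf("gap in daily follow-up >= %d days",
                                     max_gap_days)
  keep_pat <- is.na(reason)

  late <- !is.na(pat$cvh_day) & pat$cvh_day > max_follow_up_days
  pat$post_truncation_event[late] <- TRUE
  pat$cvh_day[late] <- NA_integer_
  end <- ifelse(!is.na(pat$cvh_day), pat$cvh_day - 1L, max_follow_up_days)
  end <- pmin(end, max_follow_up_days)

  keep_row <- keep_pat[as.integer(pid_f)] &
    rec$day_offset <= end[as.integer(pid_f)]
  kept <- rec[keep_row, , drop = FALSE]
  last_day <- tapply(kept$day_offset, factor(kept$patient_id,
                                             levels = pat$patient_id), max)
  pat$censor_day <- as.integer(pmin(ifelse(is.na(last_day), end, last_day),
                                    end))
  out <- .new_cohort(kept, pat[keep_pat, , drop = FALSE])
  list(cohort = out,
       exclusions = data.frame(patient_id = pat$patient_id[!keep_pat],
                               reason = reason[!keep_pat],
                               stringsAsFactors = FALSE))
}

#' Classify the device-detected AF phenotype
#'
#' A patient is persistent when the on-or-after-index burden series contains
#' at least one run of 7 or more consecutive days each with at least 23.5
#' hours (1410 minutes) of AF; otherwise paroxysmal when any day reached the
#' 2-minute detection floor. A series with no detected AF violates the
#' cohort definition and is an error.
#'
#' @param x An [icm_cohort()] or a numeric daily burden series (minutes/day,
#'   taken as already restricted to on-or-after-index days).
#' @param ... Passed to methods.
#' @return For a cohort, a data frame `patient_id`, `phenotype`; for a
#'   numeric series, a single string `"persistent"` or `"paroxysmal"`.
#' @export
classify_af_phenotype <- function(x, ...) UseMethod("classify_af_phenotype")

#' @rdname classify_af_phenotype
#' @param persistent_min Daily minutes defining a persistent day (1410 =
#'   23.5 h).
#' @param persistent_run_days Consecutive persistent days required (7).
#' @param detection_floor_min Device detection floor, minutes (2).
#' @export
classify_af_phenotype.numeric <- function(x, persistent_min = 1410,
                                          persistent_run_days = 7,
                                          detection_floor_min = 2, ...) {
  if (length(x) == 0 || all(x < detection_floor_min))
    stop("no day with device-detected AT/AF at or above the detection ",
         "floor: violates the cohort definition", call. = FALSE)
  rl <- rle(x >= persistent_min)
  if (any(rl$lengths[rl$values] >= persistent_run_days)) "persistent"
  else "paroxysmal"
}

#' @rdname classify_af_phenotype
#' @export
classify_af_phenotype.icm_cohort <- function(x, persistent_min = 1410,
                                             persistent_run_days = 7,
                                             detection_floor_min = 2, ...) {
  # device-detected amounts only: unobserved (gap) days do not count, and
  # runs are evaluated on the observed, on-or-after-index series
  rec <- x$records[x$records$day_offset >= .INDEX_DAY & x$records$observed &
                     !is.na(x$records$af_burden_min), ]
  phen <- vapply(split(rec$af_burden_min, rec$patient_id),
                 classify_af_phenotype.numeric, character(1),
                 persistent_min = persistent_min,
                 persistent_run_days = persistent_run_days,
                 detection_floor_min = detection_floor_min)
  data.frame(patient_id = names(phen), phenotype = unname(phen),
             stringsAsFactors = FALSE)
}

#' Follow-up accounting for a cohort
#'
#' @param cohort A post-inclusion [icm_cohort()].
#' @return A list: total `patient_days`, `n_patients`, `n_events`, mean
#'   follow-up by event status, and gap statistics (patients with at least
#'   one unobserved day, mean maximal-gap length).
#' @export
follow_up_summary <- function(cohort) {
  stopifnot(inherits(cohort, "icm_cohort"))
  rec <- cohort$records
  per <- tapply(rec$day_offset, rec$patient_id, length)
  has_event <- !is.na(cohort$patients$cvh_day)
  per <- per[cohort$patients$patient_id]
  gaps <- unlist(lapply(split(rec, rec$patient_id), .gap_runs))
  list(
    patient_days = nrow(rec),
    n_patients = nrow(cohort$patients),
    n_events = sum(has_event),
    mean_follow_up_event = if (any(has_event)) mean(per[has_event]) else NA_real_,
    mean_follow_up_censored = if (any(!has_event)) mean(per[!has_event]) else NA_real_,
    n_patients_with_gap = sum(tapply(!rec$observed, rec$patient_id, any)),
    mean_gap_days = if (length(gaps)) mean(gaps) else NA_real_,
    n_gaps = length(gaps)
  )
}
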