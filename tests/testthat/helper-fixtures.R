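# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk.

# A single-patient record table from raw daily series (day 1 = day after
# implant). Vitals default to unremarkable constants.
make_records <- function(pid, burden, longest = pmin(burden, burden),
                         activity = rep(120, length(burden)),
                         observed = rep(TRUE, length(burden)),
                         days = seq_along(burden)) {
  data.frame(
    patient_id = pid, day_offset = as.integer(days),
    af_burden_min = burden, max_continuous_af_min = longest,
    activity_min = activity,
    vrate_day_bpm = 75, vrate_night_bpm = 62, hrv_sd_ms = 90,
    observed = observed, stringsAsFactors = FALSE)
}

make_patient <- function(pid, cvh_day = NA_integer_,
                         censor_day = 730L,
                         indication = "AF management") {
  data.frame(patient_id = pid, indication = indication,
             cvh_day = as.integer(cvh_day),
             censor_day = as.integer(censor_day), stringsAsFactors = FALSE)
}

# Cohort with one patient per supplied burden series.
make_cohort <- function(burden_list, cvh = rep(NA_integer_,
                                               length(burden_list)),
                        activity_list = NULL) {
  ids <- sprintf("T%03d", seq_along(burden_list))
  recs <- do.call(rbind, lapply(seq_along(burden_list), function(i) {
    act <- if (is.null(activity_list)) rep(120, length(burden_list[[i]]))
    else activity_list[[i]]
    make_records(ids[i], burden_list[[i]], activity = act)
  }))
  pats <- do.call(rbind, lapply(seq_along(ids), function(i)
    make_patient(ids[i], cvh[i],
                 censor_day = length(burden_list[[i]]))))
  icm_cohort(recs, pats)
}

# Small simulated cohort shared by several tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_patients = 150, max_follow_up_days = 365,
                               seed = 301)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
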