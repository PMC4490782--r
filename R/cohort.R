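# Cohort construction: eligibility, index dates, baseline covariate
# assessment, weekly person-time with censoring.

#' Find eligible subjects
#'
#' Subjects with at least one medical claim whose primary diagnosis belongs
#' to a dementia-role code group and who are at least `min_age` years old at
#' that first dementia claim.
#'
#' @param bundle a `claims_bundle`.
#' @param config a [study_config()].
#' @return data.table (`subject_id`, `first_dementia_day`, `age`,
#'   `birth_year`, `sex`).
#' @export
find_eligible <- function(bundle, config = study_config()) {
  dem_codes <- bundle$code_map[role == "dementia", code]
  dem_claims <- bundle$medical[primary_dx %in% dem_codes]
  if (nrow(dem_claims) == 0L) {
    return(data.table(subject_id = character(0),
                      first_dementia_day = integer(0), age = integer(0),
                      birth_year = integer(0), sex = character(0)))
  }
  first_dem <- dem_claims[, .(first_dementia_day = min(service_day)),
                          by = subject_id]
  out <- merge(first_dem, bundle$subjects, by = "subject_id")
  out[, age := age_at_day(birth_year, first_dementia_day, config)]
  out[age >= config$min_age][order(subject_id)]
}

#' Assign index dates for the untreated arm
#'
#' The index is the earliest outpatient dementia claim whose preceding
#' baseline window (`washout_days`, ending the day before the visit) lies
#' fully inside the study period, is fully enrolled, and contains at least
#' one medical claim. Visits failing the baseline requirement are skipped
#' and the next one evaluated.
#'
#' @param bundle a `claims_bundle`.
#' @param eligible output of [find_eligible()], already restricted to
#'   untreated candidates.
#' @param config a [study_config()].
#' @return data.table (`subject_id`, `index_day`); subjects with no
#'   qualifying visit are absent.
#' @export
assign_untreated_index <- function(bundle, eligible, config = study_config()) {
  dem_codes <- bundle$code_map[role == "dementia", code]
  vis <- bundle$medical[primary_dx %in% dem_codes & setting == "outpatient" &
                          subject_id %in% eligible$subject_id,
                        .(subject_id, d = service_day)]
  if (nrow(vis) == 0L) {
    return(data.table(subject_id = character(0), index_day = integer(0)))
  }
  vis <- unique(vis)[order(subject_id, d)]
  vis[, w_from := d - config$washout_days]
  vis[, w_to := d - 1L]
  vis[, ok := w_from >= config$study_start_day]
  idx <- which(vis$ok)
  if (length(idx)) {
    vis$ok[idx] <- .cs_window_enrolled(bundle$enrollment, vis$subject_id[idx],
                                       vis$w_from[idx], vis$w_to[idx],
                                       config$month_length_days)
  }
  idx <- which(vis$ok)
  if (length(idx)) {
    q <- vis[idx, .(subject_id, d, w_from, w_to)]
    hits <- bundle$medical[q, on = .(subject_id, service_day >= w_from,
                                     service_day <= w_to),
                           nomatch = NULL, .(subject_id, d = i.d)]
    has <- q[unique(hits), on = .(subject_id, d), which = TRUE, nomatch = 0L]
    keep <- rep(FALSE, length(idx))
    keep[has] <- TRUE
    vis$ok[idx] <- keep
  }
  ok_vis <- vis[ok == TRUE]
  if (nrow(ok_vis) == 0L) {
    return(data.table(subject_id = character(0), index_day = integer(0)))
  }
  ok_vis[, .(index_day = min(d)), by = subject_id]
}

#' Assign index dates and arms
#'
#' Treated arm: eligible subjects with an incident exposure course, indexed
#' at the course start. Untreated arm: eligible subjects with no
#' exposure-class dispensing anywhere in the study period, indexed at their
#' first qualifying dementia outpatient visit. Prevalent or non-incident
#' users belong to neither arm.
#'
#' @param bundle a `claims_bundle`.
#' @param courses course table with `is_incident` (from [build_courses()]).
#' @param config a [study_config()].
#' @param eligible optional precomputed [find_eligible()] result.
#' @return data.table (`subject_id`, `arm`, `index_day`, `birth_year`,
#'   `sex`, `course_end_day` for treated).
#' @export
assign_index <- function(bundle, courses, config = study_config(),
                         eligible = NULL) {
  elig <- if (is.null(eligible)) find_eligible(bundle, config) else eligible
  any_expo <- unique(bundle$pharmacy[drug_class == config$exposure_class,
                                     subject_id])
  inc <- as.data.table(courses)[is_incident == TRUE,
                                .(subject_id, index_day = start_day,
                                  course_end_day = end_day)]
  treated <- merge(elig, inc, by = "subject_id")
  treated[, arm := "treated"]

  unt_cand <- elig[!subject_id %in% any_expo]
  unt_idx <- assign_untreated_index(bundle, unt_cand, config)
  untreated <- merge(elig, unt_idx, by = "subject_id")
  untreated[, `:=`(arm = "untreated", course_end_day = NA_integer_)]

  out <- rbind(treated[, .(subject_id, arm, index_day, course_end_day,
                           birth_year, sex)],
               untreated[, .(subject_id, arm, index_day, course_end_day,
                             birth_year, sex)])
  out[order(subject_id)]
}

#' Compute baseline covariates
#'
#' All counts and flags are measured strictly over the baseline window
#' `[index_day - washout_days, index_day - 1]` (index-exclusive).
#' Comorbidity detection uses the primary diagnosis only, for symmetry with
#' outcome detection. `rx_risk_proxy` is the number of distinct drug
#' classes dispensed in baseline, a proxy for pharmacy-based comorbidity
#' scores. `bl_<group>` flags at least one outcome-group claim in baseline.
#'
#' @param bundle a `claims_bundle`.
#' @param indexed output of [assign_index()].
#' @param config a [study_config()].
#' @return data.table: `subject_id`, `arm`, `index_day`, then one column
#'   per baseline covariate (flags coded 0/1).
#' @export
compute_baseline <- function(bundle, indexed, config = study_config()) {
  idx <- as.data.table(indexed)
  bl <- idx[, .(subject_id, arm, index_day, birth_year, sex)]
  bl[, age := age_at_day(birth_year, index_day, config)]
  bl[, sex_male := as.integer(sex == "M")]
  bl[, c("birth_year", "sex") := NULL]
  win <- bl[, .(subject_id, w_from = index_day - config$washout_days,
                w_to = index_day - 1L)]

  md <- bundle$medical[win, on = .(subject_id, service_day >= w_from,
                                   service_day <= w_to),
                       nomatch = NULL,
                       .(subject_id, setting = x.setting,
                         primary_dx = x.primary_dx)]
  cm <- bundle$code_map
  como <- unique(md[cm[role == "comorbidity"], on = .(primary_dx = code),
                    nomatch = NULL, .(subject_id, group_label)])
  como_n <- como[, .(comorbidity_count = .N), by = subject_id]
  util <- md[, .(n_clinic_visits = sum(setting == "outpatient"),
                 n_hospitalizations = sum(setting == "inpatient"),
                 n_ed_visits = sum(setting == "emergency"),
                 hospice = as.integer(any(setting == "hospice")),
                 nursing_home = as.integer(any(setting == "nursing_home"))),
             by = subject_id]
  outc <- unique(md[cm[role == "outcome"], on = .(primary_dx = code),
                    nomatch = NULL, .(subject_id, group_label)])

  ph <- bundle$pharmacy[win, on = .(subject_id, dispense_day >= w_from,
                                    dispense_day <= w_to),
                        nomatch = NULL, .(subject_id, drug_class = x.drug_class)]
  rx <- ph[, .(rx_risk_proxy = uniqueN(drug_class),
               statin = as.integer(any(drug_class == "STATIN"))),
           by = subject_id]

  out <- Reduce(function(a, b) merge(a, b, by = "subject_id", all.x = TRUE),
                list(bl, como_n, util, rx))
  for (g in config$outcome_groups) {
    flagged <- outc[group_label == g, subject_id]
    out[, (paste0("bl_", g)) := as.integer(subject_id %in% flagged)]
  }
  zero_cols <- c("comorbidity_count", "n_clinic_visits", "n_hospitalizations",
                 "n_ed_visits", "hospice", "nursing_home", "rx_risk_proxy",
                 "statin")
  for (cc in zero_cols) set(out, which(is.na(out[[cc]])), cc, 0L)
  out[order(subject_id)]
}

#' Build the weekly person-time table
#'
#' Follow-up runs from week 0 (the index week) to the censor week, the
#' minimum of the death week, the terminal-disenrollment week (a gap never
#' followed by re-enrollment), the study end week, and — for treated
#' subjects under `as_treated` follow-up — the course end week. Weeks
#' falling in temporary enrollment gap months carry `at_risk = FALSE` but
#' follow-up continues. Ties in the censor day resolve in the order death,
#' course end, disenrollment, study end.
#'
#' @param indexed output of [assign_index()].
#' @param bundle a `claims_bundle`.
#' @param config a [study_config()].
#' @param episodes optional episode table ([build_episodes()]); when given,
#'   per-group episode-start (`ep_<group>`) flags are added.
#' @param groups outcome groups to flag (default: all configured).
#' @param subjects optional subject subset.
#' @return list with `indexed` (augmented with `censor_day`, `censor_week`,
#'   `censor_reason`) and `weeks` (one row per subject-week: `subject_id`,
#'   `week`, `at_risk`, `exposed`, flag columns).
#' @export
build_person_weeks <- function(indexed, bundle, config = study_config(),
                               episodes = NULL, groups = NULL,
                               subjects = NULL) {
  if (is.null(groups)) groups <- config$outcome_groups
  idx <- as.data.table(indexed)
  if (!is.null(subjects)) idx <- idx[subject_id %in% subjects]
  if (anyDuplicated(idx$subject_id)) {
    stop("build_person_weeks: overlapping index assignments for subject(s) ",
         paste(head(unique(idx$subject_id[duplicated(idx$subject_id)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  idx <- copy(idx)

  last_en <- bundle$enrollment[, .(last_month = max(end_month)), by = subject_id]
  last_en[, disenroll_day := (last_month + 1L) * config$month_length_days - 1L]
  idx <- merge(idx, last_en[, .(subject_id, disenroll_day)],
               by = "subject_id", all.x = TRUE)
  idx <- merge(idx, bundle$death, by = "subject_id", all.x = TRUE)
  # enrollment reaching the end of the study is not a disenrollment
  idx[is.na(disenroll_day) | disenroll_day >= config$study_end_day,
      disenroll_day := NA_integer_]

  cand <- idx[, .(
    death = fifelse(is.na(death_day), NA_integer_, death_day),
    course_end = fifelse(arm == "treated" & config$followup_mode == "as_treated",
                         course_end_day, NA_integer_),
    disenrollment = disenroll_day,
    study_end = rep(config$study_end_day, .N)
  )]
  m <- as.matrix(cand)
  censor_day <- apply(m, 1L, min, na.rm = TRUE)
  prio <- c("death", "course_end", "disenrollment", "study_end")
  reason <- prio[apply(m[, prio, drop = FALSE] == censor_day, 1L,
                       function(z) which(z)[1L])]
  idx[, censor_day := as.integer(censor_day)]
  idx[, censor_reason := reason]
  idx[, censor_week := day_to_week(censor_day, index_day)]
  dropped <- idx[censor_week < 0L]
  if (nrow(dropped)) {
    warning("build_person_weeks: dropped ", nrow(dropped),
            " subject(s) censored before index")
    idx <- idx[censor_week >= 0L]
  }

  n_w <- idx$censor_week + 1L
  pw <- idx[rep(seq_len(.N), n_w),
            .(subject_id, arm, index_day, censor_day, course_end_day)]
  pw[, week := sequence(n_w) - 1L]
  pw[, d1 := index_day + config$week_length_days * week]
  pw[, d2 := pmin(d1 + config$week_length_days - 1L, censor_day)]
  pw[, m1 := day_to_month(d1, config$month_length_days)]
  pw[, m2 := day_to_month(d2, config$month_length_days)]

  enr_m <- bundle$enrollment[, .(month = seq.int(start_month, end_month)),
                             by = .(subject_id, start_month)][
                               , .(subject_id, month)]
  pw[, `:=`(r1 = FALSE, r2 = FALSE)]
  pw[enr_m, on = .(subject_id, m1 = month), r1 := TRUE]
  pw[enr_m, on = .(subject_id, m2 = month), r2 := TRUE]
  pw[, at_risk := r1 & r2]

  pw[, exposed := FALSE]
  pw[arm == "treated" & !is.na(course_end_day) &
       week <= day_to_week(course_end_day, index_day), exposed := TRUE]

  if (!is.null(episodes)) {
    anchors <- idx[, .(subject_id, anchor_day = index_day)]
    fu <- idx[, .(subject_id, first_week = 0L, last_week = censor_week)]
    eps_w <- episode_starts_to_weeks(episodes, anchors, fu, quiet = TRUE)
    for (g in unique(c(groups, eps_w$group_label))) {
      colnm <- paste0("ep_", g)
      pw[, (colnm) := 0L]
      hits <- eps_w[group_label == g]
      if (nrow(hits)) pw[hits, on = .(subject_id, week), (colnm) := 1L]
    }
  }
  pw[, ep_death := 0L]
  dth <- idx[censor_reason == "death", .(subject_id, week = censor_week)]
  if (nrow(dth)) pw[dth, on = .(subject_id, week), ep_death := 1L]
  pw[, c("d1", "d2", "m1", "m2", "r1", "r2") := NULL]

  list(indexed = idx, weeks = pw[])
}
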