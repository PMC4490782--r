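# Exposure reconstruction: supply timelines, course segmentation, incident
# course selection, weekly exposure coverage.

#' Build drug supply timelines from dispensings
#'
#' Each dispensing contributes `days_supply` supplied days beginning at the
#' later of its dispense day and the day after the previous supply ran out
#' (stockpiling extension: overlapping fills are pushed end-to-end, without
#' cap). Overlapping or adjacent supplied days are merged into maximal
#' disjoint intervals.
#'
#' Vectorized over subjects and drug classes: one timeline per
#' (`subject_id`, `drug_class`) present in the input.
#'
#' @param dispensings data.table of pharmacy claims (`subject_id`,
#'   `dispense_day`, `days_supply`, `drug_class`).
#' @param drug_class optional filter to one class.
#' @return data.table (`subject_id`, `drug_class`, `first_day`, `last_day`)
#'   of inclusive supplied-day intervals, disjoint and sorted within
#'   subject/class.
#' @export
build_supply_timeline <- function(dispensings, drug_class = NULL) {
  dt <- as.data.table(dispensings)
  if (!is.null(drug_class)) {
    cls <- drug_class
    dt <- dt[dt$drug_class %in% cls]
  }
  if (nrow(dt) == 0L) {
    return(data.table(subject_id = character(0), drug_class = character(0),
                      first_day = integer(0), last_day = integer(0)))
  }
  dt <- dt[order(subject_id, drug_class, dispense_day)]
  # supply end after fill i:  E_i = S_i + cummax_j<=i (day_j - 1 - S_{j-1})
  # with S the running sum of days_supply; a closed-form scan of the
  # "start at max(dispense day, previous end + 1)" recursion.
  dt[, `:=`(S = cumsum(as.numeric(days_supply))), by = .(subject_id, drug_class)]
  dt[, E := S + cummax(dispense_day - 1 - (S - days_supply)),
     by = .(subject_id, drug_class)]
  dt[, prev_E := shift(E, fill = NA_real_), by = .(subject_id, drug_class)]
  dt[, new_iv := is.na(prev_E) | dispense_day > prev_E + 1]
  dt[, iv := cumsum(new_iv), by = .(subject_id, drug_class)]
  out <- dt[, .(first_day = dispense_day[1L],
                last_day = as.integer(E[.N])),
            by = .(subject_id, drug_class, iv)]
  out[, iv := NULL]
  out[]
}

#' Segment a supply timeline into drug courses
#'
#' A new course starts at the first supplied day following a zero-supply run
#' of at least `gap_days`; a course ends `tail_days` after its last supplied
#' day (it persists through the first `tail_days` days of the qualifying
#' gap). Optionally truncates course ends at a per-subject cap (death,
#' terminal disenrollment, study end).
#'
#' @param timeline output of [build_supply_timeline()] (one drug class).
#' @param gap_days supply gap defining a course break (default 60).
#' @param tail_days post-supply persistence (default 60).
#' @param end_cap optional data.table (`subject_id`, `cap_day`); course
#'   `end_day` is truncated at `cap_day` and courses starting after it are
#'   dropped.
#' @return data.table (`subject_id`, `course_id`, `start_day`,
#'   `last_supplied_day`, `end_day`), ordered within subject.
#' @export
segment_courses <- function(timeline, gap_days = 60L, tail_days = 60L,
                            end_cap = NULL) {
  tl <- as.data.table(timeline)
  if (nrow(tl) == 0L) {
    return(data.table(subject_id = character(0), course_id = integer(0),
                      start_day = integer(0), last_supplied_day = integer(0),
                      end_day = integer(0)))
  }
  tl <- tl[order(subject_id, first_day)]
  tl[, prev_last := shift(last_day), by = subject_id]
  tl[, new_course := is.na(prev_last) | (first_day - prev_last - 1L) >= gap_days]
  tl[, course_id := cumsum(new_course), by = subject_id]
  out <- tl[, .(start_day = first_day[1L],
                last_supplied_day = last_day[.N]),
            by = .(subject_id, course_id)]
  out[, end_day := last_supplied_day + as.integer(tail_days)]
  if (!is.null(end_cap)) {
    out <- merge(out, as.data.table(end_cap), by = "subject_id", all.x = TRUE)
    out[!is.na(cap_day), end_day := pmin(end_day, cap_day)]
    out <- out[is.na(cap_day) | start_day <= cap_day]
    out[, cap_day := NULL]
  }
  out[]
}

#' Select each subject's incident course
#'
#' The incident course is the first course whose preceding washout window
#' (`washout_days` ending the day before the course starts) (i) lies fully
#' inside the study period, (ii) contains no supplied day of any excluded
#' anti-dementia class, (iii) is fully enrolled (every study-calendar month
#' overlapping the window), and (iv) contains at least one medical claim.
#' Subjects with no qualifying course (prevalent users, unobservable
#' washout) have no incident course.
#'
#' @param courses output of [segment_courses()] for the exposure class.
#' @param excluded_timeline supply intervals for all excluded classes, from
#'   [build_supply_timeline()].
#' @param enrollment normalized enrollment spans.
#' @param medical medical claims table.
#' @param config a [study_config()].
#' @return `courses` with a logical `is_incident` column (at most one TRUE
#'   per subject).
#' @export
select_incident_course <- function(courses, excluded_timeline, enrollment,
                                   medical, config = study_config()) {
  cs <- copy(as.data.table(courses))
  if (nrow(cs) == 0L) {
    cs[, is_incident := logical(0)]
    return(cs[])
  }
  cs[, w_from := start_day - config$washout_days]
  cs[, w_to := start_day - 1L]
  cs[, ok := w_from >= config$study_start_day & start_day <= config$study_end_day]

  ex <- as.data.table(excluded_timeline)
  if (nrow(ex)) {
    hit <- ex[cs[ok == TRUE],
              on = .(subject_id, first_day <= w_to, last_day >= w_from),
              nomatch = NULL, allow.cartesian = TRUE,
              .(subject_id, course_id = i.course_id)]
    if (nrow(hit)) {
      cs[unique(hit), on = .(subject_id, course_id), ok := FALSE]
    }
  }

  idx <- which(cs$ok)
  if (length(idx)) {
    enr_ok <- .cs_window_enrolled(enrollment, cs$subject_id[idx],
                                  cs$w_from[idx], cs$w_to[idx],
                                  config$month_length_days)
    cs$ok[idx] <- enr_ok
  }

  idx <- which(cs$ok)
  if (length(idx)) {
    md <- as.data.table(medical)
    q <- cs[idx, .(subject_id, course_id, w_from, w_to)]
    cl <- md[q, on = .(subject_id, service_day >= w_from, service_day <= w_to),
             nomatch = NULL, .(subject_id, course_id = i.course_id)]
    has_claim <- cs[idx][unique(cl), on = .(subject_id, course_id),
                         which = TRUE, nomatch = 0L]
    keep <- rep(FALSE, length(idx))
    keep[has_claim] <- TRUE
    cs$ok[idx] <- keep
  }

  cs[, is_incident := ok & cumsum(ok) == 1L & seq_len(.N) == which(ok)[1L],
     by = subject_id]
  cs[is.na(is_incident), is_incident := FALSE]
  cs[, c("w_from", "w_to", "ok") := NULL]
  cs[]
}

#' Weekly exposure coverage of a course
#'
#' Flags each analysis week of a course as exposed iff at least one supplied
#' day falls in it, and reports the proportion of covered weeks over the
#' span from the course start week to its final supplied week.
#'
#' @param course one course row (from [segment_courses()]).
#' @param timeline supply intervals for the same subject and class.
#' @param anchor_day day starting week 0 (defaults to the course start day,
#'   making week 0 the index week).
#' @return list with `weeks` (integer vector), `exposed` (logical vector),
#'   `proportion` (fraction of weeks with any supplied day).
#' @export
weekly_exposure <- function(course, timeline, anchor_day = NULL) {
  course <- as.data.table(course)
  stopifnot(nrow(course) == 1L)
  tl <- as.data.table(timeline)
  tl <- tl[subject_id == course$subject_id &
             first_day <= course$last_supplied_day &
             last_day >= course$start_day]
  if (nrow(tl) == 0L) {
    stop("weekly_exposure: course is inconsistent with the supply timeline ",
         "(no supplied days in the course span)", call. = FALSE)
  }
  if (is.null(anchor_day)) anchor_day <- course$start_day
  w0 <- day_to_week(course$start_day, anchor_day)
  w1 <- day_to_week(course$last_supplied_day, anchor_day)
  weeks <- w0:w1
  exposed <- rep(FALSE, length(weeks))
  for (k in seq_len(nrow(tl))) {
    wk <- day_to_week(max(tl$first_day[k], course$start_day), anchor_day)
    wl <- day_to_week(min(tl$last_day[k], course$last_supplied_day), anchor_day)
    exposed[weeks >= wk & weeks <= wl] <- TRUE
  }
  list(weeks = weeks, exposed = exposed, proportion = mean(exposed))
}

# Per-subject censoring cap: min(death day, terminal disenrollment day,
# study end). Terminal disenrollment = end of the last enrolled month when
# enrollment is never re-established before study end.
.cs_censor_cap <- function(bundle, config) {
  subj <- bundle$subjects[, .(subject_id)]
  last_en <- bundle$enrollment[, .(last_month = max(end_month)), by = subject_id]
  last_en[, en_day := (last_month + 1L) * config$month_length_days - 1L]
  cap <- merge(subj, last_en[, .(subject_id, en_day)], by = "subject_id",
               all.x = TRUE)
  cap[is.na(en_day), en_day := config$study_end_day]
  cap <- merge(cap, bundle$death, by = "subject_id", all.x = TRUE)
  cap[, cap_day := pmin(en_day, config$study_end_day)]
  cap[!is.na(death_day), cap_day := pmin(cap_day, death_day)]
  cap[, .(subject_id, cap_day)]
}

#' Reconstruct all exposure-class courses for a bundle
#'
#' Convenience wrapper: builds the exposure-class supply timeline, segments
#' it into courses, truncates course ends at death, terminal disenrollment
#' or study end, and flags each subject's incident course.
#'
#' @param bundle a `claims_bundle`.
#' @param config a [study_config()].
#' @return list with `courses` (with `is_incident`) and `timeline`.
#' @export
build_courses <- function(bundle, config = study_config()) {
  tl <- build_supply_timeline(bundle$pharmacy, config$exposure_class)
  cap <- .cs_censor_cap(bundle, config)
  cs <- segment_courses(tl, config$course_gap_days, config$course_tail_days,
                        end_cap = cap)
  ex_tl <- build_supply_timeline(bundle$pharmacy, config$excluded_classes)
  cs <- select_incident_course(cs, ex_tl, bundle$enrollment, bundle$medical,
                               config)
  list(courses = cs, timeline = tl)
}
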