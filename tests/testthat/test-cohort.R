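cfg <- study_config()

test_that("eligibility needs a dementia primary diagnosis at age 50+", {
  # age 49 at the only dementia claim (born 1954, claim mid-2003)
  b <- make_bundle(medical = md_row("A", 180), birth_year = 1954L)
  expect_identical(nrow(find_eligible(b, cfg)), 0L)

  b2 <- make_bundle(medical = md_row("A", 180), birth_year = 1928L)
  el <- find_eligible(b2, cfg)
  expect_identical(el$first_dementia_day, 180L)
  expect_identical(el$age, 74L) # born mid-1928, claim just before mid-2003

  # a code that is only in a comorbidity group does not qualify
  b3 <- make_bundle(medical = md_row("A", 180, dx = "CM01a"))
  expect_identical(nrow(find_eligible(b3, cfg)), 0L)
})

test_that("untreated index is the first dementia outpatient visit with an
          observed baseline", {
  # visit at day 100 lacks a full observed baseline; day 250 qualifies
  b <- make_bundle(medical = rbind(md_row("A", 100), md_row("A", 250),
                                   md_row("A", 150, dx = "ROUTINE")))
  el <- find_eligible(b, cfg)
  idx <- assign_untreated_index(b, el, cfg)
  expect_identical(idx$index_day, 250L)

  # inpatient-only dementia claims: no index
  b2 <- make_bundle(medical = md_row("A", 250, setting = "inpatient"))
  el2 <- find_eligible(b2, cfg)
  expect_identical(nrow(assign_untreated_index(b2, el2, cfg)), 0L)

  # a qualifying visit with an empty baseline is skipped; the next with a
  # claim in its baseline window is used
  b3 <- make_bundle(medical = rbind(md_row("A", 200), md_row("A", 500)))
  el3 <- find_eligible(b3, cfg)
  # day-200 visit: baseline [20,199] has no claim -> skipped;
  # day-500 visit: baseline [320,499] contains no claim either -> none
  expect_identical(nrow(assign_untreated_index(b3, el3, cfg)), 0L)
  b4 <- make_bundle(medical = rbind(md_row("A", 200), md_row("A", 400),
                                    md_row("A", 500)))
  idx4 <- assign_untreated_index(b4, find_eligible(b4, cfg), cfg)
  # day-400 visit has the day-200 claim in [220,399]... day 200 is outside;
  # but day-500 sees day 400 in [320,499]
  expect_identical(idx4$index_day, 500L)
})

test_that("subjects with any exposure dispensing leave the untreated arm", {
  b <- make_bundle(
    pharmacy = ph_row("A", 700), # non-incident user (washout has no claim)
    medical = rbind(md_row("A", 250), md_row("A", 150, dx = "ROUTINE"),
                    md_row("B", 250), md_row("B", 150, dx = "ROUTINE")),
    subjects = c("A", "B"))
  crs <- build_courses(b, cfg)
  idx <- assign_index(b, crs$courses, cfg)
  expect_identical(idx[arm == "untreated", subject_id], "B")
  expect_false("A" %in% idx$subject_id) # prevalent-like: neither arm
  # no subject in both arms
  expect_identical(anyDuplicated(idx$subject_id), 0L)
})

test_that("baseline covariates are measured index-exclusively over 180 days", {
  b <- make_bundle(
    pharmacy = rbind(ph_row("A", 250, class = "STATIN"),
                     ph_row("A", 100, class = "NARCOTIC")),
    medical = rbind(md_row("A", 250),
                    md_row("A", 100, dx = "CM01a"),
                    md_row("A", 120, dx = "CM01b"),   # same comorbidity group
                    md_row("A", 130, dx = "CM02a"),
                    md_row("A", 140, dx = "ROUTINE"),
                    md_row("A", 150, dx = "ROUTINE", setting = "inpatient"),
                    md_row("A", 160, dx = "GI01"),
                    md_row("A", 170, dx = "ROUTINE", setting = "hospice")))
  idx <- data.table(subject_id = "A", arm = "untreated", index_day = 250L,
                    course_end_day = NA_integer_, birth_year = 1930L,
                    sex = "F")
  bl <- compute_baseline(b, idx, cfg)
  expect_identical(bl$comorbidity_count, 2L)   # 3 claims, 2 distinct groups
  expect_identical(bl$n_clinic_visits, 5L)     # outpatient claims in window
  expect_identical(bl$n_hospitalizations, 1L)
  expect_identical(bl$hospice, 1L)
  expect_identical(bl$statin, 0L)              # dispensed at index day itself
  expect_identical(bl$rx_risk_proxy, 1L)       # narcotic only
  expect_identical(bl$bl_gastrointestinal, 1L)
  expect_identical(bl$bl_hepatic, 0L)
  expect_identical(bl$sex_male, 0L)

  # empty baseline: all counts zero, demographics from attributes
  b2 <- make_bundle(medical = md_row("A", 250))
  bl2 <- compute_baseline(b2, idx, cfg)
  expect_identical(bl2$comorbidity_count, 0L)
  expect_identical(bl2$n_clinic_visits, 0L)
  expect_identical(bl2$statin, 0L)
})

test_that("person weeks censor at death, course end, or terminal
          disenrollment, with gap weeks off risk", {
  # death in week 10 after index
  b <- make_bundle(medical = md_row("A", 250),
                   death = data.table(subject_id = "A", death_day = 320L))
  idx <- data.table(subject_id = "A", arm = "untreated", index_day = 250L,
                    course_end_day = NA_integer_, birth_year = 1930L, sex = "F")
  pw <- build_person_weeks(idx, b, cfg)
  expect_identical(max(pw$weeks$week), 10L)
  expect_identical(pw$indexed$censor_reason, "death")
  expect_identical(pw$indexed$censor_day, 320L)

  # temporary enrollment gap: weeks in gap months off risk, follow-up goes on
  en_gap <- data.table(subject_id = "A", start_month = c(0L, 13L),
                       end_month = c(9L, 35L))
  b2 <- make_bundle(medical = md_row("A", 250), enrollment = en_gap)
  pw2 <- build_person_weeks(idx, b2, cfg)
  expect_identical(pw2$indexed$censor_reason, "study_end")
  gap_days <- c(10L * 30L, 13L * 30L - 1L) # months 10-12 unenrolled
  gap_weeks <- pw2$weeks[at_risk == FALSE, week]
  expect_true(length(gap_weeks) > 0)
  expect_true(all(250L + 7L * gap_weeks + 6L >= gap_days[1] &
                    250L + 7L * gap_weeks <= gap_days[2] + 6L))
  expect_true(max(pw2$weeks$week) > max(gap_weeks)) # continues after gap

  # terminal disenrollment censors
  en_term <- data.table(subject_id = "A", start_month = 0L, end_month = 19L)
  b3 <- make_bundle(medical = md_row("A", 250), enrollment = en_term)
  pw3 <- build_person_weeks(idx, b3, cfg)
  expect_identical(pw3$indexed$censor_reason, "disenrollment")
  expect_identical(pw3$indexed$censor_day, 599L)

  # treated, as-treated mode: censored at course end
  idx_t <- data.table(subject_id = "A", arm = "treated", index_day = 250L,
                      course_end_day = 481L, birth_year = 1930L, sex = "F")
  pw4 <- build_person_weeks(idx_t, b2, cfg)
  expect_identical(pw4$indexed$censor_reason, "course_end")
  expect_identical(max(pw4$weeks$week), day_to_week(481L, 250L))
  expect_true(all(pw4$weeks$exposed))

  # duplicate index rows rejected
  expect_error(build_person_weeks(rbind(idx, idx), b, cfg), "overlapping")
})

test_that("at-risk person-time matches a brute-force day-level count", {
  sim <- shared_sim()
  prep <- prepare_cohort(sim$bundle, sim$config, groups = "gastrointestinal")
  pw <- prep$pweeks
  en <- sim$bundle$enrollment
  take <- head(pw$indexed[order(subject_id)], 40)
  for (k in seq_len(nrow(take))) {
    sid <- take$subject_id[k]
    a <- take$index_day[k]; cd <- take$censor_day[k]
    months <- en[subject_id == sid,
                 unlist(Map(seq.int, start_month, end_month))]
    wk <- day_to_week(a:cd, a)
    ok <- vapply(split(a:cd, wk), function(dd) {
      all(day_to_month(range(dd)) %in% months)
    }, TRUE)
    expect_identical(pw$weeks[subject_id == sid, sum(at_risk)],
                     sum(ok), info = sid)
  }
})
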