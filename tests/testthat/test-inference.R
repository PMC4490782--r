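test_that("incidence densities and confidence intervals follow the rate formulas", {
  r <- incidence_density(10L, 50)
  expect_equal(r$density, 20)
  expect_equal(r$ci_lower, 20 - 1.96 * 20 / sqrt(10))
  expect_equal(r$ci_upper, 20 + 1.96 * 20 / sqrt(10))

  r0 <- incidence_density(0L, 100)
  expect_equal(r0$density, 0)
  expect_equal(r0$ci_lower, 0)
  expect_equal(r0$ci_upper, 3.69) # exact Poisson zero-event bound

  # person-time back-solved from a published-scale example
  expect_equal(incidence_density(78L, 282.6)$density, 27.6, tolerance = 0.01)

  expect_error(incidence_density(5L, 0), "person-time")
})

test_that("incidence is invariant to splitting one subject's follow-up", {
  pw <- data.table(
    subject_id = rep(c("A", "B"), each = 40),
    arm = rep(c("treated", "untreated"), each = 40),
    week = rep(0:39, 2), at_risk = TRUE, exposed = rep(c(TRUE, FALSE), each = 40),
    ep_gastrointestinal = 0L)
  pw[subject_id == "A" & week %in% c(5L, 20L), ep_gastrointestinal := 1L]
  t1 <- incidence_table(pw, "gastrointestinal")
  pw2 <- copy(pw)
  pw2[subject_id == "A" & week >= 20L, subject_id := "A2"] # contiguous split
  t2 <- incidence_table(pw2, "gastrointestinal")
  expect_equal(t1[arm == "treated", incidence_density],
               t2[arm == "treated", incidence_density])
  expect_equal(t1[arm == "treated", n_episodes], t2[arm == "treated", n_episodes])
})

make_pw <- function(n_pairs, weeks = 30L, p_ev = 0.01, p_ev_exposed = p_ev,
                    seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(2 * n_pairs))
  pw <- data.table(
    subject_id = rep(ids, each = weeks),
    arm = rep(rep(c("treated", "untreated"), n_pairs), each = weeks),
    week = rep(0:(weeks - 1L), 2 * n_pairs),
    at_risk = TRUE)
  pw[, exposed := arm == "treated"]
  pw[, ep_gastrointestinal := rbinom(.N, 1L, fifelse(exposed, p_ev_exposed, p_ev))]
  # thin flags closer than 4 weeks apart within subject, as episodes would be
  pw[, ep_gastrointestinal := {
    x <- ep_gastrointestinal
    last <- -10L
    for (k in seq_along(x)) {
      if (x[k] == 1L) { if (week[k] - last < 4L) x[k] <- 0L else last <- week[k] }
    }
    x
  }, by = subject_id]
  pw
}

test_that("stratified Cox with all pairs in one stratum equals the
          unstratified fit, and matches an independent Newton solver", {
  pw <- make_pw(60, p_ev = 0.02, p_ev_exposed = 0.05, seed = 21)
  pairs1 <- data.table(subject_id = unique(pw$subject_id), pair_id = 1L)
  h_strat1 <- fit_stratified_cox(pw, "gastrointestinal", pairs = pairs1,
                                 variance = "model")
  h_crude <- fit_stratified_cox(pw, "gastrointestinal", variance = "model")
  expect_equal(h_strat1$hr, h_crude$hr, tolerance = 1e-8)

  # independent small-instance Newton maximizer of the same partial likelihood
  ci <- claimsignal:::.cs_counting_intervals(pw, "ep_gastrointestinal")
  pairs2 <- data.table(subject_id = unique(pw$subject_id),
                       pair_id = rep(seq_len(60), each = 2))
  h_strat <- fit_stratified_cox(pw, "gastrointestinal", pairs = pairs2)
  d <- merge(ci, pairs2, by = "subject_id")
  d[, x := as.numeric(exposed)]
  setnames(d, "pair_id", "stratum")
  expect_equal(h_strat$coef, oracle_cox_coef(d), tolerance = 1e-6)
  expect_equal(h_crude$coef,
               oracle_cox_coef(copy(d)[, stratum := 1L]), tolerance = 1e-6)
  expect_gt(h_strat$hr, 1) # doubled-rate design
  expect_true(h_strat$ci_lower <= h_strat$hr & h_strat$hr <= h_strat$ci_upper)
})

test_that("degenerate Cox inputs are flagged or rejected", {
  pw <- make_pw(4, weeks = 10L, p_ev = 0, seed = 3)
  expect_error(fit_stratified_cox(pw, "gastrointestinal"), "no events")

  # one stratum, treated event only: monotone likelihood flagged
  pw2 <- make_pw(1, weeks = 10L, p_ev = 0, seed = 4)
  pw2[arm == "treated" & week == 3L, ep_gastrointestinal := 1L]
  pairs <- data.table(subject_id = unique(pw2$subject_id), pair_id = 1L)
  h <- fit_stratified_cox(pw2, "gastrointestinal", pairs = pairs)
  expect_true(h$monotone)
  expect_identical(h$ci_upper, Inf)
})

test_that("case-crossover windows anchor on the last qualifying clinic
          visit and respect eligibility", {
  cfg <- study_config()
  # clinic visits at weeks -20 and -9 relative to the fill week
  b <- make_bundle(
    pharmacy = ph_row("A", 400),
    medical = rbind(md_row("A", 250),
                    md_row("A", 400 - 20 * 7, dx = "ROUTINE"),
                    md_row("A", 400 - 9 * 7, dx = "ROUTINE"),
                    md_row("A", 150, dx = "ROUTINE")))
  crs <- build_courses(b, cfg)
  win <- build_windows(b, crs$courses, cfg)
  pre <- win[window == "pre"]
  expect_identical(pre$start_week, -8L) # week after visit at -9
  expect_identical(pre$end_week, -3L)
  expect_identical(win[window == "w1", c(start_week, end_week)], c(0L, 5L))
  expect_identical(win[window == "w2", c(start_week, end_week)], c(6L, 11L))
  expect_true(all(win$eligible))

  # death in week 8: pre and w1 observable, w2 not
  b2 <- make_bundle(
    pharmacy = ph_row("A", 400),
    medical = rbind(md_row("A", 250), md_row("A", 400 - 9 * 7, dx = "ROUTINE"),
                    md_row("A", 150, dx = "ROUTINE")),
    death = data.table(subject_id = "A", death_day = 400L + 8L * 7L))
  crs2 <- build_courses(b2, cfg)
  win2 <- build_windows(b2, crs2$courses, cfg)
  expect_true(win2[window == "pre", eligible])
  expect_true(win2[window == "w1", eligible])
  expect_false(win2[window == "w2", eligible])

  # two same-group claims inside w1 cap at one event
  b3 <- make_bundle(
    pharmacy = ph_row("A", 400),
    medical = rbind(md_row("A", 250), md_row("A", 150, dx = "ROUTINE"),
                    md_row("A", 405, dx = "GI01"), md_row("A", 420, dx = "GI02")))
  crs3 <- build_courses(b3, cfg)
  win3 <- build_windows(b3, crs3$courses, cfg)
  expect_identical(win3[window == "w1", ev_gastrointestinal], 1L)
  # no qualifying pre-visit (all visits within 6 weeks of the fill): no pre row
  b4 <- make_bundle(
    pharmacy = ph_row("A", 400),
    medical = rbind(md_row("A", 395), md_row("A", 398, dx = "ROUTINE")))
  crs4 <- build_courses(b4, cfg)
  win4 <- build_windows(b4, crs4$courses, cfg)
  expect_identical(nrow(win4[window == "pre"]), 0L)
})

make_windows <- function(n, p_t, p_p, seed) {
  set.seed(seed)
  ids <- sprintf("W%04d", seq_len(n))
  rbind(
    data.table(subject_id = ids, window = "pre", start_week = -8L,
               end_week = -3L, eligible = TRUE,
               ev_gastrointestinal = rbinom(n, 1L, p_p)),
    data.table(subject_id = ids, window = "w1", start_week = 0L,
               end_week = 5L, eligible = TRUE,
               ev_gastrointestinal = rbinom(n, 1L, p_t)),
    data.table(subject_id = ids, window = "w2", start_week = 6L,
               end_week = 11L, eligible = TRUE,
               ev_gastrointestinal = rbinom(n, 1L, p_p))
  )
}

test_that("crossover odds ratio is the discordant-pair ratio with Wald
          interval", {
  w <- make_windows(200, 0.10, 0.05, seed = 31)
  x <- crossover_or(w, "gastrointestinal", "w1_vs_pre")
  n10 <- x$n10; n01 <- x$n01
  expect_equal(x$or, n10 / n01)
  expect_equal(x$ci_lower, exp(log(n10 / n01) - 1.96 * sqrt(1 / n10 + 1 / n01)))
  expect_equal(x$ci_upper, exp(log(n10 / n01) + 1.96 * sqrt(1 / n10 + 1 / n01)))

  # hand-built discordance: n10 = 4, n01 = 2 -> OR 2; 5/5 -> OR 1
  w2 <- rbind(
    data.table(subject_id = sprintf("a%02d", 1:10), window = "pre",
               start_week = -8L, end_week = -3L, eligible = TRUE,
               ev_gastrointestinal = c(rep(0L, 4), rep(1L, 2), 1L, 0L, 0L, 1L)),
    data.table(subject_id = sprintf("a%02d", 1:10), window = "w1",
               start_week = 0L, end_week = 5L, eligible = TRUE,
               ev_gastrointestinal = c(rep(1L, 4), rep(0L, 2), 1L, 0L, 0L, 1L))
  )
  x2 <- crossover_or(w2, "gastrointestinal", "w1_vs_pre")
  expect_identical(c(x2$n10, x2$n01), c(4L, 2L))
  expect_equal(x2$or, 2)
  w3 <- copy(w2)
  w3[1:10, ev_gastrointestinal := c(rep(1L, 5), rep(0L, 5))]
  w3[11:20, ev_gastrointestinal := c(rep(0L, 5), rep(1L, 5))]
  x3 <- crossover_or(w3, "gastrointestinal", "w1_vs_pre")
  expect_equal(x3$or, 1)

  # all concordant: undefined, warned
  w4 <- copy(w2)
  w4[, ev_gastrointestinal := rep(c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L), 2)]
  expect_warning(x4 <- crossover_or(w4, "gastrointestinal", "w1_vs_pre"),
                 "concordant")
  expect_true(is.na(x4$or))

  # degenerate: no pre-only discordants -> one-sided exact bound
  w5 <- copy(w2)
  w5[window == "pre", ev_gastrointestinal := 0L]
  w5[window == "w1", ev_gastrointestinal := c(rep(1L, 3), rep(0L, 7))]
  expect_warning(x5 <- crossover_or(w5, "gastrointestinal", "w1_vs_pre"),
                 "one-sided")
  expect_identical(x5$or, Inf)
  expect_true(is.finite(x5$ci_lower) && x5$ci_lower > 0)
})

test_that("ineligible windows drop out of the crossover contrast", {
  w <- make_windows(50, 0.3, 0.1, seed = 41)
  w[window == "w1" & subject_id %in% sprintf("W%04d", 1:25), eligible := FALSE]
  x <- crossover_or(w, "gastrointestinal", "w1_vs_pre")
  expect_identical(x$n_pairs, 25L)
})
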