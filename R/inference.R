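# Estimation: incidence densities, pair-stratified recurrent-event Cox
# hazard ratios, case-crossover conditional odds ratios.

#' Incidence density per 100 person-years
#'
#' Density = 100 x episodes / person-years, with person-years counted as
#' at-risk weeks x 7 / 365.25. The confidence interval is the normal
#' approximation on the rate (`density +/- 1.96 density / sqrt(n)`), with
#' the exact Poisson upper bound substituted when no episodes occurred
#' (`[0, 3.69 x 100 / PY]`). The lower bound is clipped at zero.
#'
#' @param n_episodes episode count.
#' @param person_years person-time at risk in years.
#' @return list: `n_episodes`, `person_years`, `density`, `ci_lower`,
#'   `ci_upper`.
#' @export
incidence_density <- function(n_episodes, person_years) {
  if (!is.finite(person_years) || person_years <= 0) {
    stop("incidence_density: zero or invalid person-time", call. = FALSE)
  }
  d <- 100 * n_episodes / person_years
  if (n_episodes == 0L) {
    ci <- c(0, 3.69 * 100 / person_years)
  } else {
    half <- 1.96 * d / sqrt(n_episodes)
    ci <- c(max(0, d - half), d + half)
  }
  list(n_episodes = n_episodes, person_years = person_years, density = d,
       ci_lower = ci[1], ci_upper = ci[2])
}

#' Incidence densities by arm for one outcome group
#'
#' Counts episode starts (`ep_<group>` flags) and at-risk person-time on
#' the weekly grid, optionally restricted to a subject subset (e.g. a
#' matched untreated cohort).
#'
#' @param pweeks person-week table from [build_person_weeks()] (element
#'   `weeks`), built with episode flags.
#' @param group outcome group label.
#' @param subjects optional subject subset.
#' @return data.table, one row per arm: `arm`, `n_episodes`,
#'   `person_years`, `incidence_density`, `ci_lower`, `ci_upper`.
#' @export
incidence_table <- function(pweeks, group, subjects = NULL) {
  col <- paste0("ep_", group)
  if (!col %in% names(pweeks)) {
    stop("incidence_table: person-week table lacks episode flags for '",
         group, "'", call. = FALSE)
  }
  pw <- pweeks
  if (!is.null(subjects)) pw <- pw[subject_id %in% subjects]
  agg <- pw[at_risk == TRUE,
            .(n_episodes = sum(.SD[[1L]]),
              person_years = .N * 7 / 365.25),
            by = arm, .SDcols = col]
  agg[, c("incidence_density", "ci_lower", "ci_upper") := {
    r <- Map(incidence_density, n_episodes, person_years)
    .(vapply(r, `[[`, 0, "density"),
      vapply(r, `[[`, 0, "ci_lower"),
      vapply(r, `[[`, 0, "ci_upper"))
  }]
  agg[order(arm)]
}

# collapse a person-week table to counting-process intervals
# (start, stop] in weeks since index, splitting at enrollment gaps,
# episode starts (recurrent events; subject back at risk the next week)
# and exposure changes
.cs_counting_intervals <- function(pw, event_col) {
  dt <- pw[at_risk == TRUE,
           .(subject_id, week, exposed, ev = .SD[[1L]]),
           .SDcols = event_col]
  if (nrow(dt) == 0L) return(dt[, .(subject_id, start = week, stop = week, ev, exposed)][0])
  setorder(dt, subject_id, week)
  dt[, run := cumsum(c(1L, diff(week) != 1L)), by = subject_id]
  dt[, nxt_exp := shift(exposed, type = "lead"), by = .(subject_id, run)]
  dt[, is_last := seq_len(.N) == .N, by = .(subject_id, run)]
  dt[, rs := week[1L], by = .(subject_id, run)]
  b <- dt[ev == 1L | is_last | (!is.na(nxt_exp) & nxt_exp != exposed)]
  b[, stop := week + 1L]
  b[, start := shift(stop), by = .(subject_id, run)]
  b[is.na(start), start := rs]
  b[, .(subject_id, start, stop, ev, exposed)]
}

#' Pair-stratified Cox model with recurrent events
#'
#' Fits the exposure effect by maximizing the stratified Cox partial
#' likelihood on a counting-process layout of the weekly person-time:
#' episode starts are recurrent events, the subject returns to risk the
#' following week, and ties are handled by the Breslow approximation. With
#' matched pairs each pair is one stratum (risk sets form within pairs on
#' the time-since-index scale); the crude analysis is the same fit with a
#' single stratum. A monotone partial likelihood (all events on one arm
#' within every informative stratum) is flagged and reported with an
#' infinite-bound confidence interval.
#'
#' Variance: the single-stratum (crude) fit uses the robust sandwich
#' clustered on subject, guarding against the overdispersion that latent
#' frailty and recurrence induce. The pair-stratified fit instead uses the
#' model-based variance of the conditional partial likelihood: with
#' thousands of two-subject strata the cluster sandwich is systematically
#' anti-conservative (its score residuals shrink within tiny strata),
#' while the stratified partial likelihood is a proper conditional
#' likelihood whose information-based variance is calibrated. Override
#' with `variance`.
#'
#' @param pweeks person-week table (element `weeks` of
#'   [build_person_weeks()]) carrying `ep_<group>` flags.
#' @param group outcome group label.
#' @param pairs optional data.table (`subject_id`, `pair_id`); when given,
#'   the fit is restricted to paired subjects and stratified on `pair_id`.
#' @param analysis label stored in the result (defaults to `"matched"`
#'   when pairs are given, else `"crude"`).
#' @param intervals optional precomputed counting-process intervals (reused
#'   across the crude and matched fits of one outcome).
#' @param variance `"robust"` (cluster sandwich on subject) or `"model"`
#'   (partial-likelihood information); default robust for the crude fit,
#'   model-based for the pair-stratified fit.
#' @return Object of class `hazard_result`: `group`, `analysis`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n_events`, `n_subjects`,
#'   `monotone`, `coef`, `se`.
#' @export
fit_stratified_cox <- function(pweeks, group, pairs = NULL, analysis = NULL,
                               intervals = NULL, variance = NULL) {
  col <- paste0("ep_", group)
  if (is.null(intervals) && !col %in% names(pweeks)) {
    stop("fit_stratified_cox: person-week table lacks episode flags for '",
         group, "'", call. = FALSE)
  }
  if (is.null(analysis)) analysis <- if (is.null(pairs)) "crude" else "matched"
  if (is.null(variance)) variance <- if (is.null(pairs)) "robust" else "model"
  variance <- match.arg(variance, c("robust", "model"))
  ci <- if (is.null(intervals)) .cs_counting_intervals(pweeks, col) else
    copy(intervals)
  if (!is.null(pairs)) {
    ci <- merge(ci, as.data.table(pairs)[, .(subject_id, pair_id)],
                by = "subject_id")
  } else {
    ci[, pair_id := 1L]
  }
  n_events <- sum(ci$ev)
  if (n_events == 0L) {
    stop("fit_stratified_cox: no events for group '", group, "'",
         call. = FALSE)
  }
  fit <- withCallingHandlers(
    if (variance == "robust") {
      survival::coxph(survival::Surv(start, stop, ev) ~ exposed +
                        survival::strata(pair_id),
                      data = ci, cluster = subject_id, ties = "breslow",
                      robust = TRUE)
    } else {
      survival::coxph(survival::Surv(start, stop, ev) ~ exposed +
                        survival::strata(pair_id),
                      data = ci, ties = "breslow")
    },
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(coef(fit)[1L])
  se <- sqrt(diag(fit$var))[1L]
  monotone <- !is.finite(beta) || abs(beta) > 8 || !is.finite(se) || se > 50
  if (monotone) {
    res <- list(group = group, analysis = analysis, hr = exp(beta),
                ci_lower = 0, ci_upper = Inf, p_value = NA_real_,
                n_events = n_events,
                n_subjects = length(unique(ci$subject_id)),
                monotone = TRUE, coef = beta, se = se)
  } else {
    z <- beta / se
    res <- list(group = group, analysis = analysis, hr = exp(beta),
                ci_lower = exp(beta - 1.96 * se),
                ci_upper = exp(beta + 1.96 * se),
                p_value = 2 * pnorm(-abs(z)),
                n_events = n_events,
                n_subjects = length(unique(ci$subject_id)),
                monotone = FALSE, coef = beta, se = se)
  }
  class(res) <- "hazard_result"
  res
}

#' @export
print.hazard_result <- function(x, ...) {
  cat(sprintf("<hazard_result> %s (%s): HR %.3f (95%% CI %.3f-%.3f), p = %.3g, %d events / %d subjects%s\n",
              x$group, x$analysis, x$hr, x$ci_lower, x$ci_upper,
              if (is.na(x$p_value)) NA else x$p_value,
              x$n_events, x$n_subjects,
              if (x$monotone) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Build case-crossover windows for treated subjects
#'
#' Three windows of `window_weeks` weeks on each incident user's grid
#' (week 0 = first-dispensing week): the first treatment window `w1`
#' (weeks 0-5), the second `w2` (weeks 6-11), and a pre-treatment referent
#' window starting the week after the most recent baseline clinic visit
#' (outpatient claim, any condition) that lets the window end before week
#' 0. A window is eligible iff it lies inside the study period and the
#' subject is enrolled and alive through all its weeks; subjects lacking a
#' qualifying pre-visit contribute no pre window. Per group, the event
#' flag is 1 iff at least one primary-diagnosis claim of the group falls
#' in the window (capped at one event per window).
#'
#' @param bundle a `claims_bundle`.
#' @param courses course table with `is_incident`.
#' @param config a [study_config()].
#' @param groups outcome groups to flag (default: all configured).
#' @return data.table, one row per subject x window: `subject_id`,
#'   `window` (pre/w1/w2), `start_week`, `end_week`, `eligible`, and one
#'   `ev_<group>` column per group.
#' @export
build_windows <- function(bundle, courses, config = study_config(),
                          groups = NULL) {
  if (is.null(groups)) groups <- config$outcome_groups
  inc <- as.data.table(courses)[is_incident == TRUE,
                                .(subject_id, anchor_day = start_day)]
  if (nrow(inc) == 0L) {
    stop("build_windows: no incident courses", call. = FALSE)
  }
  ww <- config$window_weeks

  # pre-window anchor: latest baseline outpatient visit with week <= -(ww+1)
  vis <- bundle$medical[setting == "outpatient"][
    inc, on = .(subject_id), nomatch = NULL, allow.cartesian = TRUE,
    .(subject_id, v_week = day_to_week(x.service_day, i.anchor_day),
      anchor_day = i.anchor_day)]
  vis <- vis[v_week <= -(ww + 1L) &
               v_week >= day_to_week(anchor_day - config$washout_days,
                                     anchor_day)]
  pre_anchor <- if (nrow(vis)) {
    vis[, .(pre_start = max(v_week) + 1L), by = subject_id]
  } else {
    data.table(subject_id = character(0), pre_start = integer(0))
  }

  win <- rbind(
    inc[, .(subject_id, anchor_day, window = "w1", start_week = 0L)],
    inc[, .(subject_id, anchor_day, window = "w2", start_week = ww)],
    merge(inc, pre_anchor, by = "subject_id")[
      , .(subject_id, anchor_day, window = "pre", start_week = pre_start)]
  )
  win[, end_week := start_week + ww - 1L]
  win[, start_day := anchor_day + 7L * start_week]
  win[, end_day := anchor_day + 7L * end_week + 6L]

  # eligibility: inside study period, enrolled every overlapping month,
  # alive through the window
  win[, eligible := start_day >= config$study_start_day &
        end_day <= config$study_end_day]
  idx <- which(win$eligible)
  if (length(idx)) {
    win$eligible[idx] <- .cs_window_enrolled(bundle$enrollment,
                                             win$subject_id[idx],
                                             win$start_day[idx],
                                             win$end_day[idx],
                                             config$month_length_days)
  }
  win <- merge(win, bundle$death, by = "subject_id", all.x = TRUE)
  win[!is.na(death_day) & death_day <= end_day, eligible := FALSE]
  win[, death_day := NULL]

  for (g in groups) {
    codes <- bundle$code_map[role == "outcome" & group_label == g, code]
    cl <- bundle$medical[primary_dx %in% codes,
                         .(subject_id, service_day)]
    colnm <- paste0("ev_", g)
    win[, (colnm) := 0L]
    if (nrow(cl)) {
      hits <- cl[win, on = .(subject_id, service_day >= start_day,
                             service_day <= end_day),
                 nomatch = NULL, .(subject_id, window = i.window)]
      win[unique(hits), on = .(subject_id, window), (colnm) := 1L]
    }
  }
  win[, c("anchor_day", "start_day", "end_day") := NULL]
  setorder(win, subject_id, start_week)
  win[]
}

#' Case-crossover odds ratio for one contrast
#'
#' Conditional maximum-likelihood odds ratio over subjects eligible for
#' both windows of the contrast. For this 1:1 paired binary design the
#' conditional estimate is the discordant-pair ratio `n10 / n01` (events
#' in the treatment window only over events in the pre window only);
#' concordant subjects carry no information. The confidence interval is
#' Wald on the log odds ratio, `exp(log(n10/n01) +/- 1.96
#' sqrt(1/n10 + 1/n01))`. When one discordant count is zero the odds
#' ratio is degenerate (0 or infinite) and a one-sided exact conditional
#' bound is reported with a warning; the p-value is then the exact
#' McNemar binomial test.
#'
#' @param windows window table from [build_windows()].
#' @param group outcome group label.
#' @param contrast `"w1_vs_pre"` or `"w2_vs_pre"`.
#' @return Object of class `crossover_result`: `group`, `contrast`, `or`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n10`, `n01`,
#'   `n_events_treatment`, `n_events_pre`, `n_pairs`.
#' @export
crossover_or <- function(windows, group,
                         contrast = c("w1_vs_pre", "w2_vs_pre")) {
  contrast <- match.arg(contrast)
  tw <- if (contrast == "w1_vs_pre") "w1" else "w2"
  col <- paste0("ev_", group)
  if (!col %in% names(windows)) {
    stop("crossover_or: windows lack event flags for '", group, "'",
         call. = FALSE)
  }
  w <- as.data.table(windows)
  et <- w[window == tw & eligible == TRUE, .(subject_id, et = .SD[[1L]]),
          .SDcols = col]
  ep <- w[window == "pre" & eligible == TRUE, .(subject_id, ep = .SD[[1L]]),
          .SDcols = col]
  both <- merge(et, ep, by = "subject_id")
  if (nrow(both) == 0L) {
    stop("crossover_or: no subject eligible for both windows", call. = FALSE)
  }
  n10 <- both[, sum(et == 1L & ep == 0L)]
  n01 <- both[, sum(et == 0L & ep == 1L)]
  m <- n10 + n01

  if (m == 0L) {
    warning("crossover_or: all subjects concordant; odds ratio undefined")
    or <- NA_real_; ci <- c(NA_real_, NA_real_); p <- NA_real_
  } else if (n10 > 0L && n01 > 0L) {
    or <- n10 / n01
    se <- sqrt(1 / n10 + 1 / n01)
    ci <- exp(log(or) + c(-1.96, 1.96) * se)
    p <- 2 * pnorm(-abs(log(or) / se))
  } else {
    p <- stats::binom.test(n10, m, 0.5)$p.value
    if (n01 == 0L) {
      warning("crossover_or: no pre-window-only discordant subjects; ",
              "reporting one-sided exact lower bound")
      piL <- 0.025^(1 / m)
      or <- Inf; ci <- c(piL / (1 - piL), Inf)
    } else {
      warning("crossover_or: no treatment-window-only discordant subjects; ",
              "reporting one-sided exact upper bound")
      piU <- 1 - 0.025^(1 / m)
      or <- 0; ci <- c(0, piU / (1 - piU))
    }
  }
  res <- list(group = group, contrast = contrast, or = or,
              ci_lower = ci[1], ci_upper = ci[2], p_value = p,
              n10 = n10, n01 = n01,
              n_events_treatment = both[, sum(et)],
              n_events_pre = both[, sum(ep)],
              n_pairs = nrow(both))
  class(res) <- "crossover_result"
  res
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf("<crossover_result> %s (%s): OR %.3g (95%% CI %.3g-%.3g), p = %.3g; n10 = %d, n01 = %d, pairs = %d\n",
              x$group, x$contrast, x$or, x$ci_lower, x$ci_upper, x$p_value,
              x$n10, x$n01, x$n_pairs))
  invisible(x)
}
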