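# Synthetic claims generator with known ground truth: confounding by
# indication (latent frailty), per-outcome exposure hazard ratios, episode
# claim bursts, enrollment churn.

#' Default diagnosis code-group map
#'
#' A compact code map with the structure of a grouper dictionary: one
#' dementia group, five outcome groups (gastrointestinal, psychological,
#' respiratory, hematological, hepatic) and ten comorbidity groups. One
#' anemia code belongs to both the hematological outcome group and a
#' comorbidity group, exercising the rule that outcome and comorbidity
#' roles may share codes while dementia and outcome roles may not.
#'
#' @return data.table (`code`, `group_label`, `role`).
#' @export
default_code_map <- function() {
  cm <- rbind(
    data.table(code = sprintf("DEM%02d", 1:5), group_label = "dementia",
               role = "dementia"),
    data.table(code = sprintf("GI%02d", 1:6), group_label = "gastrointestinal",
               role = "outcome"),
    data.table(code = sprintf("PSY%02d", 1:4), group_label = "psychological",
               role = "outcome"),
    data.table(code = "RSP01", group_label = "respiratory", role = "outcome"),
    data.table(code = sprintf("HEM%02d", 1:4), group_label = "hematological",
               role = "outcome"),
    data.table(code = "HEP01", group_label = "hepatic", role = "outcome"),
    data.table(code = c(sprintf("CM%02da", 1:10), sprintf("CM%02db", 1:10)),
               group_label = rep(sprintf("comorb_%02d", 1:10), 2L),
               role = "comorbidity"),
    # anemia: an outcome code that also counts as a comorbidity
    data.table(code = "HEM01", group_label = "comorb_01", role = "comorbidity")
  )
  cm[order(role, group_label, code)]
}

#' Scenario specification for the synthetic-claims generator
#'
#' Defines one simulated study population: subject mix, latent frailty,
#' treatment assignment (confounded by frailty and its observable proxies),
#' per-outcome weekly hazards and true exposure hazard ratios, death
#' process, refill persistence, and enrollment churn. All hazards are
#' weekly Bernoulli probabilities on the 1-week analysis grid.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed; all randomness flows from one generator stream.
#' @param frailty_shape gamma shape (mean fixed at 1); smaller shape means
#'   more heterogeneity.
#' @param age_mean,age_sd,age_range age distribution (years, truncated).
#' @param p_female probability of female sex.
#' @param entry_day_range range of the first dementia visit day.
#' @param treatment_model named logit coefficients for treatment
#'   (`intercept`, `age10`, `comorbidity`, `statin`, `hospice`,
#'   `nursing_home`, `frailty`); frailty enters negatively to make the
#'   untreated group frailer.
#' @param outcome_groups outcome group labels.
#' @param h0 per-outcome baseline weekly hazards.
#' @param frailty_exp per-outcome frailty exponents (hazard multiplied by
#'   `frailty^exp`).
#' @param beta_age10 per-outcome log-hazard effect per decade of age.
#' @param hr per-outcome true exposure hazard ratios; the effect applies
#'   over the exposure era as defined by the course convention (supplied
#'   days plus the course tail), so it coincides with the as-treated
#'   analysis estimand.
#' @param h0_death,frailty_exp_death,hr_death death process parameters;
#'   death risk starts at the entry week.
#' @param transient_multiplier,transient_weeks,transient_group optional
#'   acute effect: the hazard of `transient_group` is multiplied by
#'   `transient_multiplier` during the first `transient_weeks` exposed
#'   weeks only.
#' @param refill_stop_prob per-refill probability of stopping therapy.
#' @param restart_prob probability of one later refill chain after stopping.
#' @param prevalent_frac fraction of treated subjects given an extra
#'   dispensing inside the washout window (prevalent users).
#' @param treat_delay_max maximum days from dementia visit to first fill.
#' @param p_disenroll_month monthly disenrollment probability.
#' @param p_reenroll probability a disenrollment gap is temporary.
#' @param gap_months_max maximum temporary gap length in months.
#' @param n_comorbidity_groups,comorbidity_rate latent comorbidity: each
#'   group is present with probability `1 - exp(-rate * frailty)`.
#' @param comorbidity_claim_rate daily claim rate per present comorbidity.
#' @param clinic_rate_week weekly clinic-visit rate at frailty 1 (visits
#'   scale with frailty, making utilization an observable frailty proxy).
#' @param hosp_rate,ed_rate daily hospitalization and ED visit rates at
#'   frailty 1.
#' @param statin_model,hospice_model,nursing_model logit models
#'   (`intercept`, `frailty`) for the health-status indicator drugs/care.
#' @param extra_rx_prob base probability of each additional confounder drug
#'   class (antidepressant, anxiolytic, narcotic).
#' @param memantine_frac fraction of subjects dispensed the other
#'   anti-dementia class.
#' @param burst_p,burst_max follow-up claim burst per event: 0 to
#'   `burst_max` extra claims, geometric(`burst_p`)-truncated, at 7-21 day
#'   offsets.
#' @param study_start_day,study_end_day study period (inclusive days).
#' @param study_start_year calendar year at day 0.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_subjects = 4000L,
                          seed = 1L,
                          frailty_shape = 2,
                          age_mean = 77, age_sd = 11, age_range = c(45, 99),
                          p_female = 0.72,
                          entry_day_range = c(200L, 850L),
                          treatment_model = c(intercept = -0.7, age10 = -0.1,
                                              comorbidity = -0.08, statin = 0.5,
                                              hospice = -1.0, nursing_home = 0.3,
                                              frailty = -0.6),
                          outcome_groups = c("gastrointestinal", "psychological",
                                             "respiratory", "hematological",
                                             "hepatic"),
                          h0 = c(gastrointestinal = 0.004, psychological = 0.006,
                                 respiratory = 0.005, hematological = 0.003,
                                 hepatic = 0.0008),
                          frailty_exp = c(gastrointestinal = 0.3,
                                          psychological = 0.3, respiratory = 0.4,
                                          hematological = 0.3, hepatic = 0.3),
                          beta_age10 = c(gastrointestinal = 0.1,
                                         psychological = 0.1, respiratory = 0.1,
                                         hematological = 0.1, hepatic = 0.1),
                          hr = c(gastrointestinal = 1, psychological = 1,
                                 respiratory = 1, hematological = 1,
                                 hepatic = 1),
                          h0_death = 0.0035, frailty_exp_death = 0.8,
                          hr_death = 1,
                          transient_multiplier = 1, transient_weeks = 0L,
                          transient_group = "hematological",
                          refill_stop_prob = 0.12, restart_prob = 0.15,
                          prevalent_frac = 0.08, treat_delay_max = 28L,
                          p_disenroll_month = 0.01, p_reenroll = 0.7,
                          gap_months_max = 3L,
                          n_comorbidity_groups = 10L, comorbidity_rate = 0.14,
                          comorbidity_claim_rate = 1 / 60,
                          clinic_rate_week = 0.6,
                          hosp_rate = 0.19 / 180, ed_rate = 0.11 / 180,
                          statin_model = c(intercept = -0.9, frailty = -0.6),
                          hospice_model = c(intercept = -4.5, frailty = 1.5),
                          nursing_model = c(intercept = -2.2, frailty = 0.5),
                          extra_rx_prob = 0.25,
                          memantine_frac = 0.03,
                          burst_p = 0.5, burst_max = 3L,
                          study_start_day = 0L, study_end_day = 1079L,
                          study_start_year = 2003) {
  spec <- mget(names(formals()))
  class(spec) <- "scenario_spec"
  validate_scenario_spec(spec)
  spec
}

#' @rdname scenario_spec
#' @param spec a `scenario_spec` to validate.
#' @export
validate_scenario_spec <- function(spec) {
  stopifnot(spec$n_subjects >= 1L)
  if (!setequal(names(spec$h0), spec$outcome_groups) ||
      !setequal(names(spec$hr), spec$outcome_groups)) {
    stop("scenario_spec: h0 and hr must be named by outcome_groups",
         call. = FALSE)
  }
  haz <- c(spec$h0, death = spec$h0_death)
  if (any(haz <= 0 | haz >= 1)) {
    stop("scenario_spec: degenerate spec — weekly hazards must lie in (0, 1)",
         call. = FALSE)
  }
  peak <- spec$h0 * spec$hr
  peak[spec$transient_group] <- peak[spec$transient_group] *
    max(1, spec$transient_multiplier)
  if (any(peak >= 1) || spec$h0_death * spec$hr_death >= 1) {
    stop("scenario_spec: degenerate spec — weekly hazard reaches 1 under ",
         "exposure", call. = FALSE)
  }
  if (any(spec$hr <= 0) || spec$hr_death <= 0) {
    stop("scenario_spec: hazard ratios must be positive", call. = FALSE)
  }
  probs <- c(spec$p_female, spec$refill_stop_prob, spec$restart_prob,
             spec$prevalent_frac, spec$p_disenroll_month, spec$p_reenroll,
             spec$extra_rx_prob, spec$memantine_frac, spec$burst_p)
  if (any(probs < 0 | probs > 1)) {
    stop("scenario_spec: probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(spec)
}

#' Named scenario presets
#'
#' Four study conditions mirroring the reaction classes a directed
#' surveillance run interrogates:
#' * `null_all` — every exposure hazard ratio 1 (type-I error conditions).
#' * `gi_effect` — gastrointestinal HR 2.0, all others 1 (an expected,
#'   sustained reaction).
#' * `frailty_death` — death HR 1 with strong frailty-treatment and
#'   frailty-death links: the crude death comparison looks protective while
#'   the matched comparison is null (confounding by indication).
#' * `acute_transient` — hematological hazard multiplied by 3 during the
#'   first 6 exposed weeks only (an acute, transient reaction for the
#'   case-crossover design).
#'
#' @param name preset name.
#' @param n_subjects,seed passed to [scenario_spec()].
#' @return A `scenario_spec`.
#' @export
preset <- function(name, n_subjects = 4000L, seed = 1L) {
  switch(
    name,
    null_all = scenario_spec(n_subjects = n_subjects, seed = seed),
    gi_effect = scenario_spec(n_subjects = n_subjects, seed = seed,
                              hr = c(gastrointestinal = 2, psychological = 1,
                                     respiratory = 1, hematological = 1,
                                     hepatic = 1)),
    frailty_death = scenario_spec(
      n_subjects = n_subjects, seed = seed,
      hr_death = 1, h0_death = 0.004, frailty_exp_death = 1.2,
      treatment_model = c(intercept = -0.5, age10 = -0.1, comorbidity = -0.1,
                          statin = 0.5, hospice = -1.5, nursing_home = 0.3,
                          frailty = -1.2)),
    acute_transient = scenario_spec(n_subjects = n_subjects, seed = seed,
                                    transient_multiplier = 3,
                                    transient_weeks = 6L,
                                    transient_group = "hematological"),
    stop("preset: unknown preset '", name, "'; available presets: ",
         "null_all, gi_effect, frailty_death, acute_transient",
         call. = FALSE)
  )
}

# uniform integers in [lo, hi], vectorized over n
.cs_runifint <- function(n, lo, hi) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# first TRUE column index per row (NA when none)
.cs_first_true <- function(m) {
  any_hit <- rowSums(m) > 0
  fc <- max.col(m, ties.method = "first")
  ifelse(any_hit, fc, NA_integer_)
}

#' Simulate a claims bundle with ground truth
#'
#' Generates one study population under a [scenario_spec()]: latent gamma
#' frailty drives comorbidity burden, utilization, hospice and nursing-home
#' care and (negatively) statin use; treatment assignment depends on those
#' observables and on frailty itself; per-outcome latent events follow
#' weekly Bernoulli hazards multiplied by the true exposure hazard ratio
#' during exposure eras; each latent event emits an index claim plus a
#' truncated-geometric burst of follow-up claims, producing the clustered
#' claim structure that episode detection resolves. Claims are only emitted
#' while the subject is alive, enrolled, and inside the study period.
#'
#' Deterministic given `spec$seed`; the caller's RNG state is restored.
#'
#' @param spec a [scenario_spec()].
#' @return list with `bundle` (a `claims_bundle`), `truth` (class
#'   `ground_truth`: `subjects`, `events`, `exposure`, `spec`), and
#'   `config` (the matching [study_config()]).
#' @export
simulate_bundle <- function(spec) {
  validate_scenario_spec(spec)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(spec$seed)

  N <- as.integer(spec$n_subjects)
  end_day <- spec$study_end_day
  W <- day_to_week(end_day) + 1L # weeks 0 .. W-1
  ids <- sprintf("S%06d", seq_len(N))
  code_map <- default_code_map()
  cfg <- study_config(study_start_day = spec$study_start_day,
                      study_end_day = end_day,
                      study_start_year = spec$study_start_year)

  ## --- latent subject attributes -------------------------------------
  frailty <- rgamma(N, shape = spec$frailty_shape, rate = spec$frailty_shape)
  age <- pmin(pmax(round(rnorm(N, spec$age_mean, spec$age_sd)),
                   spec$age_range[1]), spec$age_range[2])
  sex <- ifelse(runif(N) < spec$p_female, "F", "M")
  entry <- .cs_runifint(N, spec$entry_day_range[1], spec$entry_day_range[2])
  birth_year <- floor(spec$study_start_year + entry / 365.25 - 0.5) - age

  statin <- as.integer(runif(N) < plogis(spec$statin_model["intercept"] +
                                           spec$statin_model["frailty"] * frailty))
  hospice <- as.integer(runif(N) < plogis(spec$hospice_model["intercept"] +
                                            spec$hospice_model["frailty"] * frailty))
  nursing <- as.integer(runif(N) < plogis(spec$nursing_model["intercept"] +
                                            spec$nursing_model["frailty"] * frailty))
  G <- spec$n_comorbidity_groups
  p_com <- 1 - exp(-spec$comorbidity_rate * frailty)
  com_hit <- matrix(runif(N * G) < p_com, N, G)
  com_count <- rowSums(com_hit)

  tm <- spec$treatment_model
  lin <- tm["intercept"] + tm["age10"] * (age - spec$age_mean) / 10 +
    tm["comorbidity"] * com_count + tm["statin"] * statin +
    tm["hospice"] * hospice + tm["nursing_home"] * nursing +
    tm["frailty"] * frailty
  assigned_tx <- runif(N) < plogis(lin)

  ## --- enrollment spans (monthly churn) -------------------------------
  last_month <- day_to_month(end_day, cfg$month_length_days)
  spans <- list()
  s <- rep(0L, N)
  active <- rep(TRUE, N)
  while (any(active)) {
    ia <- which(active)
    L <- 1L + rgeom(length(ia), spec$p_disenroll_month)
    end_m <- pmin(s[ia] + L - 1L, last_month)
    spans[[length(spans) + 1L]] <-
      data.table(subject_id = ids[ia], start_month = s[ia], end_month = end_m)
    terminal <- runif(length(ia)) > spec$p_reenroll
    gap <- sample.int(spec$gap_months_max, length(ia), replace = TRUE)
    new_s <- end_m + 1L + gap
    cont <- end_m < last_month & !terminal & new_s <= last_month
    s[ia[cont]] <- new_s[cont]
    active[ia[!cont]] <- FALSE
  }
  enrollment <- rbindlist(spans)
  enrollment <- merge(enrollment,
                      data.table(subject_id = ids, birth_year = birth_year,
                                 sex = sex),
                      by = "subject_id")
  enr_months <- enrollment[, .(month = seq.int(start_month, end_month)),
                           by = .(subject_id, start_month)][, .(subject_id, month)]

  ## --- exposure dispensings -------------------------------------------
  fills <- list()
  tr_idx <- which(assigned_tx)
  run_chain <- function(start_day, subj_idx) {
    rows <- list()
    cur <- start_day
    act <- rep(TRUE, length(subj_idx))
    while (any(act)) {
      ia <- which(act)
      ok <- cur[ia] <= end_day & cur[ia] >= 0L
      if (any(ok)) {
        rows[[length(rows) + 1L]] <-
          data.table(subject_id = ids[subj_idx[ia[ok]]],
                     dispense_day = cur[ia[ok]], days_supply = 30L,
                     drug_class = "ACHEI")
      }
      stop_now <- runif(length(ia)) < spec$refill_stop_prob
      nxt <- cur[ia] + 30L + .cs_runifint(length(ia), -3L, 7L)
      keep <- ok & !stop_now
      cur[ia] <- nxt
      act[ia[!keep]] <- FALSE
    }
    rbindlist(rows)
  }
  if (length(tr_idx)) {
    first_fill <- entry[tr_idx] + .cs_runifint(length(tr_idx), 0L,
                                               spec$treat_delay_max)
    fills[[1L]] <- run_chain(first_fill, tr_idx)
    # one optional later chain (restart: gap may or may not break the course)
    restart <- runif(length(tr_idx)) < spec$restart_prob
    if (any(restart)) {
      last_fill <- fills[[1L]][, .(lf = max(dispense_day)), by = subject_id]
      rs_ids <- ids[tr_idx[restart]]
      lf <- last_fill[match(rs_ids, subject_id), lf]
      has <- !is.na(lf)
      if (any(has)) {
        rs_start <- lf[has] + 30L + .cs_runifint(sum(has), 20L, 160L)
        fills[[2L]] <- run_chain(rs_start, tr_idx[restart][has])
      }
    }
    # prevalent users: an extra dispensing inside the washout window
    prev_u <- runif(length(tr_idx)) < spec$prevalent_frac
    if (any(prev_u)) {
      fills[[length(fills) + 1L]] <-
        data.table(subject_id = ids[tr_idx[prev_u]],
                   dispense_day = entry[tr_idx[prev_u]] -
                     .cs_runifint(sum(prev_u), 30L, 170L),
                   days_supply = 30L, drug_class = "ACHEI")
    }
  }
  achei <- if (length(fills)) rbindlist(fills) else
    data.table(subject_id = character(0), dispense_day = integer(0),
               days_supply = integer(0), drug_class = character(0))

  ## --- true exposure eras (supply + course tail) ----------------------
  if (nrow(achei)) {
    tl <- build_supply_timeline(achei)
    eras <- segment_courses(tl, cfg$course_gap_days, cfg$course_tail_days)
  } else {
    eras <- data.table(subject_id = character(0), course_id = integer(0),
                       start_day = integer(0), last_supplied_day = integer(0),
                       end_day = integer(0))
  }
  E <- matrix(FALSE, N, W)
  if (nrow(eras)) {
    ei <- match(eras$subject_id, ids)
    w1 <- day_to_week(eras$start_day)
    w2 <- day_to_week(pmin(eras$end_day, end_day))
    for (k in seq_len(nrow(eras))) {
      E[ei[k], (w1[k] + 1L):(w2[k] + 1L)] <- TRUE
    }
  }
  TRW <- matrix(FALSE, N, W) # transient (first exposed weeks) indicator
  if (spec$transient_weeks > 0L && nrow(eras)) {
    first_era <- eras[, .(fw = day_to_week(min(start_day))), by = subject_id]
    fi <- match(first_era$subject_id, ids)
    for (k in seq_len(nrow(first_era))) {
      to_w <- min(first_era$fw[k] + spec$transient_weeks - 1L, W - 1L)
      TRW[fi[k], (first_era$fw[k] + 1L):(to_w + 1L)] <- TRUE
    }
    TRW <- TRW & E
  }

  ## --- death (risk starts at entry week) ------------------------------
  entry_week <- day_to_week(entry)
  base_d <- spec$h0_death * frailty^spec$frailty_exp_death
  hz <- matrix(base_d, N, W)
  if (spec$hr_death != 1) hz[E] <- hz[E] * spec$hr_death
  before_entry <- col(hz) - 1L < entry_week
  hz[before_entry] <- 0
  if (any(hz >= 1)) {
    stop("simulate_bundle: degenerate spec — weekly death hazard reached 1",
         call. = FALSE)
  }
  death_col <- .cs_first_true(matrix(runif(N * W), N, W) < hz)
  death_week <- death_col - 1L
  death_day <- ifelse(is.na(death_week), NA_integer_,
                      pmin(7L * death_week + .cs_runifint(N, 0L, 6L), end_day))
  horizon <- ifelse(is.na(death_day), end_day, death_day)

  ## --- latent outcome events ------------------------------------------
  ev_list <- list()
  for (g in spec$outcome_groups) {
    base_g <- spec$h0[[g]] * frailty^spec$frailty_exp[[g]] *
      exp(spec$beta_age10[[g]] * (age - spec$age_mean) / 10)
    hzg <- matrix(base_g, N, W)
    if (spec$hr[[g]] != 1) hzg[E] <- hzg[E] * spec$hr[[g]]
    if (g == spec$transient_group && spec$transient_multiplier != 1 &&
        spec$transient_weeks > 0L) {
      hzg[TRW] <- hzg[TRW] * spec$transient_multiplier
    }
    if (any(hzg >= 1)) {
      stop("simulate_bundle: degenerate spec — weekly hazard for '", g,
           "' reached 1", call. = FALSE)
    }
    hit <- which(matrix(runif(N * W), N, W) < hzg, arr.ind = TRUE)
    if (nrow(hit)) {
      ev_list[[g]] <- data.table(si = hit[, 1L], group_label = g,
                                 week = hit[, 2L] - 1L)
    }
  }
  events <- rbindlist(ev_list)
  if (nrow(events)) {
    events <- events[is.na(death_week[si]) | week <= death_week[si]]
    events[, subject_id := ids[si]]
  } else {
    events <- data.table(si = integer(0), group_label = character(0),
                         week = integer(0), subject_id = character(0))
  }

  ## --- claims emission -------------------------------------------------
  med <- list()
  grp_codes <- split(code_map[role == "outcome", code],
                     code_map[role == "outcome", group_label])
  if (nrow(events)) {
    ev <- copy(events)
    ev[, day := pmin(7L * week + .cs_runifint(.N, 0L, 6L), end_day)]
    ev[, code := {
      cs <- grp_codes[[group_label[1L]]]
      cs[sample.int(length(cs), .N, replace = TRUE)]
    }, by = group_label]
    ev[, setting := sample(c("outpatient", "emergency", "inpatient"), .N,
                           replace = TRUE, prob = c(0.8, 0.1, 0.1))]
    med[["events"]] <- ev[, .(subject_id, service_day = day,
                              primary_dx = code, setting)]
    n_extra <- pmin(rgeom(nrow(ev), spec$burst_p), spec$burst_max)
    if (sum(n_extra)) {
      bi <- rep(seq_len(nrow(ev)), n_extra)
      med[["bursts"]] <- data.table(
        subject_id = ev$subject_id[bi],
        service_day = ev$day[bi] + .cs_runifint(length(bi), 7L, 21L),
        primary_dx = ev$code[bi],
        setting = sample(c("outpatient", "emergency"), length(bi),
                         replace = TRUE, prob = c(0.9, 0.1)))
    }
  }

  dem_codes <- code_map[role == "dementia", code]
  med[["entry"]] <- data.table(subject_id = ids, service_day = entry,
                               primary_dx = sample(dem_codes, N, replace = TRUE),
                               setting = "outpatient")
  # recurring dementia care after entry
  n_dem <- rpois(N, pmax(horizon - entry, 0) / 90)
  di <- rep(seq_len(N), n_dem)
  if (length(di)) {
    med[["dementia"]] <- data.table(
      subject_id = ids[di],
      service_day = entry[di] + ceiling(runif(length(di)) *
                                          pmax(horizon[di] - entry[di], 1)),
      primary_dx = sample(dem_codes, length(di), replace = TRUE),
      setting = "outpatient")
  }

  emit_pois <- function(rate_per_day, setting, dx = "ROUTINE",
                        from_day = rep(0L, N)) {
    len <- pmax(horizon - from_day + 1, 0)
    n <- rpois(N, rate_per_day * len)
    i <- rep(seq_len(N), n)
    if (!length(i)) return(NULL)
    data.table(subject_id = ids[i],
               service_day = from_day[i] +
                 floor(runif(length(i)) * len[i]),
               primary_dx = dx, setting = setting)
  }
  med[["clinic"]] <- emit_pois(spec$clinic_rate_week / 7 * frailty, "outpatient")
  med[["hosp"]] <- emit_pois(spec$hosp_rate * frailty, "inpatient")
  med[["ed"]] <- emit_pois(spec$ed_rate * frailty, "emergency")
  if (any(hospice == 1L)) {
    hr_rate <- ifelse(hospice == 1L, 1 / 30, 0)
    med[["hospice"]] <- emit_pois(hr_rate, "hospice")
  }
  if (any(nursing == 1L)) {
    nh_rate <- ifelse(nursing == 1L, 1 / 30, 0)
    med[["nursing"]] <- emit_pois(nh_rate, "nursing_home")
  }

  # comorbidity claims: one stream per present comorbidity group
  com_idx <- which(com_hit, arr.ind = TRUE)
  if (nrow(com_idx)) {
    si <- com_idx[, 1L]
    gi <- com_idx[, 2L]
    n_cc <- rpois(length(si), spec$comorbidity_claim_rate * (horizon[si] + 1))
    ci <- rep(seq_along(si), n_cc)
    if (length(ci)) {
      med[["comorb"]] <- data.table(
        subject_id = ids[si[ci]],
        service_day = floor(runif(length(ci)) * (horizon[si[ci]] + 1)),
        primary_dx = sprintf("CM%02d%s", gi[ci],
                             sample(c("a", "b"), length(ci), replace = TRUE)),
        setting = "outpatient")
    }
  }

  medical <- rbindlist(med, use.names = TRUE)

  ## --- other pharmacy streams -----------------------------------------
  rx <- list(achei = achei)
  st_idx <- which(statin == 1L)
  if (length(st_idx)) {
    st0 <- pmax(0L, entry[st_idx] - 190L + .cs_runifint(length(st_idx), 0L, 30L))
    n_f <- pmax(0L, (pmin(horizon[st_idx], end_day) - st0) %/% 30L + 1L)
    fi <- rep(seq_along(st_idx), n_f)
    off <- sequence(n_f) - 1L
    rx[["statin"]] <- data.table(subject_id = ids[st_idx[fi]],
                                 dispense_day = st0[fi] + 30L * off,
                                 days_supply = 30L, drug_class = "STATIN")
  }
  mem_idx <- which(runif(N) < spec$memantine_frac)
  if (length(mem_idx)) {
    n_f <- 1L + rpois(length(mem_idx), 2)
    m0 <- .cs_runifint(length(mem_idx), 0L, 900L)
    fi <- rep(seq_along(mem_idx), n_f)
    rx[["memantine"]] <- data.table(subject_id = ids[mem_idx[fi]],
                                    dispense_day = m0[fi] +
                                      30L * (sequence(n_f) - 1L),
                                    days_supply = 30L, drug_class = "MEMANTINE")
  }
  for (cls in c("ANTIDEPRESSANT", "ANXIOLYTIC", "NARCOTIC")) {
    users <- which(runif(N) < plogis(qlogis(spec$extra_rx_prob) +
                                       0.25 * (frailty - 1)))
    if (!length(users)) next
    n_f <- rpois(length(users), (horizon[users] + 1) / 60)
    fi <- rep(seq_along(users), n_f)
    if (!length(fi)) next
    rx[[cls]] <- data.table(subject_id = ids[users[fi]],
                            dispense_day = floor(runif(length(fi)) *
                                                   (horizon[users[fi]] + 1)),
                            days_supply = 30L, drug_class = cls)
  }
  pharmacy <- rbindlist(rx, use.names = TRUE)

  ## --- filters: study period, death, enrollment -----------------------
  enr_mat <- matrix(FALSE, N, last_month + 1L)
  enr_mat[cbind(match(enr_months$subject_id, ids),
                enr_months$month + 1L)] <- TRUE
  filter_claims <- function(dt, day_col) {
    if (nrow(dt) == 0L) return(dt)
    d <- dt[[day_col]]
    si <- match(dt$subject_id, ids)
    keep <- d >= 0L & d <= end_day
    kw <- which(keep)
    ok <- d[kw] <= horizon[si[kw]] &
      enr_mat[cbind(si[kw], d[kw] %/% cfg$month_length_days + 1L)]
    dt[kw[ok]]
  }
  medical <- filter_claims(medical, "service_day")
  pharmacy <- filter_claims(pharmacy, "dispense_day")

  death_dt <- data.table(subject_id = ids, death_day = death_day)[
    !is.na(death_day)]

  bundle <- claims_bundle(pharmacy = pharmacy, medical = medical,
                          enrollment = enrollment, death = death_dt,
                          code_map = code_map, config = cfg,
                          validate = FALSE)

  observed_tx <- ids %in% unique(bundle$pharmacy[drug_class == "ACHEI",
                                                 subject_id])
  truth <- list(
    subjects = data.table(subject_id = ids, frailty = frailty, age = age,
                          sex = sex, entry_day = entry,
                          assigned_treatment = assigned_tx,
                          treated = observed_tx,
                          comorbidity_count = com_count, statin = statin,
                          hospice = hospice, nursing_home = nursing,
                          death_week = death_week, death_day = death_day),
    events = events[, .(subject_id, group_label, week)],
    exposure = eras,
    spec = spec
  )
  class(truth) <- "ground_truth"
  list(bundle = bundle, truth = truth, config = cfg)
}

#' Write a simulated bundle and its ground truth to a directory
#'
#' Writes the four claim CSVs, the code map, and `ground_truth.csv`
#' (per-subject latent fields).
#'
#' @param sim result of [simulate_bundle()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  write_claims_bundle(sim$bundle, dir)
  fwrite(sim$truth$subjects, file.path(dir, "ground_truth.csv"))
  fwrite(sim$truth$events, file.path(dir, "ground_truth_events.csv"))
  invisible(dir)
}
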