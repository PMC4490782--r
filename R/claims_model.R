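# Claims data model: tabular schemas, study configuration, readers/writers.

#' @import data.table
#' @importFrom stats coef glm glm.fit plogis qlogis pchisq pnorm qnorm rbinom
#'   rgamma rgeom rnorm rpois runif sd cov setNames var binomial
#'   t.test chisq.test binom.test
#' @importFrom utils head
#' @importFrom tools md5sum
NULL

.cs_settings <- c("outpatient", "inpatient", "emergency", "hospice", "nursing_home")
.cs_roles <- c("dementia", "outcome", "comorbidity")

.cs_drug_classes <- c(
  "ACHEI", "MEMANTINE", "STATIN", "ANXIOLYTIC", "ANTICONVULSANT",
  "ANTIDEPRESSANT", "ANTIPSYCHOTIC", "NARCOTIC", "SEDATIVE", "STEROID",
  "NSAID", "GASTROPROTECTIVE", "RESPIRATORY_AGENT", "PARKINSONS",
  "ANTICOAGULANT"
)

.cs_base_covariates <- c(
  "age", "sex_male", "comorbidity_count", "rx_risk_proxy",
  "n_clinic_visits", "n_hospitalizations", "n_ed_visits",
  "hospice", "nursing_home", "statin"
)

#' Default per-outcome covariate specification
#'
#' For each clinical outcome the propensity model uses the shared baseline
#' covariate set plus the subject's baseline episode flag for that outcome
#' (`bl_<group>`), which is also the exact-matching constraint. The death
#' analysis matches exactly on baseline hospice care and on age within a
#' +/- `age_band_years` band.
#'
#' @param outcome_groups character vector of outcome group labels.
#' @param age_band_years half-width of the age matching band for death.
#' @return Named list, one element per outcome plus `"death"`, each with
#'   `ps_covariates`, `key_covariates`, `exact_vars`, `band_vars`.
#' @export
default_covariates <- function(outcome_groups, age_band_years = 5) {
  out <- lapply(outcome_groups, function(g) {
    bl <- paste0("bl_", g)
    list(
      ps_covariates = c(.cs_base_covariates, bl),
      key_covariates = c("age", "comorbidity_count"),
      exact_vars = bl,
      band_vars = numeric(0)
    )
  })
  names(out) <- outcome_groups
  out$death <- list(
    ps_covariates = .cs_base_covariates,
    key_covariates = c("age", "comorbidity_count"),
    exact_vars = "hospice",
    band_vars = c(age = age_band_years)
  )
  out
}

#' Study configuration
#'
#' Holds every protocol constant of the design: the washout and course-gap
#' rules used to reconstruct incident drug courses, the episode-of-care gap,
#' the weekly analysis grid, the case-crossover window length, eligibility
#' age, matching caliper, and the per-outcome covariate lists.
#'
#' Days are integer offsets from `study_start_day` (day 0); enrollment
#' months are fixed `month_length_days`-day bins of the study calendar.
#'
#' @param study_start_day,study_end_day integer day bounds (inclusive).
#' @param study_start_year calendar year at day 0, used for age computation.
#' @param washout_days drug-free baseline period length (default 180).
#' @param course_gap_days supply gap that terminates a course (default 60).
#' @param course_tail_days days a course persists past its last supplied day
#'   (default 60).
#' @param episode_gap_days claim-free gap starting a new episode (default 28,
#'   i.e. 4 weeks).
#' @param window_weeks case-crossover window length in weeks (default 6).
#' @param week_length_days length of the discrete person-time unit.
#' @param month_length_days length of one enrollment month.
#' @param min_age minimum age at first dementia claim (default 50).
#' @param exposure_class drug class defining the treated arm.
#' @param excluded_classes classes that must be absent from the washout
#'   window (default: all anti-dementia classes).
#' @param drug_classes the drug-class vocabulary accepted in pharmacy claims.
#' @param outcome_groups outcome group labels expected in the code map.
#' @param caliper_sd propensity caliper in SD units of the logit score.
#' @param age_band_years age matching band for the death analysis.
#' @param followup_mode `"as_treated"` censors treated subjects at course
#'   end; `"full_followup"` does not.
#' @param dx_position `"primary"` (only primary diagnoses drive detection)
#'   or `"any"` when inputs carry secondary codes.
#' @param covariates per-outcome covariate lists; see [default_covariates()].
#' @param seed optional integer seed recorded with the configuration.
#' @return A list of class `study_config`.
#' @export
study_config <- function(study_start_day = 0L,
                         study_end_day = 1079L,
                         study_start_year = 2003,
                         washout_days = 180L,
                         course_gap_days = 60L,
                         course_tail_days = 60L,
                         episode_gap_days = 28L,
                         window_weeks = 6L,
                         week_length_days = 7L,
                         month_length_days = 30L,
                         min_age = 50,
                         exposure_class = "ACHEI",
                         excluded_classes = c("ACHEI", "MEMANTINE"),
                         drug_classes = .cs_drug_classes,
                         outcome_groups = c("gastrointestinal", "psychological",
                                            "respiratory", "hematological",
                                            "hepatic"),
                         caliper_sd = 0.2,
                         age_band_years = 5,
                         followup_mode = c("as_treated", "full_followup"),
                         dx_position = c("primary", "any"),
                         covariates = NULL,
                         seed = NULL) {
  followup_mode <- match.arg(followup_mode)
  dx_position <- match.arg(dx_position)
  if (is.null(covariates)) {
    covariates <- default_covariates(outcome_groups, age_band_years)
  }
  cfg <- list(
    study_start_day = as.integer(study_start_day),
    study_end_day = as.integer(study_end_day),
    study_start_year = study_start_year,
    washout_days = as.integer(washout_days),
    course_gap_days = as.integer(course_gap_days),
    course_tail_days = as.integer(course_tail_days),
    episode_gap_days = as.integer(episode_gap_days),
    window_weeks = as.integer(window_weeks),
    week_length_days = as.integer(week_length_days),
    month_length_days = as.integer(month_length_days),
    min_age = min_age,
    exposure_class = exposure_class,
    excluded_classes = excluded_classes,
    drug_classes = drug_classes,
    outcome_groups = outcome_groups,
    caliper_sd = caliper_sd,
    age_band_years = age_band_years,
    followup_mode = followup_mode,
    dx_position = dx_position,
    covariates = covariates,
    seed = seed
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

#' @rdname study_config
#' @param config a `study_config` to validate.
#' @export
validate_study_config <- function(config) {
  durs <- c("washout_days", "course_gap_days", "course_tail_days",
            "episode_gap_days", "window_weeks", "week_length_days",
            "month_length_days")
  for (d in durs) {
    if (!is.finite(config[[d]]) || config[[d]] <= 0) {
      stop("study_config: '", d, "' must be a positive duration", call. = FALSE)
    }
  }
  if (config$study_end_day <= config$study_start_day) {
    stop("study_config: study_end_day must exceed study_start_day", call. = FALSE)
  }
  if (!config$exposure_class %in% config$drug_classes) {
    stop("study_config: exposure_class not in drug_classes vocabulary", call. = FALSE)
  }
  computable <- c(.cs_base_covariates, paste0("bl_", config$outcome_groups))
  for (lbl in names(config$covariates)) {
    cv <- config$covariates[[lbl]]
    nm <- unique(c(cv$ps_covariates, cv$key_covariates, cv$exact_vars,
                   names(cv$band_vars)))
    bad <- setdiff(nm, computable)
    if (length(bad)) {
      stop("study_config: covariates for '", lbl,
           "' name non-computable baseline variables: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(config)
}

#' Read a study configuration from YAML
#'
#' Keys absent from the file take the [study_config()] defaults.
#'
#' @param path path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("read_study_config: unknown keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(study_config, raw)
}

#' Map a day offset to a discrete week index
#'
#' Week `w` contains days `anchor_day + 7w` through `anchor_day + 7w + 6`;
#' week 0 starts at `anchor_day`. Days before the anchor map to negative
#' weeks (floor-division convention).
#'
#' @param day integer day offset(s).
#' @param anchor_day day starting week 0 (e.g. a subject's index day).
#' @param week_length_days bin width, default 7.
#' @return Integer week index, vectorized over `day`.
#' @export
day_to_week <- function(day, anchor_day = 0L, week_length_days = 7L) {
  as.integer(floor((day - anchor_day) / week_length_days))
}

#' Map a day offset to a study-calendar month index
#'
#' Enrollment months are fixed `month_length_days`-day bins anchored at
#' day 0 of the study.
#'
#' @param day integer day offset(s).
#' @param month_length_days bin width, default 30.
#' @return Integer month index, vectorized.
#' @export
day_to_month <- function(day, month_length_days = 30L) {
  as.integer(floor(day / month_length_days))
}

#' Normalize enrollment spans
#'
#' Sorts spans per subject and merges overlapping or adjacent months into
#' maximal disjoint spans. Idempotent.
#'
#' @param enrollment data.table with `subject_id`, `start_month`, `end_month`
#'   (other columns are carried through from the first row per subject).
#' @return Normalized enrollment data.table.
#' @export
normalize_enrollment <- function(enrollment) {
  en <- as.data.table(enrollment)
  if (nrow(en) == 0L) return(en)
  bad <- which(en$start_month > en$end_month)
  if (length(bad)) {
    stop("enrollment: start_month > end_month in rows ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(en), c("subject_id", "start_month", "end_month"))
  en <- en[order(subject_id, start_month, end_month)]
  # a span opens a new run when it starts more than one month after the
  # running maximum end within its subject
  en[, run_end := cummax(end_month), by = subject_id]
  en[, new_run := start_month > shift(run_end, fill = -.Machine$integer.max) + 1L,
     by = subject_id]
  en[, run_id := cumsum(new_run), by = subject_id]
  keep <- en[, c(list(start_month = min(start_month),
                      end_month = max(end_month)),
                 lapply(.SD, data.table::first)),
             by = .(subject_id, run_id), .SDcols = extra]
  keep[, run_id := NULL]
  setcolorder(keep, c("subject_id", "start_month", "end_month", extra))
  keep[]
}

.cs_check <- function(cond, table, what) {
  bad <- which(!cond)
  if (length(bad)) {
    stop("claims_bundle: ", what, " violated in '", table, "' rows ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         call. = FALSE)
  }
}

.cs_need_cols <- function(dt, cols, table) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop("claims_bundle: '", table, "' is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Assemble and validate a claims bundle
#'
#' A claims bundle holds the four raw claims tables of one study population
#' (pharmacy dispensings, medical claims, enrollment spans, death records),
#' subject demographics, and the diagnosis code-group map. All type
#' invariants are checked; enrollment spans are normalized (overlapping or
#' adjacent spans merged).
#'
#' Demographics (`birth_year`, `sex`) ride as columns of the enrollment
#' table, as in eligibility files, and are split into a `subjects` table.
#'
#' @param pharmacy data.table: `subject_id`, `dispense_day`, `days_supply`,
#'   `drug_class`.
#' @param medical data.table: `subject_id`, `service_day`, `primary_dx`,
#'   `setting`.
#' @param enrollment data.table: `subject_id`, `start_month`, `end_month`,
#'   `birth_year`, `sex`.
#' @param death data.table: `subject_id`, `death_day`.
#' @param code_map data.table: `code`, `group_label`, `role`.
#' @param config a [study_config()]; used for period and vocabulary checks.
#' @param validate run the row-level invariant checks (default). Callers
#'   that construct tables satisfying the invariants by construction (the
#'   simulator) may skip them.
#' @return A list of class `claims_bundle` with elements `pharmacy`,
#'   `medical`, `enrollment`, `death`, `subjects`, `code_map`.
#' @export
claims_bundle <- function(pharmacy, medical, enrollment, death, code_map,
                          config = study_config(), validate = TRUE) {
  ph <- as.data.table(pharmacy); md <- as.data.table(medical)
  en <- as.data.table(enrollment); de <- as.data.table(death)
  cm <- as.data.table(code_map)

  .cs_need_cols(ph, c("subject_id", "dispense_day", "days_supply", "drug_class"), "pharmacy")
  .cs_need_cols(md, c("subject_id", "service_day", "primary_dx", "setting"), "medical")
  .cs_need_cols(en, c("subject_id", "start_month", "end_month", "birth_year", "sex"), "enrollment")
  .cs_need_cols(de, c("subject_id", "death_day"), "death")
  .cs_need_cols(cm, c("code", "group_label", "role"), "code_map")

  if (validate && nrow(ph)) {
    .cs_check(ph$days_supply >= 1L, "pharmacy", "days_supply >= 1")
    .cs_check(ph$dispense_day >= config$study_start_day &
                ph$dispense_day <= config$study_end_day,
              "pharmacy", "dispense_day within study period")
    .cs_check(ph$drug_class %in% config$drug_classes,
              "pharmacy", "drug_class in configured vocabulary")
  }
  if (validate && nrow(md)) {
    .cs_check(md$service_day >= config$study_start_day &
                md$service_day <= config$study_end_day,
              "medical", "service_day within study period")
    .cs_check(md$setting %in% .cs_settings, "medical", "recognized setting")
    .cs_check(!is.na(md$primary_dx) & nzchar(md$primary_dx),
              "medical", "non-empty primary_dx")
  }
  if (validate && nrow(de)) {
    .cs_check(!duplicated(de$subject_id), "death", "at most one record per subject")
    .cs_check(de$death_day >= config$study_start_day,
              "death", "death_day at or after study start")
  }
  .cs_check(cm$role %in% .cs_roles, "code_map", "recognized role")
  dem_codes <- cm[role == "dementia", code]
  out_codes <- cm[role == "outcome", code]
  overlap <- intersect(dem_codes, out_codes)
  if (length(overlap)) {
    stop("claims_bundle: codes assigned to both dementia and outcome roles: ",
         paste(head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  if (nrow(en)) {
    if (validate) .cs_check(en$sex %in% c("F", "M"), "enrollment", "sex in {F, M}")
    att <- unique(en[, .(subject_id, birth_year, sex)])
    if (anyDuplicated(att$subject_id)) {
      stop("claims_bundle: inconsistent birth_year/sex across enrollment ",
           "spans for subjects ",
           paste(head(att$subject_id[duplicated(att$subject_id)], 5L),
                 collapse = ", "), call. = FALSE)
    }
  } else {
    att <- en[, .(subject_id, birth_year, sex)]
  }
  en_norm <- normalize_enrollment(en)

  # subsetting by order() yields fresh sorted tables (leaving caller input
  # untouched); setkey on them is then a cheap sortedness check
  ph <- ph[order(subject_id, dispense_day)]
  md <- md[order(subject_id, service_day)]
  de <- de[order(subject_id)]
  setkey(ph, subject_id, dispense_day)
  setkey(md, subject_id, service_day)
  setkey(en_norm, subject_id, start_month)
  setkey(de, subject_id)
  bundle <- list(
    pharmacy = ph,
    medical = md,
    enrollment = en_norm,
    death = de,
    subjects = att,
    code_map = cm
  )
  class(bundle) <- "claims_bundle"
  bundle
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  subjects:    %d\n", nrow(x$subjects)))
  cat(sprintf("  pharmacy:    %d dispensings\n", nrow(x$pharmacy)))
  cat(sprintf("  medical:     %d claims\n", nrow(x$medical)))
  cat(sprintf("  enrollment:  %d spans\n", nrow(x$enrollment)))
  cat(sprintf("  deaths:      %d\n", nrow(x$death)))
  cat(sprintf("  code map:    %d codes, %d groups\n",
              nrow(x$code_map), length(unique(x$code_map$group_label))))
  invisible(x)
}

.cs_bundle_files <- c(pharmacy = "pharmacy.csv", medical = "medical.csv",
                      enrollment = "enrollment.csv", death = "death.csv",
                      code_map = "code_map.csv")

#' Read a claims bundle from delimited files
#'
#' Expects `pharmacy.csv`, `medical.csv`, `enrollment.csv`, `death.csv` and
#' `code_map.csv` under `dir` (individual paths can be overridden). Headers
#' must match the documented schema; all type invariants are validated and
#' enrollment is normalized on read.
#'
#' @param dir directory containing the five CSV files.
#' @param config a [study_config()].
#' @param paths optional named character vector overriding individual files.
#' @return A `claims_bundle`.
#' @export
read_claims_bundle <- function(dir, config = study_config(), paths = NULL) {
  files <- file.path(dir, .cs_bundle_files)
  names(files) <- names(.cs_bundle_files)
  if (!is.null(paths)) files[names(paths)] <- paths
  miss <- files[!file.exists(files)]
  if (length(miss)) {
    stop("read_claims_bundle: missing input files: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rd <- function(f) fread(f, colClasses = NULL, showProgress = FALSE)
  claims_bundle(pharmacy = rd(files["pharmacy"]), medical = rd(files["medical"]),
                enrollment = rd(files["enrollment"]), death = rd(files["death"]),
                code_map = rd(files["code_map"]), config = config)
}

#' Write a claims bundle to delimited files
#'
#' Inverse of [read_claims_bundle()]: writes the five CSV files with the
#' documented headers. `read_claims_bundle(write_claims_bundle(b))`
#' reproduces `b` exactly for normalized bundles.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_claims_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, .cs_bundle_files)
  names(files) <- names(.cs_bundle_files)
  en <- copy(bundle$enrollment)
  if (!"birth_year" %in% names(en)) {
    en <- bundle$subjects[en, on = "subject_id"]
    setcolorder(en, c("subject_id", "start_month", "end_month", "birth_year", "sex"))
  }
  fwrite(bundle$pharmacy, files["pharmacy"])
  fwrite(bundle$medical, files["medical"])
  fwrite(en, files["enrollment"])
  fwrite(bundle$death, files["death"])
  fwrite(bundle$code_map, files["code_map"])
  invisible(files)
}

.cs_report_schemas <- list(
  balance = c("outcome", "variable", "treated", "untreated", "p_value", "smd"),
  incidence = c("outcome", "arm", "n_episodes", "person_years",
                "incidence_density", "ci_lower", "ci_upper"),
  hazard = c("outcome", "analysis", "hr", "ci_lower", "ci_upper", "p_value",
             "n_events", "n_subjects"),
  crossover = c("outcome", "contrast", "or", "ci_lower", "ci_upper", "p_value",
                "n_events_treatment", "n_events_pre", "n10", "n01")
)

#' Write report tables
#'
#' Renders the analysis results (covariate balance, incidence densities,
#' hazard ratios, case-crossover odds ratios) as CSV files with a
#' deterministic column order. A round-trip read reproduces the numeric
#' values to full precision.
#'
#' @param results named list with elements `balance`, `incidence`, `hazard`,
#'   `crossover` (data.frames with the documented columns).
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(results, dir) {
  miss <- setdiff(names(.cs_report_schemas), names(results))
  if (length(miss)) {
    stop("write_report_tables: missing analysis section(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(.cs_report_schemas)) {
    dt <- as.data.table(results[[nm]])
    .cs_need_cols(dt, .cs_report_schemas[[nm]], nm)
    setcolorder(dt, .cs_report_schemas[[nm]])
    p <- file.path(dir, paste0(nm, ".csv"))
    fwrite(dt, p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read back report tables written by [write_report_tables()]
#'
#' @param dir directory holding the report CSVs.
#' @return Named list of data.tables.
#' @export
read_report_tables <- function(dir) {
  out <- lapply(names(.cs_report_schemas), function(nm) {
    fread(file.path(dir, paste0(nm, ".csv")), showProgress = FALSE)
  })
  names(out) <- names(.cs_report_schemas)
  out
}

#' Age at a given study day
#'
#' Mid-year convention: subjects are taken to be born mid-year, so age at
#' day `d` is `floor(study_start_year + d/365.25 - birth_year - 0.5)`.
#'
#' @param birth_year integer vector.
#' @param day study day offset(s).
#' @param config a [study_config()] providing `study_start_year`.
#' @return Integer completed age in years.
#' @export
age_at_day <- function(birth_year, day, config = study_config()) {
  as.integer(floor(config$study_start_year + day / 365.25 - birth_year - 0.5))
}

# Months (study-calendar bins) fully covered by a subject's enrollment.
# Returns a data.table keyed by subject_id with start/end months; helper for
# interval coverage queries.
.cs_enrolled_months <- function(enrollment) {
  enrollment[, .(subject_id, start_month, end_month)]
}

# TRUE iff every month overlapping [from_day, to_day] is enrolled for the
# subject. Vectorized over subjects via data.table joins.
.cs_window_enrolled <- function(enrollment, subject_id, from_day, to_day,
                                month_length_days = 30L) {
  q <- data.table(subject_id = subject_id,
                  fm = day_to_month(from_day, month_length_days),
                  tm = day_to_month(to_day, month_length_days),
                  qid = seq_along(subject_id))
  sp <- enrollment[, .(subject_id, start_month, end_month)]
  # months covered by enrollment within the query range, summed per query
  hit <- sp[q, on = .(subject_id), allow.cartesian = TRUE, nomatch = NULL][
    , cov := pmax(0L, pmin(end_month, tm) - pmax(start_month, fm) + 1L)][
    , .(cov = sum(cov)), by = qid]
  need <- q$tm - q$fm + 1L
  ok <- rep(FALSE, nrow(q))
  ok[hit$qid] <- hit$cov >= need[hit$qid]
  ok
}
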