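# Pipeline orchestration: simulate/load -> courses -> cohort -> episodes ->
# match -> estimate -> crossover, with a consolidated report and manifest.

#' Prepare the analysis cohort from a claims bundle
#'
#' Runs the deterministic data-preparation stages: course reconstruction,
#' arm and index assignment, baseline covariate assessment, episode
#' detection, and the weekly person-time table (with per-group episode
#' flags and a death flag).
#'
#' @param bundle a `claims_bundle`.
#' @param config a [study_config()].
#' @param groups outcome groups to carry through episode detection and
#'   person-week flags (default: all configured; restrict for speed when a
#'   single outcome is analysed).
#' @return list: `courses`, `timeline`, `indexed`, `baseline`, `episodes`,
#'   `pweeks` (the [build_person_weeks()] result), `attrition` (named row
#'   counts after each filter).
#' @export
prepare_cohort <- function(bundle, config = study_config(), groups = NULL) {
  if (is.null(groups)) groups <- config$outcome_groups
  crs <- build_courses(bundle, config)
  eligible <- find_eligible(bundle, config)
  indexed <- assign_index(bundle, crs$courses, config, eligible = eligible)
  baseline <- compute_baseline(bundle, indexed, config)
  episodes <- build_episodes(bundle, config, groups = groups)
  pweeks <- build_person_weeks(indexed, bundle, config, episodes = episodes,
                               groups = groups)
  attrition <- c(
    subjects = nrow(bundle$subjects),
    dementia_diagnosed = nrow(eligible),
    exposure_users = length(unique(bundle$pharmacy[
      drug_class == config$exposure_class, subject_id])),
    incident_users = sum(crs$courses$is_incident),
    treated = sum(indexed$arm == "treated"),
    untreated = sum(indexed$arm == "untreated")
  )
  list(courses = crs$courses, timeline = crs$timeline, indexed = indexed,
       baseline = baseline, episodes = episodes, pweeks = pweeks,
       attrition = attrition)
}

#' Crude and matched estimates for one outcome
#'
#' For a clinical outcome group (or `"death"`): the crude hazard ratio on
#' the full cohorts, the per-outcome propensity model, the Mahalanobis
#' matched cohort with its balance table, and the pair-stratified matched
#' hazard ratio.
#'
#' @param prep result of [prepare_cohort()].
#' @param outcome outcome group label or `"death"`.
#' @param config a [study_config()].
#' @param analyses subset of `c("crude", "matched")`.
#' @return list: `crude`, `matched` (hazard results), `model`,
#'   `matched_cohort`, `balance`, `incidence` (for clinical outcomes).
#' @export
estimate_outcome <- function(prep, outcome, config = study_config(),
                             analyses = c("crude", "matched")) {
  cv <- config$covariates[[outcome]]
  if (is.null(cv)) {
    stop("estimate_outcome: no covariate specification for outcome '",
         outcome, "'", call. = FALSE)
  }
  out <- list(outcome = outcome)
  pw <- prep$pweeks$weeks
  ci <- .cs_counting_intervals(pw, paste0("ep_", outcome))
  if ("crude" %in% analyses) {
    out$crude <- fit_stratified_cox(pw, outcome, pairs = NULL,
                                    analysis = "crude", intervals = ci)
  }
  if ("matched" %in% analyses) {
    out$model <- fit_propensity(prep$baseline, cv$ps_covariates)
    out$matched_cohort <- mahalanobis_match(
      out$model, prep$baseline, key_covariates = cv$key_covariates,
      exact_vars = cv$exact_vars, band_vars = cv$band_vars,
      caliper_sd = config$caliper_sd)
    prs <- out$matched_cohort$pairs
    pair_map <- rbind(
      data.table(subject_id = prs$treated_id, pair_id = prs$pair_id),
      data.table(subject_id = prs$untreated_id, pair_id = prs$pair_id))
    out$matched <- fit_stratified_cox(pw, outcome, pairs = pair_map,
                                      analysis = "matched", intervals = ci)
    out$balance <- balance(prep$baseline, cv$ps_covariates,
                           out$matched_cohort)
  }
  if (outcome %in% c(config$outcome_groups, "death")) {
    ss <- ci[, .(ev = sum(ev), wk = sum(stop - start)), by = subject_id]
    ss <- merge(ss, prep$baseline[, .(subject_id, arm)], by = "subject_id")
    inc_of <- function(sub) {
      a <- sub[, .(n_episodes = sum(ev), person_years = sum(wk) * 7 / 365.25),
               by = arm]
      a[, c("incidence_density", "ci_lower", "ci_upper") := {
        r <- Map(incidence_density, n_episodes, person_years)
        .(vapply(r, `[[`, 0, "density"),
          vapply(r, `[[`, 0, "ci_lower"),
          vapply(r, `[[`, 0, "ci_upper"))
      }]
      a[order(arm)]
    }
    out$incidence <- inc_of(ss)
    if (!is.null(out$matched_cohort)) {
      m_unt <- inc_of(ss[subject_id %in% out$matched_cohort$pairs$untreated_id])
      m_unt[, arm := "matched_untreated"]
      out$incidence <- rbind(out$incidence, m_unt)
    }
  }
  out
}

.cs_config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(lapply(unclass(config), unclass)), f)
  unname(tools::md5sum(f))
}

#' Run the full signal-detection pipeline
#'
#' Orchestrates every stage from one configuration: input (a claims bundle
#' directory or a simulation preset), course reconstruction, cohort and
#' baseline assembly, episode detection, per-outcome matching, hazard and
#' incidence estimation, and the case-crossover analysis; writes the
#' consolidated report tables and a plain-text run manifest. Identical
#' configuration and seed give identical outputs.
#'
#' @param config a [study_config()] (or path to a YAML file).
#' @param bundle an in-memory `claims_bundle` (alternative to `bundle_dir`
#'   and `preset_name`).
#' @param bundle_dir directory with claims CSVs (mutually exclusive with
#'   `preset_name`).
#' @param preset_name simulation preset (see [preset()]).
#' @param n_subjects,seed simulation size and seed (preset input only;
#'   `seed` falls back to `config$seed`, then 1).
#' @param out_dir output directory; `NULL` skips writing.
#' @param outcomes outcomes to analyse (default: all configured groups
#'   plus death).
#' @param crossover run the case-crossover stage.
#' @param quiet suppress stage log messages.
#' @return list of class `pipeline_result`: `prep`, `estimates`,
#'   `windows`, `crossover`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = study_config(), bundle = NULL,
                         bundle_dir = NULL, preset_name = NULL,
                         n_subjects = 4000L, seed = NULL,
                         out_dir = NULL, outcomes = NULL, crossover = TRUE,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  say <- function(...) if (!quiet) message("[claimsignal] ", ...)
  completed <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\ncompleted stages: ",
           if (length(completed)) paste(completed, collapse = ", ") else "none",
           call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }

  bundle <- stage("input", {
    if (sum(!is.null(bundle), !is.null(bundle_dir), !is.null(preset_name)) > 1L) {
      stop("give exactly one of bundle, bundle_dir or preset_name")
    }
    if (!is.null(bundle)) {
      stopifnot(inherits(bundle, "claims_bundle"))
      bundle
    } else if (!is.null(bundle_dir)) {
      read_claims_bundle(bundle_dir, config)
    } else if (!is.null(preset_name)) {
      simulate_bundle(preset(preset_name, n_subjects = n_subjects,
                             seed = seed))$bundle
    } else {
      stop("no input: give bundle, bundle_dir or preset_name")
    }
  })
  say("input: ", nrow(bundle$subjects), " subjects, ",
      nrow(bundle$medical), " medical claims, ",
      nrow(bundle$pharmacy), " dispensings")

  if (is.null(outcomes)) outcomes <- c(config$outcome_groups, "death")
  stage("validation", {
    map_groups <- unique(bundle$code_map[role == "outcome", group_label])
    bad <- setdiff(setdiff(outcomes, "death"), map_groups)
    if (length(bad)) {
      stop("outcome group(s) not defined in the code map: ",
           paste(bad, collapse = ", "))
    }
    invisible(NULL)
  })

  prep <- stage("prepare", prepare_cohort(bundle, config))
  say("attrition: ", paste(names(prep$attrition), prep$attrition,
                           sep = "=", collapse = ", "))

  estimates <- stage("estimate", {
    lapply(setNames(outcomes, outcomes), function(oc)
      estimate_outcome(prep, oc, config))
  })
  for (oc in outcomes) {
    e <- estimates[[oc]]
    say(sprintf("%s: crude HR %.2f, matched HR %.2f (%d pairs, %d unmatched)",
                oc, e$crude$hr, e$matched$hr, nrow(e$matched_cohort$pairs),
                e$matched_cohort$n_unmatched))
  }

  windows <- xover <- NULL
  if (crossover) {
    windows <- stage("windows",
                     build_windows(bundle, prep$courses, config,
                                   groups = setdiff(outcomes, "death")))
    xover <- stage("crossover", {
      res <- list()
      for (g in setdiff(outcomes, "death")) {
        for (ctr in c("w1_vs_pre", "w2_vs_pre")) {
          res[[paste(g, ctr, sep = ".")]] <-
            suppressWarnings(crossover_or(windows, g, ctr))
        }
      }
      res
    })
  }

  report <- stage("report", {
    hz <- rbindlist(lapply(estimates, function(e) rbind(
      data.table(outcome = e$outcome, analysis = "crude", hr = e$crude$hr,
                 ci_lower = e$crude$ci_lower, ci_upper = e$crude$ci_upper,
                 p_value = e$crude$p_value, n_events = e$crude$n_events,
                 n_subjects = e$crude$n_subjects),
      data.table(outcome = e$outcome, analysis = "matched", hr = e$matched$hr,
                 ci_lower = e$matched$ci_lower, ci_upper = e$matched$ci_upper,
                 p_value = e$matched$p_value, n_events = e$matched$n_events,
                 n_subjects = e$matched$n_subjects))))
    bal <- rbindlist(lapply(estimates, function(e)
      cbind(outcome = e$outcome, e$balance)))
    inc <- rbindlist(lapply(estimates, function(e) {
      if (is.null(e$incidence)) return(NULL)
      data.table(outcome = e$outcome, arm = e$incidence$arm,
                 n_episodes = e$incidence$n_episodes,
                 person_years = e$incidence$person_years,
                 incidence_density = e$incidence$incidence_density,
                 ci_lower = e$incidence$ci_lower,
                 ci_upper = e$incidence$ci_upper)
    }))
    xo <- if (length(xover)) {
      rbindlist(lapply(xover, function(x)
        data.table(outcome = x$group, contrast = x$contrast, or = x$or,
                   ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                   p_value = x$p_value, n_events_treatment = x$n_events_treatment,
                   n_events_pre = x$n_events_pre, n10 = x$n10, n01 = x$n01)))
    } else {
      data.table(outcome = character(0), contrast = character(0),
                 or = numeric(0), ci_lower = numeric(0), ci_upper = numeric(0),
                 p_value = numeric(0), n_events_treatment = integer(0),
                 n_events_pre = integer(0), n10 = integer(0), n01 = integer(0))
    }
    list(balance = bal, incidence = inc, hazard = hz, crossover = xo)
  })

  manifest <- list(
    config_hash = .cs_config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("claimsignal")),
    stages = completed,
    attrition = prep$attrition,
    n_pairs = vapply(estimates, function(e) nrow(e$matched_cohort$pairs), 0L),
    outputs = character(0)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_report_tables(report, out_dir)
    manifest$outputs <- unname(paths)
    mf <- file.path(out_dir, "manifest.txt")
    writeLines(c(
      paste0("config_hash: ", manifest$config_hash),
      paste0("seed: ", manifest$seed),
      paste0("package_version: ", manifest$package_version),
      paste0("stages: ", paste(manifest$stages, collapse = ", ")),
      paste0("attrition: ", paste(names(manifest$attrition),
                                  manifest$attrition, sep = "=",
                                  collapse = ", ")),
      paste0("pairs: ", paste(names(manifest$n_pairs), manifest$n_pairs,
                              sep = "=", collapse = ", ")),
      paste0("outputs: ", paste(basename(manifest$outputs), collapse = ", "))
    ), mf)
    manifest$outputs <- c(manifest$outputs, mf)
  }

  structure(list(prep = prep, estimates = estimates, windows = windows,
                 crossover = xover, report = report, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  attrition: ", paste(names(x$prep$attrition), x$prep$attrition,
                             sep = "=", collapse = ", "), "\n", sep = "")
  print(x$report$hazard)
  invisible(x)
}
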