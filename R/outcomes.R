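# Outcome detection from primary diagnoses and episode-of-care clustering.

#' Detect outcome events for one code group
#'
#' One event per medical claim whose primary diagnosis belongs to the
#' group's code set. Only the primary diagnosis drives detection: it
#' typically records the reason for seeking care. Duplicate same-day claims
#' yield duplicate events; the episode clustering rule absorbs them.
#'
#' @param medical medical claims table (or a `claims_bundle`).
#' @param code_map code-group map (`code`, `group_label`, `role`); ignored
#'   when `medical` is a bundle.
#' @param group outcome group label (role must be `outcome`).
#' @return data.table (`subject_id`, `group_label`, `service_day`), sorted
#'   by subject and day.
#' @export
detect_events <- function(medical, code_map = NULL, group) {
  if (inherits(medical, "claims_bundle")) {
    code_map <- medical$code_map
    medical <- medical$medical
  }
  cm <- as.data.table(code_map)
  known <- unique(cm[role == "outcome", group_label])
  if (!group %in% known) {
    stop("detect_events: unknown outcome group '", group,
         "'; configured outcome groups: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  codes <- cm[role == "outcome" & group_label == group, code]
  md <- as.data.table(medical)
  ev <- md[primary_dx %in% codes,
           .(subject_id, group_label = group, service_day)]
  ev[order(subject_id, service_day)]
}

#' Cluster outcome events into episodes of care
#'
#' The first event opens an episode; a subsequent event starts a new
#' episode iff it falls at least `episode_gap_days` after the previous
#' event (gap measured in days between consecutive claim dates, from the
#' previous claim, so an episode extends indefinitely under sustained
#' claims). Vectorized over subjects and groups; events from different
#' subjects or groups never merge.
#'
#' @param events data.table from [detect_events()] (any number of subjects
#'   and groups).
#' @param episode_gap_days claim-free gap starting a new episode
#'   (default 28, i.e. 4 weeks).
#' @return data.table (`subject_id`, `group_label`, `episode_id`,
#'   `start_day`, `n_claims`, `last_claim_day`).
#' @export
cluster_episodes <- function(events, episode_gap_days = 28L) {
  ev <- as.data.table(events)
  if (nrow(ev) == 0L) {
    return(data.table(subject_id = character(0), group_label = character(0),
                      episode_id = integer(0), start_day = integer(0),
                      n_claims = integer(0), last_claim_day = integer(0)))
  }
  ev <- ev[order(subject_id, group_label, service_day)]
  ev[, gap := service_day - shift(service_day), by = .(subject_id, group_label)]
  ev[, new_ep := is.na(gap) | gap >= episode_gap_days]
  ev[, episode_id := cumsum(new_ep), by = .(subject_id, group_label)]
  out <- ev[, .(start_day = service_day[1L],
                n_claims = .N,
                last_claim_day = service_day[.N]),
            by = .(subject_id, group_label, episode_id)]
  out[]
}

#' Map episode starts onto per-subject analysis weeks
#'
#' Converts episode start days to week indices on each subject's analysis
#' grid (week 0 = index week). Episodes starting outside the follow-up
#' range are dropped; the dropped count is attached as an attribute and
#' reported via a message. Baseline episodes (before week 0) are among the
#' dropped ones here but remain available upstream for baseline covariate
#' flags.
#'
#' @param episodes data.table from [cluster_episodes()].
#' @param anchors data.table (`subject_id`, `anchor_day`) giving each
#'   subject's index day; subjects absent from `anchors` are dropped.
#' @param follow_up optional data.table (`subject_id`, `first_week`,
#'   `last_week`) bounding each subject's follow-up; defaults to
#'   `first_week = 0` with no upper bound.
#' @param quiet suppress the dropped-count message.
#' @return data.table (`subject_id`, `group_label`, `week`) of episode
#'   starts, with attribute `n_dropped`.
#' @export
episode_starts_to_weeks <- function(episodes, anchors, follow_up = NULL,
                                    quiet = FALSE) {
  ep <- as.data.table(episodes)
  an <- as.data.table(anchors)
  x <- merge(ep, an[, .(subject_id, anchor_day)], by = "subject_id")
  n_in <- nrow(x)
  x[, week := day_to_week(start_day, anchor_day)]
  if (is.null(follow_up)) {
    x <- x[week >= 0L]
  } else {
    fu <- as.data.table(follow_up)
    x <- merge(x, fu, by = "subject_id")
    x <- x[week >= first_week & week <= last_week]
  }
  out <- x[, .(subject_id, group_label, week)]
  n_dropped <- n_in - nrow(out)
  if (!quiet && n_dropped > 0L) {
    message("episode_starts_to_weeks: dropped ", n_dropped,
            " episode start(s) outside follow-up")
  }
  setattr(out, "n_dropped", n_dropped)
  out[]
}

#' Detect and cluster episodes for all configured outcome groups
#'
#' @param bundle a `claims_bundle`.
#' @param config a [study_config()].
#' @param groups outcome groups (default: all configured).
#' @return data.table of episodes across the requested outcome groups.
#' @export
build_episodes <- function(bundle, config = study_config(), groups = NULL) {
  if (is.null(groups)) groups <- config$outcome_groups
  empty <- data.table(subject_id = character(0), group_label = character(0),
                      episode_id = integer(0), start_day = integer(0),
                      n_claims = integer(0), last_claim_day = integer(0))
  eps <- lapply(groups, function(g) {
    cluster_episodes(detect_events(bundle, group = g),
                     config$episode_gap_days)
  })
  rbindlist(c(list(empty), eps))
}
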