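# Independent brute-force oracles used by the property and acceptance tests.
# These work at day level on marked-day arrays, deliberately avoiding the
# interval arithmetic of the implementation.

library(data.table)
library(survival) # clogit formulas need strata() on the search path

# Day-level supply oracle: mark each dispensing's supplied days one at a
# time, starting at the dispense day or the first day after the last marked
# day, then read maximal runs of marked days off the array.
oracle_supply_intervals <- function(days, supplies, horizon = 4000L) {
  o <- order(days)
  days <- days[o]; supplies <- supplies[o]
  marked <- rep(FALSE, horizon)
  prev_end <- -1L
  for (k in seq_along(days)) {
    s <- max(days[k], prev_end + 1L)
    e <- s + supplies[k] - 1L
    marked[(s + 1L):(e + 1L)] <- TRUE
    prev_end <- e
  }
  d <- which(marked) - 1L
  if (!length(d)) return(data.table(first_day = integer(0), last_day = integer(0)))
  brk <- c(TRUE, diff(d) > 1L)
  iv <- cumsum(brk)
  data.table(first_day = d[!duplicated(iv)],
             last_day = d[rev(!duplicated(rev(iv)))])
}

# Day-level course oracle: scan the marked-day array for zero-supply runs of
# at least gap_days; each such run (and the array start) opens a course.
oracle_courses <- function(days, supplies, gap_days = 60L, tail_days = 60L,
                           horizon = 4000L) {
  iv <- oracle_supply_intervals(days, supplies, horizon)
  if (nrow(iv) == 0L) {
    return(data.table(start_day = integer(0), last_supplied_day = integer(0),
                      end_day = integer(0)))
  }
  marked <- rep(FALSE, horizon)
  for (k in seq_len(nrow(iv))) {
    marked[(iv$first_day[k] + 1L):(iv$last_day[k] + 1L)] <- TRUE
  }
  sup_days <- which(marked) - 1L
  starts <- sup_days[1L]
  last <- sup_days[1L]
  out <- list()
  for (d in sup_days[-1L]) {
    if (d - last - 1L >= gap_days) {
      out[[length(out) + 1L]] <- c(starts, last)
      starts <- d
    }
    last <- d
  }
  out[[length(out) + 1L]] <- c(starts, last)
  m <- do.call(rbind, out)
  data.table(start_day = m[, 1L], last_supplied_day = m[, 2L],
             end_day = m[, 2L] + tail_days)
}

# Episode oracle: for each event day, look back episode_gap_days; the event
# continues the current episode iff any event fell in that window.
oracle_episodes <- function(event_days, gap_days = 28L) {
  d <- sort(event_days)
  if (!length(d)) return(integer(0))
  starts <- d[1L]
  for (k in seq_along(d)[-1L]) {
    lookback <- d[d >= d[k] - gap_days + 1L & d < d[k]]
    if (!length(lookback)) starts <- c(starts, d[k])
  }
  starts
}

# Single-covariate stratified Cox partial-likelihood Newton solver (Breslow
# ties), independent of survival::coxph. Data: start/stop/ev/x/stratum.
oracle_cox_coef <- function(dt, tol = 1e-10, max_iter = 60L) {
  dt <- as.data.table(dt)
  beta <- 0
  for (it in seq_len(max_iter)) {
    U <- 0; I <- 0
    for (st in unique(dt$stratum)) {
      d <- dt[stratum == st]
      for (t_ev in sort(unique(d$stop[d$ev == 1L]))) {
        at_risk <- d[start < t_ev & stop >= t_ev]
        ev_rows <- d[ev == 1L & stop == t_ev]
        w <- exp(beta * at_risk$x)
        s0 <- sum(w); s1 <- sum(w * at_risk$x); s2 <- sum(w * at_risk$x^2)
        m <- nrow(ev_rows)
        U <- U + sum(ev_rows$x) - m * s1 / s0
        I <- I + m * (s2 / s0 - (s1 / s0)^2)
      }
    }
    if (I <= 0) return(NA_real_)
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}
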