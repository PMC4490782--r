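# Per-outcome propensity models, Mahalanobis metric matching within a
# propensity caliper, and covariate balance diagnostics.

#' Fit a propensity model for treatment
#'
#' Maximum-likelihood logistic regression of treatment on the listed
#' baseline covariates, with intercept. Continuous covariates (more than
#' two distinct values) are standardized internally; binary covariates
#' enter as 0/1, so their coefficients are log odds ratios. Perfect
#' separation aborts with a pointer to the ridge fallback, which adds a
#' small L2 penalty to the score equations.
#'
#' @param baseline baseline covariate table from [compute_baseline()]
#'   (must contain `arm`).
#' @param covariates character vector of covariate column names.
#' @param ridge logical; use a ridge-penalized fit (penalty `lambda`).
#' @param lambda ridge penalty (ignored unless `ridge = TRUE`).
#' @return Object of class `propensity_model`: `covariates`,
#'   `coefficients` (intercept first, standardized scale for continuous
#'   terms), `ps` (fitted scores in (0,1)), `lp` (logit scores), `treated`
#'   (logical), `subject_id`, `centers`, `scales`.
#' @export
fit_propensity <- function(baseline, covariates, ridge = FALSE,
                           lambda = 1e-3) {
  bl <- as.data.table(baseline)
  miss <- setdiff(covariates, names(bl))
  if (length(miss)) {
    stop("fit_propensity: covariates not present in baseline table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- as.integer(bl$arm == "treated")
  if (all(y == 1L) || all(y == 0L)) {
    stop("fit_propensity: need at least one subject in each arm", call. = FALSE)
  }
  X <- as.matrix(bl[, ..covariates])
  if (any(!is.finite(X))) {
    stop("fit_propensity: covariates must be computable (finite) for all ",
         "subjects", call. = FALSE)
  }
  centers <- rep(0, ncol(X))
  scales <- rep(1, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (length(unique(X[, j])) > 2L) {
      centers[j] <- mean(X[, j])
      s <- stats::sd(X[, j])
      scales[j] <- if (s > 0) s else 1
    }
  }
  Xs <- sweep(sweep(X, 2L, centers), 2L, scales, "/")

  if (!ridge) {
    fit <- withCallingHandlers(
      glm.fit(cbind(`(Intercept)` = 1, Xs), y, family = binomial()),
      warning = function(w) invokeRestart("muffleWarning"))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0 # aliased (constant or collinear) columns
    lp <- drop(cbind(1, Xs) %*% beta)
    mu <- plogis(lp)
    # diverging standardized coefficients or fitted probabilities pinned at
    # 0/1 indicate (quasi-)separation
    if (!fit$converged || any(abs(beta[-1L]) > 15) ||
        any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      stop("fit_propensity: perfect separation detected; review the ",
           "covariate list or refit with ridge = TRUE", call. = FALSE)
    }
  } else {
    # Newton iterations on the ridge-penalized log-likelihood
    Z <- cbind(`(Intercept)` = 1, Xs)
    beta <- rep(0, ncol(Z))
    pen <- diag(c(0, rep(lambda, ncol(Xs))))
    for (it in 1:50) {
      mu <- plogis(drop(Z %*% beta))
      wt <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(Z, Z * wt) + pen
      g <- crossprod(Z, y - mu) - pen %*% beta
      step <- solve(H, g)
      beta <- beta + drop(step)
      if (max(abs(step)) < 1e-10) break
    }
    names(beta) <- colnames(Z)
    lp <- drop(Z %*% beta)
  }
  ps <- plogis(lp)
  structure(list(covariates = covariates, coefficients = beta,
                 ps = ps, lp = lp, treated = y == 1L,
                 subject_id = bl$subject_id,
                 centers = setNames(centers, covariates),
                 scales = setNames(scales, covariates)),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model> ", sum(x$treated), " treated / ",
      sum(!x$treated), " untreated\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Mahalanobis metric matching within a propensity caliper
#'
#' 1:1 greedy nearest-neighbor matching without replacement. The distance
#' is the Mahalanobis metric over the logit propensity score joined with
#' the key prognostic covariates, under the pooled within-arm covariance.
#' An untreated candidate is admissible iff the absolute logit-score
#' difference is within `caliper_sd` standard deviations of the logit
#' score, all `exact_vars` agree exactly, and all `band_vars` agree within
#' their bands (e.g. age within +/- 5 years for the death analysis).
#' Treated subjects are processed in descending logit score
#' (hardest-to-match first); ties in distance break to the smaller
#' untreated identifier, so the result is fully deterministic.
#'
#' @param model a [fit_propensity()] object.
#' @param baseline the baseline covariate table the model was fitted on.
#' @param key_covariates covariates joined with the logit score in the
#'   Mahalanobis metric.
#' @param exact_vars covariates that must match exactly (hard filter).
#' @param band_vars named numeric vector: covariate -> half-width of the
#'   allowed absolute difference.
#' @param caliper_sd caliper in SD units of the logit score (pooled over
#'   both arms).
#' @param metric optional `metric` element of a previous result: freezes
#'   the Mahalanobis transform and the absolute caliper, making the pairing
#'   invariant to removal of never-matched candidates.
#' @return Object of class `matched_cohort`: `pairs` (data.table
#'   `pair_id`, `treated_id`, `untreated_id`, `distance`), `caliper`
#'   (absolute logit units), `exact_vars`, `band_vars`, `n_unmatched`,
#'   `unmatched_treated`, `metric`.
#' @export
mahalanobis_match <- function(model, baseline, key_covariates = character(0),
                              exact_vars = character(0),
                              band_vars = numeric(0), caliper_sd = 0.2,
                              metric = NULL) {
  bl <- as.data.table(baseline)
  stopifnot(identical(bl$subject_id, model$subject_id))
  tr <- model$treated
  lp <- model$lp
  Xk <- if (length(key_covariates)) {
    as.matrix(bl[, ..key_covariates])
  } else {
    matrix(numeric(0), nrow(bl), 0L)
  }

  n_t <- sum(tr); n_u <- sum(!tr)
  if (n_t == 0L || n_u == 0L) {
    stop("mahalanobis_match: need subjects in both arms", call. = FALSE)
  }
  if (length(key_covariates)) {
    konst <- key_covariates[apply(Xk, 2L, function(x) var(x) == 0)]
    if (length(konst)) {
      stop("mahalanobis_match: singular pooled covariance; collinear or ",
           "constant covariates: ", paste(konst, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(metric)) {
    # a numerically constant score (degenerate model, e.g. identical arms)
    # carries no information: it leaves the metric and the caliper opens up
    sd_lp <- stats::sd(lp)
    lp_informative <- sd_lp > 1e-8
    X <- if (lp_informative) cbind(lp = lp, Xk) else Xk
    cal <- if (lp_informative) caliper_sd * sd_lp else Inf
    R <- NULL
    if (ncol(X) > 0L) {
      # single-subject arms contribute no within-arm scatter
      wss <- function(M) if (nrow(M) < 2L) 0 else (nrow(M) - 1L) * stats::cov(M)
      S <- (wss(X[tr, , drop = FALSE]) + wss(X[!tr, , drop = FALSE])) /
        (n_t + n_u - 2)
      R <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(R) || any(diag(R) < sqrt(.Machine$double.eps) * max(diag(R)))) {
        stop("mahalanobis_match: singular pooled covariance; collinear or ",
             "constant covariates: ", paste(colnames(X), collapse = ", "),
             call. = FALSE)
      }
    }
    metric <- list(R = R, lp_informative = lp_informative, cal = cal)
  } else {
    lp_informative <- metric$lp_informative
    X <- if (lp_informative) cbind(lp = lp, Xk) else Xk
    cal <- metric$cal
  }
  Z <- if (!is.null(metric$R)) X %*% solve(metric$R) else
    matrix(0, nrow(bl), 1L)
  ti <- which(tr); ui <- which(!tr)
  # candidates kept sorted by logit score so the caliper restricts the scan
  # to an index window; ties in distance break to the smaller subject id
  ui <- ui[order(lp[ui], bl$subject_id[ui])]
  Zt <- Z[ti, , drop = FALSE]; Zu <- Z[ui, , drop = FALSE]
  lp_t <- lp[ti]; lp_u <- lp[ui]
  id_rank_u <- rank(bl$subject_id[ui], ties.method = "first")
  ex_t <- ex_u <- NULL
  if (length(exact_vars)) {
    key <- function(ii) do.call(paste, c(bl[ii, ..exact_vars], sep = "\r"))
    kt <- key(ti); ku <- key(ui)
    lev <- unique(c(kt, ku))
    ex_t <- match(kt, lev); ex_u <- match(ku, lev)
  }
  bv <- names(band_vars)
  Bt <- if (length(bv)) as.matrix(bl[ti, ..bv]) else NULL
  Bu <- if (length(bv)) as.matrix(bl[ui, ..bv]) else NULL

  avail <- rep(TRUE, length(ui))
  ord <- order(-lp_t, bl$subject_id[ti])
  m_u <- rep(NA_integer_, length(ti))
  p <- ncol(Z)
  for (i in ord) {
    lo <- findInterval(lp_t[i] - cal, lp_u, left.open = TRUE) + 1L
    hi <- findInterval(lp_t[i] + cal, lp_u)
    if (hi < lo) next
    jj <- lo:hi
    jj <- jj[avail[jj]]
    if (!is.null(ex_t) && length(jj)) jj <- jj[ex_u[jj] == ex_t[i]]
    if (!is.null(Bt) && length(jj)) {
      for (k in seq_along(bv)) {
        jj <- jj[abs(Bu[jj, k] - Bt[i, k]) <= band_vars[k]]
        if (!length(jj)) break
      }
    }
    if (!length(jj)) next
    d2 <- rowSums((Zu[jj, , drop = FALSE] -
                     matrix(Zt[i, ], length(jj), p, byrow = TRUE))^2)
    best <- which(d2 == min(d2))
    j <- jj[best[which.min(id_rank_u[jj[best]])]]
    m_u[i] <- j
    avail[j] <- FALSE
  }

  matched <- which(!is.na(m_u))
  pairs <- data.table(
    pair_id = seq_along(matched),
    treated_id = bl$subject_id[ti[matched]],
    untreated_id = bl$subject_id[ui[m_u[matched]]],
    distance = sqrt(rowSums((Zt[matched, , drop = FALSE] -
                               Zu[m_u[matched], , drop = FALSE])^2))
  )
  structure(list(pairs = pairs, caliper = cal,
                 key_covariates = key_covariates,
                 exact_vars = exact_vars, band_vars = band_vars,
                 n_unmatched = length(ti) - length(matched),
                 unmatched_treated = bl$subject_id[ti[is.na(m_u)]],
                 metric = metric),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort> ", nrow(x$pairs), " pairs; ", x$n_unmatched,
      " treated unmatched; caliper ", signif(x$caliper, 3),
      " logit units\n", sep = "")
  invisible(x)
}

#' Covariate balance diagnostics
#'
#' Compares covariate distributions across arms: Welch t-test for
#' continuous covariates, Pearson chi-square (no continuity correction)
#' for binary ones, plus the standardized mean difference
#' `SMD = (mean_t - mean_u) / sqrt((var_t + var_u) / 2)`. With a
#' `matched_cohort` the comparison runs over the matched arms; without one
#' it describes the full (pre-matching) cohorts. Covariates with zero
#' variance in both arms report p-value 1 and SMD 0. Balance p-values are
#' diagnostics, not inference: no multiplicity adjustment is applied.
#'
#' @param baseline baseline covariate table.
#' @param covariates covariate names to compare.
#' @param matched optional [mahalanobis_match()] result.
#' @return data.table (`variable`, `treated`, `untreated`, `p_value`,
#'   `smd`); `treated`/`untreated` hold means (frequencies for binary
#'   covariates).
#' @export
balance <- function(baseline, covariates, matched = NULL) {
  bl <- as.data.table(baseline)
  if (!is.null(matched)) {
    xt <- bl[matched$pairs, on = .(subject_id = treated_id)]
    xu <- bl[matched$pairs, on = .(subject_id = untreated_id)]
  } else {
    xt <- bl[arm == "treated"]
    xu <- bl[arm == "untreated"]
  }
  rows <- lapply(covariates, function(v) {
    a <- xt[[v]]; b <- xu[[v]]
    va <- var(a); vb <- var(b)
    smd <- if (va + vb == 0) 0 else (mean(a) - mean(b)) / sqrt((va + vb) / 2)
    binary <- length(unique(c(a, b))) <= 2L
    p <- if (va + vb == 0) {
      1
    } else if (binary) {
      tab <- rbind(c(sum(a == max(a, b)), length(a) - sum(a == max(a, b))),
                   c(sum(b == max(a, b)), length(b) - sum(b == max(a, b))))
      # Pearson statistic without continuity correction
      st <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (is.finite(st$p.value)) st$p.value else 1
    } else {
      stats::t.test(a, b)$p.value
    }
    data.table(variable = v, treated = mean(a), untreated = mean(b),
               p_value = p, smd = smd)
  })
  rbindlist(rows)
}
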