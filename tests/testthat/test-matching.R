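# baseline-table fixtures built directly; matching operates on covariates,
# not on raw claims

make_baseline <- function(n_t, n_u, f = NULL, seed = 1) {
  set.seed(seed)
  n <- n_t + n_u
  bl <- data.table(
    subject_id = sprintf("S%04d", seq_len(n)),
    arm = rep(c("treated", "untreated"), c(n_t, n_u)),
    age = round(rnorm(n, 77, 8)),
    comorbidity_count = rpois(n, 1.3),
    flag = rbinom(n, 1L, 0.3)
  )
  if (!is.null(f)) bl <- f(bl)
  bl
}

test_that("propensity fit recovers closed-form and null coefficients", {
  # 2x2 saturated case: coefficient equals the log odds ratio log(2.25)
  bl <- data.table(
    subject_id = sprintf("S%03d", 1:100),
    arm = rep(c("treated", "untreated"), each = 50),
    flag = c(rep(1L, 30), rep(0L, 20), rep(1L, 20), rep(0L, 30))
  )
  m <- fit_propensity(bl, "flag")
  expect_equal(unname(m$coefficients["flag"]), log(2.25), tolerance = 1e-6)

  # covariate identical across arms: coefficient ~ 0 (|z| < 0.1 at n = 2000)
  set.seed(9)
  bl2 <- data.table(subject_id = sprintf("S%04d", 1:2000),
                    arm = sample(rep(c("treated", "untreated"), 1000)),
                    x = rnorm(2000))
  m2 <- fit_propensity(bl2, "x")
  se <- sqrt(1 / 500 + 1 / 500) # rough scale; direct check on coef instead
  expect_lt(abs(m2$coefficients["x"]), 0.1)

  expect_error(fit_propensity(bl[arm == "treated"], "flag"), "each arm")
  expect_error(fit_propensity(bl, "no_such"), "not present")

  # separation detected, ridge fallback works
  bl3 <- data.table(subject_id = sprintf("S%03d", 1:60),
                    arm = rep(c("treated", "untreated"), each = 30),
                    x = rep(c(1, 0), each = 30))
  expect_error(fit_propensity(bl3, "x"), "separation")
  m3 <- fit_propensity(bl3, "x", ridge = TRUE)
  expect_true(all(is.finite(m3$lp)))
})

test_that("matching pairs clones at distance zero and respects the caliper", {
  # identical treated/untreated covariates: everyone matches at distance 0
  bl <- make_baseline(30, 30, seed = 5)
  bl[31:60, `:=`(age = bl$age[1:30], comorbidity_count = bl$comorbidity_count[1:30],
                 flag = bl$flag[1:30])]
  m <- fit_propensity(bl, c("age", "comorbidity_count", "flag"))
  mc <- mahalanobis_match(m, bl, key_covariates = c("age", "comorbidity_count"))
  expect_identical(nrow(mc$pairs), 30L)
  expect_identical(mc$n_unmatched, 0L)
  expect_equal(max(mc$pairs$distance), 0, tolerance = 1e-10)

  # caliper is applied before distance: a nearer candidate outside the
  # caliper loses to a farther one inside it
  bl2 <- data.table(subject_id = c("T1", "T2", "U1", "U2"),
                    arm = c("treated", "treated", "untreated", "untreated"),
                    age = c(70, 71, 80, 70.5), flag = c(0L, 1L, 1L, 0L))
  m2 <- fit_propensity(bl2, "flag")
  # manufacture controlled logit scores: for T1, U2 is near in age
  # (distance) but outside the caliper on the score; T2 has no admissible
  # candidate at all
  m2$lp <- c(0, 10, 0.1, 3)
  m2$ps <- plogis(m2$lp)
  mc2 <- mahalanobis_match(m2, bl2, key_covariates = "age",
                           caliper_sd = 0.2)
  # sd(lp) ~ 4.7, caliper ~ 0.95: U1 (|0.1| <= 0.95) admissible for T1,
  # U2 (|3| > 0.95) not, despite nearer age
  expect_identical(mc2$pairs$treated_id, "T1")
  expect_identical(mc2$pairs$untreated_id, "U1")
  expect_identical(mc2$n_unmatched, 1L)

  # exact constraint leaves the treated subject unmatched
  bl3 <- data.table(subject_id = c("T1", "U1", "U2"),
                    arm = c("treated", "untreated", "untreated"),
                    age = c(70, 71, 69), flag = c(1L, 0L, 0L))
  m3 <- fit_propensity(bl3, "age")
  mc3 <- mahalanobis_match(m3, bl3, key_covariates = "age",
                           exact_vars = "flag")
  expect_identical(nrow(mc3$pairs), 0L)
  expect_identical(mc3$n_unmatched, 1L)
  expect_identical(mc3$unmatched_treated, "T1")

  # band constraint: age within +/- 5 years
  bl4 <- data.table(subject_id = c("T1", "U1", "U2"),
                    arm = c("treated", "untreated", "untreated"),
                    age = c(70, 80, 74), flag = c(0L, 0L, 0L))
  m4 <- fit_propensity(bl4, "flag")
  mc4 <- mahalanobis_match(m4, bl4, key_covariates = character(0),
                           band_vars = c(age = 5))
  expect_identical(mc4$pairs$untreated_id, "U2")

  # singular covariance names the degenerate covariate
  bl5 <- make_baseline(20, 20, seed = 6)
  bl5[, konst := 1]
  m5 <- fit_propensity(bl5, "age")
  expect_error(mahalanobis_match(m5, bl5, key_covariates = "konst"),
               "singular|konst")
})

test_that("matching ignores irrelevant candidates and is deterministic", {
  bl <- make_baseline(40, 120, seed = 7)
  covs <- c("age", "comorbidity_count", "flag")
  m <- fit_propensity(bl, covs)
  mc1 <- mahalanobis_match(m, bl, key_covariates = "age")
  # drop never-matched untreated subjects; under the same frozen metric the
  # pairing must be unchanged
  used <- c(bl[arm == "treated", subject_id], mc1$pairs$untreated_id)
  bl2 <- bl[subject_id %in% used]
  m2 <- fit_propensity(bl2, covs)
  m2$lp <- m$lp[match(bl2$subject_id, bl$subject_id)]
  m2$ps <- plogis(m2$lp)
  m2$treated <- bl2$arm == "treated"
  mc2 <- mahalanobis_match(m2, bl2, key_covariates = "age",
                           metric = mc1$metric)
  expect_identical(mc1$pairs$treated_id, mc2$pairs$treated_id)
  expect_identical(mc1$pairs$untreated_id, mc2$pairs$untreated_id)

  # bit-for-bit reproducible on identical input
  mc3 <- mahalanobis_match(m, bl, key_covariates = "age")
  expect_identical(mc1$pairs, mc3$pairs)
  # each subject appears in at most one pair
  expect_identical(anyDuplicated(mc1$pairs$untreated_id), 0L)
  expect_identical(anyDuplicated(mc1$pairs$treated_id), 0L)
})

test_that("balance reports Welch t, Pearson chi-square, and SMD", {
  # identical matched arms: p = 1, SMD = 0
  bl <- make_baseline(25, 25, seed = 8)
  bl[26:50, `:=`(age = bl$age[1:25], comorbidity_count = bl$comorbidity_count[1:25],
                 flag = bl$flag[1:25])]
  b <- balance(bl, c("age", "comorbidity_count", "flag"))
  expect_true(all(b$smd == 0))
  expect_true(all(b$p_value == 1))

  # hand-computed Pearson statistic: 40/100 vs 25/100 -> X2 = 5.128
  bl2 <- data.table(subject_id = sprintf("S%03d", 1:200),
                    arm = rep(c("treated", "untreated"), each = 100),
                    flag = c(rep(1L, 40), rep(0L, 60), rep(1L, 25), rep(0L, 75)))
  b2 <- balance(bl2, "flag")
  expect_equal(b2$p_value, 1 - pchisq(5.128, 1), tolerance = 1e-3)
  expect_equal(b2$treated, 0.40)
  expect_equal(b2$untreated, 0.25)

  # a +1 SD shift gives SMD ~ 1 at n = 5000
  set.seed(11)
  bl3 <- data.table(subject_id = sprintf("S%05d", 1:10000),
                    arm = rep(c("treated", "untreated"), each = 5000),
                    x = c(rnorm(5000, 1), rnorm(5000, 0)))
  b3 <- balance(bl3, "x")
  expect_equal(b3$smd, 1, tolerance = 0.06)

  # zero variance in both arms: p 1, SMD 0
  bl4 <- data.table(subject_id = c("a", "b", "c", "d"),
                    arm = c("treated", "treated", "untreated", "untreated"),
                    k = c(2, 2, 2, 2))
  b4 <- balance(bl4, "k")
  expect_identical(b4$p_value, 1)
  expect_identical(b4$smd, 0)
})
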