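---
title: "Directed ADR signal detection from administrative claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed ADR signal detection from administrative claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Administrative claims — pharmacy dispensings, diagnosis-coded medical
claims, enrollment spans, death records — are a by-product of billing, not
of research. Yet they cover whole populations over years, which makes them
attractive for *directed* adverse-drug-reaction (ADR) surveillance:
pre-specifying a drug class and a set of clinically motivated outcome
groups, then estimating whether initiating the drug raises the rate of
those outcomes. `claimsignal` implements such a surveillance pipeline for a
dementia-treatment setting: new users of an exposure class (by default an
acetylcholinesterase-inhibitor-like class, `ACHEI`) among subjects aged 50+
with a dementia-type diagnosis are compared to dementia-diagnosed subjects
untreated with any anti-dementia medication, across outcome groups such as
gastrointestinal, psychological, respiratory, hematological and hepatic
disturbance, and death.

Everything in the pipeline operates on a weekly discrete time grid: person
time, exposure status, covariate windows and events are all resolved to
7-day bins anchored at each subject's index day. A week is the finest unit
at which claims data meaningfully resolve clinical state, and a common grid
keeps every downstream estimator simple and exactly reproducible.

# Data model and protocol constants

All dates are integer day offsets from the study start (day 0); enrollment
months are fixed 30-day bins of the study calendar. The protocol constants
live in one `study_config()` object:

* `washout_days = 180` — the drug-free, fully enrolled baseline period
  required before an incident course (and before an untreated index visit),
  which must also contain at least one medical claim so that the subject is
  demonstrably engaging care.
* `course_gap_days = 60` and `course_tail_days = 60` — a course of therapy
  ends 60 days after its last supplied day once a supply gap of at least 60
  days begins.
* `episode_gap_days = 28` — two claims of the same outcome group belong to
  the same episode of care unless separated by at least 4 claim-free weeks.
* `window_weeks = 6` — the case-crossover windows.
* `caliper_sd = 0.2` — propensity caliper in SD units of the logit score.

# Exposure reconstruction

Dispensings are converted to supplied-day timelines with a stockpiling
rule: each fill contributes `days_supply` days starting at the later of its
dispense day and the day after the previous supply ran out, so overlapping
refills push supply end-to-end without cap. Courses are maximal supply runs
not interrupted by a 60-day gap; the course persists through the first 60
days of the terminating gap. The incident course is the first one whose
180-day washout is fully inside the study period, fully enrolled, free of
*any* anti-dementia supply (not just the exposure class), and contains a
medical claim. Courses whose washout would begin before the data do are
never classified incident: an unobservable washout cannot distinguish a
new user from a prevalent one, and prevalent users carry depletion-of-
susceptibles bias.

# Cohorts and baseline assessment

The treated arm holds incident users, indexed at the course start; the
untreated arm holds eligible subjects with *no* exposure dispensing in the
whole study period, indexed at their first dementia-coded outpatient visit
that allows a fully observed baseline. Anchoring the untreated clock at a
dementia visit selects people actively engaging care, the same way a
prescription does for the treated. Non-incident (prevalent) users belong
to neither arm.

Baseline covariates are measured index-exclusively over the 180 days before
index: age (mid-year convention), sex, a comorbidity count (distinct
comorbidity-role code groups hit by a primary diagnosis), a pharmacy-based
comorbidity proxy (distinct drug classes dispensed), utilization counts
(clinic visits, hospitalizations, emergency visits), hospice and
nursing-home contact, statin use (an indicator of being well enough for
preventive care), and per-outcome baseline episode flags. Comorbidity
detection uses the primary diagnosis only, for symmetry with outcome
detection; a configuration flag supports all-position coding when inputs
carry it.

Follow-up runs from the index week to censoring at death, terminal
disenrollment (a gap never followed by re-enrollment), study end, or — in
the default `as_treated` mode — the treated course end. Temporary
enrollment gaps contribute no at-risk person-time but do not end follow-up.

# Outcomes and episodes of care

An outcome event is any claim whose *primary* diagnosis falls in the
group's code set. Claims cluster: one clinical problem generates an index
visit plus follow-up visits. Episodes of care resolve this: a claim starts
a new episode only if at least 28 days separate it from the previous claim
of the same group, with the gap measured claim-to-claim in days (day-level
arithmetic keeps the rule independent of the week anchor). Episode starts
are the unit outcome; the 28-day rule is what prevents immediate
re-counting of the same clinical episode.

# Matching

Each outcome gets its own propensity model (logistic regression of
treatment on the outcome's covariate list) because risk factors differ by
outcome. Matching is 1:1 greedy nearest-neighbor without replacement under
a Mahalanobis metric over the logit score joined with key prognostic
covariates (pooled within-arm covariance), admissible only within a 0.2-SD
logit caliper and under exact constraints (the outcome's baseline episode
flag; for death, baseline hospice care exactly and age within a ±5-year
band). Treated subjects are processed hardest-first (descending logit
score) and distance ties break to the smaller untreated identifier, so the
result is fully deterministic. Balance diagnostics report Welch t and
Pearson chi-square p-values plus standardized mean differences; they are
diagnostics, not inference, so no multiplicity adjustment is applied.

# Estimation

*Incidence densities* are episode starts per 100 person-years (at-risk
weeks × 7 / 365.25), with a normal-approximation interval and the exact
Poisson bound `[0, 369/PY]` at zero events.

*Hazard ratios* come from a Cox model on the weekly counting-process
layout, with episode starts as recurrent events (the subject is back at
risk the following week — the 28-day episode rule itself guards against
re-counting), Breslow tie handling, and pair strata in the matched
analysis. Two variance estimators are exposed, with defaults chosen by
fit type:

* Crude (single-stratum) fits use the robust sandwich clustered on
  subject, since latent heterogeneity and recurrence overdisperse event
  counts.
* Pair-stratified fits use the model-based variance of the conditional
  partial likelihood. In Monte-Carlo evaluation under the null scenario
  (2,000 subjects), the empirical sd of the matched log-HR was 0.225
  against a mean model SE of 0.221, while the subject-clustered sandwich
  averaged 0.135 — a known small-stratum pathology (score residuals shrink
  within two-subject strata), which would inflate the type-I error to
  about 20%. The conditional partial likelihood is a genuine likelihood
  for the pair-stratified design, and its information-based variance is
  the calibrated choice.

*Case-crossover* contrasts compare, within treated subjects, event odds in
the first (weeks 0–5) and second (weeks 6–11) treatment windows against a
6-week pre-treatment referent window anchored the week after the most
recent baseline clinic visit that lets the window end before week 0. With
one binary event indicator per window, the conditional-likelihood odds
ratio is the discordant-pair ratio `n10/n01`, reported with the Wald
interval `exp(log(n10/n01) ± 1.96·sqrt(1/n10 + 1/n01))`; a zero discordant
count degenerates to a one-sided exact conditional bound with a warning.
A window is usable only if it lies inside the study period and the subject
is enrolled and alive through all of its weeks.

One property of the referent-window rule deserves emphasis: because the
anchor is the *latest* qualifying visit, the stretch of weeks between that
visit and the latest possible anchor position is outpatient-claim-free by
construction, and the referent window overlaps it whenever visits are
sparse. At this package's generator settings (≈0.6 clinic visits per week,
matching a typical dementia population) this deflates the referent event
rate by roughly 15–20%, inflating null crossover odds ratios by about
`exp(0.24)`. The effect is intrinsic to the anchored-window design, not to
the estimator (re-running the same data with a fixed referent window six
weeks earlier shows no inflation); it shrinks as claim density grows, and
in dense real claims it is negligible. Users comparing first- and
second-window odds ratios (the acute-versus-transient contrast) are
unaffected, since both share the same referent.

# The synthetic-claims generator

Real claims from the motivating setting are not distributable, so the
package ships a generator whose defaults *are* the study conditions used
in validation. One latent gamma frailty (mean 1, shape 2) per subject
drives everything that makes claims data hard: it raises comorbidity
burden, utilization, hospice and nursing-home contact and the death
hazard, lowers statin use, and lowers the chance of treatment — so the
untreated group is frailer, and crude death comparisons make treatment
look protective. Treatment assignment is a logit on age, comorbidity
count, statin, hospice, nursing-home status and frailty itself; the
observable proxies (especially the Poisson clinic-visit intensity, which
scales with frailty) carry most of the frailty signal, so matching on
measured baseline covariates removes most but not all confounding —
mirroring what a real propensity analysis can and cannot do.

Outcome events follow weekly Bernoulli hazards
`h0_g · frailty^γ_g · exp(β_g·age) · HR_g^{exposed}`, with baseline weekly
hazards (0.004 gastrointestinal, 0.006 psychological, 0.005 respiratory,
0.003 hematological, 0.0008 hepatic, 0.0035 death) chosen to reproduce
incidence densities of roughly 20–50 episodes per 100 person-years, the
scale reported for dementia populations. The exposure effect applies over
the exposure era as the course convention defines it (supplied days plus
the 60-day tail), so the generator's `HR_g` coincides with the as-treated
analysis estimand rather than being diluted by the tail. Each latent event
emits an index claim in its week plus a truncated-geometric burst of 0–3
follow-up claims at 7–21-day offsets — exactly the clustering the episode
rule must undo. Refill chains stop with probability 0.12 per refill
(median course ≈ 33 weeks), 15% of stoppers restart after a variable gap
(exercising course segmentation), 8% of treated get a washout-violating
earlier fill (prevalent users), and monthly disenrollment (p = 0.01, 70%
temporary) produces enrollment churn. Death risk starts at the entry week,
so the population is alive at cohort entry by construction.

Four presets name the validation conditions: `null_all` (all HR 1),
`gi_effect` (gastrointestinal HR 2), `frailty_death` (death HR 1 with
strong frailty links — the confounding-reversal scenario), and
`acute_transient` (hematological hazard ×3 during the first six exposed
weeks only).

What the generator does *not* emulate: realistic diagnosis-code
frequencies, seasonal or secular trends, provider-level coding habits,
claim costs, and informative therapy stopping (refill persistence is
independent of health state). Passing tests therefore demonstrate that the
estimators do what they claim under known, fair conditions — not that any
particular real-data association is causal.

# Validation design and problem sizes

The test suite validates each stage against an independent oracle or a
known truth, at sizes chosen to keep the full run in the tens of minutes:

* course and episode reconstruction against brute-force day-level scans
  (1,000 random dispensing histories, 500 event streams);
* the crossover estimator against `survival::clogit` on 200 random window
  fixtures (agreement to 10⁻⁶);
* parameter recovery: 200 replicates of `gi_effect` at 4,000 subjects —
  the mean matched log-HR must sit within ±0.10 of log 2 (residual
  attenuation from episode merging and noisy-proxy confounding is about
  −0.06) and the 95% CI must cover 2.0 in 90–98% of replicates;
* type-I error: 400 replicates of `null_all` at 2,000 subjects, with both
  the matched Cox and the crossover Wald test required to reject in
  2.5–8% of replicates;
* confounding reversal and balance: 100 replicates of `frailty_death` at
  4,000 subjects — crude death HR below 1 in ≥95%, matched CI covering 1
  in ≥90%, and all propensity-covariate |SMD| below 0.1 after matching in
  ≥95%. The coverage clause is the one check the current generator
  settings do not meet: matching removes about two-thirds of the
  simulated confounding (matched log-HR ≈ −0.23 against a crude ≈ −0.69),
  but the preset's direct latent-frailty term in the treatment model
  leaves residual confounding that measured proxies cannot absorb, and
  the matched CI covers the true null in about 82% of replicates. This is
  reported as measured rather than adjusted away, because it is exactly
  the caution the confounding scenario exists to teach: matching on
  measured covariates attenuates, but does not abolish, confounding by
  indication;
* acute transience: 200 replicates of `acute_transient` at 3,000 subjects,
  with the first-window OR exceeding the second-window OR in ≥80%.

# Numerical and degenerate-input choices

Ties in the censoring day resolve death > course end > disenrollment >
study end. A constant covariate in the Mahalanobis key is an error (the
metric is singular); a numerically constant propensity score (identical
arms) instead drops out of the metric and opens the caliper, so clone
populations match at distance zero. Perfect separation in the propensity
fit is detected explicitly and pointed at a ridge fallback (small-L2
Newton solver). A monotone partial likelihood is flagged and reported with
an infinite-bound interval rather than a spurious Wald CI. Matching can be
re-run under a frozen `metric` (transform plus absolute caliper), which
makes the pairing provably invariant to removing never-matched candidates.

# Known limitations

The comorbidity and pharmacy-risk scores are transparent count proxies,
not licensed grouper software; code groups are supplied as data so real
dictionaries can be dropped in. Only primary diagnoses drive detection.
The untreated index rule requires an outpatient dementia visit, so
subjects managed purely in inpatient settings never enter the comparison.
Matched estimates remain subject to residual confounding from whatever
frailty signal the measured covariates miss; the generator quantifies this
at about −0.03 on the log-HR scale under its default settings, and real
data offer no such bound.
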