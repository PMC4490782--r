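# claimsignal

Directed adverse-drug-reaction (ADR) signal detection from administrative
claims data.

`claimsignal` implements a complete surveillance pipeline for asking
whether starting a drug raises the rate of pre-specified clinical
outcomes, using nothing but routine claims tables: pharmacy dispensings,
diagnosis-coded medical claims, monthly enrollment spans and death
records. It is built for the new-user dementia-treatment setting —
incident users of an acetylcholinesterase-inhibitor-like class compared to
dementia-diagnosed subjects untreated with anti-dementia therapy — but
every protocol constant, drug class and diagnosis code group is
configuration, not code.

The pipeline stages:

1. **Drug-era reconstruction** — dispensings become supplied-day timelines
   under an end-to-end stockpiling rule; courses end 60 days after the
   last supplied day once a ≥60-day gap begins; the *incident* course is
   the first with a fully observed, fully enrolled, 180-day anti-dementia-
   free washout containing at least one medical claim.
2. **Cohort construction** — treated subjects index at the incident course
   start; untreated subjects (no exposure dispensing at all) index at
   their first dementia outpatient visit with an observed baseline.
   Person-time is laid out on a weekly grid with censoring at death,
   terminal disenrollment, study end, or course end.
3. **Outcome detection** — primary-diagnosis claims grouped into *episodes
   of care*: a new episode requires a 4-week claim-free gap, so clustered
   claims for one clinical problem count once.
4. **Per-outcome matching** — a propensity model per outcome, then 1:1
   greedy Mahalanobis matching over the logit score plus key prognostic
   covariates, inside a 0.2-SD caliper, with exact constraints (baseline
   episode flag; for death, hospice and a ±5-year age band), plus balance
   diagnostics (Welch t, Pearson chi-square, standardized mean
   differences).
5. **Estimation** — incidence densities per 100 person-years;
   pair-stratified recurrent-event Cox hazard ratios (crude and matched);
   and a case-crossover analysis comparing event odds in the first and
   second 6-week treatment windows against a pre-treatment referent
   window, `OR = n10/n01` by conditional likelihood.

A synthetic-claims generator with explicit confounding-by-indication
structure (a latent frailty that makes untreated subjects sicker, die
more, and visit more) provides ground truth for every stage; four presets
(`null_all`, `gi_effect`, `frailty_death`, `acute_transient`) define the
validation scenarios. See the methods vignette
(`vignettes/claimsignal-methods.Rmd`) for the statistical design and its
assumptions.

## A worked example

Simulate a population of 2,000 subjects in which treatment truly doubles
the gastrointestinal hazard and has no effect on death, then run the full
pipeline:

```r
library(claimsignal)

sim <- simulate_bundle(preset("gi_effect", n_subjects = 2000, seed = 7))
res <- run_pipeline(config = sim$config, bundle = sim$bundle,
                    outcomes = c("gastrointestinal", "death"), quiet = TRUE)
res$report$hazard
#>             outcome analysis    hr ci_lower ci_upper  p_value n_events n_subjects
#> 1: gastrointestinal    crude 1.509    1.212     1.88 0.000237      501       1841
#> 2: gastrointestinal  matched 1.723    1.203     2.47 0.002993      194        748
#> 3:            death    crude 0.669    0.466     0.96 0.029064      363       1841
#> 4:            death  matched 0.818    0.492     1.36 0.439346      109        746
```

Reading the table: the matched gastrointestinal hazard ratio (1.72, 95% CI
1.20–2.47) recovers the simulated effect of 2. Death shows the classic
confounding-by-indication reversal: the crude comparison makes treatment
look protective (HR 0.67, p = 0.03) because frail subjects are both less
likely to be treated and more likely to die, while the propensity-matched
comparison is compatible with the true null (HR 0.82, 95% CI 0.49–1.36).

```r
res$report$incidence[outcome == "gastrointestinal"]
#>             outcome               arm n_episodes person_years incidence_density ci_lower ci_upper
#> 1: gastrointestinal           treated         92          253              36.3     28.9     43.7
#> 2: gastrointestinal         untreated        409         1816              22.5     20.3     24.7
#> 3: gastrointestinal matched_untreated        102          487              20.9     16.9     25.0
```

Incidence densities are episodes of care per 100 person-years: 36.3 in
treated follow-up against 20.9 in the matched untreated cohort.

```r
res$report$crossover[outcome == "gastrointestinal"]
#>             outcome  contrast    or ci_lower ci_upper p_value n10 n01
#> 1: gastrointestinal w1_vs_pre  4.00    1.501    10.66 0.00556  20   5
#> 2: gastrointestinal w2_vs_pre  2.11    0.955     4.67 0.06481  19   9
```

The case-crossover contrast compares each treated subject with themselves:
20 subjects had a gastrointestinal event in the first treatment window
only versus 5 in the pre-treatment window only (OR 4.0), attenuating in
the second window — the signature of an effect concentrated early in
therapy.

`run_pipeline(..., out_dir = "results/")` additionally writes
`balance.csv`, `incidence.csv`, `hazard.csv`, `crossover.csv` and a
plain-text run manifest. A thin command-line wrapper with the same stages
(`simulate`, `courses`, `cohort`, `episodes`, `match`, `estimate`,
`crossover`, `run`) is installed at `inst/cli/claimsignal`.

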