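---
title: "Ensemble Cox modelling with curated ad-hoc feature selection: methods and design choices"
author: "cafsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble Cox modelling with curated ad-hoc feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cafsurv)
```

## The modelling problem

The package addresses survival prediction from baseline clinical
covariates in pooled multi-trial oncology cohorts — the archetype being
metastatic castration-resistant prostate cancer patients on first-line
docetaxel, with time to death right-censored for a third or more of
patients. The covariates are heterogeneous: dozens of sparse binary
flags (medical history, prior medications, metastasis sites),
correlated laboratory values, demographics, and lesion-level
measurements with trial-specific missingness. No prespecified model
covers this space; the package's answer is a disciplined search.

All times are stored in days. Evaluation windows quoted in months use
1 month = 30.4375 days (mean Gregorian month), so the default 6–30
month window is 182.625–913.125 days.

## Risk model and fitting

Every candidate model is a Cox proportional hazards regression; the
risk score is the linear predictor $x^\top\beta$. Fitting maximises the
Breslow partial likelihood by Newton–Raphson with step halving,
declaring convergence when the relative change in log partial
likelihood falls below $10^{-9}$ (at most 100 iterations). Breslow tie
handling is used everywhere — including the univariable fits behind
z-score weights and protective/harmful labels — so every z-statistic in
the package shares one convention. The optimizer is implemented in
compiled code (the search needs $10^5$–$10^6$ fits); the test suite
verifies agreement with `survival::coxph(..., ties = "breslow")` to
$10^{-6}$ and better on coefficients and standard errors. Categorical
covariates are reference-coded against their first (alphabetical)
level; an interaction $\{A,B\}$ expands to all products of the two
terms' expanded columns; design columns are centered at their training
means, making the risk score zero for an average patient. A
rank-deficient design or failed convergence marks the model
`converged = FALSE`; the search skips such candidates instead of
stopping.

## Derived clinical features

* **Binary-block merging.** `merge_binary_block()` collapses a block of
  0/1 items by `logical_or` (any item), `sum` (item count) or
  `zscore_sum` ($\sum_j z_j x_{ij}$, $z_j$ the item's univariable Cox
  Wald statistic on the training outcome). Items constant in the
  training data get weight 0 (their fit is undefined), with a warning.
  Missing entries count as "absent" (0) — an unreported history item —
  rather than propagating `NA` through a sum; this is a deliberate
  deviation from the package's otherwise strict missingness rules and
  is confined to binary blocks.
* **Protective/harmful labels.** An item is *protective* when its
  univariable z exceeds +1.64, *harmful* below −1.64 (strict
  inequalities; 1.64 is the two-sided 10% normal quantile). Because a
  positive Cox coefficient on a presence indicator means *higher*
  hazard, the printed convention can read as inverted; the comparison
  is implemented literally and `flip_sign = TRUE` swaps the two labels
  for the opposite reading. `derive_harm_pro()` then combines the two
  per-patient counts with their joint-fit z-scores, optionally
  adjusting the fit for additional covariates (the `harm_pro2`
  variant); the fitted z's are retained so the feature is reproducible
  on new data.
* **Target lesion volume.** TLV is the per-patient sum of lesion sizes
  (one row = one lesion). A row with a missing size is dropped from the
  sum only when the patient has at least one observed size; a patient
  with no observed sizes is routed to imputation rather than silently
  zeroed. Imputation computes, within each survival stratum
  (died/censored) of a reference cohort, total TLV divided by **total**
  lesion count, and multiplies the stratum average by the target
  patient's **non-bone** lesion count. Dividing by non-bone count in
  the reference instead is arguable; the package uses total count and
  documents the alternative here.
* **Laboratory PCA.** Labs are centered and unit-scaled before the
  eigendecomposition ("normalisation" without further detail is
  operationalised as standardisation). "Contributing significantly" to
  component 1 is operationalised as an absolute loading of at least
  `loading_threshold` (default 0.25 ≈ $1/\sqrt{2p}$ for ten labs); the
  stored center/scale/loadings project new data without re-estimation.
* **Recodings.** Age risk: 0 for age > 75, 1 for age < 65, 2 for 65–75
  inclusive (the non-monotone coding reflects the empirically observed
  age–survival relation; both boundary ages fall in category 2). Race:
  case-insensitive {white, other} → 1, else 0. ECOG is emitted both as
  a numeric copy and as one-hot indicators so the search can choose the
  representation.

## Performance estimation and the search

**Monte-Carlo cross-validation.** Performance of a candidate model is
the mean of the criterion over repeated unstratified random splits:
two-thirds of patients fit the model, the remaining third is scored.
Splits that fail (non-convergence, undefined criterion) are excluded
and counted in `n_failed`. Within one screening round all candidates
share the same splits — a paired comparison that removes split-to-split
variance from the ranking (disable with `shared_split_seeds = FALSE`).
Every split derives deterministically from the configured seed.

**The criterion** is the integrated time-dependent AUC. The
cumulative/dynamic AUC at $t$ is the probability that a patient dead by
$t$ outranks a patient under observation beyond $t$; censoring is
handled by inverse-probability-of-censoring weights from a
Kaplan–Meier estimate of the censoring distribution (cases weighted
$1/\hat G(T_i^-)$, the uniform control weight cancels), risk ties
counting 1/2. Without censoring this is exactly the two-sample
Mann–Whitney statistic, which the tests verify by exhaustive pair
counting. The iAUC is the trapezoidal integral over the window,
normalised by the spanned interval, over the distinct event times in
the window by default or a fixed `eval_times` grid (a ~25-point grid
gives indistinguishable rankings at a fraction of the cost and is used
in the heavier simulation studies). The concordance index is Harrell's
c via `survival::concordance` (an exhaustive pair-count oracle backs it
in the tests); RMSE is computed over observed deaths only.

**Candidate generation.** Forward: for each feature $f$ outside the
model, one base candidate adding $f$, plus one candidate per existing
main term $m$ adding $f$ and $f{:}m$ — $|F|(1+|\text{mains}|)$
candidates. Backward: one candidate per removable term; removing a main
effect removes its interactions too (the hierarchy rule — orphaned
interactions are never kept). Features in a spec's exclusion set never
enter any candidate.

**Two-stage schedule.** Forward candidates are screened at
`reps_screen` (default 500) repetitions; the `top_k` (default 30) by
mean criterion are re-estimated at `reps_full` (default 10,000) with
fresh splits and re-ranked. At 10,000 repetitions the estimate is
stable to roughly three decimals, which is what makes improvement
tolerances of $10^{-3}$ meaningful.

**Curation.** Each iteration ends with a decision — expand with a
chosen candidate, attempt a shrink pass, or terminate — made by a
pluggable *curator* receiving the ranked candidates and the full trace.
The default `curator_greedy` chooses the top candidate and expands
while the gain is at least `improvement_tol` (default 0.001, the
operationalisation of "only marginal increases"); otherwise a shrink
pass evaluates all backward candidates at `reps_full` and accepts the
best if it strictly improves; termination follows when neither helps.
The hook is the automated stand-in for a panel of experts nominating
the best current model, and an interactive or rule-based curator can
reproduce their vetoes (e.g. rejecting an implausible interaction that
happens to top the ranking).

**Interaction bias and the complexity penalty.** Because an
interaction candidate adds two parameters where a base candidate adds
one, greedy selection on the raw criterion is biased toward
interactions. The config exposes `complexity_penalty` $\lambda$,
ranking candidates by $\bar m - \lambda\,n_{\text{terms}}$; the default
is 0 (the plain criterion), and the package's simulation studies use
$\lambda = 0.005$, which emulates a skeptical curator: a new term must
buy at least half a percent of iAUC beyond the tolerance. This is the
automated counterpart of rejecting marginal interactions by hand.

**Branching.** Ensemble members are obtained by running independent
seeded searches from different initial models and/or with per-branch
feature exclusions (e.g. banning the first lab component to force a
differently-shaped model). Branches that converge to identical specs
are deduplicated with a warning; a branch failure never aborts its
siblings.

## Ensemble and time-to-event map

The ensemble risk is $\sum_m w_m r_m(i)$ with weights on the
probability simplex. Member risk scores are z-standardised across the
scored cohort by default: linear predictors from different
specifications have incomparable scales, and unstandardised summation
would weight members by the accident of their coefficient magnitudes
(standardisation can be disabled for strictly comparable members).
`search_weights()` draws `n_init` (default 100) uniform simplex vectors,
always evaluates the equal-weight vector, scores every vector on the
same Monte-Carlo splits (members refitted per split, so the estimate is
honest), and breaks exact ties in favour of equal weights — the
documented default.

Point predictions of days to death use $TTE_i = f(risk_i) +
\varepsilon_i$ with $f$ a penalised cubic regression spline
(`mgcv::gam`, basis dimension 10, GCV-selected smoothness), fitted on
patients with observed deaths only; censored rows never influence the
fit. Predictions clamp to the fitted risk domain (spline extrapolation
of death times is unsafe) and floor at 1 day. No monotonicity
constraint is imposed; shape checks in the tests allow a 5-day wiggle
tolerance. The deaths-only regression is biased toward shorter times in
heavily censored data — a known property of the approach, retained
deliberately.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline
must survive, not any particular trial's marginals:

* several trials (default 1600 patients in three trials, matching the
  scale of a pooled training set) with a standard-normal latent
  *severity* factor per patient;
* three binary blocks (defaults: 12 history, 10 medication, 8
  metastasis items at prevalence 0.3) with sparse true log-hazards of
  |0.3|–|0.5|, one pairwise interaction (0.35);
* ten labs, the first six loading 0.8 on the severity factor with
  residual sd 0.6 — so lab PC1 is prognostic and its significant-lab
  set is known ground truth;
* severity enters the hazard at 0.8 per SD; lesion counts are Poisson
  with log-mean shifted 0.25 per severity SD (lesion burden is
  prognostic), sizes log-normal(0.8, 0.5); one trial's lesion sizes are
  hidden to exercise TLV imputation;
* event times follow a Cox–Weibull model (shape 1.2, scale 900 days —
  median survival around 600 days at average risk, rising hazard
  typical of advanced disease); censoring is independent exponential
  with its rate calibrated by root finding so the realised censoring
  fraction matches the target (default 0.35).

What it does **not** emulate: inter-trial effect heterogeneity, real
marginal distributions, informative censoring, measurement error in
labs, or missingness outside the lesion plan. Passing tests therefore
demonstrate that the machinery is correct under a proportional-hazards
world of realistic size and censoring — not that any particular
clinical conclusion transfers.

## Problem sizes in the test suite

The simulation studies in the tests use: metric-oracle equivalence on
200 exhaustive fixtures ($n \le 20$); null calibration at $n = 2000$
over 50 replicates; coefficient recovery at $n = 2000$ over 20
replicates (3-SE coverage ≥ 95%); selection recovery on 10 seeded
searches over 25 binary features (5 informative at |log HR| ≥ 0.5,
$n = 1500$, 100/1000 screening/rescreening repetitions, top 10
rescreened, $\lambda = 0.005$, 25-point iAUC grid); ensemble gain on 10
seeded branch-search runs at $n = 600$; TTE recovery on 5 fixtures of
500. These sizes give each property comfortable statistical margins
while keeping a full suite run in the tens of minutes on one core.

## Known limitations

* Cox models only: no time-varying covariates, stratified baselines,
  penalised fits, or competing risks.
* The IPCW cumulative/dynamic AUC is the standard estimator, not a
  formula-level reproduction of any specific published variant; in the
  uncensored limit they coincide (tested exactly), and the integration
  weighting (uniform trapezoid over event times) is one documented
  choice among defensible ones.
* Greedy search with curation explores one path per branch; it is not
  best-subset selection and inherits the local optima of greedy
  procedures — branching and the penalty mitigate but do not remove
  this.
* CV splits are unstratified by default; with very few events,
  stratified splitting (available by flag) is advisable.
* TLV imputation uses the *target* patient's survival stratum, so it is
  applicable to training-time imputation, not to prospective scoring of
  patients with unknown outcomes — matching its original role of
  harmonising historical trials.
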