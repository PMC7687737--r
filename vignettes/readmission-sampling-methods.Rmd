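---
title: "Sampling strategies and cluster-aware estimation for readmission models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling strategies and cluster-aware estimation for readmission models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital readmission risk models are usually built from discharge-level
data in which one patient contributes several discharges. Two analytic
choices that are often made casually turn out to matter a great deal:

1. **Sampling frame.** Including only each patient's *first* discharge
   yields one independent observation per patient, but systematically
   underestimates the population readmission rate: patients who are
   discharged often are exactly the patients who are readmitted often, and
   the first-discharge frame downweights them. Including *all* discharges
   doubles the apparent incidence in a typical chronic-disease cohort.
2. **Estimation.** With all discharges included, outcomes are clustered
   within patients, and cluster size is *informative* — the number of
   discharges a patient accumulates is correlated with that patient's
   per-discharge risk. Ordinary logistic regression ignores the
   clustering; generalized estimating equations (GEE) handle the
   correlation but are biased toward the large clusters under informative
   cluster size; cluster-weighted GEE (CWGEE) down-weights each cluster by
   its size and targets the per-patient marginal model.

`readmitclust` implements both sampling frames, all three estimators, the
cohort-construction rules (transfer merging, 30-day labeling), a two-stage
variable-selection protocol, five performance measures, and a resampling
experiment over cohort sizes — driven by a synthetic cohort generator
whose one essential feature is informative cluster size.

## The synthetic cohort

Real discharge-level cohorts of this kind are not publicly deposited, so
the package ships a generator that emulates their structure. For patient
$i$:

$$u_i \sim N(0, \sigma^2), \qquad
  n_i = 1 + \mathrm{Poisson}\!\left(\lambda e^{\gamma u_i}\right), \qquad
  Y_{ij} \mid X_{ij}, u_i \sim
  \mathrm{Bernoulli}\!\left(\operatorname{expit}(\alpha + \beta^\top X_{ij} + u_i)\right).$$

The latent frailty $u_i$ enters **both** the cluster-size intensity and
the outcome logit. This shared-parameter construction is the minimal
mechanism that makes cluster size informative: $\gamma = 0$ or
$\sigma = 0$ switches the phenomenon off, and the gap between the
all-discharge and first-discharge readmission rates grows monotonically in
$\gamma$.

Covariates come in two kinds. Discharge-varying covariates are standard
normal, drawn fresh at each discharge. Patient-constant covariates are
binary with
$X^{c}_{ik} \sim \mathrm{Bernoulli}(\operatorname{expit}(\kappa u_i))$ —
marginally Bernoulli(0.5), but correlated with the frailty
(`frailty_loading`, default $\kappa = 0.6$). The loading mimics chronic
comorbidity indicators that track a patient's underlying illness burden.
It matters for one documented phenomenon: without any observed covariate
correlated with the frailty, a fitted model's predicted risk would be
independent of cluster size by construction, whereas in real cohorts the
predicted readmission rate correlates positively with the discharge
count. With the loading, that correlation is positive here too.

### Default parameters

The defaults emulate a large single-center adult cohort: 17,284 patients,
about 2.56 discharges per patient, a ~10% readmission rate among first
discharges and ~20% among all discharges. They were chosen by matching
those cohort-level targets, and are not revisited:

| parameter | symbol | default | role |
|---|---|---|---|
| `frailty_sd` | $\sigma$ | 1.0 | between-patient heterogeneity |
| `cluster_rate` | $\lambda$ | 0.67 | mean excess discharges at $u=0$ |
| `informativeness` | $\gamma$ | 1.3 | frailty effect on cluster size |
| `baseline_logit` | $\alpha$ | $-3.0$ | overall incidence level |
| `frailty_loading` | $\kappa$ | 0.6 | frailty in constant covariates |
| `covariate_effects` | $\beta$ | mixed 0–0.5 | 12 effects, incl. weak and null |

The twelve default covariates deliberately mix strong, weak and null
effects. Readmission models in practice screen dozens of candidate
variables, most weakly informative; it is precisely the weak ones whose
selection is unstable in small samples, which is what makes model
performance size-dependent.

### Timeline mode

With `timestamps = TRUE` the generator emits admission/discharge times
such that the labeling operations reconstruct the latent outcomes
exactly: gaps after a readmitted discharge are uniform on (8 h, 30 d],
gaps after a non-readmitted discharge uniform on (30 d, 365 d], and
lengths of stay uniform on 1–10 days, all rounded to whole seconds so the
ISO-8601 CSV round-trip is lossless. Only the 30-day threshold is
scientifically meaningful; the gap distributions are conveniences. Because
a patient's last discharge has no later admission to observe, its latent
outcome is forced to 0 in this mode.

Two boundary conventions are declared (the thresholds themselves come
with no open/closed convention attached): a gap of exactly 8 h *merges*,
and a readmission at exactly 30 × 24 h *counts*. Both are tested
bit-exactly.

### Reproducibility

One global seed is split into per-patient child seeds, and every draw for
patient $i$ comes from the stream seeded by child seed $i$. Extending the
cohort therefore never perturbs earlier patients' data, and the same
`(config, seed)` pair yields a byte-identical table.

## Estimators

All three estimators solve
$\sum_i w_i D_i^\top V_i^{-1} (Y_i - \mu_i) = 0$ with a logit mean:
ordinary logistic regression (independence working structure, all
$w_i = 1$; solved by IRLS), exchangeable GEE ($w_i = 1$), and CWGEE
($w_i = 1/n_i$). The exchangeable inverse
$R^{-1} = [I - \tfrac{\rho}{1+(n_i-1)\rho} J]/(1-\rho)$ is applied in
closed form, so each Fisher-scoring pass is a set of grouped vector
operations; no per-cluster matrices are built.

Numerical choices worth knowing:

* **$\rho$ estimator.** The exchangeable parameter is re-estimated each
  outer iteration from Pearson residuals using the standard Liang–Zeger
  style convention — dispersion estimated with $N - p$ degrees of freedom
  and the pair count reduced by $p$ — rather than the bare pair-count
  denominator. The reason is cross-software agreement: this is the
  convention general-purpose GEE implementations use, and the test suite
  verifies agreement with one to $10^{-4}$ (observed: $\sim 10^{-7}$) on
  200 small datasets.
* **Valid range.** $\hat\rho$ is clamped to the positive-definiteness
  range $(-1/(n_{\max}-1),\ 0.99]$, with a warning when clamping binds.
  Negative moment estimates inside the valid range are legitimate in
  small samples and are *not* truncated at zero.
* **Damped scoring.** A proposed Fisher step larger than 2 in any
  coordinate is scaled back. On heavy-tailed draws where one giant
  cluster dominates, the $\rho \leftrightarrow \beta$ feedback can
  otherwise diverge (reference implementations return NaN on such data);
  the damped solver returns finite estimates flagged `converged = FALSE`.
* **Convergence** is the largest coefficient update falling below
  $10^{-8}$, at most 100 outer iterations, initialized at the
  independence solution. Clusters with constant outcomes contribute
  normally. Perfect separation is detected (fitted probabilities at
  machine bounds) and flagged, never silently returned.
* **Inference** uses the cluster-robust sandwich covariance for all three
  methods — for logistic regression on all discharges this is the
  cluster-robust SE, the defensible default under clustering. The
  weights $w_i$ enter bread and meat consistently.

## Variable selection

The two-stage protocol mirrors common epidemiological practice: a
univariate screen retains candidates with robust Wald $p < 0.1$; a
best-subset search then minimizes AIC (logistic) or QIC (GEE/CWGEE),
with $\mathrm{QIC} = -2\,\mathrm{QL} +
2\,\mathrm{tr}(\hat\Omega_I \hat V_r)$; finally covariates with
$p \ge 0.05$ are pruned backward, least significant first (ties: smaller
$|z|$ dropped first, then reverse lexical order), refitting after each
removal.

The subset search is exhaustive up to `exhaustive_limit` screened
candidates (default 15 when called directly — verified against an
independent `glm`/AIC enumeration at $p = 12$) and a forward search under
the same criterion beyond it. Inside the resampling study the limit
defaults to 8: a study cell refits the model for every visited subset,
and a full size grid with exhaustive enumeration over 10+ candidates
would cost hours for no change in the study's conclusions. Rank-deficient
subsets are infeasible and skipped with a note, so of two collinear
candidates exactly one can survive.

## Performance measures

Five measures are computed on the validation sample, each with an
explicit undefined marker (`NA`) for degenerate inputs rather than a
silent 0: the C statistic (Mann–Whitney form, ties counting ½), the
Pearson correlation between outcome and prediction, the coefficient of
discrimination $D = |\bar p_{Y=1} - \bar p_{Y=0}|$, the Brier score, and
the scaled Brier score $1 - \mathrm{Brier}/\mathrm{Brier}_{\max}$ with
$\mathrm{Brier}_{\max} = \bar p (1 - \bar p)$.

$\bar p$ in $\mathrm{Brier}_{\max}$ is taken to be the *observed
incidence* of the evaluation sample: for a calibrated model the mean
predicted probability approximately equals the incidence, and the
observed rate is the quantity that differs so sharply between the two
sampling frames — which is the point of scaling. The mean-prediction
convention is available as a switch (`brier_max = "mean_prediction"`).

The raw Brier score is the measure that makes first-discharge-only
analyses look deceptively good: with a ~10% incidence a noninformative
model scores about 0.09, against about 0.16 at a ~20% incidence. The
scaled score removes exactly this dependence, and the study shows the
first-discharge advantage evaporating under it.

## The resampling study

`run_study()` draws patient subsets of increasing size from a master
cohort (independently per size, not nested), splits each 60/40 *at the
patient level* — no cluster ever straddles the split — runs the full
screen/select/fit pipeline for each strategy (LR-first, LR-all, GEE,
CWGEE), and evaluates each model in its own sampling frame: a model
trained on first discharges is validated on the validation patients'
first discharges. One draw per size is the default, mirroring the
single-trajectory design such experiments usually report; the test suite
uses 5 independent seeds. `slope_analysis()` regresses each measure on
cohort size (slopes per 1000 patients) and adds an ANCOVA-style
size-by-method interaction test per metric; both the common-slope and
full-interaction models are computed since either parameterization is
defensible.

Problem sizes used by the automated checks: the qualitative-reproduction
suite runs 5 seeds over the grid {2000, 4000, 6000, 8000} on
8000-patient master cohorts; parameter recovery uses 10 seeds of 5000
patients; the cross-implementation oracle uses 200 datasets of 10–15
clusters. These sizes give stable sign conclusions at a few minutes'
runtime; larger grids change nothing qualitatively.

## What the synthetic tests do and do not show

The generator reproduces the *structural* phenomena — informative
cluster size, the first-vs-all rate gap, the falsely optimistic Brier
score, selection instability in small samples, and the positive coupling
of discharge count with readmission count and predicted risk. It does not
emulate real clinical covariates (46 administrative/clinical variables in
a real cohort, versus 12 generic synthetic ones), competing risks such as
death, secular trends over a 9-year window, or between-hospital loss of
readmissions. Passing tests therefore certify the estimators, the
pipeline mechanics, and the direction and rough magnitude of the
methodological effects — not any real cohort's coefficient values or
absolute AUCs.

## Known limitations

* The exchangeable moment estimator can leave its valid range on
  heavy-tailed small samples; the fit is then clamped and flagged rather
  than refused. Reference software fails less gracefully on the same
  draws.
* Forward search beyond `exhaustive_limit` is a heuristic; it can miss
  the criterion-optimal subset (exhaustive search is available whenever
  affordable).
* The exclusion criteria of real cohort construction (age limits,
  transfers, deaths, obstetric services) are exposed only as a
  user-supplied row-filter hook (`exclude_discharges()`); they are
  unobservable in synthetic data.
* Only the exchangeable working correlation is implemented; AR-1 or
  unstructured correlations, random-effects (conditional) models, and
  penalized selection are out of scope.
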