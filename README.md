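# readmitclust

Tools for a methodological question in hospital-readmission modelling:
**how do the discharge sampling frame and the treatment of within-patient
clustering change the observed 30-day readmission rate and the apparent
performance of risk-prediction models?**

Readmission cohorts contain several discharges per patient, and cluster
size is *informative*: patients who come back often are the patients at
highest per-discharge risk. Two common analytic shortcuts are then
consequential. Sampling only each patient's first discharge roughly
halves the observed readmission rate (and flatters the Brier score, which
shrinks mechanically with incidence); and ordinary logistic regression on
all discharges ignores correlation that generalized estimating equations
(GEE) handle and that cluster-weighted GEE (CWGEE) additionally corrects
for informative cluster size.

The package is aimed at biostatisticians and health-services researchers
who want these effects as a reusable, tested pipeline: a synthetic
clustered-cohort generator, cohort-construction rules, three estimator
families, two-stage variable selection, five performance measures, and a
resampling experiment over cohort sizes.

## The model

With patients $i = 1,\dots,N$ and discharges $j = 1,\dots,n_i$, outcome
$Y_{ij} \in \{0,1\}$ (all-cause readmission within 30 days of discharge)
and covariates $X_{ij}$, all fitted models are marginal logit models

$$\operatorname{logit} E(Y \mid X) = \alpha + \beta^\top X,$$

estimated by solving
$\sum_i w_i D_i^\top V_i^{-1}(Y_i - \mu_i) = 0$ with

* **LR** — independence working structure ($w_i = 1$), i.e. ordinary
  logistic regression by IRLS, with cluster-robust sandwich SEs;
* **GEE** — exchangeable working correlation $\rho$, re-estimated each
  iteration by a moment estimator on Pearson residuals ($w_i = 1$);
* **CWGEE** — the same machinery with cluster weights $w_i = 1/n_i$,
  which under informative cluster size targets the per-patient rather
  than per-discharge marginal model.

The synthetic cohort ties cluster size to risk through one shared
frailty: $u_i \sim N(0,\sigma^2)$,
$n_i = 1 + \mathrm{Poisson}(\lambda e^{\gamma u_i})$,
$Y_{ij} \sim \mathrm{Bernoulli}(\operatorname{expit}(\alpha + \beta^\top X_{ij} + u_i))$.

Model performance is summarized by the C statistic (AUC), the
outcome–prediction correlation, the coefficient of discrimination
$D = |\bar p_{Y=1} - \bar p_{Y=0}|$, the Brier score, and the scaled
Brier score $1 - \mathrm{Brier}/[\bar p(1-\bar p)]$.

## Worked example

```r
library(readmitclust)

cohort <- generate_cohort(generator_config(n_patients = 4000), seed = 42)

mean(first_discharges(cohort)$outcome)   # 0.109
mean(cohort$outcome)                     # 0.196  — same cohort, twice the rate

cluster_summary(cohort)
#> Cluster-size distribution:
#>  size_bin n_patients pct_patients n_discharges readmit_pct
#>         1       1929       48.225         1929    6.168999
#>         2        934       23.350         1868    9.368308
#>        3+       1137       28.425         6176   26.878238
#> Pearson r, log(cluster size) vs readmission count: 0.543

sp <- split_by_patient(cohort, train_fraction = 0.6, seed = 1)
screened <- univariate_screen(sp$train, method = "CWGEE")
sel <- best_subset_select(sp$train, screened, method = "CWGEE",
                          exhaustive_limit = 8)
sel$fit
#> CWGEE fit (exchangeable working correlation), 6036 obs in 2400 clusters
#>          term estimate robust_se       z    p_value
#> 1 (Intercept)  -3.3050   0.15571 -21.225 5.563e-100
#> 2         xc1   0.5658   0.13340   4.241  2.224e-05
#> ...
#> rho-hat = 0.3647

evaluate_model(sel$fit, sp$validation)
#>      auc correlation coef_discrimination brier brier_max scaled_brier ...
#> 1 0.6948      0.2647               0.048 0.149     0.152       0.0194
```

The numbers illustrate the package's subject matter directly: the same
cohort shows a 10.9% readmission rate under first-discharge sampling and
19.6% under all-discharge sampling; the readmitted fraction climbs from
6.2% of discharges among single-discharge patients to 26.9% among
patients with three or more; and the fitted CWGEE model's validation
Brier score (0.149) is only readable against its incidence-dependent
maximum (0.152).

The full experiment — sample-size grids, the four modeling strategies,
slope analysis and figures — runs through `run_study()`,
`slope_analysis()`, `discharge_correlations()` and `plot_study()`.

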