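---
title: "Methods: case-cohort metabolomic association and risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-cohort metabolomic association and risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabcc)
```

This vignette records the statistical choices behind `metabcc` in enough
detail that every number the package produces can be re-derived by hand.

## The case-cohort design and the Prentice pseudo-partial likelihood

A case-cohort study measures expensive assays (here, a targeted
NMR-metabolomics panel) on all incident cases plus a random *subcohort*
drawn from the full cohort at baseline, rather than on everyone. The
subcohort is a fair sample of the population and may itself contain
cases; cases outside the subcohort were selected *because* they became
cases, so an ordinary Cox partial likelihood over the assayed rows would
be biased.

`metabcc` implements the Prentice estimator: the risk set at a case's
event time consists of the subcohort members still at risk *plus the
case itself*, and a case outside the subcohort contributes to no other
risk set. Internally every analysis is expressed in counting-process
form — subject `i` is at risk at time `t` iff `start_i < t <= stop_i` —
and the Prentice rule is obtained by giving non-subcohort cases an entry
time one representable floating-point unit below their own event time:

```{r, eval = FALSE}
start[outside] <- time[outside] * (1 - .Machine$double.eps)
```

This one convention also covers delayed entry, which is how the
reverse-causality sensitivity analysis (`sensitivity_exclude_early()`)
removes the first years of follow-up without special-casing the
likelihood. When the subcohort is the whole cohort the Prentice fit
reduces *exactly* to the ordinary Cox fit; the test suite asserts this
and checks the full-cohort fit against an independent implementation.

Estimation is Newton-Raphson with step-halving from `beta = 0`,
converging when the maximum absolute score component falls below `1e-9`
or the relative log-likelihood change falls below `1e-10`. Monotone
likelihoods (e.g. a rare indicator whose few carriers are all cases)
are reported as a plateau with a diagnostic rather than an error, and
diverging coefficients trigger an explicit separation diagnostic.

### Variance estimation

Because non-subcohort cases enter only their own risk sets, the inverse
information underestimates sampling variability. All headline statistics
therefore use a grouped sandwich ("robust") variance built from
per-subject score residuals

$$U_i = \delta_i\,(X_i - \bar{x}(t_i)) -
  e^{\eta_i} \sum_{k : t_k \in (\mathrm{start}_i,\ \mathrm{stop}_i]}
  \frac{d_k}{S_0(t_k)}\left(X_i - \bar{x}(t_k)\right),$$

with `robust = I^{-1} (sum_i U_i U_i') I^{-1}`. The reported `z` is
`beta` over the robust standard error throughout the package.

### Ties

The default tie handling is Breslow; Efron is available. Score residuals
use the Breslow form under both (identical whenever event times are
untied, which is the case for the continuous follow-up times the
generator produces); on heavily tied data the robust variance under
Efron ties is therefore an approximation, while coefficients remain
exact.

### Proportional hazards

`schoenfeld_ph_test()` implements the classic pooled-variance
Grambsch-Therneau statistic on (unscaled) Schoenfeld residuals with a
rank or identity time transform. Current versions of external survival
software use exact per-event variances, so agreement is close but not
bitwise; the tests check both an exact recomputation of the documented
formula and approximate agreement with the external implementation.

## The association scan

Each biomarker is standardized to unit standard deviation *among
subcohort members* (the representative sample) and fitted as a single
continuous term, one Prentice model per (biomarker, adjustment tier):

* `basic` — age, sex, study area, education, fasting time;
* `full` — plus smoking, alcohol, physical activity, four dietary
  indicators, family history, BMI and waist circumference;
* `full_plus_glucose` — plus random plasma glucose;
* `fig2` — `full` without the adiposity terms, used when biomarker
  associations are plotted against biomarker-adiposity gradients.

Multiplicity is handled with the Benjamini-Hochberg step-up procedure,
applied per tier by default (`fdr_scope = "pooled"` is available). The
five-line implementation in `bh_fdr()` is deliberately primitive so it
can be checked exactly against the brute-force step-up definition, which
the acceptance tests do on a thousand random p-vectors.

Companion analyses mirror standard epidemiological practice: quartile
shapes (`quartile_scan()`), subgroup estimates with Cochran's Q
heterogeneity (`subgroup_scan()`), early-follow-up exclusion, PCA-based
multivariate outlier screening (report-only), and adiposity-gradient
pairing (`adiposity_gradient()`).

## Cuboid-traversal biomarker selection

With 225 correlated candidates, single-marker significance is a poor
selection tool and a single 225-term model is unstable at case-cohort
sample sizes. The package instead lays the panel on a `5 x 5 x 9`
cuboid and fits one multivariable Prentice model per *slab* (all markers
sharing one index value, plus the covariates of the established risk
model): 19 regressions of 45 or 25 markers each, every marker appearing
in exactly three. A marker is selected when its robust `|z|` exceeds 2
in all three of its slab regressions — a marker must prove itself
against three different conditioning sets, which suppresses hits that
merely proxy a correlated neighbour. Selected sets are then pruned:
pairs with absolute partial correlation (age/sex/area-adjusted, within
the subcohort) above 0.95 keep only the earlier panel member. Slab fits
that fail to converge are retried with a `1e-6` ridge and otherwise
reported as failed rather than silently skipped.

The slab dimensions, `|z| > 2` rule, three-of-three hit requirement and
0.95 pruning threshold are package defaults chosen to match the scale of
a 225-marker panel; all are configurable via `selection_config()`.

## Weighted concordance and model comparison

Discrimination is measured with a case-cohort-weighted Harrell C: over
comparable pairs (an event at `t_i` against a subject still at risk
beyond `t_i`), each pair weighted `w_i * w_j` with weight 1 for cases
and `1/f` for non-case subcohort members, where `f` is the subcohort
sampling fraction; predictor ties score 1/2. With `f = 1` this is
exactly Harrell's C. Confidence intervals are percentile bootstrap,
resampling cases and non-case subcohort members as separate strata, and
model comparisons (`compare_models()`) apply *identical* resamples to
both models so the difference in C is paired; its p-value uses the
bootstrap normal approximation.

## The synthetic cohort generator

`simulate_cohort()` is a first-class component, not a test helper. Its
defaults describe a plausible middle-aged population cohort: truncated
normal age, majority-female sex ratio, ten study areas, gamma fasting
times, correlated BMI/waist circumference, and a biomarker model in
which each measured marker's latent score loads on standardized BMI and
WC and carries a block compound-symmetry residual (14 contiguous blocks,
within-block correlation 0.5, between-block 0.1) mimicking the strong
within-subclass correlation of NMR panels. Event times are Weibull
proportional hazards with the baseline scale calibrated by root-finding
so the cohort hits a target cumulative incidence, plus administrative
censoring; `log_hr` plants effects per SD of the latent scores.
Concentrations are linear in the latent score, so planted per-SD effects
are recovered on the same scale — the parameter-recovery tests rely on
this. Glucose can additionally load on named markers
(`glucose_marker_loadings`), creating a marker-to-glucose-to-disease
mediation path; adjusting for glucose then attenuates those markers'
associations, which is the behaviour the `full_plus_glucose` tier is
designed to reveal.

One behaviour deserves emphasis: **marginal and conditional effects
differ by design**. A marker planted with a negative conditional effect
can show a *positive* single-marker (marginal) hazard ratio when
between-block correlation and shared adiposity loadings connect it to
many positively acting markers. This mirrors real metabolomics data and
is why the selection procedure conditions on slab co-members instead of
trusting marginal scans.

## Limitations

* The robust variance under Efron ties uses Breslow-form residuals
  (exact only for untied data).
* The weighted C-index uses inverse-probability weights with the known
  sampling fraction; no finite-population or shrinkage correction is
  applied.
* The Prentice estimator is implemented with unweighted risk sets;
  alternatives that reweight subcohort contributions are out of scope.
* The generator's covariates are mutually independent except where a
  loading is declared; it aims for structural, not distributional,
  realism.
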