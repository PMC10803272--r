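---
title: "Burden of Proof evidence scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burden of Proof evidence scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bprf)
```

This vignette is the package's account of the statistical machinery it
implements: the model, the choices that were genuinely open when the
package was designed, and what the validation suite does and does not
demonstrate.

## The model

All pooling happens on the log relative-risk scale. For observation $i$
of study $s$ the model is

$$y_i = \beta + X_i b + u_{s(i)} + \varepsilon_i, \qquad
u_s \sim N(0, \gamma), \qquad \varepsilon_i \sim N(0, \sigma_i^2),$$

where $y_i$ is the reported log RR, $\sigma_i$ the reported (or
CI-derived) log-scale standard error treated as known, $X_i$ a row of 0/1
bias covariates whose gold-standard level is all zeros, $\beta$ the pooled
log RR at the gold standard, and $\gamma$ the variance of the study-level
random effect. Observations within a study share $u_s$, which is what
induces the within-study correlation; for a dichotomous exposure the
random intercept and the random slope on the exposed-vs-unexposed contrast
coincide on the analysis scale, so a single study-level effect captures
both. Odds and hazard ratios are ingested as RRs without conversion: the
package pools whatever relative measure a study reports, as is standard
when outcome prevalence is low.

A reported 95% CI is converted with
$\sigma = (\log \mathrm{UI} - \log \mathrm{LI}) / (2 \times 1.96)$, using
1.96 exactly to match the 95% convention used throughout. CIs that are
asymmetric around the point estimate on the log scale are accepted as-is;
the symmetric-in-log formula is applied without adjustment because
extraction sources rarely record what produced the asymmetry.

## Selection cascade and repeated measurements

Studies typically report several effect sizes per outcome. The cascade in
`select_observations()` keeps, per study and population group: first the
best exposure-definition match (smoking status, then location, then
source, then current-before-ever timing, each an ordered priority list
anchored to the reference definition of current exposure among nonsmokers
at home or work); then the least granular analyses — whole-population and
combined-endpoint rows are preferred, but subgroup rows are only dropped
when an aggregate row actually exists in the same study, and subtype
outcome labels (for example stroke subtypes) are dropped only when the
aggregate outcome is reported; finally the most-adjusted rows. Remaining
ties break deterministically to a single record (smallest standard error,
then lexicographic id); `break_ties = FALSE` retains all tied-best rows
for tables where equal-priority definitions genuinely coexist.

When a study reports $k \ge 2$ non-mutually-exclusive effect sizes within
one age–sex–smoking-status group, each of their standard errors is
multiplied by $\sqrt{k}$, so the group's total inverse-variance weight
equals that of a single observation. The literal multiplier $k$ is
available via `factor = "k"`; $\sqrt{k}$ is the default because it is the
information-preserving reading of "a factor matching the number of
repeated measurements" — multiplying by $k$ would make a duplicated group
carry *less* information than a single observation.

## Estimation

Estimation is profile maximum likelihood. For fixed $\gamma$ the fixed
effects have the GLS closed form; the study-block covariance
$V_s = D_s + \gamma \mathbf{1}\mathbf{1}'$ is rank-one structured, so the
Woodbury identities reduce every solve to sums over studies. The profile
objective is optimized over $\gamma \ge 0$ in one dimension
(`stats::optimize`, tolerance $10^{-10}$, boundary at zero checked
explicitly and allowed). Profile ML rather than REML was chosen because
the per-observation likelihood contributions used by the trimming loop and
the Fisher-information variance of $\gamma$ are both defined under the
same marginal likelihood, keeping the three pieces mutually consistent;
at the study counts the package targets (tens of studies) the REML
correction to $\gamma$ is small relative to its sampling uncertainty. The
implementation is validated in the test suite against
`metafor::rma.mv(..., method = "ML")`, which agrees to five decimals, and
against the closed-form inverse-variance mean when $\gamma = 0$
(tolerance $10^{-8}$).

The uncertainty of $\gamma$ comes from the inverse Fisher information:
with $\partial V_s / \partial \gamma = \mathbf{1}\mathbf{1}'$,
$I(\gamma) = \tfrac{1}{2} \sum_s (\mathbf{1}' V_s^{-1} \mathbf{1})^2$,
and $\mathrm{SD}(\gamma) = I(\gamma)^{-1/2}$. This is the quantity that
makes the conservative intervals sensitive to the number of studies: few
studies mean little information about $\gamma$, a large
$\mathrm{SD}(\gamma)$, and hence a wide interval with heterogeneity even
when the point estimate of $\gamma$ is small. A single study leaves
$\gamma$ unidentified; it is fixed at zero with a warning.

## Trimming

`fit_trimmed()` removes a fixed fraction (default 10%) of the most
outlying observations: alternately fit on the current inliers, score
every observation by its negative marginal log-likelihood contribution
(study effect integrated out observation-wise), and trim the
$\lfloor 0.1 n \rfloor$ worst, until the trimmed set is stable. The floor
guarantees never trimming more than the stated fraction; ties in the
score break by observation id, making the result invariant to row order.
Analysis sets with fewer than ten observations are never trimmed — small
sets cannot support outlier detection and the fit falls back to the
untrimmed model. Hard 0/1 trimming is used rather than the continuous
trimming weights of the original meta-regression tool; this is an
approximation, chosen for transparency, and it is what the planted-outlier
tests validate. Oscillating trimmed sets (possible with hard assignment)
hit an iteration cap and return the last iterate flagged non-converged.

## Bias-covariate selection

Candidate covariates are the `bc_*` flags of the table. Eligibility
requires at least two observations at each level; among identically
distributed columns one is retained by a seeded draw (the choice is
arbitrary by construction — the columns are indistinguishable in the
model — but must be reproducible). The default "step-wise Lasso" ranks
covariates by entry order along a decreasing-penalty weighted Lasso path
(glmnet, columns standardized to unit variance), then adds them in that
order to the unpenalized mixed model, retaining each only if its Wald
test is significant at $\alpha = 0.05$, with no multiple-testing
correction. Because the exact published algorithm is not fully specified,
two variants ship alongside: pure forward step-wise selection
(`method = "stepwise"`) and the Lasso support at the BIC-optimal penalty
refit unpenalized (`method = "lasso_refit"`). Coefficients are always
reported on the original 0/1 scale from the final mixed-model refit, and
the pooled effect refers to the gold standard (all covariates zero), so
selecting a covariate with a positive coefficient moves the reported RR
down for the biased subset, and vice versa.

## Evidence scoring

Writing $s$ for the SE of $\beta$, the package reports

- 95% UI without $\gamma$: $\exp(\beta \pm 1.96 s)$ — the conventional
  meta-analytic interval;
- $\gamma_{95} = \gamma + z_{0.95} \mathrm{SD}(\gamma)$, the 95th
  quantile of heterogeneity under a normal approximation (a draws-based
  variant via `gamma_draws` exists for cross-checking and agrees within
  Monte-Carlo error in the test suite);
- 95% UI with $\gamma$: $\exp(\beta \pm 1.96 \sqrt{s^2 + \gamma_{95}})$;
- BPRF: for a harmful exposure
  $\exp(\beta - z_{0.95}\sqrt{s^2 + \gamma_{95}})$, the 5th quantile of
  the risk estimate closest to the null — the most conservative effect
  consistent with the data; mirrored to the 95th quantile for protective
  exposures;
- ROS $= \log(\mathrm{BPRF}) / 2$ (sign flipped for protective), and the
  star rating: 0 stars when the no-$\gamma$ interval crosses 1 (in which
  case BPRF and ROS are undefined); otherwise 1 star for ROS $\le 0$,
  2 for $(0, 0.14]$, 3 for $(0.14, 0.41]$, 4 for $(0.41, 0.62]$, 5 above.
  Upper bounds are inclusive, reading the published ranges as
  lower-exclusive half-open intervals; the boundary cases are pinned by
  unit tests.

Reported rounding follows the publication convention: RR and BPRF to two
decimals, ROS to two decimals, or three when its magnitude is below 0.01
(`round_ros()`).

## Publication bias

Egger's regression is run on post-trim, bias-adjusted residuals against
their heterogeneity-inflated standard deviations
$\sqrt{\sigma_i^2 + \gamma}$, weighted by their inverse squares — the same
quantities the modified funnel plots display, which is why the residual
form was chosen over raw effect sizes. A significant slope at 0.05 flags
potential publication or reporting bias; the pipeline never corrects for
it (no trim-and-fill or selection models), because a flagged funnel is a
property of the literature, not a correctable nuisance parameter, under
this framework. Fewer than three untrimmed observations make the test
not evaluable.

## The synthetic generator

`generate_synthetic()` draws exactly the model above: study random
effects, study-level bias-covariate indicators, log-uniform standard
errors, optional outlier contamination ($\pm$shift with random sign by
default; `outlier_sign = "positive"` gives the one-sided gross-error
scenario used in robustness checks), optional duplicated
non-mutually-exclusive exposure groups, and a publication-bias mode that
censors below-mean results from noisier studies. Defaults — pooled RR
1.2, $\gamma = 0.01$, 40 studies of 1–3 observations, standard errors
log-uniform on $[0.05, 0.4]$ — were fixed once to echo the secondhand-
smoke literature the package targets: study counts per outcome there run
from 9 to 125 and reported CI widths correspond to log-scale standard
errors of a few hundredths to a few tenths. A master seed fans out to
per-study substreams, so generation is byte-reproducible and extending
the study count leaves earlier studies untouched.

What the generator does *not* emulate: correlated bias covariates,
non-normal random effects, within-study correlation beyond the shared
study effect, exposure misclassification, or the messiness of real
extraction (free-text fields, inconsistent subgroup definitions). Tests
that pass on synthetic tables therefore validate the estimator under its
own assumptions, not the robustness of those assumptions to real
literature data.

## Validation problem sizes

The package's simulation-based checks use: 200 replicates of 100 studies
for bias and coverage of $\beta$ (true RR 1.2, $\gamma = 0.04$); 100
replicates of 40 studies with 10% one-sided contamination of magnitude 2
for trimming robustness; 200 replicates of 50 two-observation studies
with a planted 0.5 log-RR bias covariate and two null covariates for
selection power and size; 500 direct funnel replicates of 30 observations
for the Egger test's size and 100 pipeline replicates of 50 studies under
censoring for its power; and 500 replicates of 60 single-observation
studies for the coverage property of the profile-ML interval. These sizes
keep each Monte-Carlo standard error small relative to the property being
asserted while remaining comfortable to run routinely.

## Known limitations

- Exposure is strictly dichotomous; no dose–response or spline machinery.
- Hard trimming approximates the continuous-weight trimming of the
  original tool; with contamination just above the trim fraction some
  outliers necessarily survive.
- The normal approximation to the 95th quantile of $\gamma$ can be
  liberal when the number of studies is very small and $\hat\gamma$ sits
  at the boundary; the draws-based variant is the cross-check.
- $\sigma_i$ is treated as known, as in standard meta-analysis; extraction
  errors in reported CIs propagate directly.
- The cascade resolves ties to one record by default; tables whose
  equal-priority rows are genuinely distinct measurements should use
  `break_ties = FALSE` so the $\sqrt{k}$ inflation can do its job.
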