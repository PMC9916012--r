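---
title: "Methods: intersectional gender-score stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intersectional gender-score stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Public health monitoring usually reports prevalence stratified by the
male/female binary. That comparison mixes two sources of difference:
sex-related factors and the socially structured ("gendered") distribution of
living conditions. This package separates them with a propensity-score
device. For respondent $i$ with intersectional covariables $x_i$ (twelve
categorical variables spanning sociocultural, sociodemographic and
socioeconomic dimensions), the *intersectional gender-score* is

$$e(x_i) = \Pr(\text{recorded as a woman} \mid x_i).$$

If men and women lived under exchangeable conditions, $e(x)$ would be
uninformative and its distributions would coincide across the sexes. The
more the covariable profile is gendered, the further the distributions
separate. After estimating $e(x)$, the analysis proceeds as a
subclassification:

1. **Common support.** Records with scores outside
   $[\max(\min_m, \min_w),\ \min(\max_m, \max_w)]$ — combinations of
   covariables that identify the sex with certainty within the sample — are
   excluded and profiled separately.
2. **Stratification.** The trimmed sample is sorted by score and cut into
   $K$ contiguous, equal-size strata; stratum 1 is male-dominated, stratum
   $K$ female-dominated. $K$ is chosen from 4–7 by balance diagnostics.
3. **Balance.** For every covariable category, the standardized mean
   difference between men and women,
   $\mathrm{SMD} = (\bar p_m - \bar p_w) / s_{\text{ref}}$ with
   $s_{\text{ref}} = \sqrt{(s_m^2 + s_w^2)/2}$, is computed in the total
   sample and within each stratum. $|\mathrm{SMD}| \le 0.10$ is negligible,
   $\le 0.20$ low, $> 0.20$ unbalanced.
4. **Contrasts.** Prevalence of four binary health indicators (frequent
   mental distress, lifetime depression, self-rated health not good,
   lifetime hypertension) is compared for seven group pairs: men vs women
   in the full sample, within stratum 1, within stratum $K$, the
   *traditional gender* pair (S1 men vs SK women), the *non-traditional*
   pair (SK men vs S1 women), and the women–women and men–men pairs across
   S1/SK. Differences carry continuity-corrected Wald intervals and
   chi-square tests for equality of proportions at $\alpha = 5\%$.

The interpretive core is an attenuation argument: if an indicator is driven
by the gendered covariable profile rather than by sex, the within-stratum
sex differences shrink relative to the full-sample difference; if it is
driven by sex-related factors, they persist.

## Score estimators

`fit_igscore_gbm()` implements gradient boosting with Bernoulli deviance in
the package itself (no boosted-tree library is assumed): depth-limited
CART-style trees on the categorical covariables, categories ordered by
their Newton mean and split by the best prefix, one Newton step per leaf
($\sum r / \sum p(1-p)$, capped at $\pm 4$), shrinkage and bagging. Missing
values are routed per split to whichever side yields the larger gain and
the chosen default direction is stored — the same purpose surrogate splits
serve in tree ensembles: no imputation, no row deletion. Defaults are the
conventional propensity-boosting settings: tree depth 3, shrinkage 0.05,
bag fraction 0.5, minimum leaf size 10, 150 rounds. Cross-validated
selection of the number of rounds (5-fold, AUC over a grid) is implemented
(`cv_folds > 0`) but is off by default: with the pure-R tree builder it
multiplies the fit cost several-fold, and a fixed modest round count keeps
the default pipeline and test suite inside a single-CPU budget without
materially changing the stratification.

`fit_igscore_logistic()` is the conventional benchmark: a main-effects
logistic regression on one-hot covariables with an explicit "(missing)"
category. Separation is detected from the fitted object (non-convergence,
absolute coefficients above 10, or fitted probabilities within $10^{-8}$ of
0/1 — `glm` can converge on separated data without warning) and triggers a
ridge-IRLS refit with penalty $10^{-6}$ so small or degenerate cohorts
still return a usable fit.

Discrimination is summarised by the Mann–Whitney AUC (ties count half).
Scores and AUC are **in-sample** by default, matching single-cohort usage.
In-sample AUC carries optimism: with roughly forty dummy parameters a null
logistic fit at $n = 5000$ sits near 0.55, not 0.50, and a flexible boosted
fit far higher. `cross_fit = TRUE` scores each record out-of-fold (5
folds), which removes the optimism; the null-recovery tests use exactly
this distinction — in-sample bands for the logistic benchmark, out-of-fold
scores when asserting that boosted trees carry no signal under the null.

## Common support and stratification

Bounds are derived **once** and applied once. Re-deriving bounds from an
already-trimmed sample necessarily moves them inward (the sex attaining
each bound keeps it; the other sex's extreme retreats), and iterating that
to a fixed point can cascade until small samples empty. The trim is
therefore defined as a one-pass rule, and idempotence holds in the
operational sense: `common_support(scores, sex, bounds = recorded)` applied
to the trimmed sample excludes no one. The excluded records are reported as
a category-frequency profile — a substantive output, since they carry
covariable combinations unrepresented in the other sex.

Stratification sorts by `(score, record_id)`; the stable tie-break makes
the record-to-stratum map independent of input order. Stratum sizes differ
by at most one. `select_k()` counts covariable-category × stratum cells
with $|\mathrm{SMD}| > 0.1$ (total-sample cells are not counted — the
candidates are compared on what stratification can change) and picks the
$K$ with the fewest, ties to the smaller $K$. Whether "imbalanced
covariables" should count covariables or category cells is ambiguous in
prose descriptions of such procedures; cells are the finer and more
conservative reading and are what the balance tables report per row.

## Balance conventions

The reference standard deviation of each category indicator is computed
once on the full trimmed sample and reused for every stratum, so SMDs are
comparable across scopes (the convention of standard balance-assessment
tooling); a per-stratum denominator would shrink whenever a stratum is
homogeneous and make scopes incommensurable. Every category gets its own
indicator — no omitted reference level — matching per-category reporting.
Missing covariable values are excluded pairwise, from that covariable's
indicators only. Signs are retained (men minus women); classification uses
the absolute value. A constant indicator has SMD 0 by definition, with a
warning.

## Prevalence and contrasts

Prevalence intervals default to exact binomial (Clopper–Pearson), which
reproduced the published reference intervals on spot checks; Wilson and
Wald are available. Differences of proportions use the Yates
continuity-corrected Wald interval
$\hat\Delta \pm \left[z\sqrt{\hat p_1\hat q_1/n_1 + \hat p_2 \hat q_2/n_2}
+ \tfrac12(1/n_1 + 1/n_2)\right]$ and the continuity-corrected chi-square
test, implemented from the formulas and verified against `prop.test` and a
first-principles 2×2 computation. Contrasts in which both proportions are
0 (or both 1) are flagged degenerate with an undefined p-value rather than
tested. No multiplicity adjustment is applied ($\alpha = 5\%$ per test),
matching the descriptive reporting convention.

**Display convention.** Tables are rounded to two decimals half-up, at the
reporting layer only. The displayed difference is the difference of the
*displayed* prevalences (`format_contrast_table(diff_from_rounded =
TRUE)`), so a printed prevalence panel and its contrast column are
internally consistent for a reader checking the arithmetic; published
reference tables in this area follow the same convention, which in a
handful of cells differs from the rounded full-precision difference by one
unit in the last place. Internal values are always full precision.

## The synthetic stated world

Because the motivating survey microdata are access-restricted, every
downstream stage is exercised against a generator whose ground truth is
known. One configuration draws: sex $\sim$ Bernoulli($p_w$), default
$p_w = 0.54$ at $n = 23{,}000$; each covariable from
$\mathrm{softmax}(\log \pi + \mathrm{sex} \cdot \gamma \cdot s)$, where
$\pi$ are baseline category probabilities and $s$ per-category log-odds
shifts — strongly gendered for employment status (part-time, maternity/
parental leave, housewife/-husband shifted toward women, full-time toward
men) and occupational status (blue-collar toward men), weak for migration
background, household language, disability and urbanity; each indicator
from $\text{logit}^{-1}(\beta_0 + \beta_{\text{sex}}\,\mathrm{sex} +
\beta_{\text{prof}}\,\text{profile})$ with base prevalences in the 5–25%
band; MCAR missingness per column at sub-3% rates. The latent profile is a
fixed linear score of the (pre-missingness) categories with weights shipped
as constants (`profile_weights()`); its standardisation constants were
computed once, analytically, from the preset mixture distribution and
hard-coded, so nothing is re-estimated from data and ground truth is exact.

The preset outcome models encode the attenuation switchboard: depression
and self-rated health are purely profile-driven
($\beta_{\text{sex}} = 0$, $\beta_{\text{prof}} > 0$ — their full-sample
sex gap exists only because $\gamma > 0$ genders the profile), hypertension
purely sex-driven, frequent mental distress a mixture. $\gamma = 0$
(`null_config()`, with sex effects also zeroed) is the exchangeable world:
identical covariable distributions and outcome prevalences by construction.

What the generator does **not** emulate: household clustering, longitudinal
panel structure, informative missingness, survey weights, or the exact
category frequencies of any real survey. A green test therefore establishes
that the pipeline recovers the truth of *this* stated world — null
recovery, monotone signal response in $\gamma$, attenuation of
profile-driven contrasts — not that any real-data estimate is reproduced.
Published real-data quantities that the package can reproduce at a desk
(prevalence differences, their intervals and the sample accounting, from
published aggregate counts) are checked exactly in the acceptance suite;
quantities that require the microdata (AUC values, the five-subgroup
choice, stratum sex shares) are replaced by those properties.

## Numerical choices

* Boosted leaf values capped at $|\gamma_j| \le 4$ on the log-odds scale;
  denominators floored at $10^{-12}$.
* Logistic ridge fallback penalty $10^{-6}$, intercept unpenalised, IRLS
  tolerance $10^{-10}$.
* Stratum boundaries on tied scores: stable sort by record id, with a
  warning when ties span a boundary (boosted scores are discrete, so this
  is common and harmless).
* `select_k` skips candidates with fewer than two records of either sex in
  any stratum.
* Seeds: every stochastic step (generation, bagging, fold assignment)
  derives from a single user-supplied integer seed recorded in all
  artifacts; identical configuration and seed give byte-identical output.

## Limitations

The score is a binary-sex construct; the approach cannot represent gender
identities beyond the recorded binary and says nothing about individuals.
In-sample AUC overstates discrimination and is reported as such only for
comparability with single-cohort usage. The boosted-tree learner is a
compact reimplementation: adequate for twelve categorical covariables, not
tuned for wide numeric feature spaces. Multiple imputation of covariables
and survey-weight reweighting are out of scope.
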