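---
title: "Methods: harmonized IPD meta-analysis of subcortical volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized IPD meta-analysis of subcortical volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitemeta)
library(dplyr)
```

## The problem and the model

Individual neuroimaging case-control studies of major depressive disorder
(MDD) are typically too small to detect subcortical volume differences of
the magnitude that plausibly exists (|d| around 0.1-0.2). Multi-site
consortia address this, but subject-level data usually cannot leave the
sites. The individual-participant-data (IPD) meta-analytic design solves
both problems: every site fits the *same prespecified* regression to its
own subjects, and only effect estimates and their sampling variances are
pooled centrally. `sitemeta` implements that design end to end for
consortia analyzing nine measures: the mean ((left+right)/2) volumes of
seven subcortical gray-matter structures (nucleus accumbens, amygdala,
caudate, hippocampus, pallidum, putamen, thalamus), the lateral ventricles,
and total intracranial volume (ICV).

### The site-level model

At each site, for each measure, ordinary least squares:

$$Y = \beta_0 + \beta_{Dx}\,Dx + \beta_a\,\mathrm{age} +
  \beta_s\,\mathrm{sex} + \beta_i\,\mathrm{ICV} + \varepsilon,$$

with $Dx$ coded 0 = control, 1 = patient, and $k-1$ scanner indicator
columns appended when a site pools $k \ge 2$ scanners. When the outcome is
ICV itself, the ICV covariate is dropped (ICV is adjusted for age and sex
only). Missing values are deleted listwise *per outcome*, so the analyzed
n legitimately differs across measures.

The diagnosis effect is standardized from the regression t-statistic:

$$d = \frac{t\,(n_1+n_2)}{\sqrt{n_1 n_2}\,\sqrt{df}},\qquad
  v = \frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2(n_1+n_2)}.$$

This is the standard conversion for a covariate-adjusted group indicator;
it reduces to $2t/\sqrt{df}$ for balanced groups and agrees with the
direct pooled-SD standardized mean difference up to $O(1/n)$ (verified in
the test suite against a brute-force oracle). We deliberately apply **no
small-sample correction** by default: the conversion sits in one function
(`cohens_d_from_t()`) with a `hedges_correction` flag, so the alternative
is a one-argument change. Percent difference is reported from
least-squares adjusted means evaluated at the pooled covariate means of
the analyzed site sample; this is a conventional choice — other
evaluation points change the denominator slightly but not the inference,
which never uses percent differences.

For continuous predictors (symptom severity among patients), the effect
size is the partial correlation $r = t/\sqrt{t^2 + df}$ with variance
$(1-r^2)^2/(n - m - 1)$, $m$ the number of partialled covariates. Whether
a consortium should pool $r$ raw or on the Fisher-z scale is genuinely
open; we default to the raw scale and provide `r_scale = "fisher_z"`
(variance $1/(n-m-3)$, estimate and CI back-transformed). For |r| < 0.3
and site sizes above ~40 the two differ well below reporting precision.

### Pooling

Per-site estimates are combined under the random-effects model
$d_i = \delta + u_i + e_i$, $u_i \sim N(0,\tau^2)$, $e_i \sim N(0,v_i)$.
Heterogeneity uses fixed-effect weights $w_i = 1/v_i$:
$Q = \sum w_i (d_i - \bar d_{FE})^2$ and
$I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$. Two $\tau^2$ estimators are
implemented:

* **DerSimonian-Laird** (moment): $\tau^2 = \max\{0,\,
  (Q - (k-1)) / (\textstyle\sum w_i - \sum w_i^2 / \sum w_i)\}$ — closed
  form, used as the fallback and as a hand-checkable oracle;
* **REML** (default): Fisher scoring on the restricted log-likelihood,
  tolerance $10^{-8}$, at most 100 iterations, falling back to DL with a
  warning on non-convergence (observed in well under 1% of simulated
  meta-regressions, always near the $\tau^2 = 0$ boundary).

REML is the default because it is the default of the standard
meta-analytic tooling this pipeline is meant to interoperate with; the
choice matters little here since both truncate to zero whenever
$Q \le k-1$. The pooled effect uses $w_i^* = 1/(v_i + \tau^2)$, with
$se = (\sum w_i^*)^{-1/2}$, Wald 95% CI, and a two-sided normal p-value —
not Knapp-Hartung, matching the CI semantics of the reporting layout the
package emits. Both truncations ($\tau^2$, $I^2$) are recorded in the
result's `notes`.

Meta-regression enters one site-level moderator at a time:
$d_i = \beta_0 + \beta_1 x_i + u_i + e_i$, $\tau^2$ by the same REML
engine (general design matrix), $\beta$ by weighted least squares, Wald
test for $\beta_1$. At least $k = 3$ sites are required — with two sites
the slope saturates the mean structure and $\tau^2$ is unidentifiable.
Categorical moderators (segmentation software version) enter as a single
integer code; this mirrors consortium practice of treating version as an
ordered scalar and is an explicit encoding contract, not a claim that the
coding is metrically meaningful.

### Contrast families and multiplicity

The primary contrast compares all patients with all controls across the
nine measures, with Bonferroni threshold $0.05/9 = 5.6\times10^{-3}$.
Bonferroni is applied *per contrast family* of nine measures, not across
families — the secondary analyses are explicitly exploratory. Clinical
stratifications reuse all controls against one patient stratum (first
episode, recurrent, onset $\le 21$ years, onset $> 21$; onset exactly at
the cutoff counts as early). Patient-vs-patient questions (recurrent vs
first episode, early vs late onset) are answered by a *direct*
two-patient-group regression at each site pooled via `compare_groups()`,
never by eyeballing two stratum-vs-control intervals. The
diagnosis-by-sex interaction adds the product term to the site model with
main effects retained; its coding is symmetric, so the arbitrary sex
reference (0 = female) only flips signs.

Any site that cannot support a contrast (no stratum members, single sex,
rank-deficient design, too few patients with a severity score) is dropped
from that contrast only, with a machine-readable reason code retrievable
via `run_log()` — exclusions are never silent.

## Power analysis

`min_detectable_d()` inverts the exact noncentral-t power function of the
two-sided two-sample test by root finding; at (1728, 7199, $\alpha=0.05$,
power 0.80) it gives 0.0751, and 0.0968 at $\alpha = 0.05/9$. The
familiar normal approximation
$(z_{1-\alpha/2}+z_{power})\sqrt{1/n_1+1/n_2}$ is exposed as
`method = "normal"`; at these sizes it sits 8 units in the fifth decimal
below the exact solution (0.07505 vs 0.07506), which is why the exact
path is the default. `required_n_per_group()` bisects the noncentral-t
power on integer n and returns the minimal n meeting the target — 802,
545 and 394 per group for d = 0.14, 0.17 and 0.20 at 80% power — and the
normal-approximation shortcut $2((z_{1-\alpha/2}+z_{power})/d)^2$ is again
available, running about one subject low.

## What the synthetic consortium emulates — and what it does not

`simulate_consortium()` generates data *from the model the pipeline
assumes*, with defaults mirroring the consortium scale the package
targets: 15 sites, 1728 patients and 7199 controls in total (per-site
sizes from seeded lognormal weights), a true standardized hippocampal
deficit of $-0.14$ with between-site SD $\tau = 0.05$, 65.7% recurrent
patients, 35.2% early onset with 57% of early-onset patients recurrent.
$\tau = 0.05$ is our choice of a plausible mild heterogeneity level (the
same order as the deficit itself); nothing downstream is tuned to it.
True effects are injected on the residual-SD scale, so configured deltas
are directly comparable to recovered Cohen's d — this is what makes
parameter recovery a meaningful acceptance surface. Site effects enter as
random intercepts (3% of the measure mean) plus the heterogeneous
$\delta_s$; covariate structure (age slopes, sex shifts, ICV scaling) is
typical of adult volumetrics. Severity scores are generated independent
of volume by default — the null configuration — with an injectable
partial correlation for power checks; moderator effects can likewise be
injected against the *realized* site percentage of, e.g., antipsychotic
users, so meta-regression recovery is not attenuated by errors-in-x.

The generator deliberately does **not** emulate: segmentation or
acquisition error and site differences therein (all "sites" share one
generating model up to intercepts), left/right asymmetry (volumes are
emitted as the L/R mean directly), non-normal residuals, covariate-effect
heterogeneity across sites, informative missingness (volume cells are
MCAR at 2%), or longitudinal structure. Passing calibration and recovery
tests therefore demonstrates that the estimation machinery is correct
under its own assumptions — not that real multi-site data meet those
assumptions.

## Numerical choices and degenerate inputs

* Rank deficiency is detected on the model matrix QR before fitting; the
  error names the aliased column (single-sex sites alias `sex`).
* Adjusted means use pooled covariate means including scanner dummy
  proportions.
* REML: DL start value, score/information steps truncated at 0;
  convergence $|\Delta\tau^2| < 10^{-8}$.
* Wald CIs everywhere; $z$-based p-values from the standard normal.
* `required_n_per_group()` verifies minimality (power at $n-1$ fails) by
  construction of the bisection bracket.
* Onset exactly at the cutoff is early; controls carrying clinical fields
  are rejected at validation with row diagnostics.

## Problem sizes used in the test suite and acceptance script

Monte-Carlo checks run the full pipeline on consortia of 15 sites with
450 patients / 900 controls in total (about 30/60 per site) — the study's
site count at roughly a fifth of its per-site size, our chosen balance
between Monte-Carlo resolution and suite runtime: 300-400 replicates for
null calibration (SE honesty, CI coverage, family-wise error), 150-200
for parameter recovery, 25-30 for stratified patterns. At these sizes the
per-replicate pooled SE is about 0.06, so recovery checks resolve biases
of ~0.015 at 3 Monte-Carlo SEs. All replicate counts and tolerances were
fixed before the checks were first run and are not adapted to outcomes.

## Known limitations

* Ordinary least squares only at sites; no robust or mixed-effects
  site models (by design — the harmonized analysis prescribes OLS).
* No publication-bias diagnostics, multivariate pooling, or
  mega-analysis of pooled subject-level data; the pipeline's unit of
  exchange is the per-site effect size.
* The percent-difference aggregation (inverse-variance-weighted mean of
  site percent differences) is presentation-only; no inference attaches
  to it.
* The severity analysis treats the score at inclusion as the exposure;
  episode-level severity history is out of scope.
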