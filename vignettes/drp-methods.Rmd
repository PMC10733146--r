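---
title: "Methods and design choices in drpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in drpscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drpscreen)
```

## The measurement model

A profiled sample occupies one 384-well plate (16 rows x 24 columns):
63 drugs at five concentrations each (one well per drug and
concentration), 64 DMSO solvent controls, and a handful of empty wells.
Well luminescence is proportional to the number of metabolically active
cells, so the drug effect at a given dose is estimated as *relative
viability*

$$v = \frac{\text{luminescence}}{\operatorname{median}(\text{inner DMSO controls})}.$$

Only controls off the outermost well ring enter the median: edge wells
are the most exposed to evaporation and thermal gradients, and a biased
control median would bias every viability on the plate. The outer ring
is interpreted as the single outermost ring of wells (the ring depth is
a design choice; one ring removes the dominant edge artefact while
keeping 16 protected controls). Viabilities are deliberately **not**
capped at 1 — values slightly above 1 are ordinary measurement noise,
and truncation would bias resistant profiles downward.

Technical replicates of the same drug and concentration are averaged
arithmetically. Plate quality is gated on the sample standard deviation
(n − 1 denominator) of the control viabilities: a plate fails when it
exceeds 0.3, and failed plates are excluded outright rather than
rescaled — rescaling cannot repair a noisy baseline.

## Dose-response summaries

The per-drug summary is the trapezoidal AUC over *concentration ranks*
1..5, normalized by the rank span:

$$\mathrm{AUC} = \frac{1}{4}\left(\tfrac{v_1}{2} + v_2 + v_3 + v_4 +
\tfrac{v_5}{2}\right).$$

Ranks rather than log-molar doses make drugs with different (and partly
unpublished) concentration ranges comparable, and the normalization
calibrates the scale so a flat profile at viability $v$ has AUC $= v$:
the AUC reads directly as an average surviving fraction, with **higher
AUC meaning more ex vivo resistance**. `auc_trapezoid()` also accepts an
explicit axis for users who prefer log-concentration integration. Drug
combinations use the analogous volume under the viability surface (VUC)
over the two drugs' rank grid, normalized by the grid area; for a
separable surface the VUC factorizes into the product of the two AUCs,
which the tests verify.

Five-parameter logistic curves
$v(x) = c + (d - c)\,/\,(1 + e^{b(\ln x - \ln e)})^f$
serve visualization, not inference. Fitting uses Levenberg–Marquardt
least squares with box constraints ($c, d \in [-0.5, 2]$, $e$ within
a 100-fold window around the tested range, $f \in (0.1, 10]$), starting
from $d = \max v$, $c = \min v$, $e$ at the geometric mean dose,
$b = f = 1$, with two fallback starts before a fit is declared
unconverged; flat profiles short-circuit to the exact constant curve.
Robustness is favoured over precision because the AUC, not the curve,
is the analysis quantity.

## Association analyses

Per-drug comparisons between in vivo response groups (R vs PD) are
two-sided two-sample t-tests on AUC. The Welch test is the default —
the group variances have no reason to be equal — with a pooled-variance
option for exact replication of a "standard unpaired t-test" convention.
The reported mean difference is signed group1 − group2, so with
responders first, a *negative* difference means responders were more
drug-sensitive ex vivo. Pathway-level profiles average the AUCs of a
class's drugs per sample over whatever drugs were measured
(available-case mean). Exploratory-cohort analyses report raw p-values
with 0.05 significance; validation-style analyses apply
Benjamini–Hochberg adjustment with a 10% FDR cutoff. Both conventions
are explicit arguments, never silent defaults of a cohort label.

Blocking on a nuisance covariate (e.g. tumor infiltration) uses a
two-factor additive linear model `auc ~ group + stratum` with a partial
t-test on the group term; a continuous blocking variable is binned at
its quartiles. A stratified permutation test would be a reasonable
alternative; the linear model was chosen for transparency and
determinism, and aliasing between group and strata raises an error
rather than a silently dropped term.

## Elastic-net stability selection

The covariate-selection procedure fits an elastic-net regularized
logistic regression of the binary endpoint (R vs PD, progression as the
positive class) on the chemotherapeutic AUCs:

$$\min_{\beta_0,\beta}\;\frac{1}{n}\sum_i -\left[y_i\eta_i -
\log(1+e^{\eta_i})\right] + \lambda\left(\alpha\|\beta\|_1 +
\tfrac{1-\alpha}{2}\|\beta\|_2^2\right),$$

with $\alpha = 0.3$: mostly ridge-like shrinkage (stable under the
strong within-class correlation of the regressors) with enough L1 to
produce exact zeros for selection. Regressors are divided by 0.10
before fitting so $e^\beta$ is the odds ratio per 10% change in
viability. The penalty path holds 100 log-spaced values from the
data-derived $\lambda_{\max}$ (smallest penalty with all coefficients
zero) down to $\lambda_{\max}\times 10^{-3}$.

One *model* is one random stratified 3-fold split: out-of-fold
predicted probabilities are pooled across folds, the AUROC is computed
per $\lambda$, and the best $\lambda$ (ties broken toward the larger,
sparser penalty) indexes a full-data refit. Stratification is not
optional: with around 5 progressors among 38 complete cases,
unstratified 3-fold splits frequently produce single-class folds and
the procedure would be infeasible as stated. The procedure repeats over
1,000 independently seeded splits and reports, per covariate, the
selection proportion, the median log odds ratio over **all** models
(zeros included) and over selected models only — the natural reading of
"median overall estimated coefficients" is over all models, but both
are computed because the phrase is ambiguous — and the median
cross-validated AUROC of the models in which the covariate's OR
differed from 1. One master seed spawns the per-model fold seeds, so
the whole result is reproducible bit for bit.

Two behaviors of this procedure are worth knowing. First, on a cohort
with *no* signal, the selection proportion of the spuriously
best-correlated covariate is still high: the 1,000 splits share one
dataset, so in-sample accidents persist across splits. The null
diagnostic is therefore the global median CV AUROC (near 0.5 under
noise), not the selection proportions. Second, with so few events the
AUROC criterion is granular, which is exactly why the tie-break toward
sparser models matters.

## Survival analyses

EFS is the time from treatment start to the earliest of progression,
treatment change, or death; participants without an event are censored
at the last assessment. Kaplan–Meier curves come from
`survival::survfit`; the reported median is the earliest time with
$S(t) \le 0.5$ (undefined when the curve never reaches 0.5). Median
follow-up uses the reverse Kaplan–Meier estimate (event and censoring
roles swapped). Cox models use Efron tie handling, the de-facto default
of the R survival ecosystem. Covariate scalings are recorded in the
result: AUC x 10 ("per 10% viability"), mean-centered/2-s.d. (to put a
continuous covariate on a scale comparable with binary risk-group
dummies), or treatment contrasts with a configurable reference level
(intermediate risk by default).

Maximally selected log-rank cutpoints serve *display only*: candidate
cutpoints are the unique marker values whose split keeps the low group
between the 10% and 90% quantiles (the bounds are a declared default;
no authoritative choice exists), the statistic is the standardized
two-sample log-rank sum $|S(\mu)| = |\sum (O - E)| / \sqrt{\sum V}$
with hypergeometric variances, ties go to the smaller cutpoint, and no
p-value for the maximal statistic is computed. Samples with marker
above the cutpoint are "weak responders". Inference about a drug's
survival association always comes from the *continuous* Cox model, and
the pipeline reports the continuous Wald p next to every
dichotomization.

Exact binomial rates (feasibility endpoints) use the Clopper–Pearson
interval from Beta quantiles; among standard interval constructions it
is the one that reproduces a published interval of 82.8–96.4% for
73/80 to one decimal, which identifies it as the convention in use.
Percentages are rounded half away from zero to one decimal (so 91.25%
prints as 91.3%, matching clinical-report convention rather than IEEE
half-to-even).

## The synthetic-data generator

`sim_config()` / `simulate_cohort()` / `simulate_plate()` generate a
complete study with known ground truth. Design targets, chosen once:

- **Plate design**: 63 drugs x 5 concentrations, 64 DMSO controls of
  which 16 sit off the outer ring (the normalization set) and 48 on it,
  5 empty wells. Drug-well luminescence is
  $\text{baseline} \cdot v \cdot e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.08$ — the control
  s.d. a good plate exhibits; an optional additive edge effect on the
  outer ring exercises the boundary-exclusion rule.
- **Cohort scale**: 43 participants (5 stable disease), a fixed 5
  progressors among the 38 R/PD samples drawn with probability
  proportional to the logistic-link probabilities. Fixing the class
  sizes (rather than Bernoulli sampling) keeps the cohort at the design
  regime where 3-fold stratified CV is feasible; an unconditional draw
  occasionally produces 0–2 progressors, for which the published
  procedure is undefined.
- **Effect structure**: a latent chemosensitivity $L \sim N(0,1)$ loads
  (0.14) on the AUCs of the 5 effect drugs and drives both links:
  $\operatorname{logit} P(\mathrm{PD}) = \gamma_0 + \sum_d \gamma_d
  \mathrm{AUC}_d / 0.10$ with $\gamma_d = 0.7$ for effect drugs, and an
  exponential proportional-hazards EFS with $\beta_d = 0.3$ per 10%
  viability and baseline hazard $\log 2 / 365$ per day (one-year median
  EFS at the average profile). Non-effect drugs share a per-class
  latent factor (loading 0.05) that is independent of outcome,
  reproducing the within-class correlation blocks of real screens.
  With the latent structure each effect drug is a strong, mutually
  correlated readout of the same chemosensitivity — the regime in which
  a handful of drugs can stand in for in vivo chemosensitivity at all.
  A sum-of-independent-drugs link cannot produce that regime at n = 38
  with 5 events: each drug's marginal signal dilutes by $1/\sqrt 5$ and
  drowns in event noise.
- **AUC -> curve mapping**: a target AUC $a$ maps to a monotone
  logistic-in-rank viability profile whose normalized trapezoid equals
  $a$ exactly ($2as$ for $a \le 0.5$; $(2a-1) + (2-2a)s$ for
  $0.5 < a \le 1$; a constant shift above 1), so noiseless plates
  round-trip the truth to machine precision.
- **Censoring**: independent uniform on $[0, c_{\max}]$ with
  $c_{\max}$ solved numerically for a 30% target censoring fraction.

What the generator does **not** emulate: spatial noise correlation
within plates beyond the single edge offset, batch drift between
plates, cell-count/seeding effects, interactions between drugs on
single-agent wells, non-exponential baseline hazards, and informative
censoring. Passing tests therefore demonstrate correctness of the
computations and calibration under the stated model, not robustness to
these real-data phenomena.

## Problem sizes and tolerances in the test suite

Oracle-equivalence tests run exhaustively where enumeration is cheap
(all 720 permutations of 6 p-values for BH; every split of n <= 15 for
maxstat) and at tolerance 1e-12 for quadrature identities, 1e-6 against
IRLS for the penalized fit at zero penalty. Recovery tests use 40
random 5PL curves (noiseless residual sum of squares < 1e-10), 300
Cox replicates at n = 500 (mean coefficient within 0.05 of the
truth, Wald coverage within [92.5%, 97.5%]), 1,000 replicates for the
5% null calibration of the group tests, 200 simulated plates for the
control-s.d. distribution, and 20 replicate cohorts x 100
cross-validation models for the stability-selection ranking property —
sizes at which the suite completes in a couple of minutes while keeping
binomial noise well inside the asserted bands. The acceptance script
uses the full 1,000-model configuration.

## Known limitations

- The 5PL fit reports the best local optimum of three starts; adversarial
  profiles can defeat it (flagged via `converged = FALSE`).
- `enet_logistic_fit()` inherits glmnet's coordinate-descent tolerance;
  coefficients at interior penalties are accurate to ~1e-7, not machine
  precision.
- The maxstat statistic carries no small-sample or multiple-looking
  correction; it must not be used for inference, only display.
- Pathway averages weight every measured drug equally; no attempt is
  made to reweight unbalanced class sizes.
- The pipeline treats one plate per sample per panel; multi-panel merging
  assumes drug identifiers are disjoint or identical across panels.
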