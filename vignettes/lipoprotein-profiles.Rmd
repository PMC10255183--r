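---
title: "Deriving stability-selected lipoprotein profiles for telomere-related outcomes"
author: "LipoProfile authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving stability-selected lipoprotein profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LipoProfile)
```

## Scope and model

LipoProfile derives sparse linear *profiles* that relate a 12-variable NMR
lipoprotein particle panel — VLDL-P, LDL-P, HDL-P and their
large/medium/small subclasses — to three telomere-related outcomes:
leukocyte telomere length (qPCR T/S ratio), and the leukocyte mRNA
expression of *TERT* and *WRAP53*. The statistical problem is a weak-signal,
small-n (tens of subjects), strongly collinear regression: each class total
is, up to measurement noise, the sum of its three subclasses, and
subclasses within a class are mutually correlated.

The profile for an outcome $y$ is
$$\mathrm{score}_i = \sum_{v \in S} \bar\beta_v\, Z_{iv},$$
where $Z$ holds the rank-normal (inverse-normal-transformed) panel, $S$ is
the set of variables whose Lasso coefficient is nonzero in at least 48 of
the 54 leave-one-out fits, and $\bar\beta_v$ averages the coefficient over
all 54 fits (zeros included). Association is quantified by the Pearson
correlation between the outcome and the held-out LOOCV predictions, with
Fisher-z 95% intervals and exact-t p-values, plus RMSE.

## The preprocessing chain

`preprocessCohort()` applies, in order:

1. **Panel imputation** (`rfImpute()`): the iterative random-forest scheme —
   initialise missing cells at column means, sweep columns in increasing
   order of missingness, regress each on all others with a random forest on
   its observed rows, and stop as soon as the summed squared change of the
   imputed cells increases (returning the previous sweep) or after
   `maxIter` sweeps. Observed cells are never modified; this is asserted in
   code after every run.
2. **Inverse normal transformation** (`inverseNormalTransform()`): Blom
   offsets, $\Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$, average ranks for
   ties. Columns come out with mean exactly 0 and SD ≈ 0.98 at $n = 54$
   (rank-based, so the SD is slightly below 1 by construction). Class
   totals are transformed independently of their subclasses; they are not
   re-derived from subclass sums after imputation.
3. **Outcome outlier screen** (`detectOutcomeOutliers()`): the robust
   statistic $s_i = |y_i - \mathrm{median}(y)| / \mathrm{MAD}(y)$, flagging
   $s_i$ strictly above the empirical 99th percentile (type-7 quantile) of
   the statistics. The statistic is scale-free, so the MAD constant cancels.
   At $n = 54$ at most one value can strictly exceed that percentile, which
   makes "exactly one exclusion per outcome" the generic behaviour for a
   single gross outlier. Flagged values are set missing — rows are never
   dropped, so downstream arithmetic keeps the full $n$. The screen runs on
   the raw scale before the log transform (the `outliersOnLog` switch
   exposes the other order, since either is defensible).
4. **log₁₀** of *TERT* and *WRAP53*.
5. **Outcome imputation** (`miceImpute()`): chained equations with
   predictive-mean-matching draws from a 5-donor pool, cycling `nCycles`
   times, with the covariates and the transformed panel as predictors. One
   completed dataset is returned (all downstream computation uses a single
   dataset, so Rubin-style pooling is out of scope); imputed values are by
   construction inside the observed range.

## Penalty tuning and stability selection

Within each leave-one-out training fold, `tuneLambdaBootstrap()` draws 25
bootstrap resamples, fits the full 100-point log-spaced penalty path
(`lambdaPath()`, from $\lambda_{\max} = \max_j |X_j^\top(y - \bar y)|/n$
down to $10^{-4}\lambda_{\max}$) on each resample, and scores every grid
value by out-of-bag RMSE. The grid value minimising the mean out-of-bag
RMSE wins; ties break toward the larger penalty — reproducible and
conservative. The interpretation of "bootstrap aggregation" as
resampling-based tuning matches the default resampling behaviour of the
caret-style training loop; the alternative reading (averaging 25 bagged
coefficient vectors per fold) is available via
`lassoConfig(aggregate = "bagged")`.

`fitLasso()` minimises $(1/2n)\sum_i (y_i - \beta_0 - x_i\beta)^2 +
\lambda\sum_j w_j|\beta_j|$ through glmnet's coordinate descent
(`thresh = 1e-12`, warm-started along a path ending exactly at the
requested $\lambda$). The tests pin it against two independent closed
forms: the normal-equations OLS solution at $\lambda = 0$ and
coordinate-wise soft-thresholding on a centred orthonormal design.

`stabilitySelect()` retains variable $v$ iff its coefficient is nonzero in
at least $\lceil f N\rceil$ of the $N$ fits, $f = 48/54 \approx 88.89\%$.
The per-variable "95% interval" reported with the averaged weights is the
2.5th/97.5th percentile of the 54 per-iteration coefficients; these
iterations share 52 of their 53 training rows, so the interval is
*descriptive*, not inferential, and is labelled as such. In the adjusted
sensitivity analysis (`runAdjusted()`), the six covariates enter the
design with penalty factor 0 — adjustment cannot be shrunk away — and
selection and scoring are computed over the panel columns only.
Per-fold random streams derive from the master seed, and each fold sorts
its training rows canonically by subject label, so results do not depend
on the input row order.

## The synthetic cohort generator

No subject-level data are distributable, so `simulateCohort()` emulates the
assumed cohort structure; its defaults are fixed design choices, not tuning
knobs:

* $n = 54$ subjects; subclass concentrations lognormal with within-class
  log-scale correlation 0.5 and log-SD 0.25 (~25% CV, typical of NMR
  particle panels). No reference median/IQR table for the panel is
  available, so the medians are chosen once as
  representative particle concentrations honouring two structural
  constraints: concentrations increase as particle size decreases within
  VLDL and LDL, and the S-HDL-P/L-HDL-P median ratio is 28
  (VLDL 1.8/8/42 nmol/L, LDL 170/440/690 nmol/L, HDL 1.0/8.5/28 µmol/L).
* Class totals are the subclass sums times lognormal noise (log-SD 0.03),
  making the total/subclass collinearity explicit.
* Outcomes are built on their analysis scales (T/S ratio raw; expressions
  log₁₀) as location + scale × latent, with the latent equal to
  $r\,\tilde s + \sqrt{1-r^2}\,\varepsilon$, where $\tilde s$ is the
  standardised true score from sparse `trueWeights` on the rank-normal
  panel: the population correlation with the true score equals `targetR`.
  Locations and scales reproduce the reference cohort's medians and IQRs (TL 0.76
  [0.63, 0.88]; TERT 8.57 [7.37, 11.05]; WRAP53 3.46 [2.93, 3.72]);
  default `targetR` are the reference profile correlations
  0.347/0.316/0.379, and the default weight signs follow the reference
  coefficient rankings.
* Missingness is MCAR (no mechanism is assumed):
  `round(0.0216 · 54 · 12) = 14` panel cells, no variable above
  `floor(0.1111 · 54) = 5` cells; five subjects lack all three outcomes
  (no nucleic-acid sample); one 10-MAD outlier is planted per outcome.

What the generator does **not** emulate: a real cohort's correlation
pattern across classes (blocks are independent between classes here), any
covariate–lipoprotein dependence (covariates are drawn independently, so
they are pure noise in the unadjusted fit), non-MCAR missingness, and
measurement error in the outcomes beyond the Gaussian latent. Passing
tests on these cohorts therefore demonstrates correctness of the
*procedure* under the assumed structure, not recovery of any real
cohort's biological findings.

## What the pipeline can and cannot show at n = 54

Two Monte-Carlo facts, both visible in the test suite, deserve emphasis:

* **Held-out correlations are attenuated and left-skewed.** With a planted
  profile correlation of 0.35 at $n = 54$, the true score itself falls in
  its own Fisher 95% band ~96% of the time, but an oracle that knows the
  true four-variable support and merely re-estimates OLS coefficients per
  LOOCV fold achieves a median held-out r of only ≈ 0.21 and lands in the
  band ~70% of the time; the full pipeline (which must also select
  variables) lands there ≈ 40% of the time. When a fold shrinks all
  coefficients to zero its held-out prediction is the training mean
  $\bar y_{-i}$, an exactly decreasing function of $y_i$ — so null-ish
  runs produce *negative* held-out correlations (down to exactly −1), a
  well-known LOOCV artefact. The corresponding permutation-null mean
  held-out r is ≈ −0.4, not 0. Consequently a single observed held-out
  correlation near 0.35 at n = 54 carries a wide sampling band, and
  workflows of this shape should interpret it accordingly.
* **The 48-of-54 rule is stringent under collinearity.** With four equal
  true weights sharing a population $R^2$ of 0.36, each variable's
  individual signal is weak (marginal correlations ≈ 0.17–0.35 depending
  on sign placement), and the class totals act as ready proxies for their
  subclasses. All four true variables survive the 48-of-54 rule in only
  ≈ 20% of cohorts, and on average ≈ 1.5–1.9 proxy variables (typically
  class totals) are retained besides; a no-signal cohort still yields a
  non-empty selection ≈ 10% of the time. The rule therefore behaves as a
  high-precision, low-recall filter on *this* panel — it finds few, strong,
  stable variables rather than complete supports. The recovery experiment
  in the tests places its four signals on subclasses only: a class total
  in the support would make the "true" support non-identifiable (the total
  is a noisy linear function of its subclasses), and support recovery is
  then ill-posed.

## Numerical and degenerate-input conventions

Quantiles are type 7 throughout (the outlier cut-off and the coefficient
intervals). The inverse normal transform rejects constant vectors; the
outlier screen rejects zero MAD; `lambdaPath()` rejects zero-variance
columns and a response orthogonal to the panel ($\lambda_{\max}=0$).
Bootstrap resamples with an empty out-of-bag set are redrawn. An empty
stability selection returns a well-formed empty model (score ≡ 0, flagged
"no stable profile" in reports) rather than an error. Perfect predictions
(r = 1) are reported with a point interval and the p-value at the
representable boundary, since the Fisher and t formulas degenerate there.
Confidence intervals and p-values use the full $n = 54$: the reference
interval arithmetic reproduces at $n = 54$ exactly (not at 53), which is
consistent with exclusion-then-re-imputation rather than row deletion. One
rounding note: with r reported to three decimals as 0.347, the reference TL
interval (0.088, 0.563) corresponds to an r at the upper edge of the
rounding bin (≈ 0.3474); exact arithmetic at 0.347 gives (0.087, 0.562).

Problem sizes used by the test suite — 50-seed calibration runs, 25-seed
recovery and 100-seed null-calibration experiments, bootstrap counts of
10 for the Monte-Carlo blocks and 25 for single worked analyses — were
chosen so the whole suite completes in minutes on a single core while
keeping Monte-Carlo standard errors a few percent.

## Known limitations

* The generator's panel medians are placeholders chosen for structural
  realism; all results that depend only on ratios and ranks are
  unaffected, but absolute RMSEs on the concentration scale are not
  comparable across panels calibrated differently.
* The descriptive coefficient intervals should not be read as confidence
  intervals; LOOCV iterations are almost fully dependent.
* Covariate adjustment assumes complete covariates; no imputation model is
  provided for them.
* Multiple-testing correction across the three outcomes is deliberately
  not applied, and elastic-net/grouped penalties are out of scope.
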