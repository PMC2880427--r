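---
title: "Classifying disease status from whole-blood expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying disease status from whole-blood expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodsig)
```

## The problem

Whole blood is an attractive surrogate tissue for minimally invasive
disease detection: immune cells circulate through every organ and their
transcriptional state shifts with systemic disease. The statistical
setting, however, is hostile. Single-channel microarray studies of blood
are run in hybridization batches over months, so technical batch effects
can dwarf the biological signal; the case/control effect sizes are
modest; and the number of probes (thousands) vastly exceeds the number
of subjects (around a hundred). Any classifier built in this regime can
look spectacular through selection bias alone, so honest error
estimation has to keep feature selection strictly inside the
cross-validation loop.

`bloodsig` implements a complete pipeline for this setting: a
quality-aware preprocessing chain, a PLS1 classifier with jackknife
feature selection nested inside double leave-one-out cross-validation,
a permutation null for the whole procedure, a permutation-based global
test that reduces a signature to its core probes, and gene-set
over-representation statistics. A seeded generator reproduces the
batched study design so the entire pipeline is testable offline.

## The synthetic study design

`sim_config()` encodes the emulated design: 13 hybridization batches,
each holding 10 study samples (5 cases, 5 healthy controls — batches
are class-balanced by design) plus 2 technical controls, i.e. 156
arrays of which 130 are study samples; 3 subjects contribute biological
replicate arrays, so replicate averaging leaves 127 independent
subjects. The intensity model on the log2 scale is additive:

$$x_{ps} \;=\; \mu_p \;+\; \delta_p\,c_s \;+\; u_{p,\mathrm{subj}(s)}
\;+\; b_{p,\mathrm{batch}(s)} \;+\; \varepsilon_{ps}$$

with probe baselines $\mu_p \sim N(8, 1.5^2)$ (a log-normal-like
intensity distribution on the raw scale), planted effects
$\delta_p = \pm\,\mathrm{effect\_size}\cdot\mathrm{noise\_sd}$ on a
random subset of probes (signs random per probe, recorded as ground
truth), and zero-mean per-probe batch shifts
$b_{p\cdot} \sim N(0, \mathrm{batch\_sd}^2)$, re-centered across
batches so that a probe's grand mean is exactly invariant to the batch
effect magnitude. The within-group variance `noise_sd^2` (default 1) is
split evenly between a between-subject component $u$ and a technical
component $\varepsilon$; replicate arrays share $u$ and redraw
$\varepsilon$, giving a within-subject correlation of 0.5. Technical
controls are noisy copies of one fixed reference profile (the baseline
vector) plus the batch shift, which makes controls within a batch more
correlated with each other than with study samples whenever
`batch_sd > 0`.

Default nuisance parameters are chosen to be realistic for blood
microarray data rather than convenient: `batch_sd = 0.5` (batch shifts
comparable to half the biological noise — batch effects in this kind of
data are large), `effect_size = 0.5` (a moderate multivariate
signature spread over 50 of 1000 probes, individually weak),
`p_low_snr = 0.02` low-quality measurements and a 0.005 rate of
scanner flags at 9000 (above the 8191 masking threshold). Low-quality
entries keep a numeric value; deciding what to mask is deliberately the
preprocessor's job, mirroring the real division of labour between
scanner output and analysis.

What the generator does *not* emulate: heavy-tailed intensity noise,
probe-probe correlation beyond the planted signature, demographic
covariates (age, menstrual status, benign lesions), and
intensity-dependent missingness. Passing tests therefore demonstrate
the correctness and calibration of the *procedure*, not the expected
performance on any particular clinical cohort.

## Preprocessing chain

`preprocess_pipeline()` runs, in fixed order:

1. **Quality masking** — an entry is set missing when its
   signal-to-noise ratio is below 3 or its flag exceeds 8191 (both
   strict comparisons).
2. **Probe filtering** — probes missing in more than 5% of all arrays
   are dropped.
3. **Standardization** — each probe is centered and scaled to unit
   sample (n−1) sd over its observed entries. Per-probe (not per-array)
   standardization is required for the imputation step, which measures
   distances between probes. Constant probes are an error in isolation
   and are dropped with a warning in pipeline mode, where aborting a
   whole run for a degenerate probe would be disproportionate.
4. **KNN imputation** — each gap is filled with a 1/distance-weighted
   mean of the k = 10 nearest probes (Euclidean distance over mutually
   observed arrays, rescaled by the number of shared arrays so probes
   with different missingness are comparable) among probes observed at
   the target array. A zero-distance guard of 1e−6 is added before
   inversion; with fewer than k eligible neighbours all are used, and
   with none the probe's own mean (zero after standardization) is the
   fallback. The implementation is pinned to an exhaustive-search
   oracle in the tests.
5. **Batch adjustment** — one-way-ANOVA mean-centering: per probe, the
   batch mean is subtracted from every entry of that batch. Technical
   controls are still present at this stage, so all 12 arrays of a
   batch inform its mean. The grand level is deliberately not restored
   (step 8 re-normalizes arrays), and singleton batches are refused
   because centering would annihilate their signal.
6. **Technical-control removal** (156 → 130 arrays by default).
7. **Replicate averaging** — arrays of the same subject are replaced by
   their per-probe mean (130 → 127); class labels must agree within a
   replicate group.
8. **Global mean subtraction** — each array's mean over probes is
   subtracted (idempotent within-array normalization).

Preprocessing is performed **once on the full dataset, before any
cross-validation**. This mirrors the analysis tradition the package
follows; it leaks a small amount of information (standardization,
imputation and batch means see all samples, including each future
held-out sample) and is documented rather than "fixed", because the
published error estimates this package reproduces are defined under
exactly this protocol. The leakage does not touch the response, so its
effect on error estimates is second-order; the permutation test, which
permutes labels against the fixed processed matrix, measures the
procedure's null behaviour under the same protocol.

## The classifier

The response is coded −1 (healthy) / +1 (case) and regressed on the
probe matrix by univariate-response partial least squares (PLS1) using
the NIPALS deflation: at step $a$, $w_a = X_{a-1}^\top y$ (normalized),
$t_a = X_{a-1} w_a$, $p_a = X_{a-1}^\top t_a / t_a^\top t_a$,
$q_a = y^\top t_a / t_a^\top t_a$, $X_a = X_{a-1} - t_a p_a^\top$.
Coefficient vectors at every truncation are
$B_a = W_{1:a}(P_{1:a}^\top W_{1:a})^{-1} q_{1:a}$, and a sample is
called a case when its raw score $\bar y + (x - \bar x)^\top B_a$ is
strictly greater than zero. With as many components as probes PLS1
reproduces least squares, a property the tests exploit as an oracle.
Predictors are centered but not rescaled inside the model by default:
the pipeline has already standardized probes, and keeping the model's
scaling trivial makes the leave-one-out algebra exact.

**Component choice.** Leave-one-out cross-validation classifies every
sample from the other n−1; the component count `a_opt` is the smallest
one minimizing the misclassification rate (ties toward fewer
components, favouring the simpler model). `A_max` defaults to
min(30, n−2).

**Jackknife feature selection.** The LOO segments provide, at `a_opt`,
a coefficient vector per left-out sample. Each probe's full-data
coefficient is tested against zero with the jackknife standard error
$se_i^2 = \frac{M-1}{M}\sum_m (b_i - b_{i,m})^2$ over the $M = n$
segments and a two-sided Student-t p-value with $M-1$ degrees of
freedom. Probes with $p \le 0.05$ (inclusive, configurable) are kept, a
PLS1 model is rebuilt on them, and a second LOO pass picks its
component count. If nothing passes, the single smallest-p probe is kept
and flagged — a deliberate fallback so that outer cross-validation
folds never abort on conservative inner selections. Probes that are
constant within a training split carry zero coefficients there rather
than failing the split.

The jackknife with the $(M-1)/M$ factor is the classical Tukey scaling;
applied to leave-one-out perturbations it is approximately calibrated,
which the tests verify empirically (the pooled null selection rate at
$\alpha = 0.05$ falls in [0.02, 0.10]). Note what calibration does and
does not buy: with ~1000 candidate probes and 50 true ones, a 5% false
positive rate still admits ~47 null probes alongside the true hits, so
the *precision* of the selected set plateaus near 50% even when
*recall* is essentially complete. Selection lists from a single fit
should be read accordingly.

**Double cross-validation.** An outer leave-one-out loop wraps the
entire training procedure (inner LOO, jackknife selection, refit,
second LOO): the held-out sample never influences its fold's probe set
or component counts, which the suite verifies with a spy test
(perturbing the held-out sample leaves its fold's selection
bit-identical). Accuracy, sensitivity and specificity come from the
outer confusion counts; the ROC/AUC from the outer raw scores, with AUC
computed by the midrank Mann–Whitney statistic (ties get half credit),
pinned in tests to brute-force pair counting.

**Computational note.** For centered, unscaled predictors every NIPALS
quantity lies in the row space of $X$, so leave-one-out refits run on
the n×n Gram matrix $K = XX^\top$ rather than the n×p data, and
coefficient vectors are recovered as $X^\top c$ from n-vectors. The
Gram matrix is computed once and shared across outer folds and
permutations. These loops are implemented in C++ (RcppArmadillo); the
pure-R NIPALS fit is the reference implementation and the two paths are
pinned to each other at machine precision in the tests.

**Permutation null.** `permutation_test()` permutes the −1/+1 labels
against the fixed processed matrix and reruns the full double CV per
permutation, reporting the permuted accuracy/AUC distributions, their
maxima, and add-one empirical p-values $(1 + \#\{perm \ge obs\})/(k+1)$
— never exactly zero. `learning_curve()` repeats the double CV on
class-balanced subsamples to show how AUC and its spread respond to
sample size.

## Global test and core probes

For standardized probes and a centered response, each probe's influence
is $Q_i = (\sum_j x_{ij}(y_j - \bar y))^2$ and the set statistic is the
mean influence. Both are invariant to flipping the response sign and to
probe order. The null distribution is obtained by permutation — the
package deliberately uses the permutation rather than an asymptotic
variant, because it makes the per-probe null mean $E_i$ and sd $s_i$
well-defined without distributional assumptions — giving z-scores
$z_i = (Q_i - E_i)/s_i$ ("standard deviations of influence above the
reference line"), an add-one set-level p-value, and a direction from
the sign of the probe's covariance with the case code (zero covariance
is assigned "up" with a warning; such probes cannot reach the core
threshold). Core probes are those with $z_i > 2$ (strict), split into
up- and down-regulated lists. `B` defaults to 10,000; the tests pin
z-scores at B = 5,000 against an independent 50,000-permutation oracle
within Monte-Carlo error.

## Over-representation statistics

`enrich()` scores gene sets against a query list and background
universe with the hypergeometric upper tail (`fisher`) or its
conservative overlap-minus-one variant (`ease`, the default, matching
the DAVID service's default score since that is the analysis style this
mirrors). Fold enrichment is the query frequency over the background
frequency of the term, and Benjamini–Hochberg adjusted p-values are
reported in percent, matching the conventional table format. The
recommended background is the post-preprocessing probe universe mapped
to genes — enrichment of a selected list should be judged against what
could have been selected. Which multiple-testing variant a published
"FDR" column used is often unstated; the package computes and labels
Benjamini–Hochberg.

## Numerical choices and degenerate inputs

* Strict inequalities throughout where thresholds are stated strictly:
  SNR < 3 masks, flag > 8191 masks, missing fraction > 5% drops,
  score > 0 calls a case, z > 2 is core.
* NIPALS components stop early when the residual weight norm falls
  below 1e−12 (the split's numerical rank); held-out scores beyond a
  split's rank reuse the last attainable component.
* Jackknife degenerate limits: se = 0 with a zero coefficient gives
  p = 1; se = 0 with a nonzero coefficient gives p = 0.
* Score orthogonality is guaranteed by deflation and asserted to 1e−8
  relative in tests; batch means after adjustment are zero to 1e−10.
* Ties in the error curve resolve to fewer components; ties in scores
  get AUC half credit.

## Desk-scale study conditions

Simulation-based checks run at sizes chosen for a laptop-class single
CPU, stated here as the package's simulation conditions: null
calibration uses 20 datasets of 40 samples × 200 probes (component cap
10); null double-CV behaviour uses 10 datasets of 40 × 500 with k = 50
label permutations each (cap 10); signal recovery uses 20 datasets of
60 × 1000 with 50 planted probes at effect 1.0 sd and k = 50
permutations (cap 5 — planted signatures are low-rank, and a deeper
component search adds nothing under these conditions); the global-test
oracle comparison uses a 16 × 50 instance at B = 5,000 vs 50,000. The
acceptance script analyses one full default study (156 arrays, 1000
probes) with a component cap of 20 and k = 20 permutations. Caps and
sizes were fixed as part of the study design, not tuned to outcomes.

## Known limitations

* Preprocessing outside the CV loop leaks (response-independent)
  information, as discussed above.
* The jackknife treats LOO coefficient perturbations as exchangeable
  segments; its p-values are approximate, and the selection threshold
  is best regarded as a tuning constant with a calibration that the
  null tests bound rather than guarantee.
* Set precision of jackknife selection is capped by the false positive
  budget (see above); the global test's core-probe reduction is the
  intended remedy, not a guarantee of a pure list.
* `misclass_association()` tests one binary covariate at a time with a
  Fisher exact test and no multiplicity adjustment across covariates.
* PLS2, multi-class responses, sparse PLS and stratified k-fold outer
  loops are out of scope in this version.
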