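---
title: "Interpretable drug assignment: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable drug assignment: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoassign)
```

## The problem

An ex-vivo drug screen measures, for each patient in a cohort, the
sensitivity of that patient's tumor cells to each drug in a panel —
typically as a log-IC50, where lower means more sensitive.  Together with a
biomarker matrix (binary mutation calls and/or continuous expression
values), the precision-medicine question is *patient-centered*: which single
drug should each patient receive?  This package implements two deliberately
interpretable answers — a decision tree a clinician can read, and a sparse
linear model that names the handful of biomarkers it uses — plus the
normalization and validation protocol that makes the comparison honest.

## Response normalization: IC50\*

A raw IC50 confounds two things: how potent a drug is for everyone, and how
*differentially* sensitive this patient is.  A uniformly cytotoxic compound
has a low IC50 in every sample and would win every per-patient argmin while
carrying no personalization signal (and likely unacceptable toxicity).
`compute_ic50_star()` therefore centers each drug's log-IC50 column to mean
zero over its observed entries.  The centered quantity, IC50\*, is invariant
to any per-drug constant shift (potency can be re-dosed), idempotent under
re-centering, and makes the per-patient minimum pick out the drug with the
largest differential effect.  All fitting and evaluation in this package
happens on this scale (internally flipped to a "benefit" scale where larger
is better, so every optimizer is a maximizer; `to_benefit()` carries the
sense on the matrix itself rather than guessing per call).

## Optimal decision trees

At each node the tree solves, over the patients reaching that node, a joint
optimization: choose a biomarker $m$ (and a threshold $th$ if $m$ is
continuous) and one drug per branch $(d_1, d_2)$ maximizing

$$A + B,\qquad
A = \sum_{p:\;x_{pm} \ge th} f(y_{p d_1}),\qquad
B = \sum_{p:\;x_{pm} < th} f(y_{p d_2}),$$

with $y$ on the benefit scale and $f$ either the identity or a signed square
root.  Binary markers use the presence/absence indicator instead of a
threshold.  Because the objective decomposes over branches, the best drug
pair for a given split is found by maximizing each branch independently —
$O(D)$, not $O(D^2)$ — and the search over splits is exhaustive.  The
recursion then descends into each branch and stops when a branch is smaller
than `min_group_size`, when the best split would put the same drug on both
sides (at that point splitting adds nothing: $d_1 = d_2$ is always a
feasible point, so the split objective can never fall below the best single
drug), when no marker separates the patients, or at `max_depth`.

Numerical and structural choices:

* **Thresholds** are midpoints between consecutive distinct observed values
  within the node (`threshold_policy = "midpoints"`): they exhaust every
  distinct partition and do not depend on scan order.
* **Tie-breaking** is deterministic: among objective-maximal decisions the
  lexicographically smallest (marker index, threshold, drug-true index,
  drug-false index) wins.  This makes the search reproducible and lets tests
  compare it decision-for-decision against brute-force enumeration.
* **Marker re-use** is forbidden along a single root-to-leaf path (a binary
  re-split is vacuous, and threshold-refinement re-splits would hurt the
  readability that motivates trees in the first place); re-use across
  sibling subtrees is allowed.
* **Signed square root** `sign(y) * sqrt(|y|)`: IC50\* values are centered
  and therefore negative exactly where a drug works well, so a plain square
  root is undefined on the interesting half of the data.  The signed form is
  the minimal odd, strictly increasing extension — it compresses dynamic
  range (damping single extreme responders) without ever reordering two
  responses.
* **Missing responses**: the default refuses an incomplete matrix, because
  branch *sums* over unequal observation counts silently bias drug choice.
  The opt-in `na_action = "mean"` scores branches by per-drug observed-entry
  means instead, which is the defensible analogue when screens are sparse.
* **`min_group_size` defaults to 10**: small enough to find subgroups in
  cohorts of a few hundred, large enough that a leaf's drug rests on a
  clinically arguable number of patients.  It is the main stopping control
  and always user-settable; `max_depth` defaults to unlimited.

## The vote matrix and the soft-label multinomial lasso

Treating drug assignment as hard multiclass classification throws away the
margin structure: recommending the second-best drug is not as wrong as
recommending the worst.  Each patient therefore splits one vote over the
drugs,

$$z_{pd} = \frac{\exp(-K\, y_{pd} / \min_p)}{\sum_{i=1}^{D} \exp(-K\, y_{pi} / \min_p)},$$

a softmax at inverse temperature $K$.  At $K = 0$ every drug receives $1/D$;
as $K \to \infty$ the vote concentrates on the patient's most effective
drug.  The scaling constant $\min_p$ is, by default, patient $p$'s minimum
response across drugs (`min_scope = "patient"`); this is the reading under
which the two limits above hold exactly.  A per-drug column-minimum variant
(`min_scope = "drug"`) is provided for users who want each drug's column
standardized by its own best responder instead; its large-$K$ limit
concentrates on the drug for which the patient is closest to being the best
responder, which is a different (also defensible) notion.  The formula
requires strictly positive responses; centered IC50\* input must either be
shifted (`positivity = "shift"`, which translates by
$-\min(Y) + 10^{-6}\cdot\mathrm{range}$) or supplied on a raw positive
scale.  $K$ has no canonical value; it defaults to 1 and is stored on the
vote matrix so a fitted pipeline is self-describing.

`fit_multinomial()` then minimizes the soft-label multinomial negative
log-likelihood

$$-\frac{1}{P}\sum_p \sum_d z_{pd} \log \mathrm{softmax}_d\!\left(\beta_{0d} + x_p \beta_{\cdot d}\right)
\;+\; \lambda \Omega(\beta),$$

with $\Omega$ either the elementwise lasso $\sum_m \lVert\beta_{m\cdot}\rVert_1$
or the grouped lasso $\sum_m \lVert\beta_{m\cdot}\rVert_2$, which zeroes each
marker's coefficients jointly across all drugs so that one small variable
set serves the whole panel — the property that makes the model's variable
count a meaningful interpretability metric.  Intercepts are unpenalized;
features are standardized internally and coefficients reported on the
original scale.  The solver is a monotone accelerated proximal-gradient
method (FISTA with function-value restarts, falling back to a plain
guaranteed-descent step whenever acceleration would increase the
objective), with constant step $1/L$,
$L = \sigma_{\max}([\mathbf{1}\,X])^2 / (2P)$, the Lipschitz bound of the
multinomial log-likelihood gradient.  Probabilistic targets are handled
directly by the weighted likelihood — never by expanding pseudo-observations.
Convergence is declared at relative objective change below `tol` (1e-9 at
the final fit); the objective trace is stored, and tests verify the
optimum against an independent quasi-Newton optimizer run on the identical
criterion.

The $\lambda$ path has 100 log-spaced values from $\lambda_{\max}$ (the
smallest $\lambda$ with an all-zero coefficient matrix, computed in closed
form from the gradient at $\beta = 0$) down to $10^{-4}\lambda_{\max}$.
`lambda = "cv"` runs seeded k-fold cross-validation (5 folds by default)
over the path with warm starts.  **Selection rule:** the default is the
one-standard-error rule — the largest $\lambda$ whose mean held-out deviance
is within one SE of the minimum — rather than the raw minimizer.  The
reason is statistical, not cosmetic: on data with *no* biomarker signal the
CV curve near $\lambda_{\max}$ is flat up to first-order noise, so the raw
minimizer wanders below $\lambda_{\max}$ and admits spurious variables in a
substantial fraction of runs, while the 1-SE rule returns the empty model
almost always and costs little sparsity-side accuracy when signal is
present.  `cv_rule = "min"` remains available for pure prediction use.

## Evaluation protocol

* **Oracle** (`oracle_assign()`): each patient's observed-minimum-IC50\*
  drug — the best achievable assignment, and the zero point of the regret
  scale.
* **Regret / ΔIC50\*** (`delta_ic50()`): achieved IC50\* of the assigned
  drug minus the patient's best observed IC50\*; non-negative by
  construction and zero exactly on Oracle agreement.  Patients whose
  assigned drug was not measured are reported missing, never imputed.
* **Cross-validation** (`cross_validate()`): seeded, balanced, unstratified
  folds whose labels depend only on (sorted patient ids, seed, k).  Each
  fold's model is fit strictly on the complement; held-out patients are
  scored by their *own measured* response to the assigned drug — a method
  outputs a drug, not a predicted value, so evaluation must read the
  measurement.  Per-fold failures are recorded and flag the report partial
  rather than aborting the study.
* **Intragroup validation** (`intragroup_test()`): for each drug, a
  two-sided two-sample rank-sum (Mann–Whitney) test comparing that drug's
  ΔIC50\* between the patients it was recommended to and everyone else.
  The comparison is read as independent-groups (recommended vs rest), not
  paired.  The exact null distribution is used when both groups have at
  most 12 patients and the data are tie-free; otherwise the normal
  approximation with tie and continuity correction.  ΔIC50\* is the default
  compared quantity, with `measure = "value"` switching to raw IC50\*.
* **Interpretability** (`count_selected_variables()`): distinct split
  markers for a tree; coefficient rows with any entry above 1e-8 in
  absolute value (after unstandardization) for the multinomial model.

## What the synthetic cohorts emulate — and what they do not

`simulate_planted_tree_cohort()` draws binary markers as Bernoulli and
continuous markers as standard normal, routes each patient down a planted
tree to an intended drug, and sets
$y_{pd} = \text{baseline}_d - \text{effect}\cdot[d = \text{intended}_p] + \mathcal N(0, \text{noise\_sd})$,
with per-drug baselines drawn once from $\mathcal N(0,1)$ so that the
IC50\* correction is exercised non-trivially (on the raw scale the row
argmin is *not* the intended drug; after centering it is, exactly so in the
noiseless limit).  Default conditions: 200 patients, 30 markers, 4 drugs,
depth-2 tree, effect 1.0, noise 0.25, missingness never masking a patient's
intended drug so the Oracle stays defined.

One generator choice deserves emphasis.  The planted markers follow a
prevalence hierarchy — root 0.5, subordinate markers 0.3 (background
markers 0.3).  With a single uniform prevalence the greedy split objective
ties *exactly in expectation* between the planted root and the planted
child markers: for any split that keeps a leaf group intact, the objective
contribution reduces to (winner group size) × (opposite side size) / N,
which is identical for all three planted markers.  The planted topology is
then identifiable only up to re-rooting, and no split-optimizing fitter —
this one or any other — could recover it reliably.  The hierarchy breaks
the symmetry (the root's advantage is ≈ 0.14·n·effect, far above objective
noise) and mirrors how real driver-lesion frequencies are themselves
hierarchical.  The generator does **not** emulate the real mutational
spectrum of any cohort, batch effects, dose–response curve fitting, or
correlated markers; recovery results on it demonstrate correctness of the
optimization, not clinical performance.

`simulate_sparse_linear_cohort()` plants `n_active` (default 5 of 100)
nonzero coefficient rows ($\mathcal N(0, 2^2)$ entries, 300 patients),
builds $y_{pd} = c_d - \text{logit}_{pd} + \mathcal N(0, 0.5)$ and
translates the matrix to minimum 1 so the strict vote-positivity policy
applies.  The intended drug is defined as the drug the response matrix
noiselessly favors, $\arg\max_d(\text{logit}_{pd} - c_d)$ — including the
baselines keeps "intended" equal to the noiseless row argmin, so Oracle,
votes and truth all agree; with `n_active = 0` the intended drug is
baseline-driven and constant, the correct null.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely on generated data at
the scales above: 200 random split instances per marker type (P = 15,
M = 6, D = 4) checked bit-for-bit against exhaustive enumeration; 50
seeded planted-tree cohorts (plus 20 noiseless) for structure recovery;
one 300 × 100 cohort at three fixed $\lambda$ for the optimizer
cross-check; 25 signal and 25 null cohorts for CV support recovery; all
tie-free rank-sum instances with $n_1 + n_2 \le 10$ against full
enumeration plus 500 null replicates for calibration; and a 5-fold CV
comparison of ODT (both transforms), the multinomial lasso, the best
single-drug baseline and the Oracle on one planted cohort.

## Known limitations

* The split search is exhaustive and in-memory; cohorts far beyond ~10^4
  patients × 10^3 markers would need pre-screening of markers.
* The vote temperature $K$ interacts with the response scale; there is no
  automatic selection for it, only the stored, logged value.
* Missing biomarker values are rejected outright (impute upstream);
  missing responses are supported only through the mean-scored branch mode
  and exclusion-with-reporting at evaluation time.
* Cross-cohort transfer (train on one screen, predict another) is supported
  mechanically — `predict()` accepts any aligned biomarker matrix — but no
  harmonization of scales between cohorts is attempted.
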