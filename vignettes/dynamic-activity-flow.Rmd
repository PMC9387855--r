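---
title: "Dynamic activity flow modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic activity flow modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaflow)
```

## The model

dynaflow asks whether the brain's *intrinsic* network architecture —
estimated from task-free resting-state recordings — is sufficient to predict
the *future* task-evoked activity of a target functional network. The model
has two stages.

**Stage 1: lagged resting-state connectivity (MVAR).** For each target
region $j$ and each rest pseudo-trial, the target's activity at time $t_0$
is regressed on three predictor blocks: contemporaneous source activity,
lagged source activity (lags $1..p$), and the target's own lagged activity
(self-coupling). With $R$ regions and order $p$ the design holds
$(R-1) + (R-1)p + p$ columns — 2,903 at the reference scale of 264 regions
and $p = 10$. The regression is regularized by principal-component
regression: predictors are centered, the response is regressed on the top
$n$ PC scores, and the coefficients are mapped back to predictor space. The
component count is selected by sliding-window cross-validation that
preserves the serial order of pseudo-trials (train on pseudo-trial $k$,
test on $k+1$), minimizing test MSE averaged over targets and test
pseudo-trials. Per-pseudo-trial coefficient estimates are averaged into the
final weights. Four properties motivate this estimator: it is *dynamic*
(lagged terms), *lagged* (contemporaneous terms are co-estimated so the
lagged terms are unbiased, then discarded for prediction), *direct* (fully
multivariate in space and time), and *directional* (past predicts future).

**Stage 2: activity flow prediction.** Predicted target activity is the dot
product of lagged *actual* task activations with the rest-derived weights:

$$Y_{t} = \sum_{i=1}^{p} X_{t-i} F_{i} + \sum_{i=1}^{p} Y_{t-i} C_{i}$$

where $X$ are source-region activations restricted to networks outside the
target network, $F$ the lagged source weights, and $C$ the self-coupling
weights. Prediction is one-step-ahead and teacher-forced: every lag uses
actual data, never the model's own earlier outputs, so errors cannot
compound and each predicted sample is a genuine out-of-sample statement
about $t_0$ given the past. Contemporaneous terms and the other
target-network regions are excluded at this stage — the former to keep the
prediction strictly in the future, the latter to focus on long-range flow.

**Evaluation.** Predicted target activations are treated exactly like
recorded ones: response-locked, decimated, averaged into subtrials, and
decoded time point by time point with a linear SVM; the predicted and
actual decoding time courses are compared by Pearson $r$ at group and
subject level and by the sum-of-squares $R^2$ (0 marks a mean-only null
model; negative values are possible and meaningful). Additional probes are
the lateralized motor ERP (contralateral-minus-ipsilateral difference
waves, plus spatial and spatiotemporal pattern overlap), representational
overlap (correct-minus-incorrect template correlation, training on
predicted and testing on actual data), an FC-scrambling permutation null,
and simulated network lesioning.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `order` | 10 (200 Hz) | lag depth; 10 lags = 50 ms of history. Synthetic tests use 3. |
| `pc_grid` | steps of 540, or rank fractions {.05,.2,.4,.6,.8,1} below 540 predictors | candidate PC counts for CV |
| `pseudo_trial_length` | 20 s | long enough for two cycles of 0.1 Hz fluctuations |
| `set_size` | 14 | trials averaged per subtrial before decoding |
| `n_iter` | 10 | randomized subtrial assignments (2 in fast configurations) |
| `train_frac` | 0.2 | training fraction per condition; see below |
| `alpha` | 0.05 | familywise level, Bonferroni across time points |

**The train/test fraction.** The reference procedure describes an "80/20
train/test split" but its worked arithmetic computes the *training* count
as the rounded-up 20% (8 subtrials → 2 training, 6 testing per condition).
`train_frac = 0.2` honors that worked arithmetic and is the package
default; users who want the literal 80/20 reading set `train_frac = 0.8`.
Training counts round up, testing counts round down, and both are equated
across conditions on every fold.

**Wilcoxon policy.** Group tests are two-sided one-sample signed-rank
tests. Zero differences are discarded; the exact distribution is used for
$n \le 25$ without ties, otherwise a normal approximation with continuity
and tie corrections. Note an arithmetic consequence for small cohorts: the
smallest attainable two-sided exact p is $2 \cdot 2^{-n}$, so with $n$
subjects and $T$ time points no Bonferroni-corrected effect can exist
unless $2^{1-n} < \alpha / T$. The synthetic study default of 16 subjects
and 37 decoded time points respects this bound with margin; 12 subjects
would not.

## What the generator emulates — and what it does not

`make_random_stable_var()` draws sparse random lagged weights and rescales
them so the companion-matrix spectral radius equals the stability bound
exactly (scaling lag $i$ by $s^i$ scales every companion eigenvalue by
$s$). Rest data are independent stable-VAR realizations with Gaussian
i.i.d. innovations; task data inject condition-specific half-cosine bumps
(opposite sign patterns across designated source regions) into the
*innovations* of source regions, centered just before each trial's
truncated-normal reaction time, so condition information can reach the
target network only through the lagged ground-truth weights. Optional
instantaneous diagonally dominant mixing emulates field spread.

The default study conditions are: 16 subjects, 16 regions in 4 networks
(Motor targets, Visual sources carrying the evoked information, DAN as an
information-isolated control, FPN), order 3, density 0.2, stability bound
0.9, 10 rest pseudo-trials of 2,000 samples at 200 Hz, 56 trials per
response hand, stimulus-locked epochs of −0.5..1.5 s. The DAN is generated
with no incoming between-network connections: it sends real connections to
the target (so it contributes rest-estimated flow) but can never carry
evoked task information — giving simulated lesioning a known-uninvolved
comparison. These sizes keep the full pipeline at a few minutes on one
core while exercising every code path; they are stated here as the
package's reference conditions and are not meant to reproduce
cohort-specific headline values from any real dataset.

The generator is linear and Gaussian by construction — exactly the working
model the estimator assumes. Passing tests therefore demonstrate correct
implementation and internal consistency (parameter recovery, flow
specificity, null calibration), not robustness to the nonlinearities,
oscillatory structure, nonstationarity, or residual artifacts of real
recordings.

## Numerical and design choices

- **Z-scoring** uses the population (divide-by-$n$) standard deviation per
  trial and region; this matches common neural-time-series toolbox
  convention and only rescales regressors uniformly. It is idempotent to
  1e-8 and validated as such.
- **PCA determinism**: each component's sign is fixed by making its
  largest-magnitude loading positive, so fits are reproducible across BLAS
  implementations up to that convention. At full rank the estimator equals
  the minimum-norm least-squares solution (tested against a direct solver
  on random instances).
- **CV tie-break**: equal mean MSE selects the smaller component count.
- **Response locking** uses nearest-sample rounding of the reaction time —
  no interpolation, raw samples preserved; trials whose window exceeds the
  epoch are dropped and counted, never padded. The response-locked analysis
  window is −0.45..+0.45 s. No re-baselining is applied after response
  locking: the epochs entering the package are already baseline-corrected
  upstream, and re-baselining on a response-locked window would subtract
  condition-relevant pre-response activity.
- **Decimation** is sequential sample selection without an anti-alias
  filter, deliberately matching the reference decoding procedure.
- **SVM ties**: an exactly-zero decision value counts as incorrect
  (conservative).
- **Leakage regression** fits per trial with an intercept, removing the
  target's contemporaneous series from every source before lagging
  (residual-target correlation < 1e-10). It runs over the whole trial, so
  the strict "permute the future, the past prediction is unchanged"
  causality property holds exactly only with leakage regression disabled;
  with it enabled, future samples influence predictions solely through this
  contemporaneous-removal step, which is its purpose.
- **Lesioned models** reuse the full fit's weights with the source set
  restricted and self-coupling removed — no re-estimation — so the
  single-network predictions sum to the full prediction exactly (the
  module's structural oracle, tested at 1e-10).
- **FC scrambling granularity**: one random permutation of the
  non-target-network source axis per target, shared across lags, leaving
  self-coupling intact. This destroys source-target correspondence while
  preserving the weight magnitude distribution, the lag structure, and the
  autoregressive terms. Per-lag or global scrambling variants would be
  stricter or looser nulls respectively; the per-target, lag-shared scheme
  is the middle ground and is what the permutation machinery implements.
- **Permutation statistic**: `permutation_null()` defaults to the full
  decode-and-correlate pipeline. At small region counts this statistic has
  little power *by construction*: a linear decoder is invariant to the
  invertible linear map the flow weights implement, so any scrambled
  weights that still touch an informative source yield predictions that
  decode (and correlate) about as well as the true ones. The built-in
  `"activation"` statistic — Pearson r between predicted and actual target
  series — measures weight correctness directly and is the recommended
  choice below a few dozen regions; the package's own calibration and
  detection tests use it. At the reference scale (hundreds of regions, few
  informative sources) the decode statistic regains its power because
  scrambled weights land almost surely on uninformative sources.
- **Permutation p-values** use the add-one convention
  $p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})$, valid at finite
  samples; with 500 permutations the smallest attainable p is ≈ 1/501.
- **Pseudo-trial PCA scope**: PCA is computed per (target, pseudo-trial)
  design matrix rather than on a pooled basis, mirroring the
  per-pseudo-trial fitting that the final across-pseudo-trial averaging
  implies. A pooled-basis variant would couple the fits across
  pseudo-trials and was deliberately not implemented.
- **Seeding**: one master seed expands into per-stage, per-subject,
  per-permutation subseeds through a counter-based integer hash
  (`expand_seed()`), so every stochastic output is reproducible from a
  single integer and stages remain independently re-runnable.

## Known limitations

- The estimator and generator are linear-Gaussian; oscillatory or
  band-specific dynamics, nonlinear transfer, and task-state connectivity
  changes are out of scope.
- Predictions are teacher-forced; the package deliberately does not offer
  free-running simulation, whose compounding errors answer a different
  question.
- Leakage regression assumes instantaneous mixing; delayed artifact
  spread would require upstream handling.
- Decoding-based permutation nulls are insensitive at small feature counts
  (see above); use the activation statistic there.
- Group statistics require at least 6 subjects, and Bonferroni-corrected
  significance is arithmetically impossible for small cohorts at dense
  time grids (see the Wilcoxon note above).

## Pipeline configuration

`run_pipeline()` takes a nested list or YAML file with sections `simulate`,
`fit`, `flow`, `decode`, plus a master `seed` and an `out_dir`. Unknown keys
are rejected rather than ignored. `dry_run = TRUE` validates and reports the
design geometry without computing. Outputs are `decode_actual.tsv`,
`decode_predicted.tsv` (time, group mean accuracy, raw and
Bonferroni-corrected p, significance), `report.json` (overlap summary), and
`manifest.json` (package version, config hash, seed). Re-running an
identical configuration reproduces every output byte for byte.

```{r, eval = FALSE}
res <- run_pipeline(list(seed = 42), out_dir = "run1")
glance(res$overlap)
autoplot(res$predicted)
```
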