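---
title: "Local subset augmentation for spectral calibration: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local subset augmentation for spectral calibration: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Inline UV/Vis monitoring of protein chromatography yields an absorbance
spectrum per elution fraction, and reference analytics yield the
concentrations of the co-eluting species in that fraction. Calibration sets
built this way are small — a few hundred samples from a handful of runs —
which starves flexible regressors such as convolutional networks. This
package implements a generative augmentation method, *local subset
augmentation* (LSA), that manufactures realistic in-silico spectra from
such a set, plus the surrounding workflow: a small 1-D CNN engine trained
on the generated spectra, a NIPALS PLS1 baseline, a hyperparameter-search
harness with median pruning, per-wavelength attribution, and an in-silico
robustness study.

## The augmentation model

A calibration set is $\{(\mathbf{x}_i^\top, \mathbf{y}_i^\top)\}_{i=1}^M$
with spectra $\mathbf{x}_i \in \mathbb{R}^N$ over $N$ wavelengths and
concentrations $\mathbf{y}_i \in \mathbb{R}^P$ of $P$ species. LSA assumes
Beer–Lambert bilinearity *locally*: in a neighborhood of a given
composition, absorbance is a concentration-weighted sum of per-unit
pure-component profiles. One generated sample is produced by:

1. **Concentration sampling.** Each column of $Y$ is modeled by an
   independent univariate Gaussian kernel density estimate
   (Scott's-rule bandwidth $\hat\sigma M^{-1/5}$); a new vector
   $\mathbf{y}^*$ is drawn componentwise. Uniform and normal samplers are
   available for comparison. Negative draws are redrawn (up to 100
   attempts) and then clamped at zero.
2. **Subset selection.** The $n_{\mathrm{LSA}}$ calibration samples with
   the smallest $\lVert \mathbf{y}^* - \mathbf{y}_i \rVert_l$
   ($l \in \{1, 2\}$) form the local subset $(\tilde X, \tilde Y)$. Ties
   break by ascending row index.
3. **Local pure-component estimation.** $\tilde S \in \mathbb{R}^{N\times P}$
   minimizes $\lVert \tilde X - \tilde Y \tilde S^\top \rVert_F^2$, solved
   independently per wavelength, by ordinary least squares (minimum-norm
   under rank deficiency) or non-negative least squares.
4. **Synthesis and perturbation.** $\mathbf{x}^* = \tilde S\, \mathbf{y}^*$,
   then one wavelength shift $\delta \sim \mathcal N(0, \sigma_{shift})$
   re-evaluates the spectrum at $\lambda - \delta$ (linear interpolation,
   edges held), then i.i.d. noise $\mathcal N(0, \sigma_{noise})$ is added
   per feature.

The local estimation is the point: profile estimates absorb whatever
systematic deviations from global bilinearity (saturation, buffer
absorbance, baseline drift) exist in that composition neighborhood, so the
generated spectra inherit them.

### Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `n_lsa` | local subset size (samples) | 5 | small enough to stay local; tuned per data set by `tune_lsa()` |
| `norm_order` | distance norm $l$ | 2 | Euclidean neighborhoods |
| `solver` | `nnls` / `ols` | `nnls` | absorptivities are physically non-negative |
| `sigma_noise` | white-noise SD (absorbance units of the stored spectra) | 0.001 | typical detector noise at mAU scale |
| `sigma_shift` | shift SD (wavelength units) | 0.01 | sub-resolution wavelength registration error |
| `n_gen` | generated samples | 1e5 | ample calibration data for the CNN |
| `sampler_mode` | `kde` / `uniform` / `normal` | `kde` | follows the observed concentration distribution |

`tune_lsa()` screens any subset of these over a grid and selects by
leave-one-group-out reconstruction RMSECV: each held-out sample's spectrum
is re-synthesized at its measured concentrations from profiles estimated on
the retained groups only. Whether the configured noise/shift are applied
during this tuning is exposed (`apply_perturbation`); the default off keeps
the criterion a pure reconstruction error. Pooled RMSECV (over all held-out
residuals) is the default; per-rotation averaging is available
(`pooling = "averaged"`), since small groups weigh differently under the
two conventions.

### Numerical choices

- **Equation orientation.** The estimation step is stated here as
  $\tilde X \approx \tilde Y \tilde S^\top$; this is the only orientation
  under which $\tilde S \mathbf y^*$ is a spectrum, and it is what the
  implementation solves.
- **Batched NNLS.** Augmentation calls NNLS once per wavelength per
  generated sample. The in-package solver (`nnls_multi()`) exploits the
  shared design matrix: the unconstrained solution is accepted where
  already non-negative (making NNLS = OLS exact in that case), remaining
  wavelengths are resolved by active-set enumeration (largest support
  first) with column-scaled KKT tolerances, and degenerate leftovers fall
  back to the Lawson–Hanson solver in `pracma`. Tests cross-check it
  against `pracma::lsqnonneg` on random problems.
- **Shift before noise**, so the added noise statistics are unaffected by
  interpolation; edge values are held rather than extrapolated.
- **Rank-deficient local OLS** returns the minimum-norm solution with a
  warning rather than failing: near-duplicate compositions are normal in
  adjacent elution fractions.

## The synthetic data generator

Because the workflow's original calibration sets are proprietary, the
package ships a generator (`synthetic_spec()`, preset `ds1_like_spec()`)
with exactly known ground truth: smooth pure-component spectra as sums of
Gaussian absorption bands on a 240–300 nm, 1 nm grid (61 features);
Gaussian elution peaks per component and experiment over the fraction
index; Beer–Lambert mixing; optional linear baseline; homoscedastic
Gaussian cell noise. The preset emulates a three-protein, five-experiment
calibration (225 samples) with retention drifting across experiments.

Elution peaks overlap substantially (widths 7/9/7.5 fractions at 45
fractions per run): fractions are genuine mixtures, which is the co-elution
regime the method targets. This matters beyond realism — with nearly pure
fractions the concentration vectors lie on a thin curve, independently
sampled $\mathbf y^*$ fall far off it, and the ill-conditioned local solves
amplify into extreme synthetic spectra. Retention times and widths scale
with `n_fractions` so reduced-size test sets keep every component inside
the collected window.

What the generator does *not* emulate: detector saturation, scatter,
correlated (heteroscedastic) noise, IR-type backgrounds, and
cross-component concentration correlation beyond what the elution curves
induce. Tests passing on this generator therefore demonstrate correctness
of the algorithms and recoverability under the bilinear model — not
performance on real chromatography data.

## CNN engine

No deep-learning backend is assumed: the package contains a purpose-built,
fully vectorized 1-D CNN engine (im2col convolutions, analytic backprop,
Adam) for the small architectures this problem needs. The family: 1–3
convolutional layers (1–10 filters, odd widths, no padding so the feature
length shrinks by width−1), max pooling of width 2 after layers 1 and 2
only, flatten, one fully connected layer (5–100 units, tanh), dropout,
dense output with ReLU so concentrations are non-negative. Convolution
activations default to identity ("linear"), matching the near-linear
mixing physics. Training minimizes the mean MSE over all responses with
Adam (learning rate 1e-3, batch 100), stops when the validation loss —
computed on the *experimental* training spectra, never the generated ones —
fails to improve for `patience` (default 4) consecutive epochs, and
restores the best-epoch weights. Gradient correctness is tested against
finite differences; parameter counts against hand formulas.

Numerical choices: random-uniform init in [−0.05, 0.05] (Glorot-uniform
optional); the ReLU output bias starts at 0.01 so no output unit is born
dead; L2 (when configured) applies to all trainable parameters; dropout
sits after the FC activation; Adam's constant learning rate is never
decayed.

`cross_validate_cnn()` implements the leave-one-group-out protocol in which
the in-silico data are regenerated per rotation from the retained groups
only, and held-out predictions are pooled before computing per-component
$R^2$. `train_unaugmented()` is the baseline protocol: random 80/20 split,
fixed 300 epochs, early stopping disabled, best-validation epoch reported.

## PLS baseline

Single-response NIPALS PLS1 per component, after Savitzky–Golay filtering
(second-degree polynomial; derivative orders 0–2; odd windows 3–31,
derivatives scaled by the wavelength step) and mean centering (filter
first, then center — centering is linear so the order only affects the
stored constants). `tune_pls()` grids components (1–10) × derivative ×
window with the same leave-one-group-out rotations as the CNN and selects
by the scaled criterion
$SSE_{CV,scaled} = \sum_i (\hat y_i - y_i)^2 / (M - n_{PLS} - 1)$, where
$M$ counts the pooled CV predictions. Ties prefer fewer components, then
smaller windows, then lower derivatives. The NIPALS implementation is
cross-checked against an independent reference (mixOmics) to 1e-6, which
also makes the VIP inputs trustworthy. When deflation exhausts the
response (exactly low-rank noise-free data), the fit truncates to the
attainable number of components; `fit_pls1()` errors only if the user
requested more.

## Hyperparameter search

`run_hpo_study()` samples architecture + `n_lsa` per trial, trains once on
the full training set to get the intermediate objective
$\sum_p R^2_{train,p}$, applies median pruning (active after
`activation_after` completed trials, default 100; prune iff strictly below
the median of all previously reported intermediate values), and scores
surviving trials by cross-validated $\sum_p R^2_{CV,p}$. Trial failures
are recorded and the study continues; records stream to JSON lines. The
`"tpe"` sampler names the Bayesian phase that follows the 100-trial random
phase; no tree-structured Parzen estimator backend ships with this
package, so that phase currently continues with the seeded random sampler
(and says so once per study). The search ranges mirror the architecture
family above; the `n_lsa` range is user-supplied, a sensible default being
±5 around the grid-tuned value. `select_and_retrain()` ranks completed
trials, exposes the top-5 table, and retrains the chosen configuration 10
times with patience 10 and fresh seeds.

## Attribution

- **Grad-CAM** (`gradcam_map()`): backward gradients of one output with
  respect to the last convolutional layer's feature maps, averaged over
  positions into one weight per filter, weighted sum rectified and
  linearly interpolated from the reduced feature length to $N$. Gradients
  are taken through the post-ReLU output.
- **Permutation Shapley values** (`permutation_shap()`): model-agnostic,
  interventional. Random feature orderings are walked from a sampled
  background row to the explained spectrum, forward and (antithetically)
  reversed; attributions are averaged marginal prediction changes. Each
  walk's attributions sum exactly to $f(x) - f(\text{background})$, giving
  exact local additivity; agreement with exhaustive coalition enumeration
  is tested on 5-feature models. Conditional-density masking is out of
  scope — masked wavelengths take values from background rows.
- **VIP scores**: $v_j = \sqrt{N \sum_a ss_a (w_{aj}/\lVert w_a\rVert)^2 /
  \sum_a ss_a}$ with $ss_a = q_a^2\, t_a^\top t_a$; the mean of $v_j^2$ is
  1 by construction (the conventional square-root form). Regression
  coefficients are reported on the preprocessed-spectrum scale with the
  preprocessing chain in the result metadata.

## Robustness study

`run_robustness_study()` sweeps white-noise SDs (default
{0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1}) and wavelength-shift SDs
(default {0, …, 0.3}) one axis at a time. *Fixed* models train once on the
unperturbed generated data; *retrained* models train on generated data
perturbed at the level under test; both are evaluated on perturbed copies
of the evaluation spectra, summarized as the sum of per-component NRMSE.
PLS models in this study are trained on the same generated data as the
CNN, so both model types see identical calibration conditions; per-level
re-tuning of the PLS preprocessing is deliberately not the default.

## Problem sizes used by the tests

The shipped tests and the acceptance script run the full workflow at sizes
chosen for a single desk CPU: data sets of 2–5 experiments with 14–45
fractions (32–225 samples), $10^3$–$10^4$ generated spectra, 10–20-trial
search studies, and a robustness grid reduced to noise SDs {0, 0.05, 1}
with three seeds. These sizes are large enough for every oracle,
invariance and learnability check; they are not performance benchmarks.

## Known limitations

- Per-component independent concentration sampling ignores cross-component
  correlation; strongly anti-correlated species (e.g. monomer vs aggregate
  fractions) can yield compositions never seen experimentally. Overlapping
  calibration designs mitigate the resulting extrapolation.
- The local least-squares step assumes the subset spans all $P$ components;
  compositions near a pure tail give poorly determined profiles for the
  absent species (NNLS clamps, OLS extrapolates).
- The CNN engine targets small spectra (tens to hundreds of features) on
  CPU; it is not a general deep-learning framework.
- The Bayesian phase of the search harness is a seeded random fallback
  until a TPE backend exists in this environment.
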