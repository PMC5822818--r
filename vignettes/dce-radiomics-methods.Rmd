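---
title: "Pharmacokinetic DCE-MRI radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacokinetic DCE-MRI radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dceradiomics` implements an end-to-end radiomics analysis of dynamic
contrast-enhanced (DCE) breast MRI: forward simulation of contrast-enhanced
acquisitions, voxelwise pharmacokinetic mapping, enhancement-threshold
lesion segmentation, extraction of a 163-feature radiomic panel, and a
bootstrap-based multivariable logistic modeling scheme for binary
histological outcomes (receptor status, proliferation level, grade). This
vignette explains the underlying models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## 1. Signal model and simulation

### Spoiled gradient-echo signal

All simulated volumes follow the steady-state spoiled gradient-echo (SPGR /
VIBE) equation

$$S = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1 \cos\alpha}, \qquad
  E_1 = e^{-TR \cdot R_1},$$

with flip angle $\alpha$, repetition time $TR$ (ms) and longitudinal
relaxation rate $R_1$ (1/ms internally; maps are reported in 1/s). The
emulated acquisition uses the protocol that motivated the package: 60
dynamic phases at 9 s per phase with $\alpha = 20^\circ$, six
variable-flip-angle (VFA) volumes at $\alpha \in \{2, 5, 8, 12, 15,
20\}^\circ$ for T1 mapping, and $TR = 5.3$ ms, plus a TIRM-like precontrast
volume on a coarser grid and a delayed postcontrast volume on a finer grid
(so that mask resampling between native spaces is exercised).

### Kinetics

Tissue contrast concentration follows the standard Tofts model

$$C_t(t) = k^{trans} \int_0^t C_p(\tau)\, e^{-k_{ep} (t - \tau)}\, d\tau,$$

driven by a biexponential population arterial input function

$$C_p(t) = D \left( a_1 e^{-m_1 t} + a_2 e^{-m_2 t} \right)$$

with dose $D = 0.1$ mmol/kg, $a_1 = 3.99$, $a_2 = 4.78$ mM·kg/L, $m_1 =
0.144$, $m_2 = 0.0111$ /min — the classical population parameterization.
The commercial software used in the motivating protocol ships a proprietary
"intermediate" population AIF whose functional form is unpublished; the
package substitutes this standard, citable population AIF and exposes all
constants (`aif_model()`). Absolute map values therefore need not match any
particular vendor pipeline — which is immaterial here, since validation is
against the simulator's own ground truth.

Contrast changes relaxation linearly, $R_1(t) = R_1(0) + r_1 C_t(t)$, with
relaxivity $r_1 = 4.5$ /mM/s by default (typical of gadolinium chelates at
3 T; the protocol source does not state a value, so it is configurable).

Contrast arrival is modeled at the end of the first dynamic phase (9 s),
matching the protocol's injection scheme; the true in-vivo bolus delay is
unknown, and the onset is configurable through the AIF.

### Convolution scheme

The convolution is evaluated by an exact recursion under a
piecewise-linear $C_p$: over each interval $[t_{n-1}, t_n]$,

$$I_n = E I_{n-1} + C_{p,n-1}(q - r) + C_{p,n} r, \qquad
  E = e^{-k_{ep}\Delta},\; q = \frac{1-E}{k_{ep}},\;
  r = \frac{\Delta - q}{k_{ep}\Delta},$$

which is exact for the sampled input (no quadrature error accrues on the
grid), stable for all $k_{ep}\Delta$, and switches to a series expansion
for $k_{ep}\Delta < 10^{-8}$. Because simulator and fitter share this
discretization, noiseless round trips are limited only by optimizer
tolerance, which is what makes 2%-level recovery assertions meaningful.

### Phantoms and cohorts

A phantom (`phantom_spec()`, `simulate_phantom()`) is a homogeneous
spherical lesion on a homogeneous background: the simplest geometry that
still exercises every shape feature nontrivially. Defaults: a 24³ grid at
2 mm isotropic spacing with a 12.4 mm lesion radius (≈ 970 voxels ≈ 8 cm³),
lesion $k^{trans} = 0.25$/min, $k_{ep} = 0.5$/min (so $v_e = 0.5$),
background $k^{trans} = 0.02$/min, $R_1 = 1$/s, and additive Gaussian noise
with standard deviation `noise_sd` × the per-voxel baseline signal
(default 0.02, a high-SNR breast protocol). With these defaults the lesion
peak relative enhancement is ≈ 1.2, comfortably above the 0.75 segmentation
threshold, while the background stays near 0.1. Noise is Gaussian on the
magnitude signal: adequate at the simulated SNRs, where the Rician
correction is negligible; Rician noise, B1 inhomogeneity, motion and
realistic anatomy are deliberately out of scope.

Cohorts (`cohort_spec()`, `generate_cohort()`) draw per-lesion
pharmacokinetic parameters log-normally around the template truth
(`lesion_sd = 0.15`, i.e. ±15% between-lesion biological variability) and
assign exact-count binary labels per task. Planted associations are
multiplicative shifts of $k^{trans}$ and/or $k_{ep}$ in the positive class;
the default tasks emulate a proliferation-marker outcome (×1.6 on
$k^{trans}$) and a grade outcome (×1.5 on $k_{ep}$), effect sizes chosen
once as clearly-detectable vascular differences at n = 40. A cohort of 40
lesions at balance 0.5 is the default study condition.

## 2. Pharmacokinetic mapping

`fit_vfa_r1()` estimates $R_1$ and $M_0$ by the classical linearized
(DESPOT1) regression of $S/\sin\alpha$ on $S/\tan\alpha$; voxels whose
slope leaves $(0,1)$ are flagged invalid and propagate as missing through
the maps and into feature extraction (masked out).

`signal_to_concentration()` inverts the SPGR equation for $R_1(t)$ per
phase — the full inversion, not the small-enhancement linearization — using
the VFA-fitted $M_0$, then converts to concentration through the relaxivity
relation. The reference rate is taken from the inversion of the baseline
phase itself, which forces $C_t = 0$ at baseline by construction; the
VFA-fitted $R_1$ serves as fallback when the baseline inversion is invalid.
Signals implying $E_1 \notin (0,1)$ are clamped and flagged.

`fit_tofts()` performs the nonlinear least-squares fit of
$(k^{trans}, k_{ep})$ within bounds $k^{trans} \in [0, 5]$/min, $k_{ep} \in
[10^{-3}, 10]$/min. Because the model is linear in $k^{trans}$ at fixed
$k_{ep}$, the fit is profiled: a closed form gives the optimal $k^{trans}$
for each $k_{ep}$, and the profiled residual is minimized over $k_{ep}$ by
a 48-point log-grid bracket, a 17-point local refinement shared across
voxels with the same bracket, and a final parabolic interpolation in
$\log k_{ep}$. The global grid bracket plays the role a multi-start scheme
would otherwise play; the whole map fits in a handful of matrix products,
which is what keeps 40 lesions × ~2000 voxels in seconds. $v_e =
k^{trans}/k_{ep}$ identically (clipped to [0, 1] in the map bundle), so the
$v_e k_{ep} = k^{trans}$ identity is exact by construction.

`compute_iauc()` integrates the concentration curve by trapezoids from
contrast onset over a 60 s window (linear interpolation at the window
edges). The window length is a convention — the motivating protocol does
not define one — and is exposed as `iauc_window`; integrals that would
extend past the last phase are truncated and flagged. Inside
`compute_pk_maps()` the integral is applied as a precomputed linear
functional of the curve, which is exact and vectorizes over voxels.

## 3. Segmentation

`relative_enhancement()` computes $RE = (\max_{t>t_1} S(t) - S(t_1)) /
S(t_1)$ per voxel; the maximum-over-phases reading is the default (the
first-post-phase alternative is available via `first_post_only`), and
voxels with non-positive baseline are excluded. `segment_lesion()` selects
voxels with $RE$ *strictly* above the threshold (default 0.75, i.e. "a
signal increase higher than 75% of the first time point") inside a
user-supplied bounding box, then `keep_largest_component()` erases voxels
disconnected from the biggest 26-connected component (size ties break
toward the component containing the lowest linear voxel index; the
operation is idempotent). Inputs are assumed aligned — the simulator
generates them aligned, and a geometry check rejects mismatched grids —
so no motion correction is performed.

`resample_mask()` maps the tumour mask to the TIRM and postcontrast grids
by nearest neighbour in physical coordinates. Only axis-aligned geometries
are supported; oblique orientations are rejected with a clear error, which
is the honest boundary of the phantom scope.

## 4. The 163-feature panel

Per lesion: 9 shape features from the dynamic-space mask, and for each of
the seven images ($R_1$, $k^{trans}$, $k_{ep}$, $v_e$, iAUC, TIRM,
postcontrast) 13 first-order and 9 co-occurrence features, each image
evaluated in its native space against a geometry-matched mask:
$9 + 7 \times 22 = 163$. Names follow `<image>__<feature>` and
`shape__<feature>`.

Choices that needed fixing where the conventions diverge:

* **Normalization.** Within-mask values are clipped to $\mu \pm 3\sigma$
  (population $\sigma$, divisor N) before both histogram and texture
  computation; a zero-variance region is a no-op.
* **First order.** Energy and RMS use raw clipped values
  ($\sum x_i^2$), while entropy and uniformity use 256-bin histogram
  probabilities — both appear in the panel, so they must be distinct
  statistics. Binning is equal-width over the post-clip range, left-closed
  with a right-closed final bin. Variance, skewness and kurtosis are
  population moments; kurtosis is not excess-corrected; at zero variance
  skewness and kurtosis are defined as 0 to avoid NaN propagation into
  modeling.
* **Quantization.** 32 equal-width grey levels,
  $\ell = \min(\lfloor (x - \min)/w \rfloor + 1, 32)$; constant regions map
  to level 1.
* **GLCM.** One merged symmetric matrix over all 26 neighbours at distance
  1 (13 direction pairs, both orientations), normalized to sum 1 —
  "simultaneously taking into account" all 3D directions rather than
  averaging per-direction matrices. Correlation of a degenerate
  (zero-marginal-variance) matrix is defined as 1. All entropies use
  log base 2.
* **Shape.** Surface area is measured by exposed-voxel-face counting:
  deterministic and exactly testable. Its known bias is that staircase
  surfaces overestimate smooth ones — for a sphere by exactly 3/2, so
  digitized-sphere sphericity concentrates near $2/3$, not 1; the shape
  features remain exact descriptors of the digitized object and perfectly
  valid covariates, but their absolute values are not mesh-comparable.
  "Minimum diameter" is not uniquely defined in common usage; it is
  implemented as the smallest principal-axis extent,
  $2\sqrt{3\lambda_{\min}}$ of the voxel-centre covariance (exact for a
  uniform box). Maximum diameter is the largest voxel-centre pairwise
  distance, computed on boundary voxels for large masks.

## 5. Feature reduction and modeling

### Gain-equation reduction

For each task the 163 features are reduced to 25 by forward selection:
the first feature maximizes $|\rho|$, the absolute Spearman correlation
with the outcome (estimated as the mean over imbalance-adjusted bootstrap
samples, 1000 by default; plain correlations via `n_boot = 0`); each
subsequent feature maximizes

$$\text{gain} = \delta\,|\rho| - (1 - \delta)\,\overline{\mathrm{MIC}}
  (\text{candidate}, \text{selected}),$$

the maximal information coefficient term penalizing redundancy with the
already-selected features. The weight $\delta = 0.5$ balances the two
terms equally (the originating methodology does not print its weights);
it is exposed as `delta`. MIC values are cached per feature pair, and ties
break deterministically by column order.

### MIC

`mic()` computes the maximal normalized mutual information over all
$n_x \times n_y$ grids with $n_x n_y \le n^{0.6}$. For $n \le 30$ the
search over grid lines is exhaustive (and therefore exact — this is the
path the test-suite oracle checks to $10^{-12}$). For larger samples the
standard MINE approximation is used: one axis is equipartitioned, the
other optimized exactly by dynamic programming over clump boundaries
(capped at $c = 15$ times the bin count), both axis orders tried. The
approximation is a deterministic lower bound on the exhaustive value and
coincides with it for monotone relationships. At cohort sizes
($n \approx 40$, $B = 9$) grids are at most 4 × 2 and 3 × 3, so the DP is
essentially exact in practice.

### IABR and the 0.632+ bootstrap AUC

`iabr_sample()` draws each bootstrap observation by first picking a class
fairly (probability 1/2) and then a member uniformly within the class:
the sample's expected class balance is 1:1 whatever the cohort imbalance,
which keeps logistic fits from collapsing onto the majority class. The
name-giving procedure is not formally defined in the sources that use it;
this class-balanced bootstrap is the natural reading.

`bootstrap_632plus_auc()` estimates out-of-sample AUC of a fixed feature
subset: per IABR sample, fit in-bag (features z-scored by in-bag
statistics), score out-of-bag; combine the apparent AUC and the mean
out-of-bag AUC by the 0.632+ rule transcribed to AUC with no-information
value $\gamma = 0.5$,

$$R = \frac{AUC_{app} - AUC_{oob}}{AUC_{app} - \gamma} \in [0,1], \qquad
  w = \frac{0.632}{1 - 0.368 R}, \qquad
  \widehat{AUC} = (1-w) AUC_{app} + w\,AUC_{oob}.$$

Samples with a single-class out-of-bag set are redrawn (bounded retries).
Sensitivity, specificity and accuracy are evaluated out-of-bag at the
probability-0.5 operating point (the operating point is a package choice).
The reported uncertainty is the standard error of the bootstrap
distribution (its mean), which is one of the two readings of a
"standard error over bootstrap samples"; it is labeled as such in the
output.

Logistic fits are unpenalized maximum likelihood with a tiny ridge
($10^{-6}$) IRLS fallback on separation or non-convergence, recorded in
the fit metadata. Features are z-standardized before fitting to stabilize
coefficients; the serialized model stores the transform together with
raw-scale coefficients, so a printed model applies directly as
$g(x) = \sum \beta x + \beta_0$, $p = 1/(1 + e^{-g})$.

### Stepwise models and the final model

`build_models()` grows models of order 1–10: order 1 is the best single
feature by 0.632+ AUC; order $i$ adds the candidate maximizing the
order-$i$ model's estimate. Within an order all candidates are evaluated
on the same bootstrap draws (a per-order derived seed), so comparisons are
paired; AUC ties break toward the earlier reduced-set rank.
`select_final_model()` takes the order maximizing the AUC-versus-order
curve (ties toward the smaller order) and averages the in-bag logistic
coefficients over IABR replicates for the final model.
`univariate_analysis()` adds per-feature Mann-Whitney U tests with
Bonferroni correction at the reduced-set size.

Mann-Whitney p-values are exact by complete enumeration when
$n_0 n_1 \le 64$ with no ties, otherwise a tie-corrected normal
approximation with continuity correction.

### What the synthetic validation shows — and what it cannot

Planted-effect cohorts verify the machinery end to end: a feature that
truly determines the outcome is found first by the reduction and retained
by the stepwise models, physics round trips recover the generative
parameters, and fixed seeds reproduce runs bit for bit.

One property deserves honesty: the *null* behaviour. All resampling in
this scheme — reduction, stepwise selection, and the final 0.632+
estimate — draws from the same cohort. The 0.632+ rule corrects the
optimism of *fitting*, not of *selection*: once a feature has been chosen
because it looks associated in this particular sample, its chance
association persists in every bootstrap replicate, in-bag and out-of-bag
alike. On cohorts with no planted effect the final estimated AUC therefore
does not concentrate at 0.5 but substantially above it, increasingly so
with feature-panel size and model order. This is a real property of the
selection-inside-the-sample design (shared by the radiomics literature
that uses it), not an implementation artifact; unbiased null behaviour
would require nesting the entire selection inside each resample or an
external validation cohort, both outside this package's scope. The test
suite measures and documents this inflation rather than asserting it
away.

The synthetic cohorts also idealize real data in ways that bound what
green tests mean: lesions are homogeneous spheres (no intratumoral
heterogeneity unless per-voxel jitter is enabled), inputs are perfectly
aligned (no motion), noise is Gaussian and stationary, and the AIF is
known exactly to the fitter. Real-data performance claims need real data.

## 6. Problem sizes and reproducibility

Default validation scales were chosen so the full suite runs on a single
CPU in minutes: cohorts of 40 lesions of ~10³ voxels with 100 bootstrap
samples for the end-to-end structural checks, 1000 bootstrap samples where
the bootstrap itself is under test, feature-level cohorts (n = 40,
12 correlated blocks of 5 features) for the 20-seed recovery and 10-seed
null studies. Every stochastic stage derives its seed from the single
master seed, and identical configurations are bit-reproducible.

## 7. Interfaces

Volumes are NIfTI-1 (`read_volume()`/`write_volume()`, 4D series with a
times sidecar via `read_dynamic()`/`write_dynamic()`); feature tables,
labels and AUC curves are CSV; models, reduced sets and the run manifest
are JSON; configurations are YAML (`read_config()`/`write_config()`). The
functions compose the pipeline (`run_pipeline()`), and
`inst/scripts/run_pipeline.R` wraps it for shell use.
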