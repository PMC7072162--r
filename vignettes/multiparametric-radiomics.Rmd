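---
title: "Methods: multiparametric prostate radiomics on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric prostate radiomics on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprad)
```

`mprad` reimplements a complete prostate-mpMRI radiomic analysis — from raw
multiparametric volumes to order-selected logistic classifiers — as tested,
reusable code. This vignette records the models, the numerical choices, and
the design decisions taken where several defensible options existed.

## 1. Signal models and map fitting

**Diffusion.** The DWI signal follows the diffusion-kurtosis representation

$$S(b) = S_0\,\exp\!\big(-b D + \tfrac{1}{6} b^2 D^2 K\big),$$

with diffusion coefficient $D$ (mm²/s) and dimensionless kurtosis $K$
measuring the departure from Gaussian diffusion. `fit_dki()` minimizes the
squared error on the signal scale under box constraints
$D \in [0, 4\times10^{-3}]$, $K \in [0, 3]$ (the plausible tissue range;
estimates on the boundary are flagged `clamped`). The optimizer starts from
the log-quadratic solution — $\log S$ is exactly quadratic in $b$ under the
model — so noiseless data converge immediately and to machine precision.
`fit_adc()` is deliberately simpler: the log-linear slope restricted to
$b \le 1500$ s/mm², matching how scanner in-line software computes clinical
ADC maps. Fitting ignores the Rician likelihood (as virtually all clinical
DKI tools do); at the simulated SNR this contributes a small, documented
bias that the recovery tests bound below 5% at baseline SNR 50.

**Perfusion.** Tissue contrast kinetics follow the standard Tofts model,
driven by a bi-exponential population arterial input function (AIF) with the
classic Weinmann constants ($a_1 = 3.99$, $a_2 = 4.78$ kg/L, $m_1 = 0.144$,
$m_2 = 0.0111$ min⁻¹), scaled by dose and shifted by a bolus-arrival time
(default 0.15 min, the end of the first dynamic phase). The commercial
population AIF used in the original clinical workflow is proprietary, so a
documented, parameterized AIF replaces it — users can substitute their own
`aif_params`. The convolution integral is evaluated exactly for a
piecewise-linear AIF (closed-form per-interval integrals), which keeps the
generator and the fitter consistent and is verified against the
constant-input closed form $C_t = c\,(K^{trans}/k_{ep})(1 - e^{-k_{ep}t})$
to within 0.1%. In `fit_tofts()`, $K^{trans}$ enters linearly and is
profiled out, leaving a 1-D search over $k_{ep}$ (coarse log-grid, then
`optimize()`); the voxel-wise map variant shares the grid across voxels and
refines by parabolic interpolation in $\log k_{ep}$, which keeps whole-cohort
map fitting to seconds while preserving ~0.1% accuracy. $v_e$ is always the
derived ratio $K^{trans}/k_{ep}$. The iAUC integrates the observed curve by
trapezoid over 60 s from enhancement onset, where onset is the first sample
exceeding the baseline mean plus three baseline standard deviations
(baseline = first 3 phases); a flat curve has no onset and scores 0.

**Grids.** All maps live on `mprad_volume` grids (array + spacing + origin)
and are resampled to the T2W reference by trilinear interpolation in
physical coordinates, with nearest-edge extrapolation. No non-rigid
registration is implemented: the phantom generates all series pre-aligned,
so only grid resampling is needed.

## 2. Segmentations, normalization, features

Each segmentation is a binary mask (3D VOI). The 2D ROI of a VOI is the
axial slice whose in-plane mask has the longest major axis, defined as the
maximum pairwise distance between pixel centres in physical units (the Feret
diameter — more robust on small, irregular masks than an ellipse fit); ties
go to the smallest slice index so the rule is deterministic.

Within a segmentation, intensities are normalized by clamping to
$\mu \pm 3\sigma$ ($\sigma$ = population SD over the in-mask voxels,
recomputed on the 2D region for 2D ROIs). Thirteen first-order features are
computed from the clamped values and their 256-bin equal-width histogram
over $[\mu - 3\sigma, \mu + 3\sigma]$: energy, entropy, kurtosis, max, mean,
mean absolute deviation, median, min, RMS, skewness, SD, uniformity,
variance. Conventions worth stating explicitly:

* energy and RMS are computed on the raw clamped values, entropy and
  uniformity on histogram probabilities (the texture-toolbox lineage);
* kurtosis is **non-excess** (a normal distribution scores 3) — not to be
  confused with the diffusional kurtosis $K$;
* a constant region is degenerate: skewness/kurtosis/entropy 0,
  uniformity 1.

Second-order features (T2W and ADC only, `std3D` task) come from a single
merged gray-level co-occurrence matrix: the region is quantized to 32
equal-width levels over the clamped range, level pairs are accumulated over
the 13 unique displacement directions of the 3D 26-neighbourhood at distance
1 (both voxels in-mask), symmetrized and normalized to sum 1. Merging the
directions into one matrix — rather than averaging per-direction features —
reflects reading texture "simultaneously in all 3D directions". Regions
confined to one slice use the 4 unique in-plane directions of
8-connectivity. Nine Haralick statistics follow; GLCM "variance" uses
deviations from the marginal mean and "sum average" is the classic
$\sum_k k\,p_{x+y}(k)$, since the names alone underdetermine the formulas.

Shape and size features are deliberately excluded: healthy-tissue
segmentations do not follow anatomical boundaries, so shape would encode the
delineation protocol rather than biology.

The three feature catalogs are `std3D` (T2W + ADC, first + second order,
$2 \times (13 + 9) = 44$ columns) and `adv3D`/`adv2D` (first-order on all 8
maps, $8 \times 13 = 104$ columns). The source analysis reports 120
features for its advanced sets, a count not reconstructible from its own
catalog description (8 × 13 = 104; adding T2W/ADC texture gives 122); this
package implements the literal catalog and flags the discrepancy here.

## 3. Feature reduction: Spearman relevance, MIC redundancy

The reduction selects $k = 25$ features stepwise. Rank 1 maximizes
$|\rho(f, y)|$ (mid-rank Spearman against the binary outcome); each later
rank maximizes

$$\mathrm{gain}(f) = \delta\,|\rho(f, y)| - (1-\delta)\,
  \frac{1}{|S|}\sum_{s \in S} \mathrm{MIC}(f, s),$$

with $S$ the already-selected set and $\delta = 0.5$ by default (the
published description says "a linear combination" without coefficients; equal
weighting is the neutral choice and $\delta$ is exposed). The redundancy
penalty is computed against the *already-selected* features: penalizing
similarity to not-yet-selected features would be incoherent, and the cited
methodology uses the selected set. Ties break on lexicographic feature name;
constant features are admitted only when nothing else remains.

MIC is estimated in-package (no R implementation of the reference estimator
is available): for every grid shape $(n_x, n_y)$ with
$n_x n_y \le n^{0.6}$, the y-axis is an equal-frequency partition and the
x-axis starts from equal-frequency cuts refined by hill climbing on mutual
information; the score is $\max I/\log_2 \min(n_x, n_y)$ over shapes and
both axis orderings, giving a symmetric value in $[0, 1]$ that reaches 1 for
noiseless functional dependence and stays below ~0.35 for independent
vectors at $n = 200$. The search is exact enough at cohort sizes of order
10² and is implemented in C++ because the reduction evaluates thousands of
pairs.

## 4. Model building under imbalance-adjusted bootstrap

`iabr_samples()` concretizes imbalance-adjusted bootstrap resampling (IABR),
which the source describes only by name: each of $B$ samples draws a
training multiset of size $n$ with replacement, *class-balanced*
($\lceil n/2 \rceil$ positives, $\lfloor n/2 \rfloor$ negatives, each from
its own class), and tests on the out-of-bag instances; samples with an empty
or single-class test set are redrawn. A plain stratified bootstrap is
available behind a flag.

Logistic fits use IRLS with a mild ridge ($\lambda = 10^{-6}$ on
standardized slopes) so that separable bootstrap samples stay finite;
coefficients are returned on the raw scale. Performance per feature
combination is the 0.632+ blend of apparent and mean out-of-bag values,

$$R = \frac{\mathrm{app} - \mathrm{oob}}{\mathrm{app} - 0.5}
  \in [0,1], \qquad w = \frac{0.632}{1 - 0.368R}, \qquad
  \widehat{\theta} = (1-w)\,\mathrm{app} + w\,\max(\mathrm{oob}, 0.5),$$

applied identically to AUC (rank-based, mid-rank ties) and to
sensitivity/specificity at a 0.5 probability cutoff (the thresholding used
for the published curves is undocumented; 0.5 is the neutral choice and is
configurable). Forward building adds, at each order $1..10$, the candidate
maximizing the 0.632+ AUC; every order draws its bootstrap substream from
`seed + order`, so results are independent of evaluation order, and all
candidates within an order share the same samples. The best order is the
smallest within `tol = 0.005` of the maximum AUC (a parsimony plateau rule;
`tol = 0` recovers the literal argmax — the published chosen orders are not
strict argmaxes of their curves, which motivates exposing the tolerance).
Final coefficients average the per-bootstrap training fits ("using IABR");
a full-data refit is available via `method = "refit"`.

## 5. The phantom's stated world

`cohort_spec()` defaults encode the cohort structure the analysis was
designed around: 65 subjects carrying 69 lesion and 49 healthy-tissue VOIs
(round-robin assignment, so subjects can carry both classes); b-values
0, 250, 500, 1000, 1500, 2000, 2500 s/mm² with grouped signal averages
4/4/4/6/6/8/8 (averaging is emulated by dividing the Rician noise SD by
$\sqrt{\text{averages}}$ — the distribution of the mean is identical); 60
DCE phases at 9 s. The grid (32 × 32 × 16 voxels at 2 × 2 × 3 mm) is a
desk-scale stand-in for a prostate field of view.

Class parameter means are not published for this cohort, so they were chosen
once from the prostate DKI/DCE literature and exposed as configuration,
never hard-coded downstream: lesions have restricted, more non-Gaussian
diffusion ($D = 0.90$ vs $1.55\times10^{-3}$ mm²/s, $K = 1.05$ vs $0.60$),
faster transfer ($K^{trans} = 0.35$ vs $0.12$ min⁻¹, $k_{ep} = 1.0$ vs
$0.55$) and darker T2W signal (90 vs 130 a.u.). Per-VOI parameters are
lognormal draws around the class means (CV 8%), with an additional 5%
within-VOI voxel jitter; VOIs are random axis-aligned ellipsoids (semi-axes
2.2–4.5 voxels) placed without overlap, failing loudly when they cannot fit.
DWI noise is Rician (magnitude MRI), DCE noise Gaussian on the concentration
scale (the simulator emits concentration directly; signal-to-concentration
conversion via T1 mapping is out of scope). Everything is reproducible from
the spec seed.

What the phantom does **not** emulate: k-space artifacts, coil profiles,
motion, susceptibility distortion (the things non-rigid registration
corrects in clinical pipelines), partial-volume mixtures at lesion borders,
spatially correlated texture beyond the class mean/SD contrast, and
inter-scanner variability. A green test therefore establishes that the
*computational pipeline* is correct and that the stated class separations
are recoverable — not that the features or models transfer to clinical data.

## 6. Null behaviour and selection optimism

Two properties frame what the bootstrap machinery can and cannot guarantee,
and both are exercised by the test suite:

* For a **fixed** feature combination, the 0.632+ estimate of a permuted-
  label cohort stays near chance (the suite asserts [0.4, 0.6] across 20
  permutation seeds for an order-1 model): the estimator itself is
  calibrated.
* For the **full pipeline** — reduction plus forward selection re-run on
  permuted labels — per-order 0.632+ AUCs drift well above chance (the
  acceptance suite measures this at $n = 118$ and currently fails its
  [0.4, 0.6] band by design: the observed per-seed maxima reach ~0.6–0.7).
  The mechanism: with 104 features and 118 samples the best spurious
  Spearman correlation is sizeable, and since features are selected on the
  same data the bootstrap resamples, out-of-bag testing honestly reproduces
  that spurious signal. The 0.632+ weight corrects refit optimism, not
  selection bias. This is the familiar radiomics pitfall: honest validation
  of a selected model requires the selection to live inside the resampling
  loop (or an external cohort), which the replicated design does not do.
  The package keeps the test red rather than widening the band, because the
  gap is the scientifically interesting finding.

With the default planted signal, by contrast, the best-order 0.632+ AUC
saturates near 1 — the synthetic analogue of the near-perfect discrimination
reported clinically — so the pipeline has power where signal exists.

## 7. Numerical conventions and edge cases

* Quantization maps $[\mu-3\sigma, \mu+3\sigma]$ to equal-width levels; the
  top bound maps to the top level, a zero-width range to level 1.
* Degenerate inputs are flagged, never silent: constant DWI signal gives
  $D = K = 0$ (`degenerate`), a flat DCE curve gives $K^{trans} = 0$ and
  iAUC 0, single-voxel masks give a pair-free GLCM whose features default to
  0 (energy/homogeneity 1), zero-variance vectors correlate 0.
* All stochastic entry points (`simulate_*`, `generate_cohort`,
  `iabr_samples`) take explicit seeds and restore the caller's RNG state.
* The DKI fitter uses all seven b-values by default (the published analysis
  does not state a subset); the ADC cutoff and AIF are configurable.
* Scale: tests and examples run the bootstrap at $B = 15..200$ rather than
  the production default of 1000; the 0.632+ means are already stable at
  $B = 200$, and `iabr_control(n_samples = 1000)` restores the full-scale
  setting.
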