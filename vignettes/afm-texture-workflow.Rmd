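---
title: "Surface-texture classification of AFM cell images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-texture classification of AFM cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(afmtexture)
```

## The problem and the model

Atomic-force microscopy can map the surface of a living cell at ~20 nm
pixel pitch, and modern sub-resonance modes record several physical
channels at once: topography (height, nm), adhesion-type maps (nN) and
Ringing-mode channels (RM adhesion, RM restored adhesion, RM viscoelastic
adhesion). Cell lines of different cancer aggressiveness differ in the
*texture* of these maps, and a classifier trained on whole-image texture
descriptors can separate them. The question this package addresses is
*where on the cell surface* that signal lives.

The workflow has three steps:

1. **Step 1 — whole-cell classifier.** Every channel image is reduced to a
   fixed registry of ~30 areal surface-texture parameters (the SPIP /
   ISO-25178 families). Parameters are ranked by Gini importance from a
   bagged decision-tree ensemble, the top-ranked subset (10 for a single
   channel, 20 for a channel combination) feeds a binary Gaussian-process
   classifier with an RBF kernel, and each cell receives a probability of
   belonging to the high-aggressiveness class; a 50% threshold makes the
   call.
2. **Step 2 — informative scale.** The images are degraded with moving
   averages of growing kernel size and Step 1 is re-run at each kernel.
   The kernel size at which accuracy collapses identifies the spatial
   scale carrying the class signal; the sliding-window ("zoom") size is
   the largest kernel retaining at least X = 80% of the baseline accuracy,
   floored at 32 px because the surface parameters themselves need a
   minimum number of pixels.
3. **Step 3 — heatmaps.** The Step-1 classifier is applied to every
   overlapping 32 × 32 window of a cell image (stride 1). The probability
   of each window is stored at its center pixel, giving a per-pixel map of
   P(high aggressiveness) whose thresholded regions localize the surface
   areas driving the classification.

A deliberate property of the original procedure, reproduced faithfully
here, is a *scale mismatch*: the classifier is trained on whole-image
parameters and applied to 32-px windows. Window-level parameter
distributions are broader and slightly biased relative to whole-image
ones, so heatmap probabilities are compressed toward 0.5; the heatmap's
information is in its spatial contrasts, not its absolute calibration.
`build_window_table()` provides the documented alternative (train on
windows sampled from labeled cells at the same scale), off by default.

## The surface-parameter registry

The source procedure used "~40" commercial SPIP parameters without
enumerating them; this package fixes a canonical, documented set of 30
(`parameter_registry()`), which covers every family that software reports,
and the pipeline is agnostic to the exact list (the registry can be
subset). All parameters are computed about the mean-leveled surface; no
plane fit is applied inside the computation so that windowed and
whole-image evaluation treat tilt identically. Definitions (z = leveled
values, N = pixels, pitch in nm):

| family | parameters | notes / units |
|---|---|---|
| amplitude (min window 4 px) | Sa, Sq, Ssk, Sku, Sp, Sv, Sz, S5p, S5v, S10z | mean |z|, RMS, skewness, kurtosis, peak/valley extremes; S5p/S5v average the 5 highest strict 8-neighborhood peaks / deepest valleys (interior pixels); value units |
| hybrid (4 px) | Sdq, Sdr, Ssc, Sds | RMS gradient (central differences, one-sided at edges, per nm); developed-area excess in % via bilinear facet triangulation; mean summit curvature −(z_xx+z_yy)/2; summit density per µm² |
| spatial (8 px) | Sal, Str, Std | FFT circular autocorrelation; Sal = shortest radial 0.2-decay length (72 directions, 0.5-px radial steps, periodic bilinear interpolation, linear crossing), nm; Str = shortest/longest (∈ (0,1]); Std = angle of the dominant Fourier component, degrees in [0, 180), tie broken by column-major scan order |
| functional (8 px) | Sk, Spk, Svk, Smr1, Smr2, Sbi, Sci, Svi, Sxp | Abbott–Firestone curve from descending-sorted heights at material ratios (i−0.5)/N·100; Sk from the flattest 40%-width secant extended to 0% and 100%; Spk/Svk as 2·area/width of the peak/valley zones; Sbi = Sq/h(5%); Sci, Svi from void volumes at 5%/80%; Sxp = h(2.5%) − h(50%) |
| volume (8 px) | Vmp, Vmc, Vvc, Vvv | material/void volumes of the bearing curve at the standard 10%/80% thresholds, in height units (volume per unit area) |

Degenerate inputs: a zero-variance surface leaves Ssk, Sku and the
Sq-normalized indices undefined and raises an undefined-moment error; a
window smaller than a parameter's minimum raises a scale error. When no
strict local extrema exist, the summit-based parameters return 0. Every
parameter is checked against an independently written naive (loop-based)
implementation on random grids to a relative 1e-9 in the test suite.

## Feature ranking and the GP classifier

*Gini ranking.* Importances are mean decreases in Gini impurity from a
bagged tree ensemble (bootstrap rows, random feature subsets of size
floor(sqrt(p)), 500 trees by default — enough for two-figure stability),
normalized to sum to 1. Columns are put in a canonical sorted order before
fitting so the ranking is exactly invariant to the caller's column
permutation; ties are broken by table column order. The *ranking order* is
invariant under strictly monotone transforms of a feature; the importance
estimates themselves carry small Monte Carlo noise because the ensemble's
internal split bookkeeping is value-sensitive, which is why the tests
assert order, not bit-equality, for that property.

*Ranking precedes the split.* As in the original workflow, features are
ranked on the full labeled table and the train/test split happens
afterwards. This leaks a small amount of selection information into the
test accuracy; the label-permutation control in the tests sits slightly
above 50% for exactly this reason, and is judged against binomial noise at
the dataset size.

*GP classifier.* Binary Gaussian-process classification with an isotropic
RBF kernel, fitted by the Laplace approximation with a logistic link
(Newton mode search capped at `max_iter = 1000`). Features are z-scored
with training statistics — the feature space mixes nm, nN, percent and
degrees, and an unstandardized RBF distance would be dominated by a single
unit. The length-scale and signal variance maximize the approximate log
marginal likelihood (L-BFGS-B over log parameters; length-scale
initialized at the median pairwise distance and searched within e^±4 of
it; signal sd constrained to [e^−2, e^2] because the Laplace evidence
degrades for very large signal variance — on separable data the likelihood
saturates, the Hessian term vanishes and the evidence would otherwise push
the amplitude, and with it the predictive variance, to arbitrarily large
values). Predictions integrate the logistic likelihood over the latent
Gaussian with the standard logistic–probit approximation
p = sigmoid(μ/√(1 + πs²/8)). P(low) is exactly 1 − P(high); ties at the
threshold go to "high". The split is stratified with a default 0.7 train
fraction (the source procedure states no fraction).

## Blur scan and zoom selection

`blur_average()` replaces each pixel by the mean of the k × k window
anchored at the pixel's top-left corner, truncated at the image edges —
shape-preserving, parameter-free, and the identity at k = 1.
`accuracy_vs_blur()` re-runs the full Step-1 pipeline per kernel (the
blurred feature table is computed once per kernel; ranking, split and
training are re-seeded per replicate and accuracies averaged over the
configured seeds). Whether the published 80% is absolute accuracy or
relative to baseline is ambiguous; both modes are implemented and
*relative* is the default. The default kernel ladder is 1, 2, 4, 8, 16,
32, 64.

## Heatmap conventions

Window centers: for even windows the center is the top-left pixel of the
central 2 × 2 block (offset (w−1) %/% 2 for any parity). Borders whose
window would leave the image are masked, never padded — padding would
fabricate texture. With stride 1 the valid region of an n-px image is
(n − w + 1)²; larger strides fill intermediate valid pixels with the
nearest computed value (ties toward the smaller index). Heatmaps always
store P(high); rendering for a low-class cell may invert the colormap but
the data do not change. Region extraction thresholds the valid region at
0.5, labels 8-connected components, drops those below a minimum area and
traces boundaries with contour lines at physical coordinates (pixel center
of 1-based index i at (i − 0.5)·pitch).

## The synthetic generator

Real AFM images of the cell lines behind this method are not publicly
deposited, so the package ships a generator that emulates the statistical
structure the method assumes; every stage is testable without a download.
Each channel of a synthetic cell is composed of:

* a large-scale Gaussian random field (spectral synthesis, Gaussian
  autocorrelation with 1/e length 0.5 µm; amplitude e.g. 40 nm for
  height) — identical between classes in the default configuration;
* Gaussian-profile bumps (FWHM 400 nm, Poisson centers snapped to pixel
  centers) emulating microvilli/microridges, density 2.0 /µm² (low class)
  vs 0.8 /µm² (high class);
* fine-scale granularity (a second random field, 30 nm correlation
  length) with amplitude doubled in the high class — the 20–40 nm scale;
* instrument noise: per-pixel sensor noise plus per-scan-line offsets
  (the standard AFM streak artifact, pronounced on soft living samples);
* per-cell biological heterogeneity: one log-normal multiplier (CV 0.15)
  per texture component, drawn once per cell and shared across its
  channels, as the surface state of one cell is common to its
  simultaneously recorded maps.

Channels share latent white noise mixed at `cross_channel_corr = 0.5` — a
placeholder, since the real cross-channel correlation structure of cells
is unknown. Adhesion-type channels are offset to non-negative values
(cosmetic; all parameters level internally). Default geometry is 512 × 512
px over 10 × 10 µm (pitch 10000/512 = 19.53 nm).

Two design points deserve emphasis because they determine what the blur
scan can show. First, a moving average is linear: it *attenuates* but
never erases a fine-scale component, and an amplitude-ratio class signal
keeps a constant signal-to-noise ratio in scale-clean statistics such as
summit density. A noiseless population of statistically identical cells
would therefore remain classifiable at any kernel size. The accuracy
collapse observed in practice requires (a) a noise floor whose residual
decays more slowly than the signal's under averaging — the scan-line
artifact attenuates ~k^−1 against the fine signal's ~k^−3/2 — and (b)
irreducible inter-cell variability that bounds accuracy once the
fine-scale signal is attenuated into it. The generator includes both, and
their levels are fixed by the two operating points the workflow is
specified to exhibit: near-ceiling accuracy at full resolution and
collapse toward chance past the class-distinguishing scale. Second, class
contrast lives in exactly two scales (20–40 nm granularity and ~0.5 µm
bump density) so the blur curve has an interpretable shoulder.

What the generator does *not* emulate: Ringing-mode signal formation and
instrument physics, membrane biophysics (bumps are geometric stand-ins,
not modeled microvilli), broadband/fractal spectra of real membranes,
scanner drift and feedback artifacts beyond line offsets, and real
cross-channel physics. Passing tests therefore demonstrate that the
pipeline recovers planted class structure with the assumed statistics —
not that real cells of different aggressiveness are separable, which is an
empirical claim about data this package cannot ship.

`generate_composite()` plants a known class map (blend width ≤ 4 px) and
stores it as ground truth, giving the heatmap stage an objective
localization target, with the guarantee that a uniform mask reproduces
`generate_cell()` bit-for-bit.

## Numerical choices and problem sizes

* Text rasters serialize at full double precision (`%.17g`); TIFF samples
  are stored 32-bit normalized to [0, 1] with the range in the JSON
  sidecar (~2^−32 relative representation precision), because the R TIFF
  writer exposes no float sample format.
* The spectral synthesis is periodic (wrap-around); tests use interior
  windows.
* Derived child seeds use a small LCG-style map kept below 2^31.
* Heatmap batch prediction uses dense matrix algebra; identical inputs in
  identical batches are bit-reproducible, while the same window evaluated
  in a different batch can differ at the last-bit level (BLAS blocking),
  which is why translation consistency is asserted at 1e−12.
* Test problem sizes are chosen to exercise the method at desk scale: the
  class-recovery check uses 40 cells per class at 256 × 256 px with all
  four channels over 5 pipeline seeds; the blur scan uses 20 cells per
  class at 128 × 128 px with two channels and the kernel ladder 1, 4, 16,
  32; heatmaps are validated on 128 × 128 composites (97 × 97 valid
  positions at window 32). The generator's 512-px default is unchanged.

## Known limitations

* The exact parameter set of the commercial software is unknown; rankings
  on real data will differ with the registry, though the method is
  designed to be robust to that choice.
* Laplace-approximate GP probabilities are conservative (shrunk toward
  0.5), more so at window scale; heatmap contrasts, not absolute values,
  carry the information.
* Gini importances from small cell counts are noisy at the third figure;
  seeds are exposed everywhere and the tie-break is documented.
* A single train/test split mirrors the original procedure; it reports a
  noisier accuracy than cross-validation would.
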