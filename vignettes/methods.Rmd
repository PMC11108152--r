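---
title: "Resting-state activity maps, 3D CNN classification, and Grad-CAM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state activity maps, 3D CNN classification, and Grad-CAM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`fmrixcam` implements a three-stage analysis of resting-state fMRI for
Alzheimer's disease (AD) versus normal control (NC) classification:

1. **Voxel-wise functional activity maps** that compress a 4D scan into 3D
   volumes: ALFF, fALFF, ReHo and VMHC.
2. **3D VGG-style convolutional classifiers** on single maps or on the
   4-channel "combined" stack (channels assembled like RGB channels of a
   natural image), trained under a subject-level repeated 80/20 split
   protocol.
3. **Class activation mapping** (CAM and Grad-CAM) of the trained models,
   with trilinear upsampling to input resolution and per-class averaging,
   quantified as ROI concentration scores.

Because clinical imaging archives are access-restricted, the package ships a
**synthetic cohort generator** that injects known, ROI-localized class
effects into BOLD-like 4D volumes. Every downstream claim — the map
formulas, the leak-free training protocol, and heatmap localization — is
then testable against constructions whose ground truth is known.

# The activity maps

For a voxel time series $x(t)$ of length $n$ sampled every `tr` seconds, the
de-meaned series is decomposed into one-sided DFT terms
$x(t) = \sum_k a_k \cos(2\pi f_k t) + b_k \sin(2\pi f_k t)$ with
$f_k = k/(n \cdot tr)$. The amplitudes are *per sinusoid* ($2/n$ scaling at
interior bins, $1/n$ at the Nyquist bin), so a pure cosine of amplitude $A$
yields $a_k = A$ exactly; Parseval's identity
$\sum_k (a_k^2 + b_k^2)/2 = \mathrm{Var}(x)$ is a test invariant.

- **ALFF** is the mean spectral amplitude
  $\sum_{k \in B} \sqrt{a_k^2 + b_k^2} / N$ over the low-frequency band
  $B = \{k : 0.01 < f_k < 0.1\ \mathrm{Hz}\}$ (open interval, matching the
  strict inequalities of the defining band). The divisor $N$ is ambiguous in
  the literature formula; we take the number of in-band bins (mean in-band
  amplitude), consistent with the original ALFF literature, and expose
  `norm = "series_length"` as the alternative reading. fALFF is a pure ratio,
  so the choice cancels there.
- **fALFF** is $\sum_B \sqrt{a_k^2+b_k^2} / \sum_{\text{all } k}
  \sqrt{a_k^2+b_k^2} \in [0,1]$. Zero-power voxels are set to 0 and flagged
  in the companion missing mask rather than NaN, so map volumes stay finite
  for the CNN.
- **ReHo** is Kendall's coefficient of concordance $W$ over a voxel's
  cluster (the voxel plus its 26 neighbors, $K = 27$; 7 and 19 also
  supported) applied to band-pass-filtered series:
  $W = (\sum_i R_i^2 - n\bar R^2) / (K^2(n^3-n)/12)$ with rank sums $R_i$
  across the cluster and $\bar R = (n+1)K/2$. Ties get average ranks with no
  tie-correction term, matching the printed formula. Under independent
  columns $E[W] = 1/K$ regardless of within-series autocorrelation, which
  the tests check against a Monte-Carlo oracle. Boundary voxels use their
  available in-mask cluster; clusters smaller than 2 are flagged missing.
- **VMHC** is the Fisher z-transform $z = \mathrm{atanh}(r)$ of the Pearson
  correlation between a voxel's band-filtered series and that of its mirror
  voxel. The mirror is the reflection of the first spatial axis about its
  midline; on an odd-sized axis the midplane voxel maps to itself and is
  flagged (its $r$ would be trivially 1). $r$ is clipped to
  $\pm(1 - 10^{-7})$ before `atanh`. Symmetric-template registration of real
  brains is out of scope; the synthetic brain mask is mirror-symmetric by
  construction.

The band filter is applied uniformly (ideal band-pass: zeroing out-of-band
DFT bins) before ReHo and VMHC; ALFF/fALFF select bins directly, which is
equivalent for ALFF and checked as a test invariant. Whether input maps
should be standardized before training is not standardized in the source
protocol; the default is no normalization, with
`normalize_map(mode = "zscore_within_mask")` available. Note that z-scoring
redistributes a localized intensity effect over the whole mask (the out-ROI
mean shifts), which can smear explanation heatmaps.

# The synthetic cohort

Each in-mask voxel's series is

$$x_v(t) = \text{baseline} + s_v(t) + \varepsilon_v(t),$$

where $s_v(t)$ is a sum of `n_sinusoids` (default 6) unit-amplitude
sinusoids placed on exact DFT bins strictly inside 0.01–0.1 Hz with uniform
random phases, and $\varepsilon$ is white noise with `noise_sd` (default 1).
Placing carriers on exact bins makes ALFF closed-form checkable: an
amplitude scale $s$ inside an ROI changes the in-ROI/out-ROI ALFF ratio to
exactly $s$ at zero noise. TR is not fixed by the emulated protocol; the
default is 3.0 s (typical resting fMRI), and the configuration refuses any
TR/length combination with fewer than two in-band DFT bins. The brain mask
is the ellipsoid inscribed in the grid — cheap, mirror-symmetric, and it
exercises mask-boundary handling in ReHo/VMHC.

Class effects are applied to the band-limited component of scans whose
label matches, in list order:

- `amplitude_scale` multiplies $s_v$ inside the ROI (ALFF/fALFF contrast);
- `coherence_boost` mixes one shared ROI-wide latent band-limited series
  with weight $m$: $\sqrt{1-m^2}\, s_v + m\, s_{\text{shared}}$. The
  variance-preserving mixture leaves band power unchanged, so it moves ReHo
  without moving ALFF; $m = 1$ makes all ROI voxels identical (ReHo exactly
  1 at zero noise);
- `homotopy_shift` rebuilds mirrored pairs as
  $s_R = \rho\, s_L + \sqrt{1-\rho^2}\, s_R'$, setting their band-component
  correlation to $\rho$ (VMHC contrast; the baseline pairing is
  independent).

Optional separable Gaussian smoothing (sigma = FWHM/2.3548) is applied
last and is off by default in tests because it changes the closed-form ALFF
values. The generator does **not** model hemodynamic response shape, head
motion, scanner drift, or cardiac/respiratory confounds; passing tests
demonstrate correctness of the formulas and protocol on band-limited
signals, not performance on real ADNI data, whose effect sizes the source
protocol does not quantify.

Default desk-scale study conditions (`desk_cohort_config()`): 24x28x24
grid, 120 time points at TR 3 s, 20 subjects per class, one scan per
subject, noise sd 1, and one spherical ROI (center (8, 14, 12), radius 4
voxels, off-midline) carrying `amplitude_scale = 1.5` and
`coherence_boost = 0.6` for the AD class. The full-scale conditions
(61x73x61x140) are available but are not the test default.

# Networks and training

The classic trunk is five VGG blocks of (2, 2, 3, 3, 3) 3x3x3 convolutions
(stride 1, padding 1), each followed by batch normalization and ReLU, with
2x2x2 stride-2 max-pooling between blocks — 13 convolutional layers. Two
heads are provided:

- **FC head**: flatten, then fully connected layers of 2048 and 1024 units
  (ReLU + dropout 0.5 each) and a 2-unit softmax;
- **GAP head**: global average pooling of the final feature maps followed by
  a single linear layer to the 2 class scores. In this variant the final
  max-pool is omitted so that the linear layer acts directly on the
  capture-layer feature maps; that is exactly the structure under which
  classic CAM is defined, it makes the CAM/Grad-CAM equivalence exact, and
  it preserves heatmap resolution.

`network_spec(preset = "paper_faithful")` pins the full-scale architecture
(61x73x61 input, full-width trunk, FC 2048/1024, dropout 0.5). Training
defaults follow the reference protocol: Adam, learning rate 5e-5, weight
decay 5e-4, batch size 4, cross-entropy, 10 repeated subject-level 80/20
splits. The epoch budget and stopping rule are not part of the stated
protocol; training runs a fixed budget and keeps the weights of the epoch
with the lowest training loss (no test-set peeking).

The **desk preset** used in tests is two narrow blocks, (1 conv, 8 ch) and
(2 convs, 16 ch), GAP head, capture layer at 12x14x12. Two design
observations drove this, both verified during development:

- *Receptive-field locality.* With three blocks (two poolings before the
  capture layer) the capture-layer receptive field (~23 voxels) covers
  nearly the whole 24-voxel synthetic brain: the optimizer is then free to
  make every capture location class-discriminative and Grad-CAM is diffuse
  even at perfect accuracy. With one pooling the receptive field (~11
  voxels) is local relative to the brain, so class evidence can only appear
  at capture voxels that actually see the 9-voxel-wide lesion — the regime
  in which CAM localization is meaningful. The full-scale trunk has the
  same property relative to a real brain's much larger grid.
- *Precise BN recalibration.* Batch-norm running statistics are an
  exponential moving average collected while the weights move, so at the
  end of training they describe a mixture of past models. With a GAP head
  the class margin lives in small shifts of channel means, and the stale
  statistics can bias every evaluation-mode prediction to one class. After
  restoring the best weights, `train_model()` therefore freezes the weights
  and recomputes each BN layer's statistics over the training inputs
  ("precise BN"). Inference always uses these per-run statistics.

Desk-scale training uses learning rate 1e-3 (`desk_train_config()`): the
protocol's 5e-5 is matched to a 42M-parameter network and is far too slow
for an 83k-parameter one. A 30-epoch budget was chosen by observing that
training loss plateaus well before it on separable cohorts; the null-control
experiments use 15 epochs for the same reason.

# Grad-CAM and its quantification

For class score $y^c$ (pre-softmax, the standard Grad-CAM target) and
capture-layer feature maps $A^k$:

$$\alpha_k^c = \frac{1}{Z}\sum_{ijl} \frac{\partial y^c}{\partial A^k_{ijl}},
\qquad L^c = \mathrm{ReLU}\Big(\sum_k \alpha_k^c A^k\Big).$$

On a GAP-head model $\partial y^c / \partial A^k_{ijl} = w^c_k / Z$
identically, so $\alpha^c_k = w^c_k / Z$ and Grad-CAM equals classic CAM up
to the positive factor $1/Z$ — the package asserts this identity after
unit-max normalization. Gradients are checked against central finite
differences of $y^c$ with respect to the capture activations.

Coarse heatmaps are upsampled by align-corners trilinear interpolation (the
3D analogue of bilinear upsampling; corner voxels of the output equal
corner voxels of the input). Heatmaps are computed for the predicted class
by default (true-class mode available), unit-max normalized per sample
before class-averaging so no single high-magnitude sample dominates
(raw-mean averaging also available), and class averages may include all
test samples or only correctly classified ones.

Localization is quantified by `roi_concentration()`:
`mass_fraction / volume_fraction`, i.e. the ROI's share of heatmap mass
relative to its share of brain volume — 1 for a uniform heatmap, >1 when
the ROI is highlighted — plus whether the heatmap argmax lies in the ROI.
This turns "the heatmaps highlight specific ROIs for AD while covering the
whole brain for NC" into a number.

# Numerical conventions and degenerate inputs

- Band membership is the open interval; an empty band raises an error
  suggesting a longer series or smaller TR.
- fALFF of a zero-power series is 0 (flagged), not NaN.
- VMHC clips $r$ to $\pm(1-10^{-7})$; zero-variance pairs, unpaired voxels
  and midplane self-pairs are flagged missing and set to 0.
- KCC uses average ranks on ties, no tie correction.
- Max pooling uses floor semantics on odd axes; axes of size 1 pass
  through.
- BN eps 1e-5, momentum 0.1 during training, replaced by precise
  recalibration afterwards; Adam beta (0.9, 0.999), eps 1e-8; weight decay
  applies to conv/dense weights only (not biases or BN parameters).
- All randomness (simulation, splits, initialization, shuffling, dropout)
  is seeded; cohort scans draw from per-subject streams derived from the
  master seed, and generators save/restore the caller's RNG state.

# Known limitations

- The synthetic generator's realism limits (no hemodynamics/motion/drift)
  mean accuracy numbers here say nothing about accuracy on clinical data.
- The full-width 13-conv network is provided and construction-tested, but
  training it requires GPU-scale resources; desk-scale results use the
  narrow preset.
- Grad-CAM resolution is capped by the capture layer (12x14x12 at desk
  scale); upsampling cannot recover sub-capture-voxel structure.
- Anatomical atlas labeling of highlighted regions is out of scope; ROIs
  are known by construction in the synthetic setting.
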