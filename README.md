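# fmrixcam

Explainable 3D convolutional classification of resting-state fMRI activity
maps, with a synthetic-cohort harness that makes every stage verifiable.

## The problem

Deep networks can separate Alzheimer's disease (AD) patients from normal
controls (NC) using resting-state fMRI, but clinicians need to know *where*
a model looks when it decides. A practical pipeline for this is:

1. compress each preprocessed 4D scan into voxel-wise **functional activity
   maps** —
   - **ALFF**: mean spectral amplitude of each voxel's series in the
     0.01–0.1 Hz band, `sum_{k in band} sqrt(a_k^2 + b_k^2) / N_band`;
   - **fALFF**: the in-band amplitude as a fraction of total amplitude;
   - **ReHo**: Kendall's coefficient of concordance
     `W = (sum R_i^2 - n*Rbar^2) / (K^2 (n^3 - n)/12)` over each voxel's
     27-voxel neighborhood;
   - **VMHC**: Fisher z-transformed Pearson correlation between each voxel
     and its left–right mirror;
2. classify the maps (single kind, or all four stacked like RGB channels)
   with a **3D VGG16-style CNN** — 13 conv layers in 5 blocks, batch norm +
   ReLU, 2×2×2 max-pools — with either the fully connected head
   (2048/1024 units, dropout 0.5) or a **global-average-pooling (GAP)**
   head, trained with Adam (lr 5e-5, weight decay 5e-4, batch 4) over 10
   repeated subject-level 80/20 splits;
3. explain predictions with **3D Grad-CAM**:
   `alpha_k = (1/Z) sum dY_c/dA_k`, `L_c = ReLU(sum_k alpha_k A_k)`,
   upsampled trilinearly to input resolution (on GAP models this equals
   classic CAM exactly).

Real cohorts of this kind are access-restricted, so `fmrixcam` also ships a
synthetic BOLD generator that injects known class effects into a named
spherical ROI (band-limited amplitude scaling, neighborhood coherence,
homotopic-correlation shifts). The whole chain — map formulas, leak-free
protocol, heatmap localization — is then testable against ground truth:
the package reports whether the CNN recovers the lesion and whether
Grad-CAM concentrates on it (`roi_concentration` = ROI's share of heatmap
mass ÷ its share of brain volume; 1 = uniform, >1 = highlighted).

## Worked example

```r
library(fmrixcam)

# cohort with an injected AD lesion: 20 subjects/class, 24x28x24x120, TR 3 s,
# spherical ROI with amplitude x1.5 and coherence boost 0.6
cfg    <- desk_cohort_config(seed = 11)
cohort <- generate_cohort(cfg)
stacks <- cohort_map_stacks(cohort)          # ALFF/fALFF/ReHo/VMHC stacks

spec <- network_spec(preset = "desk", head = "gap")
res  <- run_experiment(stacks, cohort$manifest, spec,
                       desk_train_config(seed = 11),
                       n_repeats = 3, base_seed = 11)
res$accuracy$per_run
#> [1] 100 100 100

roi <- attr(cfg, "roi"); brain <- cohort$scans[[1]]$brain_mask
for (run in res$runs) {
  ch <- class_average_heatmaps(run, stacks)  # per-class average Grad-CAM
  ca <- roi_concentration(ch$AD, roi, brain)
  cn <- roi_concentration(ch$NC, roi, brain)
  cat("acc:", run$accuracy, " AD conc:", round(ca$concentration, 2),
      " argmax in ROI:", ca$argmax_in_roi,
      " NC conc:", round(cn$concentration, 2), "\n")
}
#> acc: 100  AD conc: 5.31  argmax in ROI: TRUE  NC conc: 2.05
#> acc: 100  AD conc: 5.34  argmax in ROI: TRUE  NC conc: 2.52
#> acc: 100  AD conc: 3.42  argmax in ROI: FALSE  NC conc: 3.38
```

Held-out accuracy is 100% on all three repeats, and the AD-class average
Grad-CAM concentrates 3–5× more mass in the injected ROI than a uniform
heatmap would, with the heatmap maximum inside the ROI in 2 of 3 repeats —
the quantitative form of "the model highlights the lesioned region for AD".
NC-class averages stay closer to uniform. `run_all(seed = 11)` wraps the
same sequence (simulate → maps → train → explain) and writes accuracy
tables, confusion matrices, PR curves and a JSON summary.

A thin CLI wrapper is installed at `inst/cli/fmrixcam`
(`simulate`, `maps`, `run` subcommands) for shell use.

## Vignette

`vignettes/methods.Rmd` documents the map formulas and their numerical
conventions, what the synthetic generator does and does not emulate, the
network presets (including why the desk-scale GAP network keeps its
capture-layer receptive field local, and why batch-norm statistics are
recalibrated after training), and the Grad-CAM identities the tests assert.
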