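# pbsr — histology-guided patch-based super-resolution for mass spectrometry imaging

MALDI-ToF mass spectrometry imaging (MSI) maps molecular ion intensities
across a tissue section, but at 10–80 µm per pixel it blurs exactly the
anatomical boundaries that the H&E-stained microscopy of the same section
resolves at sub-micron scale. `pbsr` reconstructs a high-resolution ion
image from a low-resolution MSI acquisition by using the co-registered
histology image — and, when available, a tissue segmentation — as the
structural guide. It is aimed at MSI practitioners and computational
pathology researchers who want molecularly specific images on a
histology-resolution grid.

## The method

Given a measured low-resolution image `y`, a histology guide `G`, and
class labels `ℓ` on the target grid, the estimate `x` alternates two steps
until the relative change is negligible:

* **Reconstruction** — every high-resolution pixel becomes the weighted
  mean of its neighbours in an 11×11 search window,

  `x_i ← Σ_j w_ij x_j / Σ_j w_ij`,  `w_ij = exp(−‖P_i(G) − P_j(G)‖² / h²) · [ℓ_i = ℓ_j]`,

  where `P_i(G)` is the 3×3 histology patch around `i` and the bracket is
  a hard segmentation constraint (a soft `exp(−β)` variant is available).
* **Mean correction** — each low-resolution pixel's residual
  `y_k − mean(x over block k)` is added back to its block, so the estimate
  always reproduces the measurement exactly under block averaging.

Factors 4 and 8 are reached by repeated doublings; every level's
correction is anchored to the measured image. Initialisation (and the
comparison baseline) is bilinear interpolation (LI). The package also
provides imzML reading with TIC normalization and ion-image extraction,
mutual-information similarity registration, an evaluation suite (SSIM,
Welch's t, Cohen's d on ROI-vs-ring areas, intensity profiles,
checkerboards, boxplot summaries), a seeded synthetic phantom generator,
and a CLI. See `vignettes/pbsr-methods.Rmd` for the full model, parameter
and design discussion.

## Worked example

```r
library(pbsr)

# a seeded phantom: glyph bars 1.5 LR-pixels thick cut from a tissue field,
# observed at 40 um with Gaussian noise, with a 10 um histology guide
bundle <- generate_phantom(phantom_config("glyph", noise_sd = 0.05, seed = 42))
bundle
#> phantom_bundle (glyph): HR 64 x 64 at 10 um, LR 16 x 16 at 40 um, seed 42

hr <- run_pipeline(bundle$lr_observed, bundle$histology, bundle$mask,
                   target_factor = 4)
hr
#> ion_image: 64 x 64 px at 10 um/px
#>   intensity range [0, 1.167]

li <- linear_upsample(bundle$lr_observed, 4)
evaluate_pair(hr, bundle$truth_hr, bundle$mask$labels == 2,
              ring_width = 2, clip = bundle$mask$labels > 0)
#> eval_report
#>   SSIM       0.8306
#>   Welch t    -224.478 (df 1204.8, p 0)
#>   Cohen's d  -12.710 (area1 - area2)
#>   area1 (ring, n=538)  0.353 (0.320, 0.382)
#>   area2 (ROI,  n=696)  1.005 (0.968, 1.051)
evaluate_pair(li, bundle$truth_hr, bundle$mask$labels == 2,
              ring_width = 2, clip = bundle$mask$labels > 0)
#> eval_report
#>   SSIM       0.6244
#>   Welch t    -51.880 (df 1230.9, p 4.6e-312)
#>   Cohen's d  -2.873 (area1 - area2)
#>   ...
```

Read the two reports together: against the same ground truth, PBSR scores
SSIM 0.83 versus 0.62 for plain interpolation, and retains the glyph/ring
contrast at effect size |d| = 12.7 versus 2.9 — the glyph's median
intensity under PBSR (1.005, area 2) sits at the true class mean of 1.0,
while interpolation smears it to 0.82. The negative d follows the
documented area1 − area2 sign convention: the ROI is enriched. The
convergence trace is attached to the result
(`attr(hr, "convergence")`); this run met the 1e-4 tolerance after 8 and
9 iterations on the two levels.

The same pipeline is scriptable from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "pbsr.R", package = "pbsr"))') \
    simulate --scenario glyph --seed 42 --out demo/
# ... upsample --lr demo/lr.tif --hist demo/histology.tif --mask demo/mask.png \
#              --factor 4 --out demo/hr.tif
# ... evaluate --test demo/hr.tif --ref demo/truth.tif --roi demo/mask.png \
#              --roi-label 2 --out demo/report.json
```

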