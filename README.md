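# mpsuture

Quantitative analysis of the midpalatal suture in cone-beam CT (CBCT).

The midpalatal suture — the fibrous joint along the midline of the hard
palate — matures and ossifies through childhood and adolescence, and its
status decides the timing of rapid maxillary expansion treatment. On axial
CBCT slices the suture is a narrow, meandering radiolucent band that fades
as ossification proceeds. Single-slice reading wastes most of the volume;
`mpsuture` instead:

1. extracts a normalized 50×200 suture region of interest (ROI) from every
   expert-labeled axial slice,
2. fuses the ROI stack into one composite image by **pairwise merging**:
   with `A` the pixelwise mean of two images, `e = mean(A)` and `d` a
   damping factor (default: the maximum gray difference of the pair),

   `P = A · (1 + (A − e) / (255 + d))`

   applied tournament-style (exactly `n − 1` pair fusions in `⌈log₂ n⌉`
   rounds), followed by unsharp-Laplacian sharpening,
3. computes the six GLCM texture features (contrast, dissimilarity,
   homogeneity, ASM, energy = √ASM, correlation) of the fused image and
   their Pearson/Spearman relationship with chronological age per sex,
4. trains a residual CNN (canonical 3-4-6-3 bottleneck layout, or a small
   basic-block variant for CPU-scale runs) to classify five age ranges
   (4–10, 11–12, 13–14, 15–16, 17–23 years), with the convolution,
   batch-norm, pooling and residual backward passes implemented in R and
   verified by finite differences,
5. explains predictions with Grad-CAM
   (`α_k = mean_ij ∂y_c/∂A^k_ij`, `L = ReLU(Σ_k α_k A^k)`), and
6. evaluates with a confusion matrix, per-class precision/recall/F1,
   one-vs-rest midrank AUC and their average.

Clinical CBCT databases are private, so the package ships a seeded phantom
generator: 512×512 axial stacks whose sinuous suture band is driven by a
latent ossification parameter `ω ∈ [0, 1]`, constructed so that fused-image
homogeneity and GLCM correlation rise monotonically with `ω`. Every stage
of the pipeline is testable end to end without any downloads.

## Worked example

```r
library(mpsuture)

## a small phantom cohort -> fused images -> texture features
cohort <- generate_cohort(5, seed = 1)
ph     <- generate_volume(phantom_from_cohort(cohort, 1))
stack  <- extract_roi(ph$volume, ph$bounds)
fused  <- fuse_stack(stack)
fused
#> <fused_image> S0001: 50x200 from 8 slices, sharpened

texture_features(fused$pixels)[, c("homogeneity", "correlation", "contrast")]
#>   homogeneity correlation contrast
#> 1   0.0760467   0.7208556 532.3979
```

The subject behind this scan has ω = 0.74 (a largely ossified suture), so
the fused image is relatively uniform: homogeneity 0.076 and GLCM
correlation 0.72 sit at the upper end of what young-suture phantoms
produce (ω ≈ 0 phantoms come out near 0.045 and 0.3), and both climb
further as ω → 1.

The texture-trend and classifier experiments are one call each:

```r
tr <- phantom_trend_experiment(n = 200, seed = 1)
round(tr$spearman[c("homogeneity", "correlation")], 3)
#> homogeneity correlation
#>       0.984       0.985

ex <- phantom_classifier_experiment(n = 300, steps = 300, seed = 1)
ex$accuracy              # held-out accuracy on 3 ossification classes
ex$mean_heat_fraction    # Grad-CAM heat inside the true suture band
```

A command-line front end covering the same pipeline
(`simulate | fuse | features | train | evaluate | explain | report`) is in
`inst/cli/mpsuture.R`:

```sh
Rscript inst/cli/mpsuture.R simulate --n 5 --seed 1 --out phantoms
Rscript inst/cli/mpsuture.R fuse --labels phantoms/labels.csv --volumes phantoms --out fused
Rscript inst/cli/mpsuture.R features --fused fused
```

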