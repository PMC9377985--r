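# pdeac

Adaptive level-set segmentation of intravascular OCT (optical coherence
tomography) cross-sections, for image-analysis work on coronary vessel
wall and plaque structure. The package provides the segmentation model,
its evaluation metrics (correct classification ratio and Dice
coefficient), a geodesic active-contour baseline, a seeded synthetic OCT
phantom generator with exact ground-truth masks, image/config IO, and a
command-line interface — so the full pipeline runs and validates without
clinical data.

## The model

A contour is the zero level set of a function φ (φ > 0 inside). The
region energies act not on the grayscale image *h* but on its
**edge-guided image**

    EG = sqrt(Ex² + Ey²),   Ex = h ∗ px,  Ey = h ∗ py,

the gradient magnitude under 3×3 directional kernels, rescaled to [0, 1].
On speckled OCT imagery this turns texture contrast into region contrast:
the speckle-rich vessel wall is high-EG, lumen and background are near
zero. φ evolves to minimize the four-term functional

    F = α·Fᵏ + (1−α)·Fʰ + β·Fⁱ + λ·Fʲ

where Fᵏ is a Chan–Vese-style global fit of EG by constants k₁, k₂ inside
and outside the contour, Fʰ a Gaussian-window local fit by smooth fields
l₁, l₂ (robust to radial attenuation), Fⁱ = Σ ½(|∇φ|−1)² the distance
regularization that makes reinitialization unnecessary, and Fʲ the
contour-length penalty. Constants and fields have closed-form updates
(weighted means); φ follows the explicit gradient flow of F. The methods
vignette (`vignettes/pdeac-methods.Rmd`) derives the flow term by term
and records every numerical choice and default.

## Worked example

```r
library(pdeac)

# a seeded synthetic OCT phantom: speckled 3-layer wall + plaque sector
b <- fixture_suite(1, base_seed = 7)[[1]]

# segment with default parameters from a centered circle
init <- init_spec("circle", center = c(64.5, 64.5), radius = 57.6)
res  <- pdeac_segment(b$image, model_params(), init)
res
#> <pdeac_result method=pdeac> 128x128 mask, 4569 px inside, 511 iterations (converged)
#>   final energy 9139.2

disc(res$mask, b$gt_vessel_mask)  # Dice vs exact ground truth: 0.9488
ccr(res$mask, b$gt_vessel_mask)   # correct classification ratio: 0.9026
```

The result holds the binary mask (`phi_final > 0`), the final level-set
field, and the per-iteration energy trace (monotone decreasing here —
the convergence diagnostics every run carries). A Dice of 0.95 against
an exact ground truth at this 128-pixel scale is the expected operating
point: the 3×3 gradient kernels widen the edge-guided support by about
half a pixel per boundary, a resolution-dependent bias quantified in the
vignette.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/pdeac phantom --seed 7 --out img.png --gt-vessel gt.png
Rscript inst/cli/pdeac segment img.png --out mask.png --trace energies.csv
Rscript inst/cli/pdeac evaluate mask.png gt.png
Rscript inst/cli/pdeac benchmark --n 20 --base-seed 1 --out bench.csv
```

Every command writes a run manifest (resolved parameters, digest, seeds,
paths) next to its outputs.

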