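---
title: "Ear digital imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear digital imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earpheno)
```

## The measurement problem

Maize grain yield decomposes into the number of harvestable kernels and
their individual weight, and both components are more heritable than yield
itself — which makes them attractive selection targets — but expensive to
measure: threshing, counting and weighing thousands of plot samples per
season. earpheno implements an image-based alternative: plots of de-husked
ears are photographed once, from above, on a dark cloth, and every
downstream trait (ear count and dimensions, visible kernel count and size,
total kernel number and weight) is computed from that single photograph
plus a user-supplied pixel-to-centimetre scale read off a ruler shot.

Two segmentation branches share one photograph:

* **Kernel branch** — subtract a constant from the color image (flattens
  the dark background and its illumination gradient), convert to 8-bit
  grayscale, CLAHE (local contrast, so kernel--groove edges survive uneven
  lighting), unsharp mask (sharpens those edges), Phansalkar local
  threshold (binarizes bright low-contrast objects), fill holes, watershed
  split at a tight tolerance, then particle analysis with a size/shape
  filter tuned to single kernel faces.
* **Ear branch** — subtract and convert as above, then a strong Gaussian
  blur erases the kernel texture entirely, a global Otsu threshold
  recovers the merged ear blobs, holes are filled, and a loose watershed
  tolerance separates ears that touch. Large particles are the ears.

The split into two branches exists because the two object classes live at
incompatible spatial scales: a threshold sharp enough to separate kernels
shreds ears, and a blur strong enough to merge an ear erases kernels.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `subtract_value` | 100 | intensity | drives background (cloth, shadows, gradient) to 0 while kernels survive |
| `clahe_block` | 29 | px | side of the local equalization region; about one kernel face plus its grooves |
| `clahe_max_slope` | 5 | — | contrast limit; 1 is the identity, larger amplifies local contrast (and noise) |
| `unsharp_radius` / `unsharp_weight` | 5 / 0.70 | px / — | edge sharpening: `(img − w·blur)/(1 − w)` |
| Phansalkar `radius` | 15 | px | local statistics window; must cover a kernel plus groove context |
| Phansalkar `k`, `r`, `p`, `q` | 0.25, 0.5, 2, 10 | — | threshold `T = m(1 + p e^{−qm} + k(s/r − 1))` on normalized intensities |
| kernel watershed tolerance | 3 | px (EDM radius) | split touching kernels; merges only necks within 3 px of the inscribed radius |
| ear `sigma` | 10 | px | Gaussian blur that removes kernel texture |
| ear watershed tolerance | 40 | px | ears are ~45 px in inscribed radius at 20 px/cm; 40 prevents internal splits |
| kernel filter | 0.03–1.0 cm², circ 0.15–1.0 | | a kernel face is ~0.3–0.8 cm² and fairly round |
| ear filter | > 10 cm² | | an ear silhouette is far larger than any debris |

The size bounds are expressed in cm² after scale conversion (at a
16-megapixel nadir shot a kernel face is tens of thousands of pixels, so
pixel-area bounds of order 1 would be meaningless); the scale itself
(`pixels_per_cm`) is always user input.

The tolerance value of the watershed is the difference of inscribed-circle
radii between an internal distance-transform maximum and the neck
connecting it to a larger maximum: two overlapping discs of radius 20 px
with a neck half-width of 10 px split at tolerance 3 (difference 10 > 3)
and merge at tolerance 15. One deliberate difference from the classical
plugin behavior: the returned labels partition the entire foreground —
touching labels are adjacent rather than separated by a one-pixel
background divide — which keeps per-particle areas exact.

## Calibration models

Only part of an intact ear faces the camera, so the visible kernel count
`kn` under-counts systematically; and a kernel's weight is tightly related
to its length. The package ships two linear calibrations derived from
sub-tropical dent hybrids:

* total kernel number `= 2.4051·kn − 6.7334` (340 ears, r = 0.98),
* average kernel weight (g) `= 0.7435·kl − 0.155` for mean visible kernel
  length `kl` in cm (200 ears),

and their product estimates total kernel weight per plot. Negative
predictions are floored at zero (counts and weights are physical
non-negatives; the count line crosses zero near `kn = 3`). The weight
model was built at 11–13% kernel moisture and is documented as valid
there; no moisture correction is applied. `fit_linear_calibration()`
re-derives either model from user data by ordinary least squares, and
both modes of application (plot-total by default, per-ear if the caller
assigns kernels to ears) are possible because the models are linear.

## Reliability and genetics statistics

Agreement between measured and estimated traits is summarized by Lin's
concordance correlation coefficient

$$\rho_c = \frac{2\sigma_{12}}{\sigma_1^2 + \sigma_2^2 + (\mu_1-\mu_2)^2}
         = \rho \, C_b,$$

computed with population (1/n) moments per the original definition (a
sample-moment variant is available by flag). The factorization into
precision (Pearson ρ) and accuracy (bias correction \(C_b \le 1\)) only
holds with the squared *difference* of means in the denominator; the
degenerate same-mean form occasionally seen in print would make
\(C_b > 1\) possible and is not implemented. Confidence intervals use
Fisher's z-transform of \(\rho_c\) with Lin's asymptotic variance —
chosen over the raw asymptotic variance of \(\rho_c\) because the z scale
keeps the interval inside \([-1, 1]\).

Broad-sense heritability is computed from variance components of a
genotype + replicate model,
\(H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / n_{reps})\).
Field trials of this kind are typically laid out as alpha-lattice
incomplete-block designs; the incomplete-block effect is deliberately
omitted here (the heritability formula itself is design-agnostic, and the
simplification costs a conservative bias when block effects are real).
Components come either from the balanced ANOVA method of moments
(`(MS_gen − MS_err)/n_{reps}`, truncated at zero) or from REML via lme4;
on balanced data the two agree to numerical precision whenever the REML
solution is interior. Genetic correlation between traits uses the
method-of-moments cross-trait analogue (bivariate REML is out of scope).

## The synthetic-image generator

Because the original photograph archives cannot be bundled, the generator
renders the imaging conditions the pipeline is designed for: a dark noisy
background (level 30, Gaussian sd 4) with a left-to-right illumination
ramp (amplitude 25); ellipse-shaped ears (12–18 cm × 3.8–5.2 cm) laid out
side by side without contact; on each ear a lattice of 6–8 visible kernel
rows of bright convex kernels (flat face at intensity 230 rolling off to
75% over the outer quarter of the radius — the flat-faced dent-kernel
case) separated by grooves at intensity 70, i.e. below the subtraction
offset; tip kernels shrink toward the ear axis as rows converge, so the
kernel-covered body spans the nominal ear length; and optionally
saturated specular patches over kernels. Everything stochastic is fixed
by a seed, and the ground truth (per-ear axes, visible kernel count,
per-kernel lengths) is exact by construction.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate: multi-colored flint kernels with concave faces
and hazy boundaries (known to cause under-segmentation in the field),
husk fragments and silk debris, perspective and lens distortion, and
photographic color variation beyond a fixed warm tint. Results on clean
synthetic plots are an upper bound on field behavior, not an estimate of
it.

Default problem sizes: rendered plots are 3–6 ears at 20 px/cm (roughly
400 × 700 px), and the end-to-end accuracy suite uses 20 such noise-free
renders; at those sizes the full pipeline takes a few seconds per image.

## Numerical choices

* Grayscale conversion uses ITU-R BT.601 weights (0.299, 0.587, 0.114),
  fixed and documented; images are 8-bit matrices in `[0, 255]`.
* All convolution borders are edge-replicated; Gaussian kernels are
  normalized and truncated at `ceiling(3.5σ)` taps, and the blur is an
  exact separable convolution (no FFT), so results are bit-reproducible.
* CLAHE tiles the image into ~`block`-sized cells, clips each histogram
  at `max_slope · n/bins` with iterative uniform redistribution of the
  excess, and remaps pixels by bilinear interpolation between the four
  nearest tile mappings. At slope 1 the clipped histogram is uniform and
  the mapping is the identity. The redistribution floor can lift a
  uniformly dark region by 1–2% of the dynamic range — an inherent
  property of clip-and-redistribute CLAHE, reflected in the tests as a
  2% allowance on inter-class contrast.
* The Phansalkar window is circular; statistics at the borders use
  in-bounds pixels only, with the population standard deviation. The
  printed-bracket variant `m(p e^{−qm} + k s/r)` is available via
  `bracket = "printed"` for comparison; the standard form is the default.
* Particle perimeter uses the corner-corrected boundary chain
  (straight steps 0.980, diagonal 1.406, −0.091 per direction change).
  The naive √2-weighted chain overestimates smooth perimeters by ~5%,
  which would push a perfect disc's circularity down to ~0.90; with the
  correction a radius-200 disc measures 1.00 within 0.01. Circularity is
  capped at 1, and sub-resolution particles (too small to carry a
  boundary chain) are assigned circularity 1 by policy.
* Particle length is the maximum Feret diameter and width the minimum
  caliper width, both over the convex hull of boundary-pixel corners
  (so a 10 × 100 px rectangle measures exactly √10100 × 10). The
  caliper-perpendicular-to-major-axis convention was rejected: for
  elongated rectangles it returns nearly twice the intuitive width.
  Moment-based ellipse axes are also reported for comparison.
* Watershed splitting runs h-maxima suppression (h = tolerance) on the
  exact Euclidean distance transform followed by marker-based flooding,
  delegated to EBImage; labels are relabeled to a gap-free `1..n`.

## Known limitations

* Kernel counts are of *visible* kernels; everything total is model-based
  and inherits the calibration's population (dent, sub-tropical, 11–13%
  moisture). Re-calibrate with `fit_linear_calibration()` for other
  germplasm.
* Kernel depth is not observed, so kernel weight can be slightly
  underestimated for deep-kerneled genotypes.
* The heritability module assumes one value per genotype × replicate
  (balanced or near-balanced); incomplete-block recovery and
  multi-environment decomposition are out of scope.
* No automatic ruler detection: the pixel scale is always explicit user
  input.
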