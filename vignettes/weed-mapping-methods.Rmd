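---
title: "Methods: weed mapping in rice paddies from five-band UAV imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weed mapping in rice paddies from five-band UAV imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddyweed)
```

## The problem

At tillering stage, paddy weeds (typically barnyard grass and monochoria)
share the colour, texture and shape of young rice in RGB imagery, but their
spectra differ. A five-band multispectral UAV survey (blue 450 nm, green
560 nm, red 650 nm, red edge 730 nm, near-infrared 840 nm) can therefore
locate weed patches, and a plant-protection UAV can spray only the cells of a
coarse grid that contain them. This package implements that pipeline:
radiometric calibration, a weed-sensitive spectral index, gray-level density
slicing, morphological clean-up, accuracy assessment, and prescription-map
generation.

## Radiometric calibration

Surface reflectance is recovered from raw digital numbers (DN) by
single-point linear scaling through the origin against a reference panel of
known reflectance $\rho_p$ (0.60 by default, matching the gray panels used in
paddy surveys):

$$\rho_b(x,y) = \mathrm{DN}_b(x,y)\cdot\frac{\rho_p}{\mathrm{DN}_b^{panel}}$$

One panel means one point: an empirical line with offset would need at least
two panels, which the field protocol does not provide. Calibrated values may
exceed 1 over specular water; they are counted and reported, never clipped,
because clipping would silently distort the index distribution that the
thresholds operate on.

## The weed discrimination index

The index family is built by expressing two bands as ratios to a common
*transfer band* $x_t$ and taking the base-10 logarithm of their quotient:

$$\mathrm{WDVI} = \log_{10}\!\frac{x_b/x_t}{\,x_a/x_t\,}$$

Algebraically $x_t$ cancels and the index reduces to $\log_{10}(x_b/x_a)$;
the implementation follows the two-ratio construction literally and a
property test asserts the cancellation to $10^{-12}$. The flagship variant,
`WDVI_NIR`, uses green over red edge through NIR:
$\log_{10}\big((G/NIR)\,/\,(RE/NIR)\big) = \log_{10}(G/RE)$. Young weeds
carry more green reflectance relative to their red edge than rice does, so
this ratio separates the two; crucially it also separates weeds from
floating algae mats ("water cotton"), which are green vegetation with high
NIR and therefore confound NDVI-style indices.

Choices fixed here for reproducibility:

* **Logarithm base 10.** The construction is stated with an unspecified
  "log"; base only rescales the index and every downstream threshold is
  configurable, but the value of a recorded threshold depends on the base,
  so it must be pinned.
* **Non-positive bands invalidate a pixel** rather than being
  epsilon-clamped. An epsilon fabricates extreme log values that survive
  thresholding; an invalid pixel is visible and counted.
* The five named variants `WDVI1`…`WDVI5` (G/RE, R/RE, RE/R, R/G, G/R, all
  through NIR) are enumerable as a family; comparison indices NDVI, GNDVI,
  NDRE, LCI and OSAVI use their standard literature formulas (OSAVI soil
  term 0.16), since the survey protocol names them without printing
  formulas.

## Density slicing and post-processing

The real-valued index is quantized to $L$ gray levels (default $L = 256$) by
min–max scaling with round-half-up; the scaling `(min, max)` is recorded on
the raster so a slice threshold is transferable between images. The
classical single-threshold gray partition is generalized to an interval
$[low, high]$ because field practice reports two values (a slice of 0–5 on
the stretched index, chosen manually to "cover all weeds"); whether the
slice or its complement is the weed class is an explicit flag.

`select_slice_threshold()` automates the manual covering rule given a
reference labelling: the interval is the central `coverage` quantile range
(default 0.99) of gray levels on labelled weed pixels. The 1% tail exclusion
keeps single noisy pixels from dragging the interval across a neighbouring
class; `coverage = 1` reproduces the literal min–max covering rule.

Two clean-up stages follow:

* **Majority filter** (small-patch removal): each pixel takes the majority
  class of its $k\times k$ window. Windows are cropped at borders and nodata
  pixels never vote; a tie — possible only where cropping leaves an even
  voter count — keeps the input value, which is conservative and
  deterministic. Field experience puts the useful kernel range at 3–33.
* **Clump** (dilate–erode): dilation then erosion by solid squares of ones
  (a morphological closing when equal, default 3/3), merging fragmented
  patches into sprayable clumps. Morphology uses the set definition on the
  padded plane, so structure created just outside the frame participates in
  the erosion; closing is then exactly idempotent, which the tests assert.
  Even kernel sizes anchor at the top-left-of-center pixel.

Both stages are swept against a reference (`sweep_majority_kernel()`,
`sweep_clump_kernel()`), maximizing overall accuracy with ties broken toward
the smaller kernel (least intervention). On clean synthetic scenes the best
majority kernel is small — there is little salt noise to remove; on real
imagery with per-pixel misclassification speckle, larger kernels (around 27)
win, which is why the sweep, not a constant, is the interface.

## Accuracy assessment

Weed is the positive class. From the 2×2 confusion matrix,
$p_o = (TP+TN)/n$ and Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with
$p_e = \big[(TP\!+\!FP)(TP\!+\!FN) + (FN\!+\!TN)(FP\!+\!TN)\big]/n^2$.
Only pixels valid in both masks enter $n$, and $n$ is always reported so any
published comparison is explicit about its support. The degenerate case
$p_e = 1$ (both maps single-class) returns $\kappa = 1$ for perfect
agreement and 0 otherwise. `optimal_slice()` finds the accuracy-maximal
gray interval by maximum-subarray search over per-level class counts
($O(L)$), which is how competing indices are compared on equal footing.

## Prescription grid

The final mask is vectorized (one polygon per 4-connected component, holes
preserved, area = pixel count × pixel area) and aggregated onto a metric
grid of 1 m × 1 m cells by default — the working resolution of
plant-protection UAV sprayers. Cells align to the mask's top-left corner:
deterministic without external survey input, and documented so operators can
re-grid. Each cell's weed fraction is weed / valid pixels within it. The
spray rule is `fraction > 0` at `theta = 0` (any weed triggers spraying, the
default field behaviour) and `fraction >= theta` for `theta > 0`, so
`theta = 1` sprays only fully covered cells and lowering `theta` never
un-sprays a cell. Conservation (cell fractions × cell valid counts summing
to the mask's weed pixels, exactly) is a tested invariant. A geographic
(degree-unit) CRS is refused with instructions to reproject.

## On-disk formats

No GDAL binding is available to this package, so rasters are written as
multi-page TIFF (one 32-bit float or 8/16-bit integer page per band plus a
0/1 validity-mask page) with an ESRI world file and a JSON sidecar carrying
CRS, type and value scaling. Real values are affine-scaled into [0, 1] for
float storage with the scaling recorded, making round trips exact to float32
precision; integer and boolean grids round-trip bit-exactly. Vectors are
GeoJSON. Foreign multi-band TIFFs are readable when a world file
georeferences them; a per-band file stack (as multispectral cameras write)
is supported with shape/geotransform consistency checks.

## The synthetic scene generator

`generate_scene()` emulates the survey scene: transplanted rice rows
(default spacing 6 px = 0.30 m at the default 0.05 m ground sampling
distance) over dark flooded background, elliptical weed patches (default 10
patches of mean radius 8 px, mimicking the group aggregation of paddy
weeds), and larger algae mats confined to the inter-row water. Pixel
reflectance is the class signature plus independent per-band Gaussian noise
(default SD 0.005), truncated at zero. The same spec and seed reproduce a
scene bit-exactly, and generation restores the session RNG state.

The class signatures are **invented working values, not field
measurements** — no reflectance spectra are published for the survey this
package follows. They are constrained by the qualitative claims the method
rests on: weed vs rice/algae/water separation of several noise SDs in
$\log_{10}(G/RE)$, and weed–algae overlap (< 3 SD) in NDVI. Passing tests
therefore demonstrate that the *machinery* behaves as specified and that the
index comparison has the claimed structure; they do not certify accuracy on
real paddies, where mixed pixels, BRDF effects, spatially correlated noise
and mis-registered bands — all absent from the generator — erode accuracy.
Spatial noise correlation is a noted extension point.

With the default conditions the end-to-end chain (reference-guided slice,
swept majority kernel, 3/3 clump) reaches overall accuracy above 0.99 and
kappa above 0.99 on a 512×512 scene — the synthetic analogue, under idealized
noise, of the ~93% / 0.86 reported from field imagery.

## Problem sizes used by the checks

The test-suite and acceptance computations run at sizes chosen to exercise
every code path while keeping a full run in well under half an hour on one
core: algebraic properties on 100 random 64×64 five-band images; morphology
oracle equivalence on 200 random 48×48 masks; kappa oracle on 1,000 random
contingency tables; the end-to-end study on one 512×512 scene with a
16-kernel majority sweep; the index comparison on twenty 256×256 scenes;
prescription conservation on 50 random masks.

## Known limitations

* Single-point calibration cannot remove additive offsets (path radiance,
  dark current); the field protocol provides no second panel.
* The slice thresholds reported from field work (0–5 on a 0–255 stretch)
  refer to an unspecified viewer stretch; they are shipped as defaults but
  real use should re-derive them via `select_slice_threshold()` on a
  labelled subset.
* Supervised and deep-learning classifiers are out of scope by design; the
  pipeline is a transparent, low-compute alternative.
* Shapefile output and raster reprojection require a GDAL stack and are not
  provided; GeoJSON and pre-projected inputs are the supported path.
```{r example, eval = FALSE}
sc <- generate_scene(scene_spec(seed = 42))
idx <- compute_index(sc$image, "WDVI_NIR")
gray <- quantize_to_gray(idx, 256)
th <- select_slice_threshold(gray, sc$truth)
sw <- sweep_majority_kernel(idx, sc$truth,
  detection_config(slice = c(th$low, th$high), majority = NULL,
                   clump_kernels = NULL),
  kernels = seq(3, 33, 2))
mask <- detect(idx, detection_config(slice = c(th$low, th$high),
                                     majority = sw$best,
                                     clump_kernels = c(3, 3)))
evaluate_mask(mask, sc$truth)
```
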