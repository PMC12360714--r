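---
title: "Methods: phantom-based uniformity, distortion and linearity analysis"
author: "phantomQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based uniformity, distortion and linearity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomQA)
```

# The measurement problem

Fluorescence-guided surgery systems report tissue contrast through the
detected intensity of a fluorophore such as indocyanine green. That
intensity is not a property of the tissue alone: it folds in the spatial
pattern of the excitation light and the collection efficiency of the optics
(together, the *fluorescence uniformity* of the instrument), and the
geometry of what is seen is warped by lens distortion. A structure at the
edge of the field of view can look dimmer, smaller, or displaced relative
to the same structure at the center.

phantomQA analyzes images of solid reference phantoms to characterize
both effects and to probe the consequences of "correcting" them:

* a **dot-grid target**: a square lattice of identical fluorescent wells
  (1 mm diameter, 2 mm center-to-center pitch over a 100 mm square area,
  2601 wells with the defaults), which samples the uniformity field and
  the distortion field simultaneously;
* a **nine-well dilution-series target**: a 3 x 3 arrangement of wells with
  known fluorophore concentrations including a 0 nM control, probing the
  concentration response;
* **fluorescent cylinders** (a signal/control pair), probing how
  flat-field correction treats signal versus background.

Because no public image sets exist for these phantoms, the package renders
its own: every analysis stage is validated against synthetic scenes whose
ground truth is known exactly.

# The synthetic scene model

`renderRUD()`, `renderRCS()` and `renderCylinders()` draw anti-aliased
disks at lattice positions, then pass the ideal image through an
instrument model:

1. **Illumination.** A strictly positive relative-efficiency field in the
   *camera* frame, normalized to a maximum of 1 (`IlluminationField`):
   uniform, an off-axis Gaussian, a separable polynomial, or an arbitrary
   tabulated map. Well *signal* is multiplied by the field value at the
   well center; wells are small relative to the field's length scale, so a
   single per-well factor is exact enough to serve as truth.
2. **Distortion.** Keystone first (the projective map of an object plane
   tilted by `tiltDeg` about a horizontal axis through the principal
   point, with focal length defaulting to the image diagonal), then the
   two-term Brown radial model
   $r' = r\,(1 + k_1 r_n^2 + k_2 r_n^4)$ with $r_n$ the radius normalized
   by half the image diagonal. $k_1 < 0$ is barrel, $k_1 > 0$ pincushion;
   all coefficients zero is the identity. The same map is implemented
   independently in the test suite and the two are required to agree to
   1e-6 px.
3. **PSF.** Gaussian blur of `psfSigma` pixels (default 1).
4. **Background.** An additive, spatially constant offset in counts. This
   is deliberately *not* scaled by the illumination field: detector offset
   and ambient background do not ride on the excitation path, and this
   asymmetry is exactly what makes flat-field correction misbehave (see
   below).
5. **Noise.** Either Gaussian with fixed sd, or "poisson_like": Gaussian
   with variance proportional to the signal, which gives shot-noise
   scaling without tying the simulation to an integer bit depth.

Anti-aliasing uses supersampling (default 4 x 4 subsamples) of the
one-pixel annulus straddling each disk edge; sub-pixel centroid accuracy
of the downstream detector depends on it. A fixed `SceneConfig` and seed
render bit-identically.

What the generator does **not** emulate: fixed-pattern sensor noise,
optical vignetting distinct from the illumination field, spectral effects,
depth/scattering in the phantom material, and photobleaching. Tests passing
on these scenes therefore demonstrate the correctness of the *analysis
chain*, not robustness to every artifact of real cameras.

# Well detection

`detectWells()` thresholds the image (Otsu by default, because it is
parameter-free and invariant to overall gain; fixed and quantile
thresholds are available), labels connected components, and filters by
area (default minimum: 25% of the nominal well footprint when the scene
scale is known, 5 px otherwise) and by a border margin (default 2 px;
components touching the border have biased centroids).

Two measurement choices matter:

* **Centroids** are weighted by intensity *above threshold*. For a smooth
  blurred spot this estimator is accurate to a few hundredths of a pixel;
  under an illumination gradient it is less biased than the geometric
  centroid of the binary component.
* **Mean intensity** is taken over a fixed disk of half the well diameter
  centered on the centroid (the half-diameter ROI rule) whenever the
  scene scale is known. The thresholded component itself is *not* a good
  photometric aperture: a global threshold cuts further into dim wells
  than bright ones, so the component mean is biased upward for dim wells
  by over 10% across a realistic illumination range. The fixed aperture
  keeps the reported mean proportional to true well brightness (the
  component mean is still reported as `mean_component`).

Detections are sorted by (y, x) with keys rounded to 0.01 px — wells in
one lattice row differ only by floating-point noise in y, and an exact
sort would order them arbitrarily.

# Uniformity surface

`poolSamples()` concatenates detections from any number of images taken
in the same camera frame. "Stitching" here means pooling only: the target
moves between acquisitions while the camera and its illumination stay
fixed, so samples from different images already share coordinates and no
registration is performed. Repeated observations of the same well (within
1 px) are averaged by a deterministic greedy clustering; simple
integer-pixel binning fails on even-sized frames, where lattice points
fall exactly on half-integer pixels.

`fitSurface()` offers the two fitters:

* **bspline** — a tensor-product cubic regression spline (`mgcv::gam`,
  basis dimension per axis defaulting to
  `max(4, min(12, floor(sqrt(n/2))))`), with smoothing selected by
  generalized cross-validation. Smooth, robust to noise, and the default.
* **rbf** — exact thin-plate-spline interpolation
  ($\phi(r) = r^2 \log r$ plus an affine term) with a small ridge
  (default 1e-6 on coordinates pre-scaled by the image diagonal; at most
  3000 interpolation centers). Slower and noise-sensitive, but it
  preserves sharp features — an annular dip at the edge of a structured
  illumination pattern survives the RBF fit and is smoothed away by the
  b-spline, and the test suite asserts exactly that contrast.

The fitted surface is normalized by its *fitted* maximum over the valid
region — the convex hull of the samples — so that the reported profile
peaks at exactly 1 and noise spikes in raw samples cannot set the scale.
Negative fitted values (possible at the hull edge) are clipped to 0 with a
warning. Evaluation outside the hull is refused unless explicitly
requested: both fitters extrapolate poorly.

`isoMap()` reports the fraction of the valid region at or above the
standard thresholds 60/80/90/95% of maximum (masks are nested by
construction), and `lineProfiles()` samples the normalized surface along
rows or columns at stated fractions of the frame, quarters by default.

# Local geometric distortion

Distortion is quantified against an ideal reference lattice built from the
wells nearest the image center (`buildReferenceGrid()`), on the standard
premise of dot-target methods that the central region is effectively
distortion-free. The central window (default: a disc spanning 20% of the
image diagonal) must contain at least 9 wells; the basis is estimated from
nearest-neighbour displacement vectors of the at most 25 center-most
wells, clustered into the two lattice directions, then refined by an
affine least-squares fit to those same wells. Restricting the estimate to
the innermost wells is deliberate: with 5% barrel distortion, a pitch
estimated across the full 20% window would be biased by about 0.1
percentage points — the same order as the agreement the tests demand from
the method.

Wells are matched to the nearest predicted lattice point within half a
pitch (`matchWells()`; when two wells claim one point the nearer wins and
the other is reported). For each matched well,
$$\mathrm{distortion}(\%) = 100 \cdot
  \frac{d_\mathrm{actual} - d_\mathrm{expected}}{d_\mathrm{expected}},$$
with both distances measured from the image center
$((W-1)/2,\,(H-1)/2)$ — to the well centroid and to its reference grid
point respectively. Central wells — expected distance under half a lattice
pitch, in practice at most the single centermost well — are excluded: the
ratio is undefined at the origin, and at radii comparable to the centroid
uncertainty it turns sub-pixel noise into arbitrarily large percentages.
The sign summary calls the pattern barrel or pincushion
from the mean distortion of the outermost quartile of wells, and
`keystoneAsymmetry()` reports left/right and top/bottom mean-distortion
differentials: near zero for radially symmetric distortion, split into a
positive and a negative half-plane under object-plane tilt, with signs
that flip when the tilt flips.

Because matching is nearest-lattice-point, displacements beyond half a
pitch cannot be attributed correctly; such wells are reported unmatched
rather than mismeasured. This bounds the measurable distortion at a given
radius, which is inherent to the method, not an implementation limit.

# Flat-field correction and its artifacts

`buildCorrection()` inverts the normalized profile into a per-pixel gain
map. Two guards:

* profile values below a **floor** (default 0.05) are clamped before
  inversion, bounding the gain at 1/floor; the number of clamped pixels is
  recorded so downstream analyses can see how much of the frame was
  rescued this way;
* the valid region is the hull of well *centroids*, but image content
  extends about a well radius beyond it, so the profile is extrapolated
  over a narrow band (default 5 px) around the hull. Without the band, a
  gain seam runs through the outermost wells and corrupts their corrected
  means. Beyond the band, pixels pass through unchanged and are counted.

`applyCorrection()` is a pixelwise product, kept in floating point;
quantization happens only on export. `evaluateFlatness()` re-detects and
refits corrected scenes with the b-spline method and reports the minimum
of the refit normalized surface — a perfectly corrected scene gives 1.

The package intentionally reproduces the failure mode of this simple
multiplicative correction. The scene model renders intensity
$s \cdot I + b$ (signal times illumination plus additive background); the
correction divides by (an estimate of) $I$, giving $s + b/I$. Where $I$ is
small, $b/I > b$: corrected background is *amplified* at the edge of the
field. On synthetic cylinder pairs the corrected 0 nM control measures
higher at the field edge than at the center even though the corrected
fluorescent cylinder is restored correctly — and in the dilution-series
experiment the post-correction linearity exponent moves away from its
uncorrected value at edge placements, in the direction predicted by exact
arithmetic on the scene truth, with the direction depending on the
orientation of the concentration layout relative to the illumination
gradient. Correction is only benign when the background is negligible
relative to the signal being corrected.

# Concentration linearity

`extractRCSWells()` measures each of the nine wells with a circular ROI of
half the well diameter (radius = diameter/4), subtracts the 0 nM control
mean (baselining), and normalizes to the maximum baselined value among
wells eligible for the fit. `fitLinearity()` fits
$$y = 10^{C} x^{m}$$
by unweighted ordinary least squares in log10–log10 space over wells with
positive concentration and positive baselined intensity; $m = 1$ is the
ideal linear response. A well whose baselined value is driven non-positive
(typically a low concentration overtaken by an amplified control after
correction) is excluded from the fit and reported with its reason;
fewer than three usable wells is an error. Baselining makes the fit exactly
invariant to shared additive offsets, and the normalization plus log-log
slope make it invariant to overall gain; both invariances are asserted
exactly in the tests.

The default synthetic dilution series is {0, 1, 3, 10, 30, 60, 100, 300,
1000} nM: a decade-spanning series with the named control, 60 and 100 nM
members; the exact series and the 3 x 3 layout geometry are configurable
because they are properties of a physical target, not of the method.

# Numerical and design choices

* Pixel coordinates are 0-based with pixel centers on integers, origin at
  the top-left, x rightward, y downward; the image center is
  $((W-1)/2, (H-1)/2)$.
* All CSV outputs carry 6 significant digits in fixed column orders;
  rendered figures are optional, flag-gated products — the CSV data behind
  them is the interface.
* Every stochastic step is seeded through `SceneConfig@seed`; pipelines
  are deterministic given config plus seed (asserted byte-for-byte on CSV
  artifacts).
* Degenerate inputs fail loudly and early: overlapping wells, sub-2-pixel
  footprints, frames too small to hold a well, missing control wells,
  clipped ROIs, collinear or insufficient samples, too few central wells.
  An image with no detectable wells is a warning with an empty result, so
  multi-image pipelines can skip it and continue.

# Problem sizes in the tests

The test-suite and acceptance scenes are chosen so that the full suite
runs in about two minutes: dot grids of 9 to 2601 wells at 0.1–0.25 mm/px
(frames of 80–540 px), the flat-field study at its full 16 images
(4 positions x 4 rotations, 169 wells each), and dilution-series frames
of 280–400 px. One deliberately full-scale case is kept — the default
2601-well target rendered and detected end to end — because the well count
of the default geometry is itself a claim worth pinning.

# Known limitations

* The distortion model in the renderer (Brown radial + single-axis
  keystone) spans the patterns the analysis is designed to detect, but the
  analysis itself is model-free; it reports whatever local deviation the
  matched lattice shows.
* Otsu's threshold assumes a roughly bimodal histogram. In scenes whose
  dimmest wells fall below roughly a third of the brightest (a much
  steeper falloff than the instruments this method targets), Otsu can drop
  the dimmest wells; the fixed and quantile thresholds cover such cases
  and are used for the steepest synthetic fields in the tests.
* The thin-plate RBF solves a dense system: beyond 3000 samples it
  interpolates through a deterministic subset (with a warning) rather than
  attempting an approximate sparse solve.
* Correction quality outside the sampled hull is unknowable from the data;
  the narrow extrapolation band is a pragmatic compromise, and everything
  beyond it is left uncorrected by design.
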