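---
title: "The color-patch method: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The color-patch method: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundpatch)
```

This vignette is the package's account of the science behind its
pipeline: what is modeled, what the tunable parameters mean, which
numerical choices were open and how they were settled, and what the
synthetic validation does and does not demonstrate about real
photographs.

## The measurement model

A wound photograph is treated as a projective image of a *plane*. The
fiducial patch — a printed 3×3 grid of colored cells, cell side 0.7 cm,
gross side 2.1 cm — lies in that plane next to the wound. Because the
patch's physical geometry is known, the four outer corners give four
point correspondences between image pixels and plane centimeters, which
determine a 3×3 homography $H$ (eight degrees of freedom, exactly
determined by four points; estimated here by the direct linear
transform). Warping by $H^{-1}$ produces a *rectified* frame: a
fronto-parallel view with a known scale $s$ (cm per pixel), in which any
region's physical area is its pixel area times $s^2$.

The nine cell colors double as a color reference. An affine map
$c' = M c + b$ (12 parameters, fitted per channel by least squares over
the nine observed/reference pairs) absorbs channel gains, offsets and
cross-talk introduced by the device and the lighting. Nine
well-separated colors overdetermine the twelve parameters comfortably;
a diagonal gain model cannot represent cross-talk, while higher-order
polynomial models are underdetermined at nine samples.

Segmentation is the automatic two-stage procedure the pipeline is named
for: k-means clustering proposes the wound region and seeds a closed
contour, and a gradient-vector-flow (GVF) active contour refines it to
the boundary. The snake minimizes
$\int \alpha |x'|^2 + \beta |x''|^2 \, ds$ plus an external image term,
iterated semi-implicitly as
$x_{t+1} = (I + \gamma K)^{-1}(x_t + \gamma \kappa F(x_t))$ with the
fixed weights $\alpha = 0.2$, $\beta = 0.2$, $\gamma = 1.0$,
$\kappa = 0.5$. GVF is used (rather than the raw edge-map gradient)
because its diffusion extends the capture range of the external force
and lets the contour descend into boundary concavities — the property
that makes it suitable for irregular wound outlines.

### Assumptions

* **Planarity.** The wound and the patch are coplanar. On curved
  anatomy (limbs, scalp) this is an approximation; the package treats
  out-of-plane wounds as a documented limitation, not an error.
* **Pinhole optics.** No lens-distortion model is fitted; consumer
  cameras at 30–50 cm are close enough to pinhole for the patch-scale
  geometry used here.
* **sRGB processing.** Colors are handled in the image's native sRGB
  encoding without linearization; the correction is an empirical device
  map, not a colorimetric calibration.

## Tunable parameters

| Parameter | Default | Units | Meaning / rationale |
|---|---|---|---|
| `snake.alpha` | 0.2 | – | elasticity (first-derivative) weight; fixed |
| `snake.beta` | 0.2 | – | rigidity (second-derivative) weight; fixed |
| `snake.gamma` | 1.0 | – | evolution step size; fixed |
| `snake.kappa` | 0.5 | – | external (GVF) force weight; fixed |
| `gvf.mu` | 0.2 | – | GVF regularization; the canonical literature value |
| `gvf.n_iter` | `NA` (auto) | iterations | `80·max(side)/64`, scaling diffusion range with image size |
| `gvf.dt` | 1.0 | – | explicit-scheme step; stability needs `dt ≤ 1/(4μ)` |
| `edge.sigma` | 1.0 | px | Gaussian smoothing before the gradient magnitude |
| `kmeans.k` | 2 | – | color clusters (wound vs. skin) |
| `rectify.px_per_cm` | 100 | px/cm | sampling density for standalone rectification |
| `measure.px_per_cm` | 25 | px/cm | working resolution of the full pipeline (below) |
| `snake.max_iter` / `snake.tol_px` | 500 / 0.01 | – / px | stop when mean vertex displacement falls below `tol_px` |
| `patch.max_color_dist` | 0.3 | RGB | per-pixel match radius in cell detection |

**Working resolution.** The homography makes measured area independent
of sampling density to first order, and the snake is sub-pixel, so the
pipeline's accuracy is set by edge localization, not raster resolution.
GVF diffusion cost, however, scales linearly with pixel count and with
iteration count. 25 px/cm (0.4 mm pixels) resolves a centimeter-scale
wound boundary to far better than 1 % of area while keeping a full
distance/angle study tractable on one core; 100 px/cm remains the
default for standalone rectification, where no diffusion runs.

## The synthetic scene generator

`renderScene()` emulates the validation setup used to characterize the
method: a planar scene holding a wound of known analytic area (circle,
ellipse, or star-shaped "blob" polygon) and the color patch, imaged by
an ideal pinhole camera at distance $d$ and elevation $\theta$ between
the optical axis and the plane ($\theta = 90^\circ$ is perpendicular).
The reference model is a circular defect of area 12.57 cm² — the area
is authoritative and fixes the radius at 2 cm
($\pi \cdot 2^2 = 12.57$); a 2 cm *diameter*, with which this model is
sometimes described, would give only 3.14 cm².

Rendering details that matter for validity:

* **Adaptive antialiasing.** Pixels whose corners all see the same
  scene element are filled flat; boundary pixels are area-averaged on
  an 8×8 subgrid, so edge positions are encoded to ~1/64 coverage.
  (Uniform low-order supersampling leaves staircase edges phase-locked
  to the pixel grid — no camera produces those, and they quantize any
  subpixel localization built on top.)
* **Optical PSF.** A Gaussian blur of σ = 0.5 sensor px emulates lens
  blur; real edges are always smooth ramps.
* **Illumination and noise.** Per-channel multiplicative gains model a
  global tint (values clip at the sensor rails, as they do in any 8-bit
  camera), then i.i.d. Gaussian pixel noise is added and clamped.
* **Determinism.** Identical (scene, camera, seed) renders are
  bit-identical; validation replicates derive their seeds from the
  master seed by fixed offsets.

What the generator does **not** emulate: skin texture and specularity,
vignetting and local lighting gradients, lens distortion, curved
anatomy, wound-bed color heterogeneity (granulation/slough), dressing
residue, and motion blur. Passing the synthetic studies therefore
demonstrates the geometry, color and segmentation machinery under
controlled conditions; it does not certify accuracy on clinical
photographs, where the planarity assumption and the wound/skin color
contrast are the usual failure points.

## Numerical choices and degenerate inputs

* **Patch detection.** Pixels are matched to reference colors within
  RGB distance 0.3; each reference keeps its best connected component
  (15 px to 5 % of the image). Fewer than 7 of 9 located cells is
  reported as "patch not detected". Cell identities resolve the 4-fold
  orientation ambiguity automatically; the default patch arrangement
  has no rotational symmetry (validity-checked at construction).
* **Subpixel grid refinement.** The fiducial spans only 2.1 cm, so
  pixel-level noise in the nine cell centroids propagates into the
  homography's perspective terms and is *amplified with distance from
  the patch* — a centroid-only fit leaves ~1 % area error a few
  centimeters away. The detector therefore refines the homography on
  the patch's grid lines: each cell boundary is localized per sample
  row as the first moment of the color-blend derivative (exact for a
  symmetric edge ramp and robust to sampling phase, where a midpoint
  crossing by linear interpolation is not), each line is fitted
  straight, and the 16 line intersections are refit by least squares.
  Channels whose endpoint colors sit at the sensor rails are excluded
  from the blend projection, because clipping kinks the profile. Two
  refinement passes are run; the refinement is on by default.
* **Rectification.** Output pixels that back-project outside the
  source frame take the border-median color; the output window is
  clipped to ±12 cm around the patch (oblique captures back-project to
  arbitrarily distant plane points that carry no detail). A raster
  budget guards against runaway sizes and the error message names the
  remedy.
* **Color fit.** The fit uses the central 60 % of each rectified cell
  (edge bleed), and three rounds of Huber reweighting so cells driven
  into saturation by a strong tint do not poison the map. All-gray
  observations are rejected as "degenerate color set".
* **k-means seeding.** Clustering runs on up to 20 000 sampled pixels
  with 10 restarts under a fixed seed; the wound cluster is the one
  farthest in RGB from the border-median color, with ties going to the
  smaller cluster (wounds are minority area). A wound cluster smaller
  than 50 px, or closer than 0.1 RGB to the border color, means "no
  wound candidate found" — the latter guard stops sensor noise from
  being split into a phantom wound on wound-free images. The patch
  region is painted border-median before clustering and edge-map
  construction so it can never attract the snake.
* **Snake evolution.** The initial contour (convex hull of the wound
  component, dilated outward 5 % of the equivalent diameter) is
  resampled to ~1 px vertex spacing: per-vertex tension scales with
  spacing², so coarse contours bias inward. The external force is the
  *unit-normalized* GVF field: the raw field's magnitude decays with
  distance from edges, and a contour bridging a deep concavity stalls
  where tension balances the attenuated force; normalization restores
  the constant-strength attraction under which the snake descends into
  cavities (verified against a U-shaped object in the test suite).
  With a normalized force the classic snake energy is not an exact
  Lyapunov function of the iteration; the suite checks the properties
  that do hold exactly — strict energy and area decrease under pure
  internal forces, and net energy decrease from initialization to
  convergence on a static field. Contours below 8 vertices or 20 px²
  raise "contour collapse". For speed the force field is computed on a
  window 25 % larger than the initial contour; GVF forces vanish far
  from edges, so the snake cannot leave it.
* **Areas.** The wound area is the shoelace area of the sub-pixel
  polygon (not a pixel count), removing boundary quantization bias.
  The L×W baseline takes L along the principal axis of the vertex
  covariance — for isotropic outlines (circles, squares) this falls
  back to the coordinate axes, matching the clinical axis-aligned
  reading — and W along the perpendicular.
* **Longitudinal statistics.** The half-decrement crossing is linearly
  interpolated between visits (`interp`), with a `nearest`-visit mode
  available; for non-monotone series the first crossing counts
  (earliest clinically meaningful milestone). "Final" area is the last
  observation; no extrapolation. Group tables report sample SDs
  (n−1) and exclude undefined half-days with a count.

## Design choices that were genuinely open

* **Patch colors.** Only the patch's geometry is prescribed; the nine
  colors are not. The default uses maximally separated sRGB primaries
  and neutrals in an asymmetric arrangement (white, red, green / blue,
  black, cyan / magenta, yellow, mid-gray), user-overridable.
* **Stage order.** Whether color normalization runs before or after
  rectification is unspecified in the method's description; this
  package normalizes *after* rectification, where the cells are
  axis-aligned and cleanly sampled. The order is recorded in each
  measurement's stage report.
* **Validation-study conditions.** The simulated distance/angle study
  uses pixel noise σ = 0.01 (≈ 2.5 digital levels), a realistic
  sensor-noise floor; the test suite bounds its grid-wide error by the
  reported error-rate envelope of the physical experiment this study
  emulates, −3.39 % … +3.05 %.
* **Cohort emulation.** Clinical group statistics are represented only
  by a seeded synthetic cohort (facial decrease rates
  ~ N(67, 12.5²) %, non-facial ~ N(53, 18²) %, truncated to (0, 100]),
  whose generator parameters are the recovery targets; per-subject
  series realize the drawn decrease exactly via exponential decay.
  Problem sizes throughout the suite (image rasters of a few hundred
  pixels, 3 replicates per study cell, 30 subjects per cohort group,
  50 series replicates) are chosen as the smallest sizes at which the
  statistics are stable.

## Known limitations

* Out-of-plane (curved-surface) wounds violate the homography model;
  the error grows with surface curvature and obliquity and is not
  detected automatically.
* Only the largest candidate component is segmented — multi-wound
  scenes are out of scope.
* Segmentation uses color only; texture-defined wound margins (e.g.
  scar vs. intact skin of similar color) will under-segment.
* The color correction is affine in sRGB; severe mixed lighting or
  strong gamma differences between devices are beyond its reach.
* Patches partially occluded by dressing and multi-patch scenes are
  not supported.
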