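---
title: "Quantitative light field microscopy for 3D worm phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative light field microscopy for 3D worm phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormlf)
```

# The measurement problem

A light field microscope places a microlens array (MLA) at the native image
plane of a widefield microscope and relays the MLA's back focal plane onto
the camera. Each microlens forms a small circular subimage whose pixels
sample the *direction* of the rays arriving at that lateral position, so a
single exposure records a 4D radiance function $L(x, y, u, v)$: $(x, y)$
indexes microlenses (spatial samples), $(u, v)$ pixels within a subimage
(angular samples, centred on the chief ray). From one such exposure the
focus can be moved computationally, and the depth of every image feature
can be inferred — which is what makes single-camera, single-exposure 3D
tracking of a fast-moving *C. elegans* possible at full frame rate.

`wormlf` implements that reconstruction chain end to end:

1. flat-field (vignetting) correction and automatic rectification of the
   raw mosaic into the 4D array (`correct_vignetting()`,
   `estimate_lattice()`, `resample_to_4d()`); lattice parameters come from
   the prominent Fourier peaks of the mosaic, are fine-tuned by disc-mask
   cross-correlation, and finally polished by regressing subimage intensity
   centroids on the lattice indices (template-shape-free, a few hundredths
   of a pixel);
2. computational refocusing by shearing, and depth estimation from the
   defocus and correspondence cues fused by a Markov random field
   (`refocus()`, `defocus_response()`, `correspondence_response()`,
   `cue_extrema()`, `combine_depth()`, `estimate_depth()`,
   `calibrate_depth_scale()`);
3. segmentation of the worm in the on-axis view, temporal filtering, and
   3D midline extraction (`segment_worm()`, `temporal_kalman()`,
   `extract_midline()`, `skeleton_angles()`, `flag_self_occlusion()`);
4. posture and locomotion metrics, 3D eigenworms and the rhodonea model of
   rolling during swimming (`centroid_speed()`, `non_planar_deviation()`,
   `curving_rate()`, `directional_autocorrelation()`,
   `compute_eigenworms()`, `project_series()`, `fit_rhodonea()`,
   `compare_strains()`);
5. a fully ground-truthed synthetic phantom — locomotion, rendered tube
   scenes and raw mosaics consistent with the shear model — so every stage
   is testable without a microscope (`generate_locomotion()`,
   `render_worm_scene()`, `render_light_field()`, `calibration_series()`).

# Refocusing model and the shear–depth relation

Refocusing shears the light field parallel to the $(x, y)$ plane:
$$L_\alpha(x, y, u, v) = L_o\!\left(u(1 - 1/\alpha) + x/\alpha,\;
v(1 - 1/\alpha) + y/\alpha,\; u, v\right),$$
and the shear parameter maps to a physical axial offset through
$$\Delta z = P\,(1 - 1/\alpha)\,F / M^2,$$
with $P$ the subimage pitch in camera pixels, $F$ the MLA focal length and
$M$ the transverse magnification. `refocus()` implements this equation
verbatim (including the $x/\alpha$ rescaling of the refocused photograph);
`shear_to_depth()` / `depth_to_shear()` are exact inverses of each other up
to the reachable limit $\Delta z < PF/M^2$.

**Object-frame response sampling.** The $x/\alpha$ term rescales the
refocused photograph by $\alpha$, so the same image pixel refers to
*different* object points at different sweep positions. For the depth
responses this is undesirable: a pixel's response profile over $\alpha$
should describe one object point. The response kernels therefore sample
the sheared field at $x + u(1 - 1/\alpha)$ — the refocused photograph
resampled back to native object coordinates. This leaves `refocus()`
faithful to the printed operator while making per-pixel response profiles
comparable across the sweep, and it removes two artefacts at once: the
magnification-induced drift of image content across the sweep, and an
$\alpha^{-2}$ modulation of Laplacian sharpness that otherwise biases the
defocus argmax.

**Interpolation.** Rectification resamples the mosaic bilinearly. The
shear kernels, however, use separable Catmull–Rom cubic interpolation.
This is a deliberate numerical choice: with bilinear gathers the
interpolation blur is exactly zero at $\alpha = 1$ and grows with the
fractional part of the shear, which carves an artificial sharpness/variance
basin at the native plane. On synthetic phantoms this basin captured the
cue extrema for $|\Delta z| \lesssim 200\,\mu m$ and destroyed the
linearity of the calibration curve. Catmull–Rom is also exact at integer
shifts (so `refocus(lf, 1)` is still bit-identical) but its interpolation
error is an order of magnitude smaller at fractional shifts, below the true
parallax signal for all depths the sweep resolves.

**Out-of-field samples.** Samples sheared outside the spatial extent are
excluded, not zero-filled; `integrate_views()` divides by the per-pixel
count of valid samples, so edge renormalisation is automatic and the
defocus cue is not biased by edge darkening.

**Angular aperture.** Pixels outside an inscribed circle of radius
`aperture_radius_frac` $\times\;P/2$ (default 0.95) are invalid: the
corners of the square subimage tiles receive no light in the instrument.

# Depth from defocus and correspondence

For each sweep position $\alpha$ the kernel accumulates, per pixel, the
first and second moments of the sheared radiance over valid views. From
these:

* the **defocus response** is the absolute 5-point Laplacian
  $[[0,1,0],[1,-4,1],[0,1,0]]$ of the view-integrated image, box-averaged
  over a $W_D \times W_D$ window (default 5 px) — maximal in focus;
* the **correspondence response** is the per-pixel angular standard
  deviation (population normalisation, $1/N$), box-averaged over
  $W_C \times W_C$ (default 5 px) — minimal in focus.

`cue_extrema()` takes the per-pixel argmax (defocus) or argmin
(correspondence) over the sweep. Confidence is the peak ratio between the
response at the optimum and at the next-best strict local extremum
(inverted for correspondence so that $\ge 1$ always means better), found
after flattening differences below $10^{-12}$; profiles with no second
extremum receive the cap (default 100), flat profiles confidence 1 and an
unreliable flag.

## MRF fusion

The two cue estimates are fused by minimising, over the sweep's discrete
depth labels $z_p$,
$$E(z) = \sum_p \left[w_d(p)\,|z_p - z_d(p)| + w_c(p)\,|z_p - z_c(p)|\right]
 + \lambda \sum_{p \sim q} \min(|z_p - z_q|, \tau),$$
with weights $w$ the confidences normalised per pixel to sum to one,
4-neighbour pairs $p \sim q$ inside the footprint, $\lambda = 0.5$ and
$\tau = 10$ labels by default. Unreliable cues get zero weight.

The solver is exact where exactness is cheap: single chains are solved by
dynamic programming with $O(L)$ truncated-linear (lower-envelope) messages,
and narrow grids (min dimension $\le 3$ with a small joint state space) by
a chain over joint column states. General grids use alternating scanline
DP — each row/column solved exactly conditioned on its neighbours — from a
confidence-weighted-mean initialisation, followed by an ICM polish. The
test suite verifies solver output against exhaustive enumeration on all
random instances up to 6 pixels and 4 labels.

## Calibration

`calibrate_depth_scale()` fits estimated against known depth by ordinary
least squares and reports gradient, intercept, $R^2$ and the residual
RMSE (the depth sensitivity). Downstream correction **divides** estimates
by the fitted gradient so corrected estimates regress on known depth with
unit slope. (Multiplying by a fitted gradient below one — as a literal
reading of some published descriptions would suggest — shrinks rather than
corrects the estimates; division is the operation that makes the corrected
series regress with unit slope, which we take to be the intent.)

# Worm reconstruction

`segment_worm()` thresholds the on-axis pinhole view against a local mean
(window 15 px, offset 1% of the dynamic range), keeps the largest
connected component, fills holes, closes with a 3 px disc and refines the
boundary with a Chan–Vese-type active contour (level set evolved under the
two-region data force and a curvature penalty, 30 iterations, periodic
re-initialisation). The result must be a single hole-free component of at
least `min_area` pixels.

`extract_midline()` thins the mask (Zhang–Suen), prunes spur branches
shorter than `prune_len` (default 6 px), and takes the longest geodesic
path between endpoints as the 2D midline. Graph analysis of the thinned
skeleton uses 8-connectivity *minus* diagonal "triangle shortcut" edges
(a diagonal adjacency is dropped when an orthogonal skeleton pixel bridges
it); without this reduction the staircase corners that Zhang–Suen leaves
masquerade as junctions and break endpoint counting. Because thinning
retreats from the tips by roughly one body radius, the path is extended
along its end directions to the mask boundary. Depth along the midline is
the **median** over the local cross-section (a disc whose radius follows
the distance transform) — robust to edge artefacts, and consistent with
the fact that the measured depth of a semi-transparent body is a
contrast-weighted average over its thickness. A smoothing spline with a
fixed smoothing parameter (`spar = 0.6`; fixed rather than cross-validated
for frame-to-frame stability) is fitted to the 3D coordinates and
resampled at 26 equally spaced arc-length positions.

Head/tail identity is not observable in a single frame without texture
cues; endpoint order follows temporal continuity with the previous frame
(`prev`), with a `flip` override, and the first frame is flagged via the
`head_assigned` attribute.

Each of the 25 segments is described by an azimuthal angle $\theta$
(direction in the $(x,y)$ plane, unwrapped along the body) and a polar
angle $\phi$ taken as *elevation* out of the $(x,y)$ plane (an inclination
convention would differ by a constant that mean-zeroing removes). Both
25-vectors are mean-zeroed over the body, which makes the representation
invariant to rigid motion; the removed means, segment lengths and origin
are retained so `angles_to_skeleton()` reconstructs coordinates exactly.

`flag_self_occlusion()` automates the exclusion of coiled/crossing
postures: a frame is dropped when the pruned skeleton is not a simple open
curve (a cycle or more than two endpoints), or when mask area exceeds
midline length $\times$ modal width by more than 50%.

`temporal_kalman()` is a per-pixel scalar constant-position filter using
only the current and previous frame: the previous depth is the prior with
variance $r + q$, the current frame the measurement with variance $r$,
giving gain $K = (r+q)/(2r+q)$. With $r \gg q$ single-frame spikes are
pulled halfway back towards the previous frame; with $q \to \infty$ the
filter passes measurements through.

# Posture, locomotion, eigenworms and the rhodonea model

The locomotion metrics operate on the centroid track (mean of the 26
skeleton points per frame): centroid speed is the forward difference;
non-planar deviation is $R_3/R_1$ from the eigenvalues of the point
covariance (0 for planar postures); curving rate is the angle between
*successive displacement vectors* per unit time — the published formula is
written with position vectors, which is origin-dependent and inconsistent
with a "curving" quantity, so displacements are used (the folded,
absolute-value form is kept, with a `signed_angles` option); directional
autocorrelation is $D(n) = (N-n)^{-1}\sum_i v_i \cdot v_{i+n}$ over unit
displacement directions (body-axis directions are a defensible alternative
the source leaves unspecified), with $A e^{-bt}$ decay fits. Forward runs
are intervals with speed $\ge 10\,\mu m/s$ and displacement aligned with
the tail-to-nose axis sustained $\ge 0.5$ s; these thresholds are ours, as
no published values exist. Explored volumes are axis-aligned bounding
boxes (a convex-hull variant exists behind a flag). Strain comparison uses
Welch's unequal-variance t-test on per-worm means, with SEMs over worms.

Eigenworms are the principal components of the mean-zeroed angle-vector
ensemble (column-centred PCA); signs are fixed so each mode's
largest-magnitude element is positive. Azimuthal and polar eigenworms of
3D locomotion are closely similar, so one shared basis — the azimuthal
set — is used to project both channels (separate bases remain available).

For a rolling swimmer the paired projections of one eigenworm trace a
rose (rhodonea) curve:
$$a^\theta(t) = A \cos[k(at + c)]\cos(at + c), \qquad
  a^\phi(t) = A \cos[k(at + c)]\sin(at + c),$$
where $(at + c)$ is the slowly rotating orientation of the undulation
plane and $k$ the number of undulation cycles per body roll. (As printed,
the source labels both lines of this pair with the $\phi$ superscript; the
first line is the $\theta$ channel, as the accompanying figures imply.)
`fit_rhodonea()` fits this jointly per mode: the squared radius
$a_\theta^2 + a_\phi^2$ oscillates at $2ka$, so its spectral peak fixes
$ka$; $k$ is then scanned on a 0.5–20 grid (step 0.25) with a fine inner
grid on $a$ (the SSE landscape oscillates in $a$ with period
$\sim 2\pi/kT$) and a coarse phase scan, amplitude solved in closed form;
the best few candidates are refined with Levenberg–Marquardt. Modes 1 and
2 are fitted independently and summarised as mean $\pm$ SD of $k$.

# The synthetic phantom

The generator is the package's ground truth and defines its study
conditions; its defaults are fixed once:

* **Locomotion** (`locomotion_params()`): body length 1000 µm, 25
  segments, tangent-angle travelling wave of amplitude 0.6 rad and
  wavelength 1.5 body lengths at 1 Hz, body roll at 1/8.5 of the
  undulation frequency (so the roll ratio equals the rhodonea $k$ the
  swimming analysis should recover), translation 50 µm/s (the order of
  measured crawling speeds), angular noise SD 0.05 rad, seed 7. Tangents
  are integrated with fixed segment lengths, so body length is conserved
  to machine precision.
* **Scenes** (`render_worm_scene()`): the body is a tube swept along the
  midline with an elliptically tapered radius; per-sample intensity is the
  chord length of the optical column through the tube, so the intensity
  model matches the contrast-weighted-average interpretation of measured
  depth; the depth truth is the axial position of the nearest midline
  point. A multiplicative band-limited texture (SD 0.4, correlation length
  2 samples, fixed seed) emulates the DIC contrast of the cuticle and
  interior — a uniform tube carries depth information only at its two
  edges, which no defocus/correspondence method can localise at sub-step
  accuracy — and a 0.5-sample Gaussian pre-blur stands in for the in-focus
  PSF. Scenes are rasterised on an 8× supersampled grid and views are
  splatted there before block averaging, so rendered views closely
  approximate exact samples of a continuous scene.
* **Optics**: pitch 19 px, magnification 10, pixel size 6.5 µm and
  MLA focal length 6500 µm. The real MLA part this emulates (125 µm pitch
  at f/20, i.e. $F = 2500\,\mu m$) would give a reachable limit
  $PF/M^2 = 475\,\mu m$, under which a ±1 mm calibration range is not
  reachable; 6500 µm is the closest nominal that makes ±1 mm reachable
  while keeping the shear-per-micrometre sensitivity as close to the
  instrument's as that constraint allows.
* **Rendering is the exact adjoint of the refocus shear**: scene content
  at depth $\Delta z$ is shifted by $(1 - 1/\alpha(\Delta z))(u, v)$
  spatial samples in view $(u, v)$. This is deliberate: pipeline
  validation is then exact rather than approximate, and the realism knobs
  (texture, blur, vignette, read noise) are separate and optional.
* **Calibration series** (`calibration_series()`): a static textured rod
  rendered at each commanded depth, emulating a paralysed specimen
  translated through known focus offsets; 26 lenses per side (494² px
  mosaics) keep a 21-depth series within a few minutes on one CPU.

Note that the locomotion model bends the body in a single (slowly
rotating) plane, so each *instantaneous* generated posture is planar and
its non-planar deviation is zero by construction; NPD behaviour is
therefore exercised on explicit 3D space curves (helices) rather than on
generator output.

What the phantom does **not** emulate: DIC shear-direction contrast,
wavelength-dependent effects, refraction by the gel, photon (Poisson)
noise, camera fixed-pattern noise, and worms whose thickness occludes
themselves along the axis. Passing tests on the phantom therefore
demonstrate the correctness and calibration of the *reconstruction
machinery* under its own imaging model, not performance on any particular
instrument's data.

# Problem sizes and numerical defaults

The shipped tests and the acceptance script use 26-lens (494² px)
calibration mosaics with a 256-step ±1 mm sweep, a 96-lens worm scene with
a 128-step sweep, and 2000-frame locomotion ensembles — sizes chosen so a
full run completes in minutes on a single core while every estimate stays
comfortably inside its tolerance. Degenerate inputs are handled
explicitly: flat response profiles are flagged unreliable rather than
assigned a depth; pixels with fewer than two valid views have undefined
correspondence; empty footprints, all-zero backgrounds, branched
skeletons, zero-length segments and rank-deficient ensembles raise errors
with specific messages; argmax ties resolve to the first (shallowest)
label deterministically.

# Known limitations

* Self-occluded (coiled) postures are detected and excluded, not
  reconstructed; a single depth per lateral pixel is assumed throughout.
* The depth label grid is discrete (sweep steps); no sub-step refinement
  of the fused map is attempted.
* The defocus cue has a physical plateau of width $\sim$ the refocused
  depth of field; within it the correspondence cue dominates accuracy,
  and fused estimates inherit a small systematic ripple there.
* Head/tail assignment is purely temporal; a recording whose first frame
  is ambiguous stays ambiguous up to a global flip.
* The scanline+ICM solver is exact only on chains and narrow grids; on
  general grids it is a strong local minimiser, verified against exact
  solutions where enumeration is feasible.

# A worked pipeline

```{r pipeline, eval = FALSE}
optics <- lf_optics()
cfg <- render_config(optics, n_lenses = 26, noise_sd = 10)

# synthetic calibration series at 21 known depths
depths <- seq(-1000, 1000, length.out = 21)
series <- calibration_series(cfg, depths, seed = 42)
sweep <- depth_sweep(optics, -1000, 1000, 256)
lattice <- lf_lattice(19, 0, c(9, 9))
estimated <- vapply(series, function(r) {
  lf <- resample_to_4d(correct_vignetting(r$mosaic, r$background),
                       lattice, optics)
  dm <- estimate_depth(lf, sweep, footprint = r$scene$footprint)
  mean(dm$depth_um[r$scene$footprint], na.rm = TRUE)
}, numeric(1))
cal <- calibrate_depth_scale(estimated, depths)
glance(cal)
autoplot(cal)

# eigenworms and the rhodonea fit on synthetic swimming
loc <- generate_locomotion(locomotion_params(), n_frames = 2000)
basis <- compute_eigenworms(posture_ensemble(loc$angles, "theta"), m = 4)
variance_captured(basis, 4)
proj <- project_series(loc$angles, basis)
fit <- fit_rhodonea(proj, modes = 1:2)
glance(fit)
autoplot(fit)
```
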