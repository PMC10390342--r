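---
title: "Quantifying ventral nerve cord condensation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ventral nerve cord condensation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vncmorph)
```

## The biological problem

During stage 15 of Drosophila embryogenesis the ventral nerve cord (VNC)
condenses: over ~12 h the tissue shortens, in a fast anisotropic first
phase (~3 h, tail-to-head, isovolumetric — length falls while width and
height rise) followed by a slow isotropic second phase (~9 h, with volume
loss). Condensation onset coincides with the exponential assembly of
collagen IV (Col4) — delivered by hemocytes as a transient head-to-tail
gradient — into the basement membrane (BM) that ensheathes the tissue,
and with a coherent tail-to-head flow of the Col4 network over the
surface. The mechanical hypothesis is that BM assembly stress acts as an
anisotropic surface tension that reshapes the soft neural core.

`vncmorph` implements the quantification stack this argument rests on —
PIV flow measurement and coherence statistics, tissue morphometry,
intensity dynamics, photobleach stripe tracking, AFM Hertz fitting — plus
a reduced core-and-shell finite element model, and a synthetic-data
module that generates every input with known ground truth so the whole
pipeline is testable without microscopy data.

## Particle image velocimetry

`compute_piv()` matches, for each node of a regular grid, a *source*
window in frame *t* against a larger *search* window in frame *t+1* by
zero-mean normalised cross-correlation (the correlation coefficient).
Design choices:

* **Normalisation.** The correlation coefficient lies in [-1, 1], which
  makes the acquisition thresholds (0.5 whole-tissue, 0.3
  high-resolution) interpretable and modality-independent.
* **Window sizes are physical.** The presets (`piv_preset()`) are stated
  in micrometres — source 9 / search 16 / grid 5 um for whole-tissue
  confocal, 2/4/1 um high-resolution, 5/10/3 um for lattice light-sheet
  acquisitions — and converted to the nearest odd pixel count at the
  stack's pixel size so windows have a centre pixel.
* **Sub-pixel peak.** A 3-point Gaussian fit per axis (falling back to a
  parabolic fit when a correlation in the triplet is non-positive), with
  ties between equal integer peaks broken toward the smaller
  displacement. When the peak correlation is numerically 1 (an exact
  match, which arises for noise-free integer shifts) the integer peak is
  reported as-is; refining a perfect match only adds texture-dependent
  jitter.
* **Validity.** Vectors with peak correlation below the threshold, with
  zero-variance windows, or whose source window leaves the region of
  interest are flagged invalid and carry `NA`, so they can never leak
  into downstream means.

`interpolate_field_series()` smooths the field with a truncated Gaussian
in space and time (kernel size read as the truncation width, sigma as
given; the Gaussian family is the natural reading of a kernel stated as
"size + sigma"). Weights are normalised over *valid* contributors only,
making each output a convex combination of observed vectors: a uniform
field is a fixed point, and a lone valid vector fills its truncation
window. Kernel presets: spatial 50 um (sigma 10) with temporal 90 min
(sigma 40) for whole-tissue acquisitions; spatial 10 um (sigma 2) with
temporal 5 frames (sigma 2) for high-resolution fields.

Coordinates: image x is the anteroposterior (AP) axis and increases
head-to-tail; tail-to-head motion therefore has negative x-velocity.
Displacements are stored in um/frame and converted to um/min only at
reporting.

## Flow statistics

`kymograph()` averages speed (or the x-component) over valid vectors per
AP bin per frame; empty bins are missing, never zero.

`local_alignment_coherence()` samples 256 reference locations per frame
among the valid non-zero vectors of the *raw* field (without replacement
when enough exist, with replacement otherwise — the generous reading when
valid vectors are scarce), averages |cos θ| against all other valid
vectors within 8 um, and smooths the frame series with a 5-frame walking
average. The "norm of the cosine" is read as the absolute value: it maps
perfect alignment (parallel *or* antiparallel) to 1 and uncoordinated
motion to E|cos θ| = 2/π ≈ 0.637 for uniform random orientations, the
natural null reference. The reference is excluded from its own
neighbourhood, since self-comparison contributes a constant 1 and only
inflates the statistic.

`directional_coherence()` samples an 11 x 11 lattice at 3 um spacing from
the *interpolated* field and averages the signed cos θ against the
tail-to-head unit vector: +1 is pure tail-to-head motion, 0 is
perpendicular or balanced motion. Both statistics depend only on vector
orientations, so they are invariant to uniform magnitude rescaling, and
the sampling is seeded for reproducibility.

## Cell tracks

`filter_and_window_tracks()` restricts tracks to analysis windows (the
two 3-h periods at 0–3 h and 7–10 h of condensation by default), keeps
tracks whose within-window portion is *strictly* longer than 10 samples
(the conservative reading of "longer than 10 frames"), and assigns
head/tail by the track's mean AP position relative to the configured
boundary — the mean is more robust than the first position for tracks
that straddle the midline. `track_directionality()` reports start-to-end
angles with zero on the head-to-tail axis, a polar histogram
(default 20° bins), and the mean average velocity as mean path length
over duration (the tracking-software convention), which makes it
invariant to time reversal. Zero-net-displacement tracks have no defined
angle; they are excluded from the histogram and counted separately.

## Morphometry

`cylinder_geometry()` implements the elliptical-cylinder idealisation:
volume `pi (W/2)(H/2) L` and closed surface area
`perimeter x L + 2 pi (W/2)(H/2)`, with the perimeter by Ramanujan's
first approximation (relative error < 1e-4 at these aspect ratios). End
caps are included because the tissue surface is closed; note that with
caps the phase-1 area decrease of the default synthetic scene is ~12%,
while the lateral-only area decreases ~16% — absolute areas therefore
depend on this convention and only *relative changes* are asserted
anywhere in the package.

`fit_ellipse()` is the direct algebraic least-squares conic fit
constrained to an ellipse, in the numerically stable partitioned
(Halir–Flusser) form, after centroid removal and variance scaling.
Eccentricity is `sqrt(a^2 - b^2)/a`, identical to the inter-focal
distance over the major axis length. On exact circles the fit returns
eccentricity at rounding-error level (~1e-8); collinear input is a hard
error since the e → 1 limit is not fittable.

`interpolate_annotations_z()` reconstructs a volume from polygons drawn
on sparse z-planes by signed-distance (shape-based) interpolation:
polygons are rasterised (0.25 um default grid), their signed distance
fields interpolated linearly between planes, and slice areas integrated
at sub-step midpoints. For concentric circles this reproduces the cone
frustum to well under 2%. It replaces explicit triangulated re-slicing
with the same contract and far less machinery.

## Intensity dynamics

Whole-frame intensity traces use a centred 10-frame moving average (edge
windows shrink so trace length is preserved). The AP-axis profile
discards bright hemocyte puncta before averaging: the default threshold
is 70% of the image's intensity *range* above its minimum — a literal
fraction-of-maximum rule would discard every pixel of a uniform image —
and a cumulative-histogram quantile rule is available behind
`discard_mode = "quantile"`. Both are relative, so profiles are invariant
to exposure rescaling. Profiles are smoothed with a 200-um walking
average.

`tail_displacement()` turns manually clicked tail positions (2-min native
resolution) into a displacement trace zeroed at the first frame
(Euclidean or AP-projected), with the condensation rate by central
differences smoothed with the same 10-frame window as intensity.
`intensity_rate_correlation()` resamples the two traces onto a common
time base and reports Pearson's r — a descriptive coupling statistic, not
a causal claim; zero-variance input flags r as undefined.

## Photobleach stripe analysis

Profiles are normalised to their own mean (the natural normalisation for
dips measured against a local baseline), smoothed with a 150-point
walking average, and local minima detected with a topographic-prominence
floor of 5% of the profile range (the protocol gives no threshold; 5%
rejects smoothed noise wiggles while keeping half-depth stripes).
Minimum positions are refined by a parabolic fit through the three
samples around each discrete minimum, paired by rank order between
timepoints, and reported as `position_t1 - position_t0`: with the head at
the origin, negative displacements are head-ward motion, and rank pairing
guarantees displacements never cross.

## AFM Hertz fitting

Force curves are calibrated as `F = k * deflection` and
`delta = z-travel - deflection` (spring constant 0.2 N/m from
thermal-noise calibration). The contact law is the spherical Hertz model

&nbsp;&nbsp;`F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)`

with tip radius R = 5 um (a 10-um silica bead), Poisson ratio 0.5 (the
incompressible soft-tissue assumption, exposed in `contact_model()`), and
a 230 nm target fit depth. Because `F^(2/3)` is linear in the tip-sample
position, the contact point is estimated by straight-line extrapolation
of `F^(2/3)` over the high-force part of the approach (where deflection
noise is relatively smallest) to zero force; the modulus is then the
least-squares slope of F against `delta^(3/2)` over [0, 230 nm]. We
initially evaluated a residual-minimising grid search over candidate
contact points and found it strongly biased under noise — the candidate
that best fits the noise is systematically correlated with the recovered
modulus — whereas the extrapolation estimator recovers noiseless curves
exactly and is unbiased to ~1% at 5% force noise. Curves that never reach
the target depth are a hard error; a force drawdown beyond the noise
floor warns of non-monotone (slipping or adhesive) contact.

## Core-and-shell mechanics

`build_shell_model()` idealises the tissue as a soft elastic core shaped
as a capped elliptical cylinder, fixed at the head cap ("attached to the
brain"), loaded by its BM shell in one of three ways: uniform normal
pressure, isotropic membrane tension, or axially dominated anisotropic
tension, with an optional tension-reduction stripe mid-tissue.

* **Discretisation.** Trilinear hexahedra on a structured mesh (a smooth
  square-to-disc map avoids degenerate elements), with the
  mean-dilatation (B-bar) volumetric treatment so the near-incompressible
  core (Poisson ratio 0.49) does not lock. The element passes uniaxial
  and hydrostatic patch tests to machine precision.
* **The shell is not meshed.** The membrane enters as the equivalent
  surface traction of a prestressed membrane layer on the boundary
  facets: per facet, the in-plane prestress (axial and circumferential
  components in a frame built from the AP axis projected onto the facet)
  is integrated against the membrane strain-displacement operator.
  Summed over the closed faceted surface this reproduces the discrete
  Young–Laplace pressure on curved regions and the rim pull at the caps,
  and makes local tension perturbations (the stripe) a per-facet scale
  factor. On the end caps, where the axial direction degenerates, the
  circumferential component acts isotropically in the cap plane.
* **Units and defaults.** Geometry in um; moduli in Pa and tensions in
  N/m at the interface (internally nN and um, so 1 Pa = 1e-3 nN/um^2).
  Defaults: L = 200, W = 40, H = 24 um — the cross-section eccentricity
  0.8 matching the flattened nerve-cord sections that the eccentricity
  module treats as canonical — E_core = 100 Pa, sigma_ax = 1e-4 N/m with
  a 10:1 anisotropy ratio, pressure 10 Pa. These magnitudes are free
  choices that keep strains moderate (~10%); in this small-strain linear
  model every displacement scales exactly with load, so all claims made
  from the model are *sign and ordering patterns*, robust across load
  sweeps by construction, never magnitudes. The width-reduction response
  to isotropic tension is a genuine competition between differential hoop
  compression (stronger at the high-curvature ends of the wide axis) and
  the Poisson bulge from axial shortening; it requires a clearly
  elliptical section (around e = 0.8 at these parameters), which is why
  the default is not rounder.
* **Readouts.** Signed mid-section width/height changes, tail
  displacement (positive = head-ward), relative core volume change
  (tension cases conserve volume to ~1% at Poisson 0.49), and mid-section
  eccentricity via the package's own `fit_ellipse()`.

Default problem sizes: a 16 x 6 x 6 structured mesh (~2.9k nodes), which
is converged to ~1% in the length response against a doubled mesh;
stiffness assembly is cached in the model object so the three load cases
and the stripe sweep reuse one factorisation.

## The synthetic-data module

Every generator takes an explicit seed (never global RNG state) and is
bit-reproducible. What they emulate, and what they do not:

* **Speckle stacks** stand in for the Col4 surface texture: Gaussian-blob
  speckle advected by a prescribed flow (backward mapping with bilinear
  sampling, which cannot tear holes), exponential photobleaching, and
  additive Gaussian read noise clipped at zero. Real Col4 texture
  statistics are unknown ("speckle" parameters are knobs, not claims),
  and no optics — PSF, light-sheet sectioning, stitching seams — are
  modelled. Passing PIV tests therefore demonstrate correctness of the
  correlation machinery, not robustness to every imaging artefact.
* **Flow fields**: uniform, rotational, zero, and a tail-to-head gradient
  whose speed decays linearly (clamped at zero) from the tail end over a
  configurable length — the condition the gradient-flow kymographs probe.
* **The condensation scene** encodes the study conditions: phase 1
  (0–180 min) shrinks length by 30% while width and height grow by
  `sqrt(L0/L)` so volume is conserved exactly; phase 2 (180–720 min)
  shrinks all dimensions 10% linearly. Col4 intensity rises as
  `exp(k t)` with k = ln(10)/180 per min (a 10-fold induction over
  phase 1) saturating at 300 min; tail displacement follows a logistic
  ramp with time constant 1/k and midpoint 175 min, so the early
  condensation rate is proportional to intensity and peaks inside
  phase 1 — the coupling the intensity-rate correlation measures.
  Observation noise is multiplicative on intensity and on the
  *frame-to-frame displacement increments*: noise on the cumulative
  displacement would be amplified without bound by differentiation,
  and increment-relative noise is the model under which a 5%-noise
  scene retains its rate signal (and keeps displacement non-decreasing).
* **Force curves** solve the implicit cantilever-sample equilibrium
  `k d = Hertz(z - z_c - d)` per sample, so the generator is exactly the
  inverse of the fitting problem. **Outlines** are ellipse points with
  radial noise; **bleach profiles** are unit-baseline profiles with
  Gaussian dips (FWHM = stripe width) sampled at the 0.108-um light-sheet
  pixel pitch.

## Numerical conventions

Moving averages are centred with shrinking edge windows (trace length
preserved); missing values are dropped per window. Degenerate inputs are
errors, not silent results: empty field series, collinear outlines,
single annotation planes, all-constant correlation windows (invalid
vector, not NaN), force curves that never reach the fit depth. Ties in
the correlation peak go to the smaller displacement; sub-pixel and
sub-sample refinements are clamped to half a sample. All tolerances
asserted in the test suite are derived from closed forms, independent
oracles (quadrature, phase correlation, frustum volumes, random-walk and
circular statistics), or parameter-recovery constructions — never from
the pipeline's own output.

## Known limitations

The PIV engine is single-pass (no iterative window deformation or
pyramids) and 2D, as in the original analysis of projected surfaces. The
shell model is small-strain and linear: it addresses which loading
*pattern* explains the observed shape change, not force magnitudes, and
its anchoring (a rigid head cap) is the crudest reading of "attached to
the brain". The synthetic generators share no failure modes with manual
steps of the original workflow (segmentation, clicking, track curation),
so recovery tests bound algorithmic error only. Hemocyte-puncta removal
is a global brightness rule, not a segmentation.
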