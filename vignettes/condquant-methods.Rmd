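---
title: "Methods and design notes for condquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for condquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`condquant` quantifies light-activated (optogenetic) biomolecular
condensates and their interactions with single mRNA molecules in
fluorescence microscopy data: how much of a tagged mRNA species is
sequestered into condensates, how mobile the molecules are, at what
expression level a cell phase-separates, how condensate composition follows
a ternary regular-solution picture, and what the downstream functional
readouts (translation-reporter decay, FRAP mobility, dendritic-spine
growth, nascent-protein signal) look like. Because the kind of data this
pipeline consumes is rarely public, the package ships a first-class
synthetic-scene generator with full ground truth, and every estimator is
validated by recovery tests against that truth.

# The synthetic world

The generators state an explicit, fixed world; tests and the acceptance
report are statements about estimator behaviour *in that world*.

* **Optics.** Pixel size 110 nm (a 330 nm recruitment threshold is then
  ~3 pixels, the correspondence used throughout single-molecule FISH
  work on EMCCDs with high-magnification objectives), Gaussian PSF with
  lateral sigma 130 nm, z-step 0.5 µm, 20 Hz frame rate for live imaging.
  The PSF is rendered as an isotropic 2D Gaussian per z-slice with a
  Gaussian amplitude envelope along z (axial sigma 0.4 µm); a full 3D PSF
  model is out of scope and unnecessary for centroid/amplitude testing.
  Spots are *point-sampled* Gaussians, matching the localization model
  exactly, so amplitude-bias measurements reflect estimator error rather
  than model mismatch. Spine stacks use 250 nm pixels with the z-step set
  equal to the pixel size (isotropic voxels), the sampling regime of
  confocal dendrite imaging; this makes the analytic sphere volume
  (4/3)πr³ directly comparable to a voxel count.
* **Noise.** Per-pixel Poisson shot noise at a configurable gain plus
  Gaussian read noise, a constant cellular background (default 100
  intensity units, read noise 2), an optional linear flat-field gradient
  and exponential photobleaching. The per-pixel variance is
  mean/gain + read², and a test asserts exactly that.
* **Recruitment geometry.** A condensate is a disc of radius 250 nm
  (smaller than the 330 nm classification threshold). Recruited mRNAs sit
  inside the condensate core — within 60% of its radius, at the
  condensate's own z-plane, since a 250 nm object spans less than one
  0.5 µm z-step. An early draft placed recruited mRNAs up to one z-plane
  away and across the full disc; that contradicted the physical meaning of
  "inside the condensate" and was corrected (it also made merged puncta
  lose amplitude through the axial envelope). Non-recruited mRNAs are
  placed at more than twice the recruitment radius from every condensate,
  so truth labels are unambiguous under the classifier. Condensates keep a
  minimum mutual separation of 12 px so that their thresholded blobs stay
  disjoint — the paper-world condensates are resolved, well-separated
  objects.
* **Occupancy.** With 120 condensates and 200 mRNAs per scene, most
  occupied condensates hold one mRNA with a tail of multi-occupancy ones,
  reproducing the regime where amplitude weighting (rather than spot
  counting) is the right recruitment estimator: coincident mRNAs merge
  into one punctum, but their summed amplitude is preserved.
* **Determinism.** Every generator takes a mandatory seed and routes all
  randomness through one scoped RNG; identical seed and configuration
  reproduce bit-identical pixels.

What the generator does *not* emulate: spatially varying background
inside cells, PSF aberrations and depth-dependent blur, condensate fusion
and growth dynamics (condensates are parameterized objects, not simulated
fields), mRNA photophysics (blinking/bleaching of single spots), and
camera artifacts beyond gain/read noise. A green recovery test therefore
establishes correctness of the estimators under the stated statistical
structure, not robustness to every real-world artifact.

# Analysis pipeline and numerical choices

**Preprocessing.** All filters accept a plain matrix or an `ImageStack`
(pixels + pixel size, z-step, frame interval + append-only provenance).
The flat-field estimator is a deliberately simple stand-in for
retrospective illumination tools: per-pixel median over ≥20 frames,
smoothed with a Gaussian of sigma = 10% of the image width, normalized to
mean 1. Rolling-ball background subtraction is a grayscale opening; the
default structuring element is the *flat disc* (the Euclidean unit ball),
which preserves diffraction-limited peak amplitudes exactly, while the
hemispherical profile (available as an option) clips them through its
curvature — the behavioural contract (offset removed, narrow amplitudes
preserved within 10%) drove this choice. Bleach correction fits the frame
means to A·e^(−kt)+c and falls back to frame-mean ratios with a warning
when the fit degenerates. Drift and channel registration use
Hann-windowed cross-correlation with sub-pixel refinement by direct
evaluation of the upsampled discrete correlation (default 1/20 px);
plain phase normalization proved unstable on non-periodic, interpolated
images and was dropped in favour of the windowed correlator.
Coordinates are 0-based throughout: the centre of pixel (row i, col j)
is (i, j) and physical position is index × pixel size. Sub-pixel shifts
interpolate bilinearly with replicate edges.

**Detection and localization.** Spot candidates are 8-neighbourhood local
maxima of an *unclamped* difference of Gaussians above median + k·MAD
(k = 5 by default, always recorded); the exported band-pass filter clamps
at zero per its contract, but thresholding on the clamped image would
collapse the MAD, so detection uses the signed filter internally.
Candidates closer than 2 px collapse to the brighter one. Localization is
damped Gauss–Newton least squares of an isotropic 2D Gaussian with offset
on a 9×9 window; fits flag failure on non-convergence, widths outside
[0.5, 4] px, or non-positive amplitude. The paper-style amplitude
estimator (max − min of the σ=1-blurred image over the 9×9 window around
the rounded position) is separate from the fit and is what the
recruitment pipeline uses; when two spots share a window the amplitude
reflects the brighter peak, a documented bias. Condensate segmentation
supports Otsu, absolute, and a robust median + k·MAD threshold; Otsu's
bimodality assumption fails on sparse condensate scenes, so the 3D
pipeline defaults to the robust rule (k = 8). Per-plane detections merge
into 3D objects by nearest-neighbour chains across adjacent planes
(radius 2 px for spots, 3 px for condensate centroids), collapsed to the
brightest plane with ties broken toward the lower index.

**Recruitment.** Distances are centroid-to-centroid; a spot is recruited
iff its planar distance to the nearest condensate is strictly below
330 nm and its z separation is at most 2 planes. Thresholds are stored in
nanometres and converted through the pixel size, since "~3 pixels" is
camera-dependent. For multi-plane condensates the brightest plane is the
z reference. The amplitude-weighted fraction divides the summed
amplitudes of recruited puncta by the summed amplitudes of all puncta in
the cell.

**Tracking and kinetics.** Linking matches track ends to detections in
global order of increasing displacement (conflict-free by construction)
with gap closing; a full bipartite assignment solver adds nothing at the
densities the criteria exercise and none is available in the target
environment. MSDs are time-averaged over overlapping pairs up to a
quarter of the track span; the diffusion coefficient is the slope/4 of an
ordinary least-squares line through the 2nd–4th MSD points with a free
intercept — the intercept absorbs static localization noise, which is the
rationale for excluding the first lag. Binding events come from a
hysteresis state machine (enter below 400 nm, exit above 600 nm, both
sustained for 2 frames); the radii are ~1.2× and ~1.8× the recruitment
threshold and are recorded with every run. Because dwell medians are
multiples of the frame interval, recovery checks average medians over
several seeds.

**Phase behaviour.** The saturation concentration is estimated by a
maximum-likelihood logistic fit in log concentration (the transition is a
threshold on a strictly positive quantity with multiplicative cell-to-cell
variability); csat is the concentration at P(clustered) = 0.5, with a
percentile bootstrap CI, and shifts between populations use a paired
bootstrap. The ternary regular-solution free energy per site is
f = φ₁/N₁ ln φ₁ + φ₂/N₂ ln φ₂ + φ_s ln φ_s + χ₁₂φ₁φ₂ + χ₁ₛφ₁φ_s +
χ₂ₛφ₂φ_s (kT units, φ ln φ → 0 at zero). The source work cites the
ternary regular-solution concept without printing equations; this
standard Flory–Huggins form is adopted as the package's interpretation,
with χ and N free parameters. Coexistence is computed geometrically: the
lower convex hull of f sampled on a simplex grid (incremental 3D hull in
C++); facets whose vertices are farther apart than a merge tolerance
(3 grid spacings) are tie simplices, and the facet containing the overall
composition yields phases and lever-rule fractions from its barycentric
weights. A grid hull is robust where common-tangent root-finding on
ternary systems is fragile. When the overall composition has φ₂ = 0, mass
conservation forbids component 2 in any phase, so the calculator reduces
*exactly* to the 1D monotone-chain hull of the binary edge — this is a
reduction, not an approximation. The symmetric binary system has its
critical point at χ = 2; at χ = 2.5 the hull binodal agrees with the root
of ln(φ/(1−φ)) = χ(2φ−1) to better than a grid cell. With strong
solute–solvent repulsion (χ₁ₛ = χ₂ₛ = 3) and attractive coupling
(χ₁₂ = −1) the dense phase is a single mixed phase containing both
solutes — the co-condensation regime, not two immiscible dense phases.

**Functional readouts.** Reporter traces are normalized per cell by the
pre-activation value; the decay model is
P(t)/P(0) = (1−α) + α·e^(−t ln2 / T½) with T½ = 6 h by default (the decay
timescale of a destabilized fluorescent reporter). The floor-aware
half-life fit profiles the additive floor (log-linear fit at each
candidate floor, 1D minimization of the residual), which is deterministic
where self-starting nonlinear fits are brittle. FRAP traces are
normalized once to the pre-bleach mean with the first post-bleach value
as the floor, and M·(1−e^(−t/τ)) is fitted by profiling τ (closed-form M
per τ); M is clipped to [0, 1.05] with a flag, and 1−M is the immobile
fraction. A double-normalization variant exists behind a flag; the
source figures do not state their normalization. Spine volumes binarize
each z-slice of an ROI with the Phansalkar local threshold (window 15,
k = 0.25, r = 0.5 — the method's common defaults; the source names the
method without parameters) and count voxels. Two choices matter and are
documented: the normalization scale is the *global stack* maximum (an
empty slice must not rescale its own noise into foreground), and the
preprocessing chain is a 3×3 median filter followed by flat rolling-ball
subtraction — a linear blur in place of the median widens the PSF skirt
and inflates small spheres by tens of percent, while skipping the median
leaves a shot-noise pedestal that lifts the blur skirt above threshold.
With the median chain, sphere volumes are recovered within a few percent
for radii ≥ 4 px and a 1.5× imposed growth is recovered within ~1.5%.
The significance test is the pooled-variance two-tailed Student's t
(Welch available as an option), with t = 0, p = 1 for identical constant
samples.

# Degenerate inputs and tie-breaks

Empty condensate lists yield infinite distances (never recruitment);
zero-spot cells make the recruitment fraction an error, not a NaN. Blank
images segment to empty region lists. Local-maxima plateaus are resolved
by the minimum-separation rule (brighter wins, then scan order). Chain
amplitude ties collapse to the lower plane. The t test's zero-variance
convention, the bleach-correction fallback, and the FRAP clipping flag
are all exercised by tests.

# Known limitations

* The rolling-ball, band-pass and Phansalkar parameter defaults are
  conventions recorded in provenance, not values from the source
  methods (which do not state them).
* The regular-solution calculator resolves compositions only to the grid
  spacing; binodals near a critical point (shallow hulls) need finer
  grids.
* The tracker is nearest-neighbour-based and will swap identities in
  fields denser than the criteria exercise.
* Absolute spine volumes depend on the stated intensity normalization;
  ratios (growth factors) are robust to it.
* The TIFF layer reads only the dialect it writes (uncompressed
  little-endian 32-bit float, one strip per page, JSON sidecar).
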