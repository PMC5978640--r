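---
title: "Measurement models for automated DBT phantom QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models for automated DBT phantom QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoqa)
```

tomoqa analyzes reconstructed digital breast tomosynthesis (DBT) volumes of
a multi-purpose QA phantom and, because scanner data cannot ship with a
package, carries a simulator that renders synthetic volumes of the same
phantom with known ground truth. This vignette documents the measurement
models, the choices behind the tunable parameters, and what the synthetic
tests do and do not demonstrate about real scanner data.

## Phantom coordinate frame and geometry

All geometry lives in `phantom_geometry` (see `default_geometry()`), in a
right-handed frame with x lateral (0 at the phantom midline), y the depth
from the chest wall (y = 0 at the wall), and z through-plane, all in mm.
The dimensioned content is: a 42 mm overall thickness with the test objects
in the central plane; four stair-step gauges of 12 steps at 0.5 mm
increments (6.0 mm full extent) rising from the chest wall; two folded bead
ramps of 0.18 mm beads at 0.25 mm vertical spacing rising 10 mm in z, the
upper limb laterally offset and continuing one spacing above the lower
limb's top bead, so the z ladder is uniform through the fold and spans
exactly 10 mm; three 5 mm aluminum beads whose z centers are 10 mm apart;
nine low-contrast spheres of 0.8, 1, 1.5, 2, 3, 4, 6, 8 and 10 mm diameter
on a circle; an aluminum square just inside that circle; and four alignment
markers near the corners.

Placements that the phantom's printed dimensional data do not fix — the
lateral gauge positions, the sphere-circle radius (17 mm here), which
diameter sits at which angle, marker corners, and the ramps' in-plane bead
pitch (1 mm) — are package defaults chosen so that every analysis ROI
clears every object footprint by at least 2 mm (an invariant asserted in
the test suite), and they are configurable and serialized with the geometry
JSON. They should be treated as approximate relative to any physical
phantom.

Contrast fractions are not printed for the phantom's objects; the defaults
are +2% of background for the low-contrast spheres, +20% for the aluminum
square, +100% for the 5 mm aluminum beads and gauges, +200% for the
markers, and +1000% for the 0.18 mm steel ramp beads (steel point sources
are effectively saturating against a tissue-equivalent background). These
are declared modeling assumptions, not measurements.

## The simulator

`render()` draws each object as its analytic solid. Through-plane, the
object's chord at each in-plane position is integrated against the slice
profile in closed form; the slice profile (Gaussian by default, triangular
and rectangular available — vendor profiles are unpublished, so the menu is
a modeling choice) has its FWHM equal to the nominal slice width. In-plane,
cross-sections are sampled on a 3x supersampled grid and box-averaged,
which keeps 0.18 mm beads unaliased on 0.1 mm pixels; spheres smaller than
the supersampling step are deposited as volume-equivalent point sources
with bilinear splatting. The slice is then convolved with an anisotropic
Gaussian blur (defaults sigma_x = 0.15 mm, sigma_y = 0.10 mm — wider along
the tube-travel direction, producing the expected MTF anisotropy), and
i.i.d. Gaussian noise is added with SD = base_SD x (mAs/ref_mAs)^(-0.5)
(base 1.0 at 100 mAs on a background of 100). Only the square-root
SD-versus-exposure dependence is modeled, not full Poisson statistics, and
out-of-plane reconstruction artifacts are represented solely by the slice
profile's tails: the analyses measure profiles, they do not reconstruct
them. Scatter, detector MTF and iterative-reconstruction nonlinearity are
deliberately not simulated. Pose is applied by rigidly rotating object
positions about the phantom center (z-y-x, i.e. yaw-pitch-roll, intrinsic
convention) plus an in-plane translation; intensities are never resampled.

The default grid is 0.1 mm pixels and 1 mm slice increment. A full-phantom
render at that resolution is ~34M voxels; the test-suite and acceptance
runs therefore render sub-regions (the ramp strip, the bead strip, one
gauge) at full resolution and use 0.2 mm pixels only where the whole field
is needed (pose, uniformity, the end-to-end pipeline). These problem sizes
are the package's own choice of desk-scale defaults and are stated here so
results are reproducible.

Because every render carries a truth record (`render_truth()`), every
analysis below is validated against known ground truth. What passing these
tests shows is that the estimators are correct for the declared degradation
model; they cannot certify behavior under vendor-specific reconstruction
artifacts, spatially varying noise, or deformations that the simulator does
not emulate.

## Pose

`locate_markers()` finds each alignment marker by thresholding a window
around its nominal position halfway between local background and peak and
taking the intensity-weighted centroid (sub-voxel). `estimate_pose()`
registers the centroids to the geometry by orthogonal Procrustes and
extracts yaw-pitch-roll in degrees. Marker-based rigid registration was
chosen over image-based registration because it is deterministic, fast,
and directly testable against the simulator's pose truth; the residual is
reported and grows monotonically with noise. Angles beyond 15 degrees are
flagged unreliable. All downstream ROIs are pose-corrected by transforming
coordinates — never by resampling intensities, which would alter noise
statistics. Simulated poses up to 3 degrees are recovered well within 0.3
degrees per axis at default noise.

## Chest wall (missing tissue)

A step of a gauge is "visible" when its mean signal exceeds the local
background by k background-SDs (k = 2 by default). Visibility is counted
contiguously from the deepest step toward the wall and quantized to whole
steps, matching the human step-counting protocol the measurement automates;
a sub-step linear interpolation is reported separately as informational
only. The reading uses the slice of maximal gauge contrast plus/minus one
slice, averaged. Missing tissue is the full 6 mm extent minus the visible
extent, so 1.9 mm visible reads 4.1 mm missing. On noiseless synthetic
crops every half-step crop from 0 to 6 mm is recovered exactly; a CNR-based
criterion replaces the human observer, and the threshold k is configurable
because no statistical agreement criterion with observers is established.

## Slice sensitivity profile, slice width, z geometry

Each reconstructed slice samples the ramp beads with weights given by the
slice profile at the bead's z, so reading the per-bead in-plane peaks and
mapping bead index to z via the geometry samples the SSP at 0.25 mm
resolution. Per bead, the implementation averages the small column band
spanned by the blurred bead, lightly smooths the row profile, and takes
the maximum over the rows containing the ramp. The background is the same
max-over-rows statistic taken in an object-free strip beside the ramp: a
maximum of noise is biased upward, and using the identical statistic for
background makes that bias cancel instead of distorting the profile's
normalized shape (tie-break: the smoothing of the row profile keeps the
bias nearly level-independent).

A cubic smoothing spline is fitted through the peak values. The smoothing
is tied to the estimated noise SD by a discrepancy rule: the spline's
residual RMS is matched to a fraction of the noise SD estimated from the
background strip. Generalized cross-validation alone tends to chase noise
bumps near the peak at low amplitude, inflating the normalization and
biasing the width low; matching the full noise SD instead rounds sharply
peaked profiles and biases the width high. The fraction therefore scales
with the relative noise level (0.5 at low noise up to 0.85 at high). The
FWHM is read from the normalized curve by linear interpolation of the two
half-maximum crossings. The 0.18 mm bead size is negligible against 1-5 mm
slice widths and is not deconvolved here (only the resolution module
deconvolves it). The headline `slice_width()` averages the FWHM over both
folded sets and three contiguous slices — contiguous-slice SSPs agree
closely, so they act as replicates; with them the measured width stays
within 0.5 mm of nominal across 1-5 mm widths at default noise, with bias
below 5% of the width.

Slice incrementation is the mean difference of SSP peak z positions across
consecutive slices, with zero-spacing outliers (duplicated slices)
flagged. The three 5 mm beads give the z-geometry check: each bead's
through-slice response (per-slice ROI maximum) is spline-fitted for its
peak z, and consecutive differences recover the 10 mm spacing within 0.3 mm
under default noise. The ASF is read as normalized profiles through a
bead's center along x and y at a chosen slice offset.

## PSF and MTF

Ramp beads act as point sources. `extract_psf()` cuts a patch on the
bead's in-focus slice, subtracts the patch-border median, recenters on the
intensity centroid, and rejects patches whose radial profile rebounds
above 20% of the peak after first falling below it (neighboring-bead
contamination — the check is scale-free rather than a fixed radius).
`mtf_from_psf()` applies a Hann window (truncation-ripple suppression),
zero-pads to 4x the patch, and reads the normalized modulation along the
frequency axes through DC up to the pixel Nyquist. Windowing and padding
are unpublished implementation choices; the window's taper is negligible
when the patch is much wider than the PSF, which is why the closed-form
Gaussian check uses a 6.4 mm patch while the in-ramp headline measurement
uses 0.9 mm patches that stay inside the 1 mm bead pitch. Bead-size
deconvolution divides by the analytic transform of a disc of the bead's
projected diameter with a regularization floor (0.05); beyond the first
frequency where the divisor falls below the floor the curve is truncated
and flagged. Values above 1 are reported, never clipped, since anisotropic
limited-angle reconstructions can push apparent modulation above its DC
value. Only beads within 0.5 mm of the in-focus plane contribute to the
headline curve (off-plane beads blur more); per-bead curves are averaged
with a per-frequency SD. The label to keep in mind: this is the Fourier
transform of a measured PSF, a useful characterization even where strict
MTF conditions (linearity, isoplanatism) do not hold in DBT.

## Uniformity, SNR, CNR, noise law

Regional uniformity: mean and SD in two 10 mm-radius ROIs (anterior and
lateral), per slice, with the linear trend of mean versus z reported.
Global uniformity: five 5 mm-radius ROIs on a slice; the metric is
100 x (max ROI mean - min ROI mean) / grand mean of the five ROI means.
The percentage form is required because DBT pixel scales are not
normalized across vendors; the grand-mean denominator is this package's
convention and is recorded in the report provenance. The metric is
invariant under multiplicative rescaling and strictly decreased by adding
a positive constant — both directions are asserted in tests. ROI
placements are validated at run time against every object footprint
dilated by 2 mm, and measurements agree within 0.5 percentage points
whether or not the test objects are present in the render.

SNR is the uniform-ROI mean (zero offset on the raw pixel scale, offset
configurable for vendors with a known rescale) over the SD of a
neighboring noise ROI; a zero-SD (noiseless) input is reported as infinite
with a degenerate flag rather than an error. CNR is the net signal over
the aluminum square (ROI inset 2 mm from its edges, background ROI
adjacent) divided by the background SD — noise is measured in the
background, not inside the square, to avoid contrast-dependent noise.
With the square 1 mm thick and a 1 mm slice profile, partial filling
means the rendered square contrast is about three quarters of the nominal
fraction; CNR still scales as the square root of mAs. `fit_noise_vs_mas()`
fits log SD against log mAs; simulated sweeps recover the exponent
-0.5 within 0.05.

## Low contrast and the contrast-detail model

Sphere conspicuity is scored as local CNR: disc ROI of the sphere's
diameter at its pose-corrected center, background annulus around it
(1 mm gap, 2 mm wide), detected when CNR >= 1.0. The threshold is a
declared operating point, not an observer model — observer and ROC
analysis are out of scope. The contrast-detail noise datum samples circle
means from the uniform region beside the spheres: circles are placed on a
deterministic hexagonal packing (reproducible, unlike random placement),
at least 6 per diameter (the 10 mm circles pack only a handful into the
region), 50 where room allows. For white noise the SD of a circle mean is
sigma/sqrt(m) with m the pixel count, i.e. proportional to 1/diameter,
and `fit_cd_model()` fits the single-parameter hyperbola SD = k/d by
least squares, reporting the RMS residual relative to the mean SD as a
misfit flag. The fitted diameters default to 10 down to 1 mm; 0.8 mm is
omitted because too few non-overlapping 0.8 mm circles behave stably at
0.1 mm sampling.

## Pipeline, report, and interfaces

`run_pipeline()` runs positioning first, pose-corrects everything
downstream, isolates failures per metric family (a missing object fails
its family and leaves the rest of the report intact), and writes JSON and
CSV reports whose reruns are byte-identical; a timestamp enters the
provenance only if the caller supplies one, so determinism is the default.
Volumes are read from multi-frame DICOM, single-frame DICOM series
(ordered by slice position, with inter-slice gaps checked to 1%), or
stacked TIFF with a JSON sidecar. The DICOM codec is a minimal
Explicit-VR-little-endian implementation written for this package; scanner
exports in other transfer syntaxes should be converted externally or
supplied as TIFF+JSON. DICOM rescale slope/intercept is applied on read
and recorded; no other rescaling ever touches the pixels. A thin CLI
(`inst/cli/tomoqa`) exposes `analyze` and `simulate` over these functions
for shell use; the cloud-upload workflow the phantom was designed around
is reduced to this local, machine-readable form on purpose.

## Known limitations

The simulator's degradation model is deliberately simple: Gaussian noise,
separable Gaussian blur, no scatter or reconstruction physics, box objects
translated (not rotated) under pose — adequate for small angles and for
validating estimators, not for emulating any particular scanner. The
chest-wall visibility criterion and the sphere-detection threshold are
operating points that a site should calibrate against its own observers.
MTF from 0.9 mm in-ramp patches is coarsely sampled in frequency; isolated
test beads are the right fixture for accuracy checks. Absolute pixel
units are never interpreted.
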