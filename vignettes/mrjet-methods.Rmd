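---
title: "Direct quantification of mitral regurgitation from 4D flow CMR: methods and design"
author: "mrjet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct quantification of mitral regurgitation from 4D flow CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrjet)
```

## The problem

Mitral regurgitation (MR) — retrograde systolic flow from the left
ventricle into the left atrium — is conventionally quantified on CMR
*indirectly*: the regurgitant volume is taken as the left-ventricular
stroke volume (end-diastolic minus end-systolic cavity volume, from
contoured cine images) minus the forward volume through the aorta (from
phase-contrast flow imaging),

$$V_{MR} = (EDV - ESV) - V_{Ao}.$$

This difference of two large, independently measured numbers is fragile:
a few percent of error in any component translates into tens of percent
of error in the small residual. In hypertrophic cardiomyopathy the
problem is compounded by outflow-tract obstruction (biasing aortic flow)
and hypertrophied trabeculation (biasing the ventricular contours), and
the regurgitant jet itself is typically eccentric and confined to mid-to-
late systole.

4D flow CMR measures a three-directional velocity vector in every voxel
of a 3-D volume at every cardiac timeframe, which permits *direct*
quantification: find the jet in the atrium, place an oblique analysis
plane across it, integrate the through-plane velocity over the jet
cross-section to get a regurgitant flow rate, and integrate the
flow-rate curve over the regurgitant period. `mrjet` implements this
direct pipeline, the indirect comparator, MR severity grading, and the
agreement statistics used to compare methods and observers, together
with a digital jet phantom that provides ground truth for validation.

## The direct jet-tracking pipeline

For a preprocessed velocity field the pipeline
(`trackMitralRegurgitation()`) proceeds per timeframe:

1. **Jet detection** (`detectRegurgitantFrames()`). Voxels inside the
   atrial region with speed above a threshold are grouped into
   26-connected components; components of consecutive frames are linked
   into jets when they lie within 15 mm of each other. Because a jet is
   an elongated structure tens of mm long, fragments are merged on the
   smallest distance between their voxel sets, not on centroid
   distance. Once a jet exists, its frame window is extended by
   hysteresis into adjacent frames where a component persists above
   60% of the threshold near the jet: the flow pulse rises from and
   returns to zero, so the first and last regurgitant frames are
   necessarily low-velocity, while a noise-only phantom (no seed
   detection) is never extended and correctly reports zero volume.
2. **Peak-velocity landmark** (`locateJetPeak()`). The analysis plane is
   anchored at the fastest voxel of the jet component, excluding voxels
   flagged by aliasing unwrapping (when the fastest voxel is flagged the
   search falls back to the fastest unflagged voxel further along the
   jet). Near-ties — speeds within 85% of the maximum — are resolved
   toward the component centroid, which keeps the plane away from the
   jet's extremities where a noise-boosted rim voxel would otherwise
   capture the landmark and the plane would slice past the end of the
   jet core.
3. **MPR plane** (`mprPlane()`, `sampleThroughPlane()`). A 40 × 40 mm
   raster at 1 mm pixels is placed at the landmark with its normal along
   the local jet direction (the normalized mean velocity over the
   3 × 3 × 3 neighbourhood of the landmark), so regurgitant flow is
   positive through-plane. Each velocity component is interpolated
   trilinearly at the pixel centres; planes are re-derived independently
   every frame and therefore adapt to direction-varying jets.
4. **Cross-section segmentation** (`segmentJetCrossSection()`). Pixels
   at or above 25% of the in-plane maximum through-plane velocity,
   restricted to the 8-connected component containing the plane origin,
   then dilated by one pixel. The dilation recovers partial-volume flux
   at the jet rim; the background pixels it admits carry zero-mean noise
   and do not bias the flow rate.
5. **Flow rate and volume** (`computeFlowRate()`,
   `integrateRegurgitantCurve()`). The flow rate is
   $Q = \sum v_{tp} \cdot A_{pix} / 100$ mL/s (velocity in cm/s, pixel
   area in mm²). Each jet's sampled (t, Q) curve is interpolated with a
   natural cubic spline, closed to baseline with zero-flow anchors half
   a frame interval outside the sampled window, integrated on a fine
   grid, and clamped at ≥ 0; per-jet volumes are summed. An anchor is
   only added on a side whose terminal sample is nonzero — a terminal
   sample at exactly zero already is the baseline crossing, and a
   duplicated zero would artificially flatten the spline. A single-frame
   jet integrates a triangular pulse, $Q \Delta t / 2$.

### Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `speedThreshold` | 25 | cm/s | jet detection threshold |
| `minComponentVoxels` | 8 | voxels | smallest component treated as jet |
| `linkDistance` | 15 | mm | frame-to-frame linking / merging |
| `extendFraction` | 0.6 | – | hysteresis fraction for window extension |
| `planeExtent` | 40 | mm | MPR raster side |
| `planePixelSpacing` | 1 | mm | MPR pixel size |
| `relativeThreshold` | 0.25 | – | cross-section segmentation |
| `dilatePx` | 1 | px | rim dilation of the cross-section |
| `nearPeakFraction` | 0.85 | – | near-peak plateau for landmark choice |

The detection threshold of 25 cm/s deserves comment. A mild (16 mL)
regurgitant pulse spread over ~230 ms peaks around 90–110 mL/s; on a
half-sine time course the first and last active frames then carry core
velocities of only ~35–40 cm/s. A threshold of 50 cm/s — a common
first guess well above noise — provably truncates the regurgitant
window by one to two frames at each end and biases the volume low,
whereas 25 cm/s still sits five standard deviations above a 5 cm/s
velocity noise floor. The human analyst of clinical data performs the
corresponding step visually and is not bound by a single threshold;
these parameters are automation surrogates and are all exposed in
`jetTrackingParams()`.

## Preprocessing

**Aliasing** (`unwrapAliasing()`). Velocities beyond the encoding limit
VENC wrap by multiples of 2·VENC. The unwrapper compares each voxel to
the median of its six face-neighbours and adds the multiple
$2k\,\mathrm{VENC}$, $k \in \{-1, 0, +1\}$, that brings it closest,
iterating to convergence; changed voxels are flagged in `aliasFlags` and
excluded from peak-landmark selection downstream. The single-wrap search
is appropriate at clinical VENC settings (150–250 cm/s), where
velocities beyond 2·VENC do not occur. The algorithm's domain is
*spatially smooth* fields in which the wrapped region is thin (about one
voxel) relative to the neighbourhood: a wrapped region two or more
voxels thick in every direction leaves interior voxels whose
neighbourhood median is itself wrapped, and no local median rule can
repair that. The aliasing validation phantom is therefore a narrow
smooth (Gaussian-profile) jet whose peak barely exceeds VENC — the
regime the correction targets in practice.

**Eddy-current offsets** (`correctBackgroundOffset()`). A first-order
(planar) spatial polynomial is fitted per frame and component over
static-tissue voxels and subtracted from the whole volume; the fit order
is configurable (0 = constant). For flow curves the mean rate over a
declared diastasis window is subtracted. Both corrections are idempotent
within fitting tolerance. Maxwell-term correction is intentionally
absent: it requires sequence gradient information that the velocity
field alone does not carry, and fields are assumed to arrive
Maxwell-corrected from reconstruction.

## The indirect comparator and severity grading

`strokeVolumeMetrics()` takes EDV and ESV as the extrema of the
contoured volume curve (frame labels are deliberately not assumed),
`aorticForwardVolume()` integrates the positive part of the aortic rate
curve by the trapezoid rule — retrograde flow is excluded from the
forward volume; integrating net flow instead is the other defensible
convention, and the choice is surfaced in the documentation — and
`indirectMRVolume()` returns the difference unclipped, with a warning
when negative, so that agreement analyses see the measured value.
`errorPropagationDemo()` makes the fragility quantitative: independent
±5% perturbations of EDV, ESV and forward flow produce a relative spread
in the indirect MR volume roughly an order of magnitude larger than in
any input.

Severity grading (`classifyMRSeverity()`) maps volume to none
(< 10 mL), mild (10–30), moderate (30–60), severe (≥ 60). The printed
band edges overlap at 30 and 60; they are resolved as half-open
intervals closed on the left, consistent with the "< 10" and "≥ 60"
endpoints. Negative (indirect) volumes grade as none.

## Agreement statistics

`iccTwoWayRandom()` computes ICC(2,1) — two-way random effects, single
measures, absolute agreement — from the two-way ANOVA mean squares,
$$ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n},$$
with a one-sided F test of $MS_R/MS_E$ for the p-value (the conventional
test of ICC > 0). `blandAltman()` uses differences (first − second),
bias ± 1.96 · sample SD. `cohensKappa()` computes unweighted kappa on
the full severity cross-tabulation with empty rows/columns retained; its
p-value uses the Fleiss large-sample standard error under the null.
`wilcoxonSignedRank()` is exact (full sign-assignment distribution,
computed by convolution over the observed ranks, which handles midranks
from ties) up to 25 nonzero differences and uses the tie- and
continuity-corrected normal approximation beyond. Quantiles use the
linear-interpolation convention (R type 7), which matters for the IQR at
even n. Interpretation bands for ICC and kappa are decided on the value
rounded to two decimals, the precision at which the bands are defined.

## The digital jet phantom

`generateJetPhantom()` builds a velocity field with known ground truth:

* grid 40³ voxels at 2.5 mm isotropic; 20 frames at 38 ms; VENC
  150 cm/s — typical clinical 4D flow acquisition values;
* a jet modelled as a straight-to-gently-precessing cylinder (radius
  5 mm, length 50 mm) from an orifice point along an oblique, eccentric
  axis, inside a spherical "atrial" region; the axis drifts linearly
  over the regurgitant window to exercise the dynamic plane adaptation;
* an orifice flow-rate pulse $Q(t)$ shaped as a half-sine over
  228–456 ms (mid-to-late systole; frames 7–12), scaled so its analytic
  integral $2 Q_{max} T / \pi$ equals the target volume — 16 mL by
  default, a mild jet;
* a top-hat radial velocity profile with a one-voxel partial-volume
  ramp at the rim (modelling intra-voxel averaging), or a Gaussian
  profile (sd = radius/2) for smooth-jet studies; in both cases the
  core velocity is scaled by the numerically integrated effective
  cross-section area so that the discrete flux through any
  perpendicular plane equals $Q(t)$;
* additive Gaussian velocity noise (sd 5 cm/s by default) from a seeded
  generator — same config and seed give bit-identical fields;
* optionally a second, well-separated jet with its own flow pulse;
* `generateIndirectInputs()` constructs a ventricle/aorta pair that is
  consistent with the jet truth by construction
  (EDV − ESV = forward + MR volume); the sampled aortic curve is
  rescaled so its positive-part trapezoidal integral equals the
  configured forward volume exactly, eliminating discretization leakage
  from the closed-loop check.

The phantom emulates the *geometry and kinematics* that the
quantification method must handle — eccentric direction, direction
drift, a single-peaked systolic pulse, partial-volume edges, noise,
aliasing, two jets — and deliberately not the fluid dynamics it does
not rely on: no entrainment, turbulence or signal-loss modelling, no
valve apparatus, no chamber wall motion. Passing the phantom tests
demonstrates correct parameter recovery under the stated conditions; it
does not certify accuracy on clinical data, where segmentation and
landmark ambiguity are resolved by a human analyst.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere a plane samples the voxel grid;
  pixels outside the volume are excluded (not extrapolated).
* Spline integration on a fine grid (≈ 200 points per frame interval);
  the result is clamped at ≥ 0.
* A raster with no positive through-plane pixel yields an empty mask
  and zero flow; a jet absent everywhere yields zero MR volume and zero
  jets, which grades as "none".
* An entirely flagged (aliased) jet component raises an error rather
  than guessing a landmark.
* Merging and linking distances are in physical mm and therefore
  invariant to voxel size; the tracked volume is invariant (≤ 1%) under
  spatial translation of the whole phantom.

## Problem sizes

The validation suite runs 20 noisy single-jet phantoms, 1 two-jet
phantom, 1 aliased phantom and 1 noise-only phantom at the default 40³
× 20-frame size, plus the statistics oracles on 4–10⁴-element fixtures;
the full suite completes in well under a minute on one core. The batch
agreement demonstration in the pipeline uses 12 phantoms spanning
4–70 mL.

## Known limitations

* Single-wrap aliasing correction only; thick saturated (top-hat)
  aliased cores are outside the unwrapper's domain, as discussed above.
* No Maxwell-term correction (requires sequence information).
* The automation surrogates (thresholds, hysteresis, dilation) stand in
  for visual inspection and manual contouring; equivalence with any
  particular clinical software's proprietary algorithms is not claimed.
* Diastolic mitral inflow is out of scope; the tracker quantifies the
  regurgitant (systolic) jet only.
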