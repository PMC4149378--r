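---
title: "Quantifying iodine stain penetration from micro-CT time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying iodine stain penetration from micro-CT time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainkinetics)
```

## The problem

Soft tissue is nearly transparent to X-rays, so cardiac micro-CT relies on
an iodine-based contrast agent (I2KI) diffusing into the specimen during an
incubation bath. Staining time is the protocol's key free parameter: the
agent reaches the outer (epicardial) surface immediately but takes far
longer to accumulate deep in the wall, and both under- and over-staining
degrade the reconstruction. `stainkinetics` estimates, from a series of
slice images taken at successive staining durations, how long tissue at
each transmural depth needs to approach its saturated intensity — and
condenses the answer into a two-coefficient planning rule.

## Models

**Per-depth saturation kinetics.** For the tissue in a depth segment, image
intensity is modelled as an exponential approach to saturation,

$$I(t) = I_{max} - (I_{max} - I_0)\,e^{-t/\tau},$$

with native intensity $I_0$ (counts), ceiling $I_{max}$ (counts) and time
constant $\tau$ (hours). The model assumes a single dominant uptake rate
per segment and monotone accumulation; it does not model washout or
over-staining. Because polychromatic beam hardening makes the ceiling
depth-dependent (highest at the surface), "adequately stained" is defined
on the ratio $I/I_{max}$, which is invariant to any multiplicative ceiling
change. The time to reach saturation level $s$ has the closed form

$$T = \tau \,\ln\!\frac{I_{max} - I_0}{(1 - s)\,I_{max}},$$

clamped at 0 for tissue whose native ratio already exceeds $s$ (not seen in
cardiac tissue, but possible for intrinsically dense samples).

**Depth rule.** Across depths, the required times follow
$T(d) = A e^{B d}$: a straight line on a semi-log plot. It is fitted by
ordinary least squares of $\log T$ on $d$, which is exactly invertible on
noiseless data and matches the semi-log presentation of the relation;
nonlinear fitting of $T$ directly would weight the deepest (largest-$T$)
segments disproportionately. Units are forced by the measurement design:
$d$ in mm (0.1 mm segments), $T$ and $A$ in hours (incubation timescale),
$B$ per mm.

## Pipeline stages and numerical choices

**Line profile.** Intensity is sampled along a user-chosen transmural ray
at one-pixel steps, each sample the mean of `width_px = 5` nearest pixels
perpendicular to the ray. Averaging across the ray suppresses detector
noise without blurring along the sampling direction. No sub-pixel
interpolation is used: each contributing value is an actual pixel, and the
averaging width is interpreted as a perpendicular band (a plausible
alternative — five parallel rays — differs only at strongly curved
boundaries).

**Edge detection.** The epicardial edge is found in three steps on the
smoothed profile: (1) Gaussian smoothing with `sigma_px`; (2) the maximal
forward-difference gradient (first index on ties, i.e. the most epicardial,
matching the scanning direction); (3) the first subsequent sample where the
gradient has fallen to `drop_fraction` of the maximum — where the intensity
rise levels off into the tissue plateau. The drop criterion is a ratio of
gradients, so detection is invariant to affine intensity rescaling.

Defaults were set by the geometry of the rule itself. For a sharp boundary
the smoothed gradient is close to a Gaussian centred on the boundary, so
the drop point sits about $\sigma\sqrt{2\ln(1/\text{drop})}$ samples past
it — a *systematic* inward bias of about $2.15\sigma$ at
`drop_fraction = 0.1`, which heavy smoothing inflates to many voxels. The
shipped defaults `sigma_px = 1.5`, `drop_fraction = 0.5` keep that bias at
about one voxel while still averaging over three-plus voxels of noise (the
profile is already width-averaged); the half-maximum criterion also crosses
on the steep part of the gradient, where noise jitters the crossing least.
Both parameters stay exposed because real epicardial ramps are broader than
the phantom's step and may warrant heavier smoothing. Smoothing uses a
kernel truncated at $\pm4\sigma$ with half-sample symmetric (edge-repeating)
reflection padding, which leaves constant profiles untouched and conserves
the profile mean exactly.

A profile with no positive gradient is rejected ("no edge found"), and one
whose gradient never levels off before the profile ends is rejected
("edge unresolved") rather than guessed at.

**Depth segments.** Starting at the detected edge, the profile is cut into
twenty 0.1 mm half-open bins $[k\cdot 0.1, (k+1)\cdot 0.1)$ so every sample
belongs to exactly one segment; a segment's intensity is the plain mean of
its samples (membership by sample centre). Segment *labels* are the bin
start depths. When the pipeline assembles the depth–time grid for fitting,
each segment is represented by its mid-depth (`start + 0.05`): a bin-mean
intensity reflects the bin's interior, and using the start depth instead
would bias the fitted $A$ upward by $e^{B/20}$ (about 5% at $B = 1$ per mm)
while leaving $B$ untouched.

**Saturation fits.** Least squares is minimized with derivative-free
simplex (Nelder–Mead) search, the same family as MATLAB's `fminsearch`,
with relative tolerance $10^{-10}$. Positivity of $\tau$ and of the rise
$I_{max} - I_0$ is enforced by optimizing their logarithms — the simplex
simply cannot enter non-physical regions. Initialization: $I_0$ from the
first sample, $I_{max}$ from the last (inflated 5% if they coincide),
$\tau$ a third of the time span. The search restarts from its own solution
until the parameters are stationary (plus one perturbed restart if the
first run reports non-convergence), making the fit a fixed point of
refitting. A series whose intensity range is below $10^{-6}$ of its mean
magnitude is flagged degenerate — no kinetics are identifiable — and
excluded (with a report) from the saturation-time table. At least four
timepoints, including an unstained $t = 0$ scan, are required for the three
free parameters.

**Edge reference timepoint.** The edge is detected once, by default on the
last (most-stained) timepoint where boundary contrast is strongest, and
reused for all timepoints; the stack is assumed pre-aligned, and no
re-registration is attempted. The reference timepoint is configurable.
Whether fits should pool multiple hearts or be run per heart is left to the
caller: the pipeline fits whatever grid it is given.

## The phantom generator

`simulate_stack()` renders what the analysis assumes: an annular wall
(default outer radius 3.2 mm) at 11 µm voxels, staining times
{0, 6, 13, 26, 39, 58} h, intensity given by the saturation law with
$I_0 = 10^4$, $I_{max} = 3\times10^4$ counts at the surface,
$\tau(d) = 5\,e^{1.0\,d}$ h, a linearly decreasing ceiling
(1000 counts/mm) mimicking beam hardening, additive Gaussian noise
(default 200 counts, 1% of the dynamic range) and a low-contrast
background standing in for the wrapping and sample holder. Choices worth
noting:

* $\tau(d) = \tau_0 e^{\beta d}$ makes the depth rule exactly recoverable
  ($T(d) \propto \tau(d)$ when $I_0/I_{max}$ is depth-constant), so
  end-to-end tests have closed-form truth. An alternative generator based
  on semi-infinite diffusion, $C(d,t) = C_0\,\mathrm{erfc}(d/2\sqrt{Dt})$,
  is included for physically motivated fields.
* The default wall (2.2 mm) slightly exceeds the 2.0 mm analysis window so
  the twentieth segment stays intramural despite the ~1 voxel inward bias
  of the detected edge.
* The ceiling decrease is linear — the simplest monotone choice for an
  artifact only known qualitatively — and configurable.
* Geometry is a circular annulus: papillary muscles, chambers and
  out-of-plane structure are not modelled, because the analysis samples a
  single transmural ray. Images are quantized to 16-bit on write; noise
  streams derive from one master seed plus a fixed per-timepoint offset,
  so renders are bit-reproducible and earlier timepoints never change when
  one is appended.

Passing tests on this phantom therefore demonstrates correctness of the
*analysis chain* — edge localization, discretization, fitting, and the
recovery of generating parameters — not robustness to real-tissue
confounds: anatomical curvature, motion or swelling between scans,
reconstruction artifacts beyond a monotone ceiling gradient, or spatially
correlated noise.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
instances: single-slice phantoms up to ~590 px square, 6 timepoints,
20 depth segments, 100 noisy edge-detection rays, and Monte-Carlo
recovery with 200 replicates (saturation fits, 1% noise) and 500
replicates (depth-rule fits, 5% lognormal noise). These sizes give stable
medians while keeping a full run in seconds.

## Limitations

* Coefficients are point estimates; no uncertainty is propagated from the
  saturation fits into $(A, B)$.
* The kinetics are specific to the agent concentration, temperature,
  fixation state and species of the source data; the reference
  coefficients describe I2KI-stained mouse ventricle at 11 µm and should
  be recalibrated for other preparations.
* Dual-sided planning uses the literal halving rule (effective depth
  = thickness/2); it assumes both surfaces are equally accessible and
  ignores any interaction of the two diffusion fronts near the midplane,
  conservative for the saturation levels considered.
* Ray placement is manual, as in the measurement procedure the pipeline
  mirrors; there is no automatic transmural ray search and no endocardial
  edge detection.
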