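---
title: "Simulating and analyzing wide-field optic-flow fMRI experiments"
author: "egoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing wide-field optic-flow fMRI experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egoflow)
```

## Scope and model

`egoflow` implements, end to end and on synthetic data, the computational
chain of a wide-field egomotion fMRI experiment: simulation of
three-dimensional flow-field ("star field") stimuli, construction of the
event-related and block experimental designs, generation of BOLD time series
and volumes with known ground truth, first-level GLM estimation with AR(1)
prewhitening, region-of-interest definition (including the ipsilateral rule
that separates MST+ from MT), the motion-coherence coefficient MC/MI, and
phase-encoded retinotopy analysis. Because no raw data from such experiments
are consumed, every analysis operates either on its own synthetic output or
on user-supplied NIfTI volumes and CSV event tables.

The guiding principle is parameter recovery: the synthetic generator plants
known condition amplitudes, and the analysis chain must recover them — exactly
in the noiseless limit, and within stated statistical tolerances under the
calibrated noise model.

## Stimulus simulation

Dots live in flat 2-D screen-angle coordinates (degrees, x rightward, y
upward). The wide-field geometry is a flat screen at 20 cm viewing distance
whose half-sizes subtend 34.5° horizontally and 27.5° vertically; flat-screen
trigonometry gives the 69° x 55° extents and an 82° oblique diagonal:

```{r geometry}
g <- defaultFieldGeometry()
fieldExtents(g)
```

One coordinate subtlety is intrinsic to this flat domain: the Euclidean
eccentricity of the screen corner in angle coordinates,
`sqrt(34.5^2 + 27.5^2)` = `r round(cornerEccentricity(defaultFieldGeometry()), 1)`°,
exceeds the trigonometric oblique half-angle (41°) that describes the true
visual angle of the corner. The speed and size laws are defined over the full
flat-coordinate range `[0, cornerEccentricity]` so that every reachable dot
position has a well-defined speed and size; the geometry object reports the
trigonometric extents, which is what one would quote for the display.

The simulation is 2-D by design: the "3-D" character of the stimulus is
perceptual, conveyed by eccentricity scaling of speed and size (near-center
dots are slow and small as if distant). A true 3-D point cloud with
perspective projection is deliberately out of scope.

### Speed and size laws

Speed is logarithmically scaled with eccentricity,

$$v(e) = v_{\min} + (v_{\max} - v_{\min})
  \frac{\ln(1 + e/e_0)}{\ln(1 + e_{\max}/e_0)},$$

which honors the stated endpoints exactly. The scale $e_0$ is the free
parameter: it is calibrated once per speed tier by a one-dimensional root
search so that the *number-weighted* mean speed over a uniformly dense field
equals the tier's printed average (18, 30 or 50 deg/s for the 1–20, 5–50 and
10–70 deg/s tiers). Whether those printed averages are number-weighted,
area-weighted or time-averaged is not derivable from the source; the
number-weighted mean is the natural choice for a field of identical dots and
is the documented convention. Dot diameter is an affine map of eccentricity
onto [0.1°, 4°]; strict proportionality is impossible with a non-zero
minimum at the center, so the affine map is the documented resolution.

```{r speed}
p <- speedTierProfile("low")
p
dotSpeed(c(0, 10, cornerEccentricity(g)), p)
```

### Dynamics

Dots advance at 60 Hz (`dt = 1/60` s; the 350-ms lifetime is exactly 21
frames and the 500-ms reversal interval exactly 30). Translational and
radial motion use forward-Euler position updates. The tangential component
of circular and spiral motion is applied as an exact rotation by
`v_t * dt / e` radians — equal to the Euler step to first order in `dt` —
because pure Euler integration spirals dots outward at a rate proportional
to `(v/e)^2`, which becomes catastrophic near the center where `v/e`
diverges; the rotation conserves eccentricity exactly, as circular paths
must. Spiral motion mixes radial and tangential components at a fixed 45°
(configurable).

Dots older than 350 ms, and dots that exit the field, are respawned at
uniform-random positions with age zero and speed/size drawn from the laws at
the new position, keeping the dot count — hence the 0.04 dots/deg² density —
constant. Coherent conditions invert their global direction exactly at
multiples of 500 ms of stimulus time (the clock starts at 0 at clip onset,
so reversals align with trial-relative boundaries). The random condition
resamples each dot's direction (uniform on the circle — the "fly in a 3-D
box" collapsed to the 2-D domain) and speed (uniform in `[v_min, v_max]`)
at the same boundaries. Static scenes are frozen frames: zero velocities,
no aging.

Every stochastic operation takes an explicit integer seed, and each frame
derives its own stream from the clip seed, so clips are bit-reproducible.

```{r clip}
clip <- simulateFlowClip("radial", duration = 3, profile = p, seed = 7)
str(summarizeStimulus(clip))
```

## Experimental designs

The event-related run has 105 contiguous 3-s trials: 15 per condition for
seven conditions, 5 per speed tier for each stimulus condition, nulls as
consecutive triplets after every 18 non-null trials, task onset at the
beginning of the fifth volume (8 s at TR = 2 s), 162 volumes (324 s) in
total. "Pseudo-randomized order" is implemented as the weakest constraint
consistent with the phrase: no two consecutive trials share both condition
and speed tier, enforced by seeded rejection sampling. The original fixed
order is unrecoverable; only its constraints are reproduced.

Block localizers run 8 cycles of 16 s ON / 16 s OFF (256 s, 128 volumes).
The MT/MST+ localizers carry a 15°-diameter aperture centered 10° left or
right of fixation with 15 deg/s radial motion alternating in/out every 2 s.
The retinotopy design is periodic with 64-s cycles, 8 cycles per 512-s scan
(256 volumes), putting the stimulus at spectral bin 8 with harmonics at 16
and 24.

## Synthetic BOLD

The HRF is the canonical difference of gammas (delays 6/16 s, unit
dispersions, undershoot ratio 6, 32-s kernel), normalized to unit peak of
the *continuous* kernel on a 10-ms grid so the normalization does not depend
on TR. Regressors are onset boxcars convolved with this kernel on the same
10-ms grid and sampled at volume times; the simulator and the GLM share this
code path, which is what makes noiseless parameter recovery exact to machine
precision rather than approximate.

Noise is stationary AR(1) with marginal standard deviation `sigma` and lag-1
autocorrelation `rho`, plus a single low-frequency cosine drift whose period
(200 s by default) lies above the 128-s high-pass cutoff — deliberately not
inside the span of the discrete-cosine basis, so that testing the filter is
meaningful rather than trivial. Volumes plant spherical regions with known
per-condition amplitudes; per-voxel noise is independent (spatial smoothing
of real data is out of scope, so nothing in the chain depends on spatial
autocorrelation). Under a lateralized localizer design, a region with
`ipsilateralResponsive = FALSE` stays silent when the stimulated hemifield
matches its hemisphere — the ground truth that the MT/MST+ split must
recover.

## GLM estimation

The design matrix holds one regressor per stimulus condition (null/fixation
periods are the unmodeled implicit baseline, so condition betas are
amplitudes relative to fixation), `floor(2 T / 128)` orthonormal
discrete-cosine columns with periods above 128 s, and a constant.

Serial correlation is handled by two-pass prewhitening: OLS residuals give a
single pooled lag-1 autocorrelation for the whole run (the same correlation
structure is assumed at every voxel), the data and design are whitened with
it, and one correction step re-estimates the residual lag-1 correlation of
the whitened fit and adds it back before the final whitening. This is a
documented approximation to restricted-maximum-likelihood AR(1) estimation;
the tests verify that on AR(1) data with rho up to 0.4 the resulting t/F
statistics agree with a generalized-least-squares oracle using the true
covariance to within 2%.

F contrasts test joint nulls (the motion-vs-static map uses five rows, each
motion condition minus static). Voxelwise FDR control is Benjamini–Hochberg,
followed by removal of connected components smaller than the extent
threshold (10 voxels by default) under face connectivity (6-neighborhood;
18/26 are available — face connectivity is the conservative, deterministic
choice). Percent signal change is
`100 * beta * peak(unit single-trial regressor) / run mean`; PSC has no
universal definition, and this scaling — the peak of an isolated
unit-amplitude trial response against the run mean — is the package's
documented convention.

## ROI analysis and the MT/MST+ split

Peak-based regions collect masked voxels within 8 mm (Euclidean, world mm)
of each strict local maximum (26-neighborhood); voxels in range of several
maxima join the nearest, ties going to the larger statistic. Strictness
means flat plateaus yield no maxima — degenerate, but explicit.

The MT/MST+ rule: MST+ is the largest connected component of voxels active
under ipsilateral stimulation; MT is the largest component of
contralateral-not-ipsilateral voxels, trimmed of any voxel anterior to the
median anterior coordinate of MST+. "Anterior" is the world y axis by
default (configurable), measured in millimeters rather than slice indices —
the natural reading when regions are reported in world coordinates. An
empty ipsilateral mask raises an error rather than returning an empty
region: hemispheres without detectable ipsilateral responses are a real
outcome (the phenomenon occurs in a minority of hemispheres) and should be
signaled, not silently absorbed.

Regional profiles average the time series over the region's voxels first and
fit the GLM to the average. For a linear estimator this equals averaging
voxelwise estimates, which the tests verify numerically.

## The MC/MI coefficient

Per hemisphere, MC is the mean amplitude of the four coherent conditions and
MI the random-condition amplitude; the coefficient is the ratio MC/MI,
computed per hemisphere (ratio of means) and then averaged across
hemispheres (mean of ratios), summarized as mean ± SEM. Negative
coefficients are meaningful — they arise when random motion suppresses a
region below baseline — so ratios are never clamped; when |MI| falls below
5% of |MC| the profile is flagged numerically unstable instead. The
repeated-measures ANOVAs use the classical within-subject decomposition
(condition-by-subject interaction as error), with the 2 x k interaction
computed on between-region difference scores. Multiple-range post-hoc
testing is replaced by pairwise paired t-tests with Holm correction — the
legacy multiple-range procedure is deprecated and under-specified.

## Retinotopy

The periodic-response F ratio divides power at the stimulus frequency
(8 cycles/scan) by mean power over noise bins. Excluded from the noise band
are the 2nd and 3rd harmonics, and additionally the DC bin and the two bins
adjacent to the stimulus bin — the standard leakage guard; the degrees of
freedom are the conventional `(2, 2 * n_noise)` for one complex Fourier
coefficient against an averaged noise spectrum (a nonstandard alternative
phrasing of these dofs exists in the literature; the conventional form is
used). Response phase follows the Fourier sign convention in which a
response delayed by a quarter period has phase pi/2, minus a fixed,
configurable hemodynamic delay (5 s by default). Field sign is the sign of
the cross product of the polar-angle and eccentricity gradients (central
differences, one-sided at borders) on flat 2-D grids — the flattened-cortex
analog — with the sign convention anchored so the identity visual-field map
is +1 and its mirror −1. Linear phase progressions are summarized with a
circular slope estimator (mean wrapped phase increment) so that maps
crossing the 0/2pi boundary do not corrupt the slope.

## The parameter-recovery study

`recoverCoherence()` is the package's acceptance workhorse. For each
simulated hemisphere it generates six runs of the event-related design (six
scans per participant is the study protocol; each run has its own trial
order and drift phase), simulates 33 voxels per region — a 6-mm-radius
sphere on the 3-mm grid — with independent AR(1) noise (sigma 1 on a
baseline of 100, i.e. 1% noise against ~1% PSC responses; rho 0.3),
averages voxels, fits the prewhitened GLM, averages condition estimates
across runs, and computes MC/MI across hemispheres.

The planted amplitude table encodes the target coefficients exactly:
V6 0.70/0.25 = 2.8 (26 hemispheres), MST+ 0.715/0.50 = 1.43 (20), CSv
0.345/−1.50 = −0.23 (26; weak positive coherent response, strong
suppression by random motion). Run averaging matters statistically, not
just cosmetically: the hemisphere-level ratio estimator is a ratio of
noisy means, and with single-run noise against V6's small MI denominator
the mean-of-ratios acquires a visible upward bias; six-run averaging
shrinks the denominator noise to where the bias is negligible relative to
the printed SEMs.

What these recoveries do and do not show: they validate the estimation
chain (design, convolution, whitening, profiling, ratio statistics) under a
noise model with the right serial correlation and amplitude scale. They do
not emulate spatial autocorrelation, motion artifacts, physiological noise,
inter-subject amplitude variability, or registration error — conclusions
about real-data robustness are outside what passing tests can support.

## Numerical choices

* Root-finding tolerance for the speed-law calibration: `1e-12` on the
  log-scale parameter; quadrature is a 256 x 256 midpoint rule on one field
  quadrant.
* Age and reversal comparisons use a `1e-9` s guard so exact frame
  boundaries are classified deterministically.
* A fit whose OLS residual energy is below `1e-12` of the data energy skips
  whitening: an (all but) perfect fit carries no serial-correlation
  information, and the residual lag-1 coefficient of numerical noise is
  meaningless.
* In perfect fits, F is 0 where the contrasted effect is zero and Inf where
  it is not (0/0 resolved by the effect's magnitude).
* Problem sizes in the tests and acceptance study (3-s clips, 26/20/26
  hemispheres, 500 null simulations for test calibration, 5000 for the
  rm-ANOVA null) were chosen to keep each statistical check's Monte-Carlo
  error comfortably below the tolerance it is tested at.

## Known limitations

* The simulator's "3-D" is perceptual (speed/size gradients), not geometric.
* AR(1) with a single pooled rho is an approximation to full ReML noise
  modeling; higher-order serial structure is not modeled.
* Group-level inference is limited to regional repeated-measures ANOVA;
  voxelwise mixed-effects modeling and non-sphericity corrections are out
  of scope.
* Field sign operates on flat grids; cortical surface meshes are not
  handled.
* Spatial preprocessing of real data (slice timing, realignment,
  normalization, smoothing) is out of scope; inputs are assumed aligned.
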