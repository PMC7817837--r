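---
title: "Quantifying cytoplasmic fluidity and membrane-bleb kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytoplasmic fluidity and membrane-bleb kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Membrane blebs are spherical protrusions of the plasma membrane that
detach from the actin cortex, inflate under intracellular pressure, and
retract as the cortex reassembles. A bleb cycle is strongly asymmetric:
expansion is much faster than retraction. `blebkinetics` quantifies this
biology from time-lapse fluorescence microscopy along three axes:

1. **Cytoplasmic fluidity** — single-particle tracking of bright point
   probes (quantum dots) and estimation of the diffusion coefficient from
   the mean square displacement (MSD);
2. **Bleb kinematics** — radial contour profiles of a segmented cell,
   expansion/retraction ("tricolor") maps, bleb morphometrics, and
   annotation of the phases of the bleb cycle;
3. **Reporter quantification** — bleb vs cell-body intensity ratios,
   reference normalization, kymographs, and puncta counting.

Because no reference movies ship with the package, a first-class
synthetic-data module generates every input with known ground truth, and
all validation is performed against that ground truth.

## The synthetic generators and what they emulate

`simulate_brownian_tracks()` produces 2-D Brownian motion with
region-dependent diffusivity: per frame, each particle takes independent
Gaussian steps of per-axis variance $2 D \Delta t$, with $D$ looked up
from the region containing the particle at the start of the step
(sub-step crossings are ignored; at $\Delta t = 20$ ms the step is small
against region geometry). The default calibration matches quantum-dot
imaging: 0.1 µm/px and 20 ms frames (50 Hz). Boundaries reflect by
default, keeping the particle count constant as cytoplasmic probes do.

`render_particle_movie()` draws each particle as an isotropic Gaussian
(the point-spread function, default $\sigma = 0.15$ µm) and applies a
standard sCMOS noise model: Poisson shot noise on the expected-photon
image, then linear gain, then additive Gaussian read noise, then
quantization to the bit depth. Spot brightness and background default to
500 and 10 photons (signal-to-background ≈ 50); real spot densities and
SNR are acquisition-dependent, so both are plain parameters.

`simulate_bleb_movie()` renders a circular cell of radius $R_0$ carrying
one scripted bleb: a raised-cosine angular bump
$\mathrm{bump}(\theta) = \tfrac12 (1 + \cos(\pi \theta / w))$ of
half-width $w$, with contour
$r(\theta, t) = R_0 + A(t)\,\mathrm{bump}(\theta)$. The amplitude
schedule $A(t)$ is piecewise linear — expansion at $v_{exp}$, plateau,
retraction at $v_{ret}$ — and the scripted defaults keep
$v_{exp} = 5\,v_{ret}$, reproducing the expansion/retraction asymmetry
of real blebs. Bleb movies default to 2000 ms frames, the seconds-scale
of bleb cycles. The generator returns the mask movie, per-channel
fluorescence with scripted bleb/body contrasts, and three ground truths:
the contour series, the tricolor label map, and the contrast time
course. Ground-truth tricolor labels threshold the *true* radial
velocity $A'(t)\,\mathrm{bump}(\theta)$ rather than $A'(t)$ alone —
bins near the bump edge barely move and are genuinely stationary.

What the generators do **not** emulate: quantum-dot blinking, motion
blur, 3-D motion and projection, cell translation or rolling,
non-star-convex shapes, photobleaching, and spatially varying
background. Passing tests therefore demonstrate correctness of the
computations under the stated model, not robustness to every artifact
of live-cell data.

## Particle tracking

Detection follows the classic two-stage recipe. `log_filter()` convolves
each frame with a negated, scale-normalized ($\times \sigma^2$)
Laplacian-of-Gaussian kernel, so bright blobs of radius $\approx
\sigma\sqrt2$ px become positive peaks; the second-derivative factor is
zero-summed, so constant and (interior) affine images map to zero. The
kernel separates as $g''\otimes g + g \otimes g''$ and is applied as
four banded sparse-matrix products with replicate borders.

`find_maxima()` keeps 8-connected local maxima whose topographic
**prominence** — height above the highest saddle connecting them to
dominating terrain, computed by flood descent with a union–find —
exceeds a threshold. The default threshold is $5 \times$ the robust
noise SD of the response ($1.4826 \times \mathrm{MAD}$). Exact ties are
ordered by column-major index: of two equal peaks, the later one is
measured at the connecting saddle, and equal-value plateau maxima
collapse to a single detection at the plateau centroid. Accepted maxima
are refined to sub-pixel positions by an intensity-weighted centroid
over the 3×3 response neighborhood (negative weights clamped to zero);
refinement is switchable off.

Frame-to-frame correspondence uses the **stable marriage** algorithm:
detections rank opposite-frame candidates within a gate radius by
ascending distance (ties by index), and deferred acceptance with the
earlier frame proposing returns the proposer-optimal stable matching —
no unmatched-together pair prefer each other over their partners. The
gate defaults to $5\sqrt{2 D_{max} \Delta t}$, five per-axis step SDs.
Pairwise links are chained into maximal paths with **no gap closing**: a
missed detection terminates its track, and trajectories shorter than 10
frames are discarded as noise. Coordinates are 0-based
$(x, y) = (\mathrm{col}, \mathrm{row}) \times$ pixel size, and all
linking distances are in µm.

## Motion statistics

For each track the package reports the cumulative frame-to-frame
distance over a 30-frame window (600 ms at 50 Hz), the mean speed
(distance over 29 intervals), and a speed class — FAST above 3.3 µm/s,
INTERMEDIATE in (1.6, 3.3], SLOW at or below 1.6 µm/s; the classes
partition $[0, \infty)$. Velocity histograms use left-closed 0.02 µm/s
bins from zero. Note that a probe at $D = 0.005$ µm²/ms walks ≈ 16 µm of
cumulative path per 600 ms window (mean Rayleigh step
$\sqrt{\pi D \Delta t} \approx 0.56$ µm), a windowed speed near 28 µm/s,
so on such synthetic data every track is FAST; the class boundaries
separate slower subpopulations in heterogeneous real data.

The time-averaged MSD uses all overlapping pairs,
$\mathrm{msd}(n\Delta t) = \langle |r_{i+n} - r_i|^2 \rangle_i$, up to
half the track length by default — so the standard 10-lag fit range is
available on 30-frame windows. Ensemble curves weight each track's
per-lag mean by its pair count. `fit_diffusion_coefficient()` runs OLS
of the ensemble MSD against lag with a **free intercept** (absorbing the
static localization-error offset) and reports $D = \mathrm{slope}/4$,
the 2-D Einstein relation ($\mathrm{MSD} = 4 D \tau$); the raw-slope
convention is available via `d_from = "slope"` for comparison with
analyses that leave the divisor implicit.

Two fit-range conventions coexist deliberately. The package default
fits 10 lags. The reference recovery experiment
(`qd_tracking_experiment()`) instead fits `floor(n/4)` lags — the
quarter-track guidance — because on 30-frame tracks the high-lag MSD
values are noisy and strongly correlated, and including them inflates
the sampling SD of $\hat D$ from ≈ 5% to ≈ 6.5% per 100-track replicate
without reducing bias. The experiment also seeds particles a 40 px
margin inside the reflecting field edge: tracks that feel the boundary
have suppressed MSDs, and with edge-to-edge seeding this biases
$\hat D$ several percent low — confinement, not estimator error.

## Bleb kinematics

`extract_contour_series()` reduces each binary mask to a radial profile
$r(\theta_j, t)$ along 360 rays from a common origin, sampling at
quarter-pixel steps and taking the farthest foreground hit
(star-convexity is assumed; violating frames are flagged and measured
by the farthest-intersection rule). The origin is the centre of mass of
the **always-foreground core** — the stable cell body — rather than the
per-frame centre of mass: a per-frame centroid recoils toward a growing
bleb, which both dilutes the apex velocity (measured 0.22 µm/s for a
scripted 0.30 µm/s expansion) and injects spurious retraction labels
into bins on the far side of the cell. The per-frame convention remains
available (`centroid = "per_frame"`).

`radial_velocity()` central-differences $r$ over time per bin;
`tricolor_map()` classifies each (frame, bin) cell as EXPAND
($v > $ threshold, red), RETRACT ($v < -$threshold, blue) or STATIONARY
(white), with the threshold defaulting to 0.02 µm/s — one histogram
bin. Label/velocity consistency is structural: it is asserted on every
map the tests touch.

`detect_bleb_events()` subtracts a per-bin resting radius and finds
maximal spatiotemporal regions (8-connected, circular in $\theta$)
where the residual exceeds 0.5 µm over at least 5°. The resting radius
is the per-bin temporal **2nd-percentile** of $r$: blebs only protrude
outward, so the resting value is essentially the temporal minimum, and
a low quantile keeps one aberrant frame from defining it. (A median
baseline fails outright whenever one cycle spans more than half the
movie — it halves the recovered amplitude and splits events.) Per-frame
event amplitude is the maximum residual over active bins; area is the
polar integral $\sum \tfrac12 (r^2 - r_0^2)\,\Delta\theta$.

`annotate_phases()` splits an event into EARLY_EXPANSION (onset to
maximum), LATE_EXPANSION (maximum to retraction onset),
EARLY_RETRACTION (until the amplitude first falls below 80% of the
maximum) and LATE_RETRACTION (the rest). The retraction onset — the
contour-motion stand-in for cortex reassembly — is the first
post-maximum amplitude drop that is **never recovered** later in the
event. A fixed run of consecutive decreases is not robust here: on
mask-derived contours a slow retraction (0.02 µm/s is 0.4 px/frame)
descends in sub-pixel staircases, so three strict decreases in a row
either never occur or first occur far from the true onset, while the
never-recovered criterion also ignores single-frame segmentation
glitches. Expansion and retraction velocities are mean amplitude slopes
over the respective phases; scripted kinematics land phase changes on
frame boundaries, so recovery is exact up to contour quantization.

## Intensity quantification

`roi_ratio_series()` computes background-subtracted mean intensities in
user-supplied bleb and cell-body ROIs and their ratio; the background is
the mean of an extracellular ROI when given. The ratio is invariant
under global gain by construction. `normalize_to_reference()` divides a
reporter series by a reference channel (e.g. a calcium reporter by a
membrane marker) to cancel volume and membrane-density confounds.
`build_kymograph()` samples a movie along a polyline at one-pixel arc
steps, averaging across a perpendicular width, one column per frame.
`count_puncta_in_blebs()` reuses the particle detector (same LoG +
prominence operators, single frame) to count proximity-ligation-style
puncta per bleb mask, classifying each bleb EXPANDING or RETRACTING by
whether its cortex-marker mean lies below or above the across-bleb
median — one spot model throughout the package.

## Numerical choices and degenerate inputs

* Exact detection ties (plateaus) produce one detection at the plateau
  centroid; linking ties break by ascending detection index; the
  proposer side is the earlier frame. All three choices exist for
  determinism and are documented rather than load-bearing.
* A degenerate all-zero MSD yields $D = 0$ with a `degenerate` flag
  instead of an error; a monotone (never-retracting) amplitude profile
  yields truncated phases with a `truncated` flag, and asking for its
  retraction velocity errors.
* Empty detection lists, empty events, and empty histograms are valid
  empty results; empty mask frames and non-positive body means are
  errors that name the offending frame.
* All simulation randomness flows through explicit integer seeds; with
  a fixed seed every generator is bit-reproducible, and
  `run_pipeline()` derives per-stage seeds from the single config seed
  so a rerun reproduces the manifest checksums.

## Validation scales

The test suite validates the full chain at the scale of the reference
analyses: 50 seeded replicates of the 100-track × 30-frame recovery
experiment (every replicate within 15% of the true $D$, mean bias below
5%), 20 replicates of a two-region field with a 4-fold diffusivity
contrast (correct ordering in at least 95%), 1,000 random linking
instances certified blocking-pair-free with a 200-instance exhaustive
enumeration cross-check, a 3×3 grid of scripted bleb kinematics
(amplitude and velocities within 10%, the 80% boundary within ±1
frame), ≥ 95% tricolor agreement off phase boundaries, and scripted
fluorescence contrast recovered within 5% under camera noise. These
problem sizes keep the whole suite to a few minutes while leaving the
Monte-Carlo error well inside each tolerance.

## Known limitations

* No gap closing: a single missed detection splits a track, biasing
  track-length statistics at low SNR (the minimum-length filter then
  discards both halves).
* The radial representation cannot describe overhanging (non-star-convex)
  bleb necks; such frames are flagged, not corrected.
* Diffusion estimation assumes free diffusion over the fitted lags;
  confined or directed motion will bias $D$ (no anomalous-exponent
  fitting, by design).
* The bleb/body ROIs for ratio analyses are user input, as in the
  hand-drawn originals; no automatic ROI proposal is attempted.
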