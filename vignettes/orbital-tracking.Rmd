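---
title: "Orbital tracking: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orbital tracking: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitrack)
```

This vignette records the physical model behind the simulator, the
estimators of the tracking engine and the analysis pipeline, and the design
decisions taken where the measurement scheme leaves freedom. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The physical model

The excitation/detection volume is a lateral Gaussian beam of 1/e² radius
`w_xy` combined with a Gaussian axial envelope of half-width `w_z`. Two
detection planes sit at ±Δz/2 around the orbit focal plane, so a point
emitter at lateral distance ρ from the beam axis and height z contributes

$$R_p = B\,e^{-2\rho^2/w_{xy}^2}\,e^{-2(z - z_p)^2/w_z^2},\qquad
  z_{1,2}=\pm\Delta z/2,$$

photons per orbit to plane *p*, where `B` is the emitter brightness
(photons/orbit/plane for a centred emitter before axial attenuation).
Extended emitters — mitochondria are roughly 0.7 µm lines — are uniform
rows of sub-emitters integrated by the midpoint rule (33 points by default;
the quadrature error is < 0.2 % against adaptive integration, tested).

**Defaults.** `w_xy` = 300 nm, `w_z` = 700 nm, Δz = 1000 nm, orbit radius
r = 150 nm, 16 sectors, 5 ms orbits with a dark-orbit factor of 2 (100 Hz
effective sampling). The instrument that motivates the package does not
publish its beam geometry, so these values were chosen once to represent a
high-NA confocal and to make both calibration curves strictly monotone over
the stored ranges; every one of them is a constructor argument
(`psf_model()`, `orbit_config()`) and they are never adjusted per analysis.
Useful identities for this geometry: the sector pattern of a displaced
point emitter is ∝ exp(κ cos φ) with κ = 4dr/w²<sub>xy</sub>, so the lateral
modulation is the Bessel ratio I₁(κ)/I₀(κ) — strictly increasing in d — and
the axial contrast is exactly tanh(2Δz·z/w_z²), monotone everywhere.

During a sector the beam moves along the arc; sector means average the
point response at 5 equally spaced arc positions. Against a 2000-point
quadrature the total per-orbit response agrees to < 0.1 % (tested as the
photon-conservation property). Counts are Poisson; background is a
constant Poisson rate per plane. Bleaching multiplies the brightness by
exp(−bleach_rate) per illuminated orbit.

## 2. Localization and the feedback loop

The two planes are summed for lateral localization; the first-order
Fourier coefficients are computed as direct DFT sums at the sector midpoint
angles (for 16 bins this is the FFT output, written out). The calibration
tables map Mod<sub>xy</sub> → d/r on a 257-node grid over 0…1.5 r, and
Mod<sub>z</sub> → z/Δz over ±0.75 Δz; retrieval is binary search plus
linear interpolation (`stats::approx`). Noiseless round-trip error is below
max(1 %, 1 nm) laterally and 5 nm axially over the stored ranges (tested;
with these defaults it is dominated by grid interpolation, ≪ 1 nm).
Modulations beyond the stored range are clamped to the end of the table and
flagged — the particle is near the orbit edge and the next feedback step
pulls it back.

The feedback loop moves the orbit centre onto each estimate. Below the
count threshold the tracker probes an Archimedean spiral (pitch = r per
turn, 16 probes per turn, configurable) around the loss point and declares
the particle lost beyond 5 µm. Lateral galvo offsets beyond 10 µm are
absorbed by the sample stage with a per-axis dead time (63 ms x, 35 ms y)
during which no records are produced; sample-fixed coordinates
(stage + galvo) remain continuous across the event (tested). With a
dark-orbit factor of 1 the first sector of each orbit still uses the
previous centre ("on-the-fly" update); with dark orbits interleaved the
update is clean.

**Extended emitters.** The first-order coefficients read the
*excitation-weighted* centre of mass. For extension perpendicular to the
displacement the weighting is symmetric and the off-centre estimate matches
the point emitter within 2 % up to ~2/3 of the orbit diameter; parallel to
the displacement the weighting genuinely drags the apparent centre toward
the beam (up to tens of per cent at 80 nm offset for a 300 nm emitter).
This is not an estimator artefact: at the closed-loop fixed point the
weighting is symmetric again and the bias vanishes, which is why dynamic
tracking of a 600 nm emitter recovers an imposed ±2 µm sinusoid with a
residual below twice the point-emitter value (acceptance suite) while
static off-centre snapshots differ.

## 3. Motion-state segmentation

Step angles φₜ = atan2(Δy, Δx) are correlated in a sliding 64-sample window
and reduced by averaging lags 0.03–0.06 s (samples 3–6 at 100 Hz). Two
functional forms are shipped: the default cosine statistic
⟨cos(φ_s − φ_{s−τ})⟩, bounded in [−1, 1], reaching 1 for persistent
direction and 0 for isotropic noise, and the literal raw product
Σφφ/(n−τ) kept for comparison — the raw form cannot approach 1 for motion
along the axon axis (φ ≈ 0), so it is not the default.

**Positions are smoothed (5-point running mean, 50 ms) before the angle
series is formed.** This is the one place the package deliberately
re-orders the published recipe: at 100 Hz with ~5 nm noise, a slow
organelle moves 3–8 nm per sample, so unsmoothed step angles are noise-
dominated and the reduced correlation of directed motion stays below any
usable threshold (0.06–0.37 for 0.3–0.8 µm/s; measured during development).
After 50 ms smoothing the adjacent-position difference equals the
displacement over 5 samples with √2·σ/5 noise, the statistic reaches
0.7–0.97 for the same speeds, and the randomized threshold lands near 0.3 —
the regime in which the published qualitative claims (correlation
"approaches one", threshold ≈ 0.30, > 90 % correct assignment) are actually
reproducible. Kinematics are computed on the same smoothed positions.

The threshold is per-trajectory: the angle array plus its sign-reversed
copy is permuted (10 shuffles pooled, seeded), the same reduction applied,
and mean + 5 s.d. taken. The binary assignment is shifted back by half the
window, and active runs shorter than 150 ms (twice a recentering dead
time) are relabelled stationary. Note the null is conservative for
strongly directed trajectories: the cosine statistic of a shuffled
direction-dominated angle array retains a positive mean (≈ ρ², ρ the mean
resultant), so thresholds are higher for nearly-unidirectional tracks and
short slow phases embedded in such tracks may be absorbed into pauses.
The acceptance conditions (balanced directions, 0.4–3 s phases) measure
~97 % per-sample agreement; the package reports the threshold it used so
conservative segmentations are visible.

**Classification.** Phase direction is the sign of the net x displacement
(anterograde = +x by the mounting convention; a per-trajectory orientation
flag can flip it). Velocities of the dominant direction are fitted with a
two-component Gaussian mixture by EM (k-means initialisation, 10 restarts,
best likelihood kept); the class boundary is the mean of the centres. The
fit is declared degenerate when the centres are closer than twice the
larger sigma — the standard condition for two resolvable modes. A laxer
half-sigma rule was tried first and failed to flag a single Gaussian,
whose two-component EM fit typically lands ~1.2 σ apart. Degenerate fits
assign
all phases to the slow class with a warning. Phases of the non-dominant
direction are slow by construction (fast transport is unidirectional per
trajectory).

**Statistics.** Per-state sets are partitioned into 10 equal random
subsets (seeded); durations and displacements get exponential ML decay
constants, velocities Gaussian centres, and the parameter is reported as
mean ± s.d. across subsets, which also feed two-sided t-tests between
states. "Bins" could equally have meant histogram bins; random partitions
were chosen because replicate fits are what a t-test between conditions
needs. Orbit-displacement histograms are fitted by a single Gaussian
directly. Pauses between consecutive active phases are classed by their
flanking speed classes and fitted mono-exponentially; a terminal
stationary stretch is not a pause.

## 4. Wide-field pipeline

Moving objects are removed by the forward difference at lag 10 frames
(5 s at 2 Hz), clamped to negative changes; the final 10 frames have no
forward difference and are dropped (the published recipe is silent about
them). Consequence worth knowing: an organelle that pauses *longer than
the lag* is — correctly — stationary for this filter and will merge with
any resting object it touches; synthetic validation therefore measures
detector accuracy at sites the mover transits without such pauses.

Mean images are computed per segment between recentering events, the
segment after the last event being discarded (kept when there are no
events). Detection smooths with a 5×5 boxcar, binarizes at µ + 5σ of the
full smoothed frame (whether the original used masked-region statistics is
unknowable; full frame is implemented and flagged), masks a 51 × 11 px
corridor around the trajectory (a dilated polyline with half-widths 25 and
5 px, so a non-x-aligned trajectory still carries its corridor), and labels
connected components (EBImage). Centroids are intensity-weighted; lengths
are the half-maximum span of the component's intensity profile along its
principal axis — a raw binary extent would systematically include the
~2–3 px blur-and-threshold halo, while the half-maximum crossing sits at
the true edge of a plateau profile independent of blur width. On rendered
scenes with SNR ≥ 10 this yields ≤ 1 px centroid and ≤ 2 px length error
(tested over 25 random scenes).

The camera-to-tracking map is a pair of second-order bivariate polynomials
least-squares fitted to ≥ 12 (recommended 25) control points; occupancy
classifies each sample by whether it lies within 500 nm (configurable; the
original number is unpublished) of a resting object's axonal extent;
crossing-time profiles accumulate dwell per 100 nm bin and flag 1 µm bins
exceeding 10 s per trajectory. Default pixel size is 135 nm (the published
photoactivation raster pitch; the camera's own pitch is not printed).

## 5. The synthetic generators

`motion_params_invivo()` encodes the measured kinematics of axonal
mitochondria at 25 °C: Gaussian speeds 0.62 ± 0.09 (fast) and 0.36 ± 0.08
µm/s (slow) anterograde, 0.76 ± 0.08 and 0.42 ± 0.11 retrograde; fast
durations ~2.5 s, slow ~0.45 s (truncated normals), exponential pauses
(mean 2.5 s); fast motion in a single direction per trajectory and no
fast↔fast reversals. `motion_params_uniform()` is the validation regime:
speeds uniform in 0.3–0.8 µm/s, directed durations 0.4–3 s, stationary
gaps 1–5 s, 5 nm lateral noise — the conditions under which the
segmentation accuracy is scored. The generators produce straight-axon
motion with white localization noise; they do not emulate curved axons,
heartbeat oscillations (screened separately by `qc_heartbeat`), correlated
tracking noise, or photophysics beyond exponential bleaching — passing
tests bound algorithmic correctness, not biological variability.

The wide-field renderer draws resting and moving organelles as
Gaussian-blurred line segments (σ 120 nm) on a Poisson + read-noise
camera at 135 nm/px and 2 Hz, shifting the field of view at recentering
events. Problem sizes throughout the suite (60 s trajectories, 96–128 px
frames, 20-trajectory acceptance batches) were chosen as the smallest
scales at which the measured quantities are statistically stable.

## 6. Known limitations

* The PSF geometry is an assumption; absolute precision numbers (e.g.
  "< 3 nm at 200 photons") depend on it and are deliberately checked only
  as a shot-noise scaling law (std ∝ N^(−1/2)), not as absolute values.
* The randomized-null threshold is conservative on nearly unidirectional
  trajectories (Section 3); slow 0.45 s phases inside long fast runs can
  be under-segmented there.
* The segmentation cannot detect direct fast↔slow switches without an
  intervening pause, by construction of the active/stationary statistic.
* `remove_moving` classifies pauses longer than its lag as stationary
  signal; object tables inherit that ambiguity at long pause sites.
* No astigmatism, aberrations, vectorial PSF, EMCCD gain-register noise,
  or axial stage recentering are modelled.
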