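# orbitrack

Simulation and analysis of feedback-based 3D orbital single-particle
tracking, built around the measurement scheme used to follow single
mitochondria through vertebrate axons with nanometre precision at 100 Hz.

## The measurement and the analyses

**Orbital tracking.** A focused laser circles the particle of interest on an
orbit of radius r (here 150 nm) while photon counts are accumulated in 16
angular sectors and in two confocal detection planes placed equidistantly
above and below the focal plane. Expanding the sector counts in a Fourier
series

&nbsp;&nbsp;I(φ) = a₀/2 + Σₖ (aₖ cos kφ + bₖ sin kφ)

only the zero- and first-order coefficients matter for localization: the
particle sits at angle φ = atan2(b₁, a₁) and radial distance
d_r = r · f(Mod_xy) with Mod_xy = √(a₁² + b₁²)/a₀, while the axial offset is
d_z = Δz · g(Mod_z) with Mod_z = (I₁ − I₂)/(I₁ + I₂). The scaling functions
f and g are calibration look-up tables generated by simulating noiseless
orbits and inverted at run time by binary search with linear interpolation.
The feedback loop re-centres the orbit on every estimate, interleaves dark
orbits to limit photobleaching (one illuminated + one dark 5 ms orbit =
100 Hz effective sampling), falls back to an Archimedean search spiral when
the count rate drops below threshold, and hands the accumulated galvo offset
to the sample stage whenever it exceeds 10 µm (long-range recentering, with
a 35–63 ms per-axis dead time).

**Motion-state analysis.** Trajectories are segmented into active transport
and stationary phases by autocorrelating the lateral step angle
φₜ = atan2(Δy, Δx) in a sliding 64-sample window,
Cor(t, τ) = ⟨cos(φ_s − φ_{s−τ})⟩, reduced by averaging the lags
τ = 0.03–0.06 s. The statistic approaches 1 for directed motion and 0 for
isotropic noise; the active/stationary threshold is the mean + 5 s.d. of the
same statistic on a sign-augmented, randomized copy of the angle array.
Active phases are assigned anterograde/retrograde by the sign of their net
axial (x) displacement, and the phase-velocity histogram of the fast
direction is fitted by a two-component Gaussian maximum-likelihood mixture;
the mean of the two centres separates the fast from the slow transport
state, giving five states in total (fast/slow × antero/retro + stationary).
Pause durations, state transitions and per-state statistics (10-subset
replicate fits) complete the trajectory analysis.

**Wide-field colocalization.** The simultaneously acquired 2 Hz wide-field
movie is cleared of moving objects by the forward-difference rule
ΔI(x,y,t) = I(x,y,t+10) − I(x,y,t), kept only where negative, and
I_stationary = I + ΔI; segment-wise mean images (between recentering
events) are smoothed (5 px boxcar), thresholded at µ + 5σ, masked to a
51 × 11 px corridor around the mapped trajectory, and connected components
give the positions and lengths of resting mitochondria. Camera pixels map
to tracking coordinates through a second-order polynomial fitted to ≥ 25
control points. Occupancy fractions (time in each motion state with/without
a resting mitochondrion nearby) and 100 nm crossing-time profiles relate
pausing behaviour to these obstacles.

A full physical simulator — Gaussian-beam PSF, Poisson sector counts,
extended (line) emitters with bleaching, a five-state saltatory motion
generator and a synthetic wide-field renderer — provides ground truth for
every stage.

## Worked example

```r
library(orbitrack)

psf <- psf_model()                       # w_xy 300 nm, w_z 700 nm, Δz 1 µm
cfg <- orbit_config()                    # r 150 nm, 16 sectors, 5 ms orbit, dark orbits

truth <- generate_state_trajectory(motion_params_uniform(), duration = 60, seed = 42)
raw   <- run_tracking(truth, psf, emitter(brightness = 500), cfg, seed = 43)
seg   <- segment_trajectory(raw, seed = 1)
ph    <- classify_phases(extract_phases(seg$active, raw), seed = 1)

nrow(raw)                                # 6000 orbits at 100 Hz
as.numeric(seg$threshold)                # 0.229  (randomized 5-sigma threshold)
mean(seg$active == truth$active[match(round(raw$t_s, 3), round(truth$t_s, 3))])
                                         # 0.887  (agreement with ground truth)
ph[1:3, c("direction", "displacement_um", "velocity_um_s")]
#   direction displacement_um velocity_um_s
# 1    antero           2.119         0.754
# 2    antero           1.022         0.555
# 3     retro           1.370         0.646
```

The tracker follows the 60 s ground-truth walk at ~500 photons per orbit;
`segment_trajectory` separates directed phases from pauses at the
trajectory's own randomized threshold, and each active phase carries its
direction, lateral displacement and mean velocity. With the noiseless
study conditions of the validation protocol (5 nm position noise instead
of full closed-loop tracking noise) the per-sample agreement rises to
~97 %.

The same functions drive the thin command-line wrapper:

```sh
Rscript inst/cli/orbitrack.R simulate   --out run1 --seed 5
Rscript inst/cli/orbitrack.R segment    --out run1_seg run1/raw_trajectory.tsv
Rscript inst/cli/orbitrack.R colocalize --traj run1_seg/raw_trajectory_labeled.tsv \
        --movie run1/widefield.tif --out run1_coloc
```

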