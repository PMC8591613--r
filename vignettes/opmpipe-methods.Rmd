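---
title: "Recovering auditory evoked fields from moving OPM wearers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering auditory evoked fields from moving OPM wearers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Optically pumped magnetometers (OPMs) are wearable magnetic field sensors:
unlike cryogenic MEG, the array moves with the head, so participants can
stand and move during a recording. The price is interference. Even a
degaussed, OPM-optimised magnetically shielded room retains a remnant static
field of order 1.5 nT with a spatial gradient that steepens away from the
room centre. When a standing participant translates the head by a metre and
rotates it by more than a hundred degrees, each moving sensor samples this
static field along its trajectory, producing artefacts of hundreds of
picoTesla — three to four orders of magnitude above the 50–150 fT auditory
evoked fields (AEFs) of interest, and overlapping them below ~6 Hz.

`opmpipe` implements, end to end, a processing chain that recovers the AEF
under these conditions: optical motion-capture processing into a rigid-body
pose series; a sensor-space interference-suppression cascade (windowed
motion regression, homogeneous field correction, spectral interpolation,
zero-phase filtering, automated artefact rejection); and an LCMV beamformer
scanning symmetric dipole pairs. Because raw recordings of this kind are not
publicly deposited, the package pairs the analysis chain with a fully
ground-truth-annotated synthetic generator, so that every claim the pipeline
makes can be checked against known inputs.

## The synthetic recording model

Each channel measures the projection of the local field onto its unit
sensitive axis. For channel $c$ with head-frame position $p_c$ and axis
$a_c$, under head pose $(R_t, T_t)$:

$$y_c(t) = \big(R_t a_c\big)^\top \big[B_0 + G\,(R_t p_c + T_t - o)\big]
  + L_c(\text{sources}) s(t) + \text{lines}(t) + \varepsilon_c(t)$$

* **Room field.** $B(x) = B_0 + G (x - o)$ — affine, with $|B_0| = 1.5$ nT
  and a gradient whose largest singular value is 5 nT/m (a 10 cm step along
  the steepest direction changes the measured field by 500 pT). The real
  remnant field is nonlinear in space; the affine model is the minimal one
  that produces motion artefacts, makes them nonlinear in the rotation
  angles (so linear motion regression is deliberately imperfect), and makes
  the rotated projection of $B_0$ exactly spatially uniform across the
  head-fixed array (so homogeneous field correction has a well-defined
  target). This is a documented stand-in, flagged as such.
* **Sensors.** 45 dual-axis magnetometers (90 channels) on a Fibonacci
  lattice over the upper scalp hemisphere of a 9 cm sphere, one radial and
  one tangential axis each, white noise 15 fT/√Hz, optional ±5.56 nT
  dynamic-range clipping (off by default: range exceedance is data loss,
  not a modelling target).
* **Neural sources.** A mirror-symmetric pair of tangential current dipoles
  in the supratemporal plane, fully correlated across hemispheres, with a
  causal M50/M100/M200 waveform (Gaussian deflections at 50/100/200 ms,
  alternating polarity, M100 largest). The moment scale is set so the
  strongest sensor-level deflection lies in the canonical 50–150 fT AEF
  range (the default projects to ~92 fT).
* **Line interference.** 50 Hz mains harmonics plus the 120 Hz and 83 Hz
  lines of an optical motion-capture system, each coupled through a fixed
  random uniform field direction.
* **Motion.** Band-limited Gaussian pose noise per degree of freedom,
  synthesised in the frequency domain with a steep (8th-order magnitude)
  envelope, scaled to requested per-DOF ranges and starting at the identity
  pose. The moving preset requests ranges of (1.0, 0.5, 1.15) m and
  (110, 150, 180)°, with a 0.04 Hz bandwidth: this joint choice reproduces
  both metre-scale total excursions and the ~3–5 cm of movement per 0.5 s
  trial typical of deliberate continuous head movement. The steep spectral
  envelope matters: against a nanoTesla room field, even $-100$ dB spectral
  skirts in the pose series would masquerade as broadband magnetic
  interference that no real head movement produces. Pitch is kept within
  ±85° so the yaw–pitch–roll parameterisation stays in its principal branch.
* **Markers.** Six retro-reflective markers rigidly attached to the helmet,
  tracked at 120 Hz, with per-marker independent occlusion gaps drawn from a
  truncated exponential (moving preset: 8.9% occluded, 29 ms mean,
  1.24 s maximum).

What the generator does *not* emulate: nonlinear room-field structure,
sensor calibration drift and cross-axis errors, cardiac and ocular
biomagnetism, vibration-borne marker noise, and broadband mechanical
artefacts (cable rubbing is only represented by the artefact detector's
test hooks). Passing tests therefore demonstrate the pipeline's correctness
and its behaviour under the stated interference model — not performance on
any real recording. One visible consequence: the synthetic artefact is
nearly band-limited below ~1 Hz, so the 2 Hz high-pass alone removes more of
it than in real data, and the ablation grid (± motion regression × ± HFC)
shows smaller differences between branches than a real system would.

## Motion processing

Occlusion gaps are filled in three passes: pattern-based (solve the rigid
pose from any ≥3 visible markers by orthogonal Procrustes and place the
occluded markers from the template), then per-marker cubic splines for
remaining gaps up to 100 samples (0.83 s at 120 Hz) with data on both sides
— gaps touching the record edge are reported, never extrapolated — then
pattern-based again. Marker trajectories are low-pass filtered at 2 Hz
(4th-order Butterworth, bidirectional) *before* rigid-body solving, and the
pose is solved per frame by the Kabsch algorithm with a proper-rotation
correction. Euler angles are intrinsic yaw (about the down-up axis) →
pitch (right-left) → roll (back-forward), in degrees, unwrapped over time;
the convention is documented because different vendors differ.

Trajectory filtering uses quadratic-extrapolation padding rather than the
odd-reflection padding used for recordings: pose series are smooth and
slow, and reflection padding leaves edge transients of a few millidegrees
that — multiplied by nT/degree regression coefficients — would inject
spurious high-frequency field changes.

Kinematic summaries report per-DOF ranges, 50-bin histograms, and the
per-trial maximal Euclidean displacement relative to each trial's first
sample (so still data give exactly zero).

## The interference-suppression cascade

The canonical stage order, each stage appending itself to the recording's
history:

1. **Downsample** to 1000 Hz (zero-phase anti-alias low-pass at 40% of the
   target rate, integer decimation).
2. **Windowed motion regression** (moving condition only): per 10 s window
   (50% overlap, cosine-squared cross-fade recombination), each channel is
   regressed on an intercept plus the six rigid-body DOFs and the fit is
   subtracted. Windows whose regressors are near-constant fall back to the
   intercept and are flagged — this is why the still presets skip the stage
   entirely: regressing tracking data into still recordings only injects
   tracking noise.
3. **Homogeneous field correction (HFC)**: with $A$ the channels × 3 matrix
   of sensitive-axis orientations, subtract $A\,\mathrm{pinv}(A)\,y$ per
   sample. On a 90-channel dual-axis whole-head array the uniform-field
   basis captures interference while leaving ≥90% of a dipolar topography's
   energy intact. Only the 3-column uniform basis is used; gradient and
   higher spherical-harmonic extensions are out of scope.
4. **Spectral interpolation** of 50 Hz harmonics and the 120/83 Hz camera
   lines: amplitudes within ±0.5 Hz of each target are replaced by the mean
   amplitude of the 1 Hz flanking bands, phases kept — avoiding notch-filter
   ringing.
5. **Zero-phase Butterworth filters**: high-pass 2 Hz order 5 before
   artefact detection; low-pass 40 Hz order 6 after it (so high-frequency
   artefacts remain visible to the detector).
6. **Automated artefact-segment rejection** in 5 s chunks: (i) any channel
   range > 100 pT; (ii) high-frequency envelope outliers (z > 5 against the
   channel's across-chunk median, MAD floored at 5% of the median so that
   near-identical clean chunks cannot produce spurious z-scores);
   (iii) cross-channel median absolute step outliers. Reason codes are
   recorded. Criteria (ii)–(iii) are automated stand-ins for visual
   inspection; thresholds are configuration keys.
7. **Epoching** into [−0.2, 0.5) s trials, baseline −0.1–0 s, trials
   overlapping bad segments dropped with reasons; optional random
   **trial-count equalisation** across conditions.

Zero-phase filtering of recordings is implemented exactly in the frequency
domain — the signal is odd-reflection padded (pad length set by the slowest
pole's decay) and multiplied by the squared Butterworth magnitude — which is
the ideal limit of forward–backward filtering, without start-up transients.

## Forward model

A homogeneous conducting sphere (default radius 9 cm) with the analytic
current-dipole field (Sarvas' closed form), projected on each channel axis.
The sphere shares the realistic conductor's key structural property —
radial moments are silent — while remaining exactly specified; tests verify
it against a numerical gradient of the magnetic scalar potential and
against the vacuum-dipole radial-field identity. The scanning grid is an
axis-aligned lattice (default 5 mm) clipped to 90% of the sphere radius
(lead fields blow up numerically at the surface), laid out symmetrically
about the mid-sagittal plane x = 0 so that mirror pairing is an exact
involution. The auditory-cortex ROI is geometric — grid points within
12 mm of either simulated source — standing in for an atlas parcellation,
which would require an individual MRI.

## Beamforming

Sensor covariance is estimated from unaveraged single-trial data, 0–0.5 s
post-stimulus, demeaned per trial. LCMV weights for a k-column lead field
are $W = (L^\top C_\lambda^{-1} L)^{-1} L^\top C_\lambda^{-1}$ with diagonal
loading $C_\lambda = C + \frac{\lambda}{100}\,\frac{\mathrm{tr}(C)}{N}\,I$
(λ = 0.1% by default; the loading reference is the conventional mean sensor
power). Because bilateral auditory sources are nearly simultaneous and
correlated — the regime in which single-dipole beamformers cancel genuine
activity — scanning uses the 6-column symmetric-pair lead field by default.

Two numerical points deserve emphasis:

* **Rank handling.** HFC leaves the data with a 3-dimensional
  quasi-null space (variance ~10⁻⁵ of the noise floor once later stages
  re-inject rounding-level energy). Unit-gain filters of superficial points
  can hide their norm in that subspace, which silently inverts the depth
  ordering of the map. All scanning therefore operates inside the principal
  subspace of the covariance (eigenvalues above 10⁻³ of the median), and
  each scanned lead field is SVD-reduced to its magnetically visible
  columns (a spherical conductor makes each 3-column block rank 2).
* **Scalar NAI.** The neural activity index divides source power by
  beamformer-projected noise ($\sigma_0^2$ = smallest eigenvalue of
  $C_\lambda$ in the scanning subspace). With trace power over all six pair
  columns, a deep midline pair — whose four visible field patterns can
  reproduce the bilateral superficial topography almost exactly, at ~18×
  the moment — retains a residual depth advantage that weight normalisation
  only partly cancels. The default NAI is therefore the *scalar*
  (optimal-orientation) form: the largest generalised eigenvalue of window
  power against projected noise over source orientations. Likewise, the
  default window power is the second moment of the trial-averaged evoked
  response in the 0.08–0.12 s window (the M100 deflection itself);
  demeaning a 40 ms window would strip the very deflection being localised
  at the ~100-trial scale. The trace and single-trial forms remain
  available (`method = "trace"`, `power_from = "single_trial"`).

The ROI virtual channel follows the concatenated-filter PCA construction:
stack the ROI filters into $F$, take the principal eigenvector $v$ of
$F C F^\top$ (the $F C F^\top$ reading; the $F C$ alternative is noted but
not used), and apply $w = v^\top F$ to the sensor data. Polarity is fixed
so the averaged series peaks positive in 0.08–0.12 s, making the output
invariant to global sensor sign flips; no noise normalisation is applied to
ROI series, which instead carry a pointwise one-sample t-series across
trials. ROI statistics stay in arbitrary source units.

## Problem sizes and numerical choices

The default study scale is 60 s per condition at 1000 Hz with ~115 tones at
0.5 s inter-stimulus interval (the full-length option restores ~285 s and
~570 tones), 90 channels, and a 5 mm grid (~18000 points); the test suite
scans at 7.5 mm. Band-specific interference comparisons are computed as
time-domain variance after sharp zero-phase band filters, evaluated on the
record interior (outside filter edge regions): with a raw-artefact to
noise-floor dynamic range above 120 dB, tapered-periodogram leakage skirts
would otherwise dominate every band above 1 Hz. Welch PSDs (2 s Hann
segments, 50% overlap) are used for reporting and plots.

Degenerate inputs are handled explicitly: still regression windows fall
back to the intercept; grid points whose lead fields are entirely silent
(the sphere centre) are skipped with `NA`; reflection-optimal Procrustes
frames are corrected to proper rotations; zero-variance samples yield
signed-infinite t values with a flag.

## What the pipeline achieves on the synthetic study

Running `run_study(seed = 1, duration = 60)` (or equivalently
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
reproduces, from scratch, the qualitative signature of the real experiment:
raw mean per-trial maximal field changes of hundreds of pT in the moving
condition collapse by roughly two orders of magnitude through regression,
HFC and high-pass filtering; the M100 localises to the simulated source
pair; and the ROI evoked waveforms of the three conditions — independent
noise and motion realisations sharing only the neural ground truth — agree
pairwise with correlations above 0.9. The exact numbers for any seed are
written by the acceptance script; the test suite asserts the corresponding
properties (orderings, bands, correlation floors) rather than point values.

## Known limitations

* The affine room field cannot represent spatially varying gradients, so
  "standing in a steeper part of the room" is emulated by a higher field
  magnitude at the standing head position, not a changed gradient.
* Motion artefacts are narrower-band than real MSR interference; the
  relative contributions of regression, HFC and the high-pass filter differ
  accordingly from real recordings (the high-pass does more of the work
  here).
* The spherical conductor and geometric ROI replace individual anatomy;
  localisation statements are grid-relative, not anatomical.
* The NAI map at this trial count is evoked-power based; single-trial NAI
  maps need several hundred trials before the depth-unbiased contrast
  emerges from estimation noise.
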