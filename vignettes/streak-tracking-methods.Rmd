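---
title: "Methods: streak-mode microsecond tracking, decoding and diffusion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streak-mode microsecond tracking, decoding and diffusion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streaktrack)
```

This vignette documents the models, parameter choices and numerical
decisions behind `streaktrack`. It is the reference for *why* the package
behaves as it does; the README shows *how* to run it.

## The acquisition model

An EM-CCD exposes its active area for `exposure_us`, then shifts the stored
charge down the chip by `shift_height` (δ) rows at `row_shift_us` per row,
and repeats, reading the chip out only after `n_timepoints` cycles. A sparse
emitter therefore leaves one image per timepoint, stacked vertically at
δ-row spacing. The timestep is `exposure_us + δ · row_shift_us` — 307.5 µs
for 300 µs exposures with δ = 15 at 0.5 µs/row, 57.5 µs for 50 µs exposures.

**Row/time convention.** The simulator places the image of exposure *k* at
chip row `true_row + δ · (cumulative shift multiples before k)`: row 0 is
the top of the active area and successive timepoints appear at *increasing*
row index. On a physical chip it is the earlier exposures that end up
further down (they are shifted by all subsequent cycles); the two
conventions are mirror images and carry identical information, and the
package uses the one in which streak order equals time order throughout
(simulation, linking, collapse, decoding). Sub-pixel positions use the
pixel-centre convention: coordinate *p*.0 is the centre of pixel *p*.

In **variable-shift (VS) mode** each exposure *k* is followed by
`m[k] ∈ {1..4}` base shifts. Acquisitions hold the *total* time per
timestep fixed (e.g. 500 µs), so the constructor derives per-exposure
exposure times `timestep − m·δ·row_shift`. The stock 33-exposure sequence
(`vs_master_sequence()`) sums to 68 base shifts and has every window of 4
consecutive multiples unique, which is what makes short trails alignable.

## The synthetic-data generator

`sim_brownian_tracks()` draws per-axis Gaussian increments with variance
`2 D Δt` in three dimensions. A track ends when it leaves the focal slab
(`|z| > focal_depth/2`, default 1 µm) — a hard cutoff, the simplest model of
focal exit; real defocus dims gradually, so simulated track-length
statistics are slightly optimistic. Lateral positions reflect at the field
boundary (default 35 µm, the illuminated area, ≈ 220 pixels at 159 nm/px);
reflection biases the step variance down by under 1% at the fastest
simulated diffusivities, which is negligible against the ~10% statistical
scatter of pooled fits. Entry timepoints are uniform over the frame, which
reproduces the roughly exponential distribution of observed track
durations.

`sim_tube_tracks()` models a narrow tubule: free diffusion along the axis,
reflected diffusion across a width *w* (default 100 nm). The perpendicular
displacement distribution converges to the uniform stationary state, so the
perpendicular MSD plateaus at `w²/6` — the closed form the tests check. The
tube has no end caps; molecules drift freely past the seeded stretch, so
spatial-map fixtures should analyse interior bins (edge bins see a genuine
net outward flux and correspondingly distorted local MSDs).

`sim_two_state()` draws exact exponential waiting times for a two-state
continuous-time Markov chain and samples the state at the acquisition
timestep; the initial state comes from the stationary distribution
`F_c = k_close/(k_open + k_close)`.

**Rendering.** Each live molecule deposits a pixel-integrated Gaussian PSF
(σ default 1.0 px — a free parameter of the model, as is the background
rate; neither is dictated by the acquisition physics) with its expected
photon budget at the shifted row. Motion blur is approximated by 10
sub-spots evenly spaced along the straight segment toward the next
timepoint position, covering the exposed fraction of the timestep; a
linear-interpolation blur reproduces the first-order effect of
exposure-averaged positions (slope-preserving, negative MSD intercept) at a
fraction of the cost of simulating intra-exposure Brownian bridges. Charge
shifting is ideal integer row translation (no transfer loss or smear).
Background accumulates linearly: `n_timepoints · background_rate` photons
per pixel per readout frame, the price streak mode pays for many exposures
per readout.

**EM-CCD noise** is a Poisson–gamma cascade: photoelectrons `n ~ Pois(λ)`,
amplified charge `~ Gamma(n, scale = gain)`, plus Gaussian read noise. This
gives mean `gain·λ` and variance `≈ 2·gain²·λ + read_noise²` — the excess
noise factor of 2. At `em_gain = 1` the register is bypassed (pure
Poisson). The gamma upper tail matters in practice: local maxima of blank
frames exceed 5 background sigmas roughly 50× more often than Gaussian
intuition suggests (about 1.8 false maxima per 512²/4 frame at
`min_snr = 5`; none at 7).

## Localization

Detection is matched-filter: the frame is smoothed with a Gaussian kernel of
the PSF width before thresholded local-maximum search with non-maximum
suppression. This is standard single-molecule practice, and it matters here:
fast-moving molecules are motion-blurred, and a raw peak threshold
preferentially drops them — a selection that biased recovered diffusion
coefficients several percent low before smoothing was introduced.

Fitting is unweighted least squares of a pixel-integrated 2D Gaussian
(x, y, σ, amplitude, offset) by Levenberg–Marquardt in C++. Fits that fail
to converge, land outside their ROI, or return σ outside `[0.3, 3]·σ_PSF`
are discarded and counted. The per-ROI fitted offset serves as the local
background estimate, because accumulated background varies across streak
frames. Counts convert to photons by dividing by the EM gain.

The theoretical precision is the least-squares formula for a
pixel-integrated Gaussian on uniform background,
`σ² = F·(s_a²/N)·(16/9 + 8π·s_a²·b/(N·a²))` with
`s_a² = (σ_PSF² + 1/12)·a²`, multiplied by the EM excess factor `F = 2`.
Monte-Carlo RMSEs of the fitter match it within 15% from 50 to 1000
photons; ~100 photons on 160 nm pixels with ~1 background photon/px gives
~30 nm.

## Trail linking

Linking is deliberately greedy, mirroring the acquisition geometry. Within
a readout frame, the unassigned localization with the smallest row index
seeds a trail; the next timepoint is predicted one δ below the previous
detection and searched within `r = 2.55·√(4 D′ Δt)` (D′ = the largest
diffusion coefficient expected for the sample; at this radius a Brownian
step escapes with probability ~0.15%). Nearest candidate wins, ties break
to the lowest input index. A miss inserts a flagged skip placeholder and
the search continues from the predicted position; a run of 3 consecutive
skips (6 in VS mode) terminates the trail, trailing skips are stripped, and
trails with fewer than 4 detections or dominated by skips are discarded.
Used localizations leave the pool either way, so the trails plus the
discard pool partition the input.

**VS-mode linking predicts one δ-slot at a time.** The executed multiple at
each step is unknown before decoding, and the decoder needs the observed
detection/gap pattern over δ-slots — an `m = 3` step simply appears as two
skips. This is also why the VS skip-run limit is 6 (an `m = 4` gap is 3
slots; 6 tolerates a missed detection inside a gap) and why the
skip-domination threshold rises from 0.5 to 0.8 in VS mode: the reference
sequence makes 35 of 68 slots structural gaps, so a dropout-free VS trail
already has a skip fraction of ~0.51.

At the recommended ceiling of ~500 single-molecule images per frame
(chip-wide field), the wrong-link rate per linking decision measures ~5%
on a 90 µm²/s fixture; a single wrong link contaminates the rest of its
trail, so per-detection purity degrades faster than the per-decision rate.

## Barcode decoding

`translate_multiples()` writes each exposure as `1` followed by `m − 1`
zeros; the barcode length equals the total base shifts and its `1`-count the
number of exposures, and parsing is the exact inverse. A trail's observed
pattern (detection = 1, skip = 0, anchored at its first and last detections)
is compared to the master barcode at every offset where the master has a
detection; the alignment is accepted iff a unique offset minimises the
Hamming distance *and* that minimum is below 30% of the observed length.
Missed and spurious detections count symmetrically, and the minimum must be
strictly unique (the stricter reading of "uniquely achieved").

Accepted trails map each detected slot to `offset + slot` in the master;
the absolute vertical position is the chip row minus δ times that global
slot, and the slot's exposure index becomes the trajectory timepoint.
Detections that land on master gap slots are spurious under the alignment
and are dropped.

Specificity comes from length, not from the 30% rule alone: on noiseless
master windows with ≥ 5 detections the decode is always correct and unique,
but *random* binary patterns of length 12–25 clear the 30%-unique-minimum
rule about half the time; the false-acceptance rate falls below ~5% only
near observed length 50. Real protection against junk alignments comes from
trails being genuine streaks (the linker's geometry) and from the length
distribution of usable trails. `design_multiples()` constructs new
sequences by randomised backtracking against the window-uniqueness
validator and a total-shift budget; no code-design optimality is claimed.

## MSD analysis

`compute_msd()` pools **all overlapping pairs** of detected timepoints —
skips contribute nothing, and a pair spanning skips keeps its true time
separation. Overlapping pairs within one track are correlated, so the
per-lag standard error (sd of squared displacements / √n) and the naive
4-point OLS confidence interval both understate the uncertainty;
`estimate_d()` therefore offers a percentile CI from a bootstrap over whole
tracks, the independent units. The tests use the bootstrap CI whenever a
ground truth must fall inside an interval.

The linear model is `MSD = 2 d D t_lag + b` (`d` = 2 isotropic, 1
projected), fitted by OLS on the first 4 lags. The intercept is reported
with its sign: localization noise adds `+2 d σ²`, motion blur (positions
averaged over the exposure) subtracts `~(2/3)·2 d D t_E` — the tests verify
the sign flip between noise- and blur-dominated fixtures.

**Directional decomposition.** The principal diffusion direction averages
displacement directions with angle doubling (mean of unit vectors at 2φ,
halved) so antiparallel displacements reinforce; the mean resultant length
of the doubled angles flags isotropic (undefined) bins below 0.1.
Displacements at 4 timesteps' separation set the direction by default —
long enough that the confined component has saturated while the axial one
keeps growing. Projected components satisfy
`MSD_∥ + MSD_⊥ = MSD` exactly.

**Power law.** `MSD_∥ = 2 K t_lag^α + b` over the first 6 lags, fitted by
the two-step procedure: `b` from the line through the two initial points,
then α as the slope of `ln(MSD_∥ − b)` vs `ln t_lag` (lags with
`MSD ≤ b` are dropped with a warning). The two-step route is exact at
α = 1 but biased toward 1 elsewhere — the two-point intercept estimate is
only correct for a straight line — so `fit_msd(..., method = "nls")`
additionally offers the full three-parameter nonlinear fit, which recovers
exact power-law input to machine precision. The two-step remains the
default because the α maps it produces are meant to *diagnose departures
from normal diffusion*, for which behaviour at α ≈ 1 is what matters.

**Mapping.** Displacements at lags 1–10 are binned by their start position
on a 120 nm grid (the default trades spatial detail against per-bin
counts); each bin gets an orientation, a linear `D` (first 4 lags, 1D
model) and a two-step α (first 6 lags). Bins with fewer than 50
displacements or an undefined orientation are flagged invalid rather than
fitted. Sampling alone gives the two-step α a standard deviation of ~0.04
at 10³ displacements per bin, so on normal-diffusion fixtures individual
high-count bins stray outside [0.95, 1.05] at the expected Gaussian rate;
what converges is the distribution, and the tests assert exactly that
(shrinking |α − 1| with counts, ~90% of interior high-count bins in band).

## smFRET kinetics

Efficiencies are raw intensity ratios `E = I_A/(I_A + I_D)` — no gamma or
crosstalk correction, matching the two-channel ratio as acquired.
Observations classify as closed (`E > 0.65`), open (`E < 0.45`), excluded
(between), or skipped; excluded and skipped timepoints enter neither the
numerator nor denominator of
`P_cc(t_lag) = P(closed at t + t_lag | closed at t)`. Conditional
probabilities, not dwell times, are the estimator because streak-mode
traces are short and a donor-only subpopulation would corrupt dwell-time
censoring. `fit_fret_kinetics()` fits
`P_cc = (1 − F_c)e^{−k_eff t} + F_c` by bounded Levenberg–Marquardt;
`k_open = (1 − F_c)k_eff` and `k_close = F_c k_eff` hold exactly on the
output by construction, and non-decaying curves are flagged rather than
forced. Channel pairing uses a 2 px radius (closest pairs first); a
detection in one channel only keeps the timepoint with zero intensity in
the other, which is what makes donor-only molecules appear at `E ≈ 0`.
Photobleaching is not modelled in the kinetics (traces are tens of
timesteps; the simulator can emulate bleaching through `detect_prob` if
sensitivity checks are wanted).

## Reproducibility and problem sizes

Every stochastic function takes an explicit `seed` and runs under
`withr::with_seed`, so identical inputs give byte-identical outputs; the
pipeline's CSV writers stamp a content hash and package version into a
comment header. The test suite and the acceptance script size their
simulations to run on a single core in a few minutes: pooled-D recovery
uses 500–900 tracks per regime in the tests and 2000 tracks per target in
`scripts/acceptance.R` (at the typical acquisition density of ~100–150
images per frame), VS-decoding fixtures use ~150 tube-confined tracks, and
kinetics recovery uses 5000 traces of 13 timepoints. These sizes put the
statistical scatter of each recovered quantity comfortably inside the
tolerances they are tested against.

## Known limitations

* The focal-depth cutoff, linear-interpolation blur and ideal charge
  transfer are first-order models; vignetting, clock-induced charge and
  smear are not modelled, so absolute background and rare-event artefact
  rates in real data will differ.
* Greedy linking has no global assignment step; at densities beyond the
  recommended ~500 images/frame, mislinking grows quickly.
* The two-step α estimator is biased toward 1 for truly anomalous input;
  use `method = "nls"` when the exponent itself is the quantity of
  interest.
* Channel registration is an identity (or user-supplied) mapping; no
  calibration from beads is provided.
* No multi-state (> 2) kinetics, dwell-time inference, 3D MSD, or drift
  correction.
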