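# streaktrack

Wide-field single-particle tracking is normally capped by the ~10 ms frame
time of EM-CCD cameras: a molecule diffusing at tens to hundreds of µm²/s
leaves the sub-micrometre focal slab long before a second frame arrives.
Streak-mode acquisition sidesteps readout entirely by exploiting the camera's
native sub-microsecond **vertical charge shifting**: after each short
exposure (tens to hundreds of µs) the stored image is shifted down the chip
by a small number of rows (shift height δ ≈ 10–25), and only after dozens of
exposure–shift cycles is the chip read out once. Each sparse molecule then
appears as a vertical *streak* of images — one image per timepoint, δ rows
apart — projecting the time axis onto the spatial axis of the chip.
Subtracting the known shifts collapses a streak back into a microsecond-scale
single-molecule trajectory, on completely standard hardware.

`streaktrack` is an R toolkit for this acquisition mode, aimed at
single-molecule biophysicists who want to simulate, reconstruct and analyse
such data:

* **Simulation** — Brownian, tube-confined, and two-state-FRET molecular
  motion; pixel-integrated Gaussian PSF rendering under repeated
  exposure–shift cycles (including variable-shift patterns and motion blur);
  EM-CCD noise as a Poisson–gamma cascade with read noise.
* **Localization** — matched-filter spot detection and Levenberg–Marquardt
  integrated-Gaussian fitting (Rcpp), with the theoretical localization
  precision `σ² = F·(s²/N)(16/9 + 8π s² b / (N a²))`, inflated by the EM
  excess-noise factor `F = 2`.
* **Linking** — the greedy streak-grouping algorithm: seed at a trail's
  first timepoint, predict the next image one shift height below within a
  search radius `r = 2.55·√(4 D′ Δt)`, insert flagged skip placeholders for
  missed timepoints, terminate on runs of skips, and collapse trails into
  trajectories by shift subtraction.
* **Variable-shift decoding** — time-encoded shift patterns (per-exposure
  multiples *m* of δ) translate to detection/gap barcodes (`m` → `1` followed
  by `m−1` zeros); trails are aligned to the master barcode by Hamming
  distance (unique minimum below 30% of the observed length) and their
  absolute positions recovered, enabling super-resolution mapping of fast
  trajectories.
* **Diffusion analysis** — pooled and per-track MSD with
  `MSD = 4 D t_lag + b` (2D) or `MSD_∥ = 2 D t_lag + b` (1D), the intercept
  `b` absorbing static (localization, positive) and dynamic (motion blur,
  negative) errors; directional decomposition about the angle-doubled
  principal diffusion direction; spatially binned maps of local `D` and of
  the anomalous exponent `α` from `MSD_∥ = 2 K t_lag^α + b`; 2D-histogram
  super-resolution rendering.
* **smFRET kinetics** — two-channel pairing, `E = I_A/(I_A + I_D)`,
  state classification (closed `E > 0.65`, open `E < 0.45`), the
  time-correlated conditional probability
  `P_cc(t_lag) = P(closed, t+t_lag | closed, t)`, and two-state rates from
  `P_cc = (1 − F_c)·exp(−k_eff·t_lag) + F_c` with
  `k_open = (1 − F_c)·k_eff`, `k_close = F_c·k_eff`.

Everything tabular flows through tibbles, so the pipeline composes with
dplyr/tidyr; result objects have `tidy()`/`glance()` methods and
`autoplot()` figures.

## Worked example

Simulate a labelled protein diffusing at 90 µm²/s, recorded with 300 µs
exposures and 15-row shifts (307.5 µs timesteps), then run the full
reconstruction and MSD analysis:

```r
library(streaktrack)

cfg <- acq_preset("protein-pbs")     # 307.5 us per timepoint, delta = 15
trk <- sim_brownian_tracks(1000, d_um2s = 90, dt_us = cfg$timestep_us,
                           seed = 1)
lp  <- link_params(d_max_um2s = 100, timestep_us = cfg$timestep_us)
run <- run_tracking_pipeline(trk, cfg, lp, tracks_per_frame = 20, seed = 2)

msd <- compute_msd(run$trajectories, cfg$timestep_us, max_lag = 4)
fit_msd(msd)
```

```
  lag t_lag_us msd_um2  se_um2 n_pairs component
1   1      308  0.0595 0.00115    3834       iso
2   2      615  0.1736 0.00310    3365       iso
3   3      922  0.2886 0.00547    2908       iso
4   4     1230  0.4043 0.00837    2454       iso
<msd_fit> MSD = 4 D t + b: D = 93.43 um^2/s (95% CI 92.54-94.33), b = -0.0558 um^2
```

The 1000 simulated molecules yield 5216 localizations linked into 477
trails. The four MSD points grow linearly with lag; a quarter of the slope
recovers the diffusion coefficient (93 µm²/s against the 90 µm²/s ground
truth; the naive 4-point CI understates the uncertainty because overlapping
MSD pairs are correlated — `estimate_d()` gives a track-bootstrap CI of
87–100 µm²/s). The negative intercept `b` is the dynamic (motion-blur)
error: positions are exposure-averaged, which subtracts `~2 D Δt` from the
MSD without affecting its slope.

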