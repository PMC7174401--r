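---
title: "Particle-tracking microrheology of chromatin granules: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-tracking microrheology of chromatin granules: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ptmr` implements a complete passive particle-tracking microrheology
(PTM) chain for time-lapse recordings of bright, diffraction-limited
granules — the motivating application is chromatin granules inside
isolated cell nuclei imaged by fast phase-contrast microscopy (50 nm
pixels, 512 Hz, 10 s). The chain is

1. synthetic ground truth (`simulate_trajectories()`, `render_stack()`,
   `make_fixture()`),
2. sub-pixel spot detection (`detect_spots()`),
3. descriptor-based frame-to-frame linking (`compute_descriptors()`,
   `match_frames()`, `track_spots()`) with quality control
   (`qc_filter()`),
4. drift correction (`drift_correct()`),
5. MSD, diffusivity and apparent viscosity (`compute_msd()`,
   `fit_diffusion()`, `estimate_viscosity()`),
6. microrheology via the generalized Stokes–Einstein relation in the
   Mason approximation (`mason_modulus()`, `fit_voigt()`),
7. per-nucleus phenotypes and non-parametric group comparison
   (`summarize_nucleus()`, `compare_groups()`),

wired together by `run_pipeline()` and a thin command-line front end
(`inst/cli/ptmr`). This vignette documents the physical model, the
estimators, and every numerically consequential choice.

## 1. Motion models and the synthetic generator

Trajectories are simulated per particle in physical units (µm, s) at the
acquisition sampling `dt = 1 / frame_rate_hz`.

**Free diffusion.** Per-axis Gaussian increments of variance `2 D dt`,
so the 2D mean squared displacement (MSD) is exactly `4 D tau`.

**Confined (Kelvin–Voigt) motion.** A tracer bound in a medium modelled
as an elastic spring `G'` in parallel with a dashpot `eta` performs
Ornstein–Uhlenbeck (OU) motion with relaxation time `tau_r = eta / G'`.
We use the *exact discretisation*

```
u(t + dt) = u(t) exp(-dt / tau_r) + xi,
xi ~ N(0, D tau_r (1 - exp(-2 dt / tau_r)))
```

started from the stationary distribution, so the analytic 2D MSD

```
MSD(tau) = 4 D tau_r (1 - exp(-tau / tau_r))
```

holds at every lag from the first frame. An Euler scheme would bias the
plateau by `O(dt / tau_r)` and contaminate the recovery tests; the exact
update has no step-size error.

**Rigid drift.** `motion_drifting()` adds the same `v dt` displacement
to every particle in every frame and records the cumulative drift in an
attribute, giving an oracle for drift correction: the `"drifting"`
fixture preset shares its random streams with `"free_jurkat_like"`, so
after perfect correction the two coincide.

**Reproducibility.** Each particle consumes two dedicated RNG streams
(properties/placement and increments) derived from the master seed with
a prefix-stable scheme, so particle *i* is bit-identical regardless of
how many particles are simulated. Placement under `min_separation_um`
is the one exception (rejection resampling consults earlier particles).

**Rendering.** Spots are painted as symmetric 2D Gaussians (peak height
= the particle's intensity, `FWHM = diameter`) on a constant background
with optional Gaussian noise, quantised to 16-bit TIFF. Pixel centres
sit at integer coordinates; `x_um = (col - 1) * pixel_size_um` with the
origin at the top-left pixel centre, x rightward, y downward.
`render_stack()` refuses particles closer than 3 rendering sigmas to the
border rather than silently clipping their profiles. Fixture presets
keep the full acquisition defaults (512 Hz × 10 s = 5120 frames) but
accept scaled-down overrides; at full length the wander of free walkers
exceeds what a 256 px field can guarantee to contain, so full-length use
is truth-only and rendering such a recording errors explicitly.

## 2. Spot detection

Candidates are local maxima of the lightly smoothed frame (Gaussian,
sigma 1 px) exceeding `median + 4 * mad`, separated by at least 3 px.
Each candidate is refined by a Levenberg–Marquardt fit of
`I0 + A exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))`; the optical
diameter is the Gaussian FWHM `2 sqrt(2 log 2) sigma` and the spot
intensity the integrated area `2 pi sigma^2 A`. Fits are rejected (with
a recorded reason) on non-convergence, `sigma < 0.5 px`, a centre
leaving the window, or non-positive amplitude. Analysis keeps the
0.5–1.5 µm diameter class by default.

Two choices matter numerically:

* **Fit window = 2 × expected FWHM** (odd, ≥ 15 px; 41 px at the
  defaults). This covers ±2.4 sigma of a typical spot while keeping
  granules at the 2 µm fixture separation out of each other's windows.
  The price is a small truncation bias (up to ~7% on the fitted sigma of
  the largest 1.5 µm granules); positions stay sub-pixel (< 20 nm at
  SNR ≈ 10).
* **De-duplication.** With shot noise, one granule can split into
  several candidate maxima whose fits converge to the same sub-pixel
  centre. Duplicates would fragment tracks downstream, so fits closer
  than `min_separation_px` are merged, keeping the lowest-residual one.

## 3. Descriptor linking and quality control

Frame-to-frame linking uses SURF-style interest-point descriptors built
in pure R on integral images: a box-filter determinant-of-Hessian scale
ladder (filter sizes 9–75 px, scale `1.2 L / 9`), a dominant orientation
from Haar-wavelet responses in a circular neighbourhood (sliding pi/3
window), and a unit-normalised 64-dimensional descriptor of summed
oriented wavelet responses over a 4 × 4 subregion grid. Matching is
mutual nearest neighbour in descriptor space, gated spatially
(default gate `5 sqrt(4 D_expected dt)`); spots too close to the border
for a descriptor window fall back to mutual spatial nearest neighbour
under the same gate, so edge spots are not silently dropped. Matching
is one-to-one and symmetric; unmatched spots start or end trajectories
(no gap closing).

`qc_filter()` implements the spot-stability discard rules: cut at the
first frame where the step length changes by more than 50% of the
previous step, or diameter or intensity change by more than 10%; keep
the head if it has ≥ 64 frames (0.125 s at 512 Hz). Both readings of
the ambiguous 50% rule are available (`step_mode = "change"`:
`||dr(t)| - |dr(t-1)|| > 0.5 |dr(t-1)|`; `"ratio"`:
`|dr(t)| > 1.5 |dr(t-1)|`).

**Why the displacement rule is off in the pipeline default.** For free
Brownian motion the step lengths are i.i.d. Rayleigh, and the
probability that consecutive steps differ by more than 50% is ≈ 0.5 *per
frame* — the rule as stated discards genuinely Brownian trajectories
within a few frames. It exists to catch detection glitches and
off-plane excursions, which the size/intensity rules also catch without
penalising correct physics. `pipeline_config()` therefore defaults to
`qc_rules = c("diameter", "intensity")`; the displacement rule remains
available and fully tested.

## 4. Drift correction

Collective motion of the whole nucleus is removed in two stages:

1. **Rigid alignment.** For each consecutive frame pair, the
   least-squares rigid transform (rotation + translation, no scaling or
   reflection) aligning the particles present in both frames is
   estimated by SVD of the cross-covariance of the centred point sets
   (Kabsch; reflection branch corrected by the determinant sign). The
   accumulated transform is inverted, mapping all frames into the first
   frame's orientation.
2. **Centre-of-mass subtraction.** The intensity-weighted
   centre-of-mass drift path `r0(t)` is recomputed on the
   rigid-corrected positions and subtracted: `r'(t) = r(t) - r0(t)`.

The rigid stage runs first because a pure COM subtraction cannot remove
rotation; both corrections are logged per frame in a drift record.

The drift path is assembled *incrementally*: for each consecutive frame
pair, the intensity-weighted mean displacement of the particles present
in both frames is added to a running path anchored at the first frame's
absolute centre of mass. With full presence and constant intensities
this equals the per-frame centre of mass exactly. The distinction
matters as soon as tracks start or end mid-recording, which quality
control makes routine: the per-frame centre of mass of *whichever
particles happen to be present* jumps by the leaving particle's offset
(easily 1 µm) the moment a track ends, and every displacement spanning
that jump inherits it, inflating the ensemble MSD in proportion to the
lag — by an order of magnitude in our noise-free end-to-end checks. The
incremental path only ever differences positions of the same particle
in adjacent frames, so it is immune to changes in the tracked set.
Frame pairs sharing no particle keep the previous drift estimate and
are flagged in the record.

A bias worth knowing: with `n` tracers, the correction absorbs ~3
collective degrees of freedom, deflating the apparent diffusivity by
roughly `3 / (2 n)` (≈ 12% at n = 12). Oracle tests therefore compare
corrected-vs-corrected quantities (the drifting fixture against the
free fixture), never corrected estimates against the raw input `D` at
tight tolerance.

## 5. MSD, diffusivity, viscosity

`compute_msd()` evaluates the time-averaged MSD over all overlapping
origins (non-overlapping mode available for variance estimation), on
drift-corrected positions when present. `fit_diffusion()` fits
`MSD = 4 D tau` through the origin by weighted least squares (weights =
origins per lag) over the short-lag window `tau <= 0.1 s`, where the
motion is diffusive; a negative slope clamps to `D = 0` with a flag.
`fit_anomalous_exponent()` returns the log–log slope.
`estimate_viscosity()` inverts Stokes–Einstein for sticking boundary
conditions, `eta_app = kB T / (6 pi D R)`, with `R` the per-particle
time-mean optical radius (FWHM diameter / 2); `D = 0` maps to infinite
viscosity, flagged and excluded from phenotype averages.

## 6. Microrheology: Mason approximation and Voigt summary

`mason_modulus()` converts an MSD curve to the viscoelastic spectrum via
the analytic approximation of the generalized Stokes–Einstein relation:
at each measured lag (`omega = 1 / tau`, no resampling)

```
Gd(omega) = 2 kB T / (3 pi R MSD(tau) Gamma(1 + alpha(tau))),
delta(omega) = (pi/2) d log Gd / d log omega,
G' = Gd cos(delta),  G'' = Gd sin(delta),  eta(omega) = G'' / omega,
```

with `alpha(tau)` the local log–log slope of the MSD. Slopes come from
a centred quadratic fit over a 5-point sliding window (exact for power
laws, one-sided and flagged at endpoints). Points with `alpha` outside
(-0.5, 1.5) are masked — the Gamma correction approaches a pole there —
and phase excursions beyond [0, pi/2] are clipped and flagged. A direct
trapezoidal Laplace-transform evaluation (`gser_laplace()`) is included
as a numerical cross-check on smooth analytic inputs.

On exact power-law MSDs the implementation satisfies
`delta = (pi/2) alpha` for `alpha` in {0, 0.5, 1}, and for the free case
`eta(omega) = kB T / (6 pi R D)`, i.e. it reproduces Stokes–Einstein.

`fit_voigt()` summarises a spectrum as a Voigt body, reading each
element in the frequency limit where it dominates *and* where the Mason
shortcut is accurate: the spring `G'` as the median over flat points
(|local log-slope| < 0.2) within the bottom half-decade of frequencies,
the dashpot `eta` as the mean of `eta(omega)` over the top half-decade.
The low-frequency restriction matters: a true Voigt body has flat `G'`
everywhere, but the analytic approximation overshoots `G'` by ~14%
around the crossover `omega ~ 1 / tau_r`; at the ends of the spectrum
the error vanishes (< 1% on analytic OU input).

**Recovery-test design.** The Voigt recovery suite draws (`G'`, `eta`)
grids, sets `tau_r = eta / G'` and `D = kB T / (6 pi R eta)`, and
simulates OU ensembles. Relaxation times for soft/viscous combinations
fall below one frame interval at a fixed 512 Hz, making recovery
impossible *in principle* at that sampling; the suite therefore matches
sampling to the physics (`dt = tau_r / 20`, 1024 frames, lags up to
~13 tau_r) — a standard simulation-design choice that tests the
estimator rather than the sampling.

## 7. Phenotype statistics

`summarize_nucleus()` aggregates accepted particles per nucleus (mean
and SD of apparent viscosity, optical density = total integrated
intensity per total spot area, mean radius), warns below 10 particles
and errors below 2 (where drift correction is undefined).
`compare_groups()` applies the two-sided Mann–Whitney U test for two
groups and Kruskal–Wallis for more, with a `p = 1` guard for degenerate
all-equal input. The 0.05 threshold labels significance; it never
filters data.

## 8. Problem sizes and runtime

The defaults target desk-scale synthetic studies: hundreds of
trajectories of 5120 frames simulate in seconds; MSD over 51 lags for
200 × 5120 frames takes a few seconds; descriptor tracking of a
256 × 256 px stack runs at roughly 5–10 frames/s in pure R. The
acceptance-style suites (calibration, Voigt recovery, pipeline oracle)
complete in minutes on one CPU.

## 9. Limitations

* No gap closing or multi-hypothesis tracking; a missed detection ends
  a trajectory (by design, matching the QC philosophy).
* 2D only; off-plane motion is a QC discard, not modelled.
* Localisation noise is ignored in the MSD fit (no intercept), matching
  the method being implemented; an intercept mode would be the natural
  extension for low-SNR data.
* The Mason shortcut is a local approximation; its crossover bias is
  mitigated, not eliminated, by the read-out windows above.
* Synthetic models (free/OU/drift) cannot produce the hyper-diffusive
  long-time behaviour (`alpha > 1` at `tau > 1 s`) reported for real
  nuclei except through collective drift.
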