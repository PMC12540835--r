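---
title: "Quantifying chromosome congression from kinetochore trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome congression from kinetochore trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congressr)
```

## The measurement problem

During early mitosis, chromosomes whose kinetochore pairs sit near a
spindle pole ("polar" chromosomes) must move to the spindle equator —
chromosome congression. Live imaging of cells expressing a centromere
marker (CENP-A) and a centriole marker (centrin1) yields trajectories of
the two spindle poles and of sister-kinetochore pairs, typically extracted
on maximum-intensity projections, in µm and minutes. `congressr` turns
such trajectory tables into the standard quantitative readouts of
congression: who is polar, who aligns, when congression starts, how fast
pairs travel to the metaphase plate, and how fluorescent markers on those
kinetochores evolve.

All geometry is expressed in a spindle-intrinsic frame recomputed at every
frame, so cell drift and rotation do not contaminate the kinematics.

## The spindle reference frame

Given pole positions $p_A(t)$ and $p_B(t)$, each frame defines

* the midpoint $m = (p_A + p_B)/2$,
* the unit spindle axis $\hat u = (p_B - p_A)/\lVert p_B - p_A\rVert$,
* the pole separation $L$,
* the equatorial (metaphase) plane: the plane through $m$ perpendicular to
  $\hat u$. In projected-2D data the same formula describes the
  perpendicular line through $m$.

For a pair center $c$ (midpoint of the two sisters) the package computes
the distance to the plane $d_{plane} = |(c - m)\cdot\hat u|$, the distance
to the nearest pole $d_{pole}$ (ties broken deterministically to pole A),
the interkinetochore distance $d_{KT} = \lVert s_2 - s_1\rVert$ (the usual
proxy for attachment tension), and two angles, both reported as acute
values in $[0°, 90°]$ because lines rather than rays are compared:

* the positional angle between the pole–pole line and the line joining
  $c$ to its nearest pole;
* the orientation angle between the sister–sister axis and $\hat u$.

These are deliberately distinct quantities: position of the pair within
the spindle versus orientation of the pair itself. Both are exposed
because descriptions of "the angle of the pair with the spindle axis" in
the literature ambiguously refer to either.

Frames in which the poles approach within `eps_pole` (default 1 µm) are
marked undefined rather than producing a near-degenerate axis. Tracking
gaps of up to `max_gap` frames (default 2) are filled by linear
interpolation; longer gaps leave frames undefined. Both choices are
configuration, not hard-coded: interrupted tracks are the norm in crowded
prometaphase spindles.

## Event rules

The classification and event thresholds, bundled in
`congression_thresholds()`, follow the conventions used for RPE-1 cells:

| parameter | default | meaning |
|---|---|---|
| `d_align_ever` | 3 µm | a pair is "ever aligned" if $d_{plane} \le 3$ µm at any frame (inclusive) |
| `d_success` | 2 µm | the plate crossing is the first frame with $d_{plane} < 2$ µm (strict) |
| `success_window` | 30 min | window for alignment success of initially polar pairs |
| `velocity_window` | 6 min | congression velocity window (4 min for U2OS; `u2os_thresholds()`) |
| `count_start`, `count_step` | 12, 6 min | polar-count schedule from mitosis onset |
| `plate_fraction` | 0.75 | fraction of pairs within 3 µm for a "formed" plate |
| `min_dwell` | 0 min | optional persistence below 2 µm before a crossing counts |

A pair is *polar* when strictly closer to a pole than to the plane
($d_{pole} < d_{plane}$); the equidistant tie is classified not-polar.
Boundary conventions (inclusive 3 µm, strict 2 µm) are fixed so that
results are reproducible to the last pair; at measurement noise of
~0.1 µm the choice is immaterial in practice.

Congression velocity is the signed slope of $d_{plane}$ over the last
`velocity_window` minutes before the crossing,
$v = (d_{plane}(t_c - w) - d_{plane}(t_c))/w$: positive toward the plate,
negative away from it. The distance-to-plane coordinate, not path length,
is used — this matches the sign convention in which pairs drifting away
from the plate have negative velocity. When a track begins less than a
full window before its crossing, the velocity is computed over the
available span if at least half the window is covered (the span used is
reported as `window_used`); shorter coverage is an error rather than a
silently degraded estimate.

No persistence below the crossing threshold is required by default
(`min_dwell = 0`): the first strict crossing counts. Whether transient
dips should be debounced is genuinely open; the parameter exists for
sensitivity analyses.

Alignment success over a window asks whether an initially polar pair came
within 2 µm of the plane during `(t_ref, t_ref + 30]`; pairs lost before
the window ends that never crossed count as failures, so tracking dropout
cannot inflate success. The reference event `t_ref` (recording start,
drug washout, spindle elongation …) is supplied by the user; the default
is recording start.

Per-cell misalignment categories require an operational definition of
"metaphase plate formed", which is not standardized; here the plate counts
as formed when at least `plate_fraction` of pairs lie within 3 µm of the
plane. Given a formed plate: zero pairs outside is a tight plate, one to
four is low misalignment, five or more is high. Exactly five is assigned
to "high" (the conservative reading of a "more than 5"/"fewer than 5"
dichotomy that leaves five unassigned). The maximum chromosome spread is
the largest pairwise distance between pair centers.

## Fluorescence quantification

Kinetochore intensities are measured on the *sum* projection of all
acquired z-planes. For a spot region $R$ and a cytoplasmic background
region $B$:

$$ I = \frac{\sum_{R} I_{px} - \overline{I_B}\,\lvert R\rvert}{n_z} $$

i.e. integrated intensity, background-subtracted, divided by the number of
z-planes in the projection. Negative corrected intensities are retained
and flagged, not clipped, so that group means stay unbiased. Each
kinetochore's region is fixed once (from the reference channel) and reused
across channels, so channel ratios compare the same pixels.

Instead of a manually drawn oval, the spot region is deterministic: pixels
at or above half of the local dynamic range, 8-connected to the seed,
capped at radius `r_max` (6 px), with a 2-px disk fallback for flat
signal. For synthetic data the background region is an annulus (8–12 px)
around the seed; for real data an explicit cytoplasm mask should be
supplied. Pixel indices are 1-based with the origin at the top-left, x
indexing columns — the native R convention.

Two normalizations remove acquisition and expression-level differences:

1. *Reference-channel ratio*: target divided by the CENP-A intensity in
   the same region; cancels gain.
2. *Within-cell aligned-group normalization*: the ratio (and the pole
   distance) divided by the mean over that cell's aligned kinetochores, so
   aligned kinetochores average 1 by construction and cells with
   different expression levels or spindle sizes are comparable.

"Checkpoint signal loss" over a window is fractional by default,
$(I(t_0) - I(t_1))/I(t_0)$ — a definition chosen here, with the absolute
difference available behind a flag, since the literature rarely states
the formula. Binned mean ± sd profiles (`binned_profile()`) use
equal-width bins over the observed range, reporting empty bins as `NA`
rather than dropping them.

## Statistics

The battery mirrors standard practice in this literature and delegates to
base R where the test is classical: one-way ANOVA with two-sided Tukey HSD
(`aov()` + `TukeyHSD()`, which applies the Tukey–Kramer correction for
unequal group sizes), pooled two-proportion z-tests and Pearson chi-square
tests of independence without continuity correction, OLS regression with a
two-tailed t-test on the slope and $R^2$, and t-based / chi-square-based
95% confidence intervals for mean and standard deviation. Raw p-values
are always reported; star tiers (0.05 / 0.01 / 0.001 / 0.0001) are
display-only. The test suite cross-checks these wrappers against
from-scratch sums-of-squares, studentized-range and normal-equations
oracles, and verifies by simulation that each test's type-I error sits at
its nominal 5% level.

## The synthetic-data generator

No public machine-readable trajectory data exist for this assay, so the
package ships a generator that emulates the statistical structure the
analysis assumes, providing ground truth for every downstream stage:

* **Biphasic motion.** Each polar pair starts 1–3 µm from a pole
  (uniform), drifts toward the plate at `v_slow` with Gaussian positional
  noise `sigma_noise`, and after an exponential initiation delay
  $T \sim \mathrm{Exp}(\lambda_{init})$ moves at a per-pair fast speed
  (lognormal around `v_fast`) until within 1 µm of the plane, where it
  rests with jitter. The exponential (memoryless) delay encodes
  asynchronous initiation during prolonged mitosis.
* **Conditions differ only in initiation**, not movement: presets share
  `v_fast` and differ in $\lambda_{init}$ (0.1/min for a
  "reactivated"-like condition, 0.01/min for an "inhibited"-like one) and
  in the decay lead `tau_pre`. This encodes the qualitative biology that
  perturbing the congression motor gates whether congression starts, not
  how fast pairs travel once it has.
* **Tension and orientation.** Interkinetochore distance rises
  logistically from a lateral 0.6 µm to a bioriented 1.1 µm around $T$
  (rise time 4 min); the sister axis angle relaxes exponentially toward
  the spindle axis after $T$.
* **Checkpoint intensity.** Mad2-like intensity stays at $I_0$ until
  `tau_pre` = 2 min *before* $T$, then decays at a per-pair rate
  (lognormal around 0.15/min); pairs that never initiate decay at
  0.02/min from the start. Multiplicative lognormal measurement noise
  (CV 0.1) is mean-preserving. Per-pair log-speed and log-decay-rate are
  correlated with coefficient `rho` (default 0.8), which is what couples
  movement speed to signal loss.
* **Imagery.** `render_stack()` draws each kinetochore as a 3D Gaussian
  of programmed integrated amplitude (PSF sd 0.2 µm lateral / 0.5 µm
  axial at 0.1 µm pixels and 0.5 µm z-steps) on a flat cytoplasmic
  background, optionally with Poisson noise — ground truth for the
  intensity module.

Cells are built along the x axis and then given a random in-plane
rotation and translation so that analysis never benefits from an
axis-aligned special case. Every cell and pair draws from its own
substream derived from `(master_seed, condition, cell, pair)`, making any
single pair reproducible in isolation and the whole experiment
deterministic.

The numeric defaults (`v_fast` = 0.8 µm/min, spindle length 12 µm, 1-min
frames, 60-min recordings, and the rates above) are the generator's own
choices of realistic magnitudes for human cultured cells; they are not
measured values, and validation is parameter *recovery* — the pipeline
must re-extract what was programmed — rather than matching any published
number.

What the generator does *not* emulate: microtubule mechanics and force
balance (kinematics are phenomenological), tracking identity switches,
z-projection artifacts, bleaching, or spatially structured background.
Passing tests therefore demonstrate correctness of the measurement
pipeline on data satisfying its stated assumptions, not robustness to
every pathology of real microscopy.

## Validation experiments and problem sizes

The acceptance suite (mirrored by `scripts/acceptance.R`) runs, at fixed
seeds:

* geometry against a brute-force plane-sampling oracle and random rigid
  motions (100 configurations);
* boundary and monotonicity checks of the event rules on 50 simulated
  cells;
* velocity recovery: exact (to $10^{-9}$) on noise-free constant-velocity
  tracks, and within 5% of the programmed 0.8 µm/min with 0.1 µm noise
  over ~80 pairs with immediate initiation (so the whole velocity window
  lies in the fast phase);
* initiation-rate recovery: 200 pairs at $\lambda = 0.05$/min against the
  analytic 30-min success expectation $1 - e^{-1.5} \approx 77.7\%$
  (exact binomial test);
* coupling recovery: 100 replicate experiments of 300 pairs at
  $\rho = 0.8$, requiring a positive OLS slope of speed on fractional
  signal loss at $p < 0.05$ in at least 95;
* intensity round trip on rendered stacks within 2%, with gain and offset
  invariance of the normalized quantities to $10^{-6}$;
* type-I calibration of ANOVA/Tukey, two-proportion z and OLS slope tests
  at $10^4$ null replicates each.

## A worked example

```{r example}
cfg <- simulation_config(n_cells = 3, pairs_per_cell = 5, duration = 40,
                         master_seed = 7)
sim <- simulate_experiment(cfg)
res <- analyze_tracks(sim$tracks)
res$cells
head(res$events)
run_stats(res$events)
```

## Known limitations

* Frame alignment joins objects on the integer frame index; fractional
  resampling of mismatched acquisition clocks is out of scope.
* Anaphase onset is metadata, not inferred; timelines simply end at the
  data's end or a supplied endpoint.
* The half-max spot region underestimates total spot flux by design (it
  is a *position*, not a photometry, region); photometric recovery uses a
  generous disk and background annulus.
* 3D input is accepted with identical formulas, but the simulator emits
  projected-2D data, matching the projection-based tracking the analysis
  was designed around.
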