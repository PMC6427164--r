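---
title: "Models and methods behind smftrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smftrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smftrack)
```

`smftrack` turns overhead video of small laboratory fish into trajectories,
swimming velocities, occupancy maps and group statistics, and summarizes
embryo-development endpoints, for assays that compare a
static-magnetic-field (SMF) exposed group with a sham-exposed control.
This vignette explains the models the package implements, the parameters
that matter, the numerical choices, and what the synthetic-data validation
does and does not establish about real recordings.

## Detection: background subtraction and segmentation

The scene is static apart from the fish: lighting is physically controlled
in this kind of setup, so a single reference image of the empty tank is an
adequate background model. The reference is the **per-pixel median** across
the clip's frames. The median is robust to transient occupancy: a pixel's
reference value is correct as long as a fish covers that pixel in fewer
than half of the training frames, which holds easily for a few fish in a
380 × 380 px working window. Adaptive or mixture background models would
add parameters without addressing any failure mode present here.

Each frame is then reduced to blobs:

1. absolute difference against the reference — using the absolute value
   makes the polarity of fish against background irrelevant (the
   subtracted image is effectively a negative);
2. an optional **3 × 3 median filter** on the difference image, the noise
   filtering step, implemented as an exact vectorized median-of-9 exchange
   network with edge replication;
3. binarization at `diff_threshold` (default 30 intensity units on the
   0–255 scale — about 6 standard deviations of typical webcam pixel
   noise, and far below the fish/background contrast of ~160 units);
4. **8-connected component labeling** (diagonal contact joins a component;
   a fish silhouette at an oblique angle can be diagonally thin);
5. discarding components below `min_area` (default 20 px; an adult fish
   blob at this geometry is 100–200 px, single-pixel noise excursions are
   1–3 px);
6. centroid = unweighted mean of member pixel coordinates, detections
   sorted by `(y, x)` for a deterministic order.

Coordinates are 0-based, `x` rightward, `y` downward, pixel centers at
integers. Cropping (`crop_frames()`, e.g. 640 × 480 capture frames to the
380 × 380 tank window) shifts the origin to the crop corner; the default
window is centered because only the crop size, not its offsets, is part of
the assay description.

## Tracking: minimum-distance identity mapping

Between consecutive frames, identities follow the **shortest Euclidean
distance**: the cost of linking track $k$ at position
$(s_{x,i-1}, s_{y,i-1})$ to a detection $(s_{x,i}, s_{y,i})$ is
$\sqrt{(s_{x,i}-s_{x,i-1})^2 + (s_{y,i}-s_{y,i-1})^2}$. The phrase fixes
the cost but not the matching discipline, and greedy nearest-neighbor
matching is order-dependent, so the package resolves identities with the
**globally optimal injective matching**: among all matchings of maximal
size whose pairs lie within a gate, the one minimizing total distance
(shortest-augmenting-path assignment solver, $O(k^3)$). Equal-cost optima
are broken toward the lexicographically smallest (track, detection)
mapping by a fix-and-verify pass, so results are fully deterministic. A
greedy mode (`method = "greedy"`) is kept behind a flag for comparison.

The gate (`max_gate_px = 50`) is large relative to observed speeds of
1–4 px/frame; its job is only to forbid teleporting matches after a lost
target. A track with no matching detection **coasts** — it repeats its
last position with `observed = FALSE` — so every track has exactly one
position per frame and a coasted transition adds zero distance to the path
length, biasing velocity down rather than inventing motion. Tracks
initialize at the first frame with at least `n_fish` detections; surplus
detections are ignored.

## Velocity

The per-clip total path length is
$\sum_{i=2}^{n_c}\sqrt{(s_{x,i}-s_{x,i-1})^2+(s_{y,i}-s_{y,i-1})^2}$ with
$n_c$ the frame count. Two normalizations are reported:

* `velocity_px_per_frame` — divided by the $n_c - 1$ frame transitions,
  the natural denominator for a sum over $i = 2..n_c$; this is the unit of
  the bundled reference table;
* `velocity_px_per_s` — divided by the clip duration (default 300 s, the
  5-minute clip length).

The recordings' frame rate is not part of the assay description, so the
two units cannot be converted into one another here; both are carried, and
comparisons should stay within one unit. Velocity is invariant under
global translation and rotation of the coordinate frame, and path length
is additive over contiguous segments; both are property-tested.

## Spatial occupancy and field zones

`build_heatmap()` counts positions per square bin
(`floor(coordinate / bin_size)`); counts always sum to the number of
recorded positions. Coasted positions are included by default (a coasting
fish genuinely dwells where it was last seen) and can be excluded.

Magnetic-field geometry enters as **configuration, not physics**: a disk
magnet produces concentric rings of field strength that are known from
measurement, not computed, so zones are user-supplied annuli
(`annulus_zone()`, inner radius inclusive, outer exclusive) with optional
mT labels. A bin belongs to the zone containing its center point — a
deterministic rule independent of traversal order. Fractions over the
zones plus the implicit `outside` remainder form a probability vector.
Dwelling preference is quantified by comparing those fractions between
groups; no single scalar "center preference" is defined because none is
standard.

## Group statistics

`paired_t_test()` implements the two-tailed paired t-test from first
principles: $t = \bar d / (s_d/\sqrt n)$ with the sample standard
deviation and $n-1$ degrees of freedom. Degenerate variance is explicit:
identical samples give $t = 0, p = 1$; a nonzero constant difference gives
$p = 0$ with a warning rather than `NaN`. The tail probability uses the
closed-form t distribution and is verified in the suite against numerical
integration of the density to 1e-8, and the whole statistic against the
standard paired implementation; under a simulated null its type-I error is
calibrated at the 5% level within binomial error over 10 000 replicates.

The bundled reference velocity table stores each group's 12 clips sorted
ascending, as such tables are conventionally printed, so index pairing of
its rows is pairing by rank. `percent_difference()` is
$100(\bar v_{ctrl}-\bar v_{treat})/\bar v_{ctrl}$, displayed to 1 decimal.

## Embryo endpoints

Daily observations put each embryo on the medaka staging ladder
(14, 18, 22, 23, 28, 29, 30, 33, 35, 37, 39, 40). `summarize_dish()`
computes hatchability with the 20-day abandonment cutoff (unhatched by
then counts as unhatched) and mean days-to-hatch over hatched embryos;
percentages are reported to 1 decimal. `abnormality_rate()` is the
fraction of embryos flagged abnormal. `check_hatch_table()` recomputes
percentages from counts and flags inconsistent rows — the bundled
reference hatch table contains one such historical row (dish 5: 14 of 15
hatched, printed as 100%), which the package surfaces rather than
repairing. `compare_stage_curves()` pairs two groups' daily mean stages
day by day and applies the paired t-test.

## The synthetic-data generator

`simulate_tank()` emulates the recording geometry: a light background with
additive Gaussian pixel noise and dark elliptical fish. Motion is a
first-order autoregressive (correlated) random walk,
$v_t = \phi\, v_{t-1} + \varepsilon_t + b_t$, with persistence
$\phi \in [0,1]$, isotropic Gaussian perturbations of scale
`speed_scale_px`, and an optional constant-magnitude drift toward the
frame center (`center_bias`) emulating the dwelling preference observed
under SMF. Positions reflect specularly off the walls — the simplest rule
that keeps fish inside the frame with unchanged speed. Defaults
(380 × 380 px window, semi-axes 10 × 5 px, contrast 40 vs 200,
`speed_scale_px = 2`, $\phi = 0.8$) reproduce the working geometry and the
observed 1–4 px/frame speed range of the assay. Two deliberate
simplifications aid validation: trajectories are simulated before any
rendering, so ground truth never depends on pixel noise; and fish are
drawn as hard-edged (non-anti-aliased) ellipses, so blob areas are exactly
countable by an independent oracle. Setting `velocity_persistence = 1`,
`speed_scale_px = 0` and `init_speed_px = v` yields constant-speed motion
for velocity-recovery checks. The RNG consumption order is documented so
tests replay the update rule outside the package and compare positions
exactly.

`simulate_embryo_cohort()` draws, per embryo, a daily stage series
(scheduled stage plus rounded Gaussian noise, snapped to the nearest
ladder stage with ties toward the lower stage, then made monotone
non-decreasing), an abnormality flag, and a hatch day (normal, truncated
at 1, or no hatch with probability `p_hatch_fail`). The stage series and
the hatch day are **independent draws**: with zero observation noise every
embryo follows the schedule exactly whatever its hatch day. Real records
couple the two (an embryo is at stage 40 exactly when it hatches);
synthetic cohorts emulate that coupling only in distribution, which is
sufficient for the endpoints computed here since hatchability and stage
curves are analyzed separately.

## What the synthetic validation does and does not show

Passing the synthetic suites establishes that the chain is
**self-consistent**: known trajectories are recovered to sub-pixel
accuracy, identities are never swapped when fish stay separated by more
than twice the largest per-frame step, constant speeds are recovered
within 5% through the full detect → track → velocity chain, and the
statistics are calibrated on well-behaved inputs. It does not establish
robustness to phenomena the generator does not model: water-surface
reflections and refraction, shadows, body articulation and partial
occlusion when fish touch, illumination drift, or compression artifacts.
On real video those failure modes surface as merged blobs and coasting
gaps; the swap-suspect log (matches beyond 0.8 × gate) is the first
diagnostic to inspect.

## Numerical choices and problem sizes

* Background training requires ≥ 3 frames; the reference is exact (no
  running approximation).
* The assignment tie-break re-solves the LAP per candidate; with the few
  fish of a behavioral assay this is negligible against detection cost.
* Synthetic validation sizes: 300-frame 380 × 380 two-fish clips for
  tracking checks, 250-frame constant-speed clips per speed for velocity
  recovery, 10 000 replicates for t-test calibration, 1 000 random small
  instances against the brute-force matching oracle. These sizes give
  stable pass/fail behavior at sub-minute runtimes per suite.
* All simulations restore the caller's RNG state; identical seeds give
  bit-identical frames, ground truth and cohorts.

## Known limitations

* The day-paired t-test on stage curves is **anticonservative under the
  null** for cohort data: monotone stage progression autocorrelates
  consecutive daily means, so the independence assumption of the paired
  test fails and a true null rejects at roughly twice the nominal 5%
  level in simulation. The suite asserts this behavior explicitly. Curves
  whose day-to-day fluctuations are independent are correctly calibrated.
  Conclusions of "no difference" from such curve comparisons are
  conservative in the safe direction; claimed differences near the
  threshold should be treated with caution.
* Occlusion handling is minimal by design: coasting spans single-frame
  dropouts, but identities are not re-reasoned across multi-frame merges.
* Velocities in physical units require the (unrecorded) frame rate; only
  within-unit comparisons are meaningful.
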