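---
title: "Trajectory kinematics for rodent behavioral assays: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory kinematics for rodent behavioral assays: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethokinetics)
```

## The analysis in one paragraph

A single dark animal is video-recorded in a behavioral arena (open field,
three-chamber sociability box, or elevated plus maze). Thresholding each
grayscale frame and taking the centroid of the largest dark particle gives a
per-frame position; calibrating pixels to the arena's physical dimensions
gives a trajectory in cm sampled at the frame interval $\Delta t$. From the
per-step displacements $d_i = \lVert p_{i+1} - p_i \rVert$ the package
computes five statistics that together describe the *micro-structure* of
locomotion:

* **traveled distance** $D = \sum_{i \in M} d_i$, summed over the set $M$ of
  *moving* steps ($d_i > \varepsilon$);
* **effective velocity** $v_\mathrm{eff} = D / (|M|\,\Delta t)$ — the mean
  velocity *while moving*, deliberately excluding immobile time;
* **mean acceleration** — per-step speeds $v_i = d_i/\Delta t$ are formed
  for moving steps, velocity increments $\Delta v_i = v_{i+1} - v_i$ are
  taken over consecutive pairs that are both moving (never across a stop),
  and the mean of the *positive* increments is divided by $\Delta t$;
* **stops** — the number of maximal immobile runs flanked by movement on
  both sides (an interruption of one movement series by at least one
  immobile frame, followed by more movement);
* **distance/stop** $D/\#\mathrm{stops}$.

The same statistics are evaluated per arena zone (e.g. social chamber vs.
center + empty chamber), per minute bin, and compared across treatment
groups with the nonparametric and ANOVA machinery described below. The
scientific motivation is that distance and velocity can look entirely
normal while acceleration and stop structure — and especially their
*modulation by social context* — are altered; the package makes that
dissociation measurable and testable.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `frame_interval_s` | 1/30 (with a warning when defaulted) | s | consumer webcams record near 30 fps but do not guarantee it; every velocity and acceleration unit scales with it, so it is config, not a constant |
| `epsilon_cm` | 0.3 | cm/step | immobility threshold. Real centroids jitter even in a still animal; 0.3 cm/step is sub-body-scale jitter at 30 fps. It drives *all five* statistics and is therefore always echoed in output |
| `intensity_threshold` | none (required) | gray level | the original workflow's threshold value is not recoverable; it is configuration |
| `min_area_px` | 1 | px | particle filter against specks; the largest surviving particle is the animal |
| `bin_s` | 60 | s | habituation profile bin |
| `straightness_min`, `min_steps` | 0.95, 3 | — | straight-walk detector (net/path displacement ratio); automated where the original selection was visual, so counts are comparable in kind, not number |
| `window_s`, `angle_tol_deg` | 3, 10 | s, ° | turning-event heuristic; a discretized closed loop of $n$ steps accumulates only $360(n-1)/n$ degrees, hence the tolerance |

### Reading of "mean positive change of velocity"

Two readings are defensible: average only the positive increments
(default), or average $\max(\Delta v, 0)$ over all moving pairs
(`denominator = "all_pairs"`). Both are implemented; the default is the
more literal reading. Increments are counted as positive only above
`1e-9` cm/s: with synthetic, noise-free speeds, coordinate round-off
otherwise produces masses of ~1e-15 "positive" increments from
equal-speed cruise steps and floods the mean. This is a floating-point
tie guard, not a behavioral threshold.

### Sub-threshold jitter and the distance sum

Traveled distance sums *moving* steps only. This keeps the identity
$v_\mathrm{eff} \times t_\mathrm{moving} = D$ exact and is consistent with
extracting moving frames before computing distance and velocity;
`include_jitter = TRUE` restores the all-steps sum for sensitivity
analyses.

### Minute bins

Bins are half-open windows $[k \cdot 60, (k+1) \cdot 60)$ s, each
segmented *independently*; a stop spanning a boundary is counted in
neither bin, and per-bin distances sum to the session distance up to one
boundary step per bin edge. Independence makes each bin's numbers
reproducible in isolation.

### Zones

Zone rectangles are half-open, first-match-wins in declaration order, so
every boundary point is assigned deterministically. In the three-chamber
arena the center chamber is declared first: the dividing planes (where the
10 cm doors sit) and transitional crossings fall to the center, never
inflating social-chamber statistics. Steps, not frames, carry kinematics,
and a step belongs to its *earlier* frame's zone. A stop whose flanking
bouts lie in different zones is attributed to neither (reported as
`boundary_stops`) but remains in whole-session totals. The elevated plus
maze hub counts toward neither arm type; closed-arm percentage uses the
full session as denominator.

## Group statistics

Totals are compared with the two-tailed Mann-Whitney U test (midrank
ties; exact tail from the exact U distribution when $n_a + n_b \le 16$
and tie-free, otherwise normal approximation with tie and continuity
corrections). Minute and area profiles use the standard mixed two-way
ANOVA — between factor tested against subjects-within-groups, within
factor and interaction against the within-by-subject residual — with
Tukey (studentized range) contrasts for first-vs-last minute and
Sidak-adjusted cell contrasts for social/non-social areas. Fully
between-subjects layouts use type-III sums of squares with sum-to-zero
contrasts, appropriate for unequal group sizes. No correction is applied
across the five statistics (matching the original analysis); reports note
this. Degrees of freedom are the standard ones for these designs; the
original report prints internally inconsistent df for some ANOVAs, which
this package does not reproduce.

Subjects that never move are flagged `degenerate` and excluded from group
statistics with a log entry, mirroring the exclusion of non-moving
animals in the modeled experiment.

## The synthetic world

Because the original videos are unavailable, every stage is verified
against a generative model with known ground truth:

* **Bout structure.** Immobility gaps are exponential with initiation
  rate `bout_rate_hz`; bouts are exponential with mean `mean_bout_s`.
  Within a bout, speed ramps up at `ramp_accel_cm_s2`, cruises, and ramps
  down (trapezoid; triangle for short bouts). The measured mean
  acceleration tracks the ramp rate *only when the ramp spans several
  frames* (about `cruise / (a dt)` frames); defaults (18 cm/s, 80 cm/s²,
  30 fps) give ~7-frame ramps. This is a real observability limit of the
  statistic, not a simulator artifact: a ramp finished within one frame
  interval is invisible to frame-to-frame increments.
* **Headings.** A correlated random walk: per-step von Mises turning
  noise (Best-Fisher sampler, concentration 4 by default), specular
  reflection at walls (exact triangle-fold of the unbounded path in the
  vectorized integrator). A step that crosses a wall is recorded as the
  chord of the bent path, which is how a real centroid track looks too.
* **Zone bias.** While moving, the animal reorients at rate
  `zone_attract_hz` toward the center of a zone drawn proportionally to
  its role weight. In the three-chamber arena, dividers reflect movement
  except through the central 10 cm door strip.
* **Social modulation.** Multiplicative factors on the ramp rate, the
  bout-termination hazard and the cruise speed apply while inside the
  social chamber.
* **Phenotype presets.** `control_like`: social modulation accel ×0.65
  and stop hazard ×1.9, social-chamber weight calibrated to ~63%
  occupancy (the control social preference of the modeled experiment).
  `vpa_like`: ramp ×1.7, bouts ×0.4 as long with the initiation rate
  raised ×2.9 — the calibrated point at which expected traveled distance
  matches the control preset, making the preset distance/velocity-neutral
  *by construction* (a bare 1/0.4 rate raise preserves moving time but
  not distance, because short bouts spend proportionally more time in
  ramps) — no social modulation, and a weak social attraction calibrated
  to ~50% occupancy so its social/non-social *count* ratios are neutral.
  All preset magnitudes are tuning constants of the synthetic world, not
  measured facts; the treated phenotype's real social-preference deficit
  (~36%) is deliberately *not* emulated, because count-ratio neutrality
  and occupancy deficit cannot both hold with a two-chamber non-social
  pool.
* **Subject variability.** Lognormal per-subject multipliers (SD 0.15 on
  the log scale) on cruise speed, ramp rates, bout rate and bout length.
* **Determinism.** Every simulated object is a pure function of (config,
  seed); cohort subject $i$ uses `base_seed + i`.

What a green test does **not** establish: the generator has rectangular-
to-trapezoidal speed profiles, memoryless bout durations, and a single
rigid disc for a body — none of which is true of a rat. Green means the
*analysis chain* is correct and the stated group contrasts are
recoverable from data with the assumed structure; it says nothing about
biological effect sizes.

## Numerical choices

* Velocity-increment positivity tolerance `1e-9` cm/s (see above).
* Identity checks (`velocity × moving time = distance`,
  `distance/stop × stops = distance`) hold to 1e-9 relative tolerance.
* Largest-particle ties are broken toward the component containing the
  smallest pixel index (deterministic, where the original workflow used
  manual review).
* Tracking gaps: interior MISSING runs of at most `max_gap = 5` frames
  are linearly interpolated; longer or leading/trailing runs stay
  MISSING and block calibration with an explicit error.
* Timestamps must be uniform to 1e-6 s; minute bins with fewer than two
  frames are dropped.

## Known limitations

* No multi-animal tracking, pose estimation, or rearing detection (a 2-D
  centroid cannot see posture); rearing counts from the modeled
  experiment are therefore out of scope.
* Straight-walk and turning detectors are automated heuristics; their
  counts are not comparable to visually scored ones.
* Frame input is in-memory stacks or ASCII PGM files; binary video
  containers are upstream of this package.
* Repeated-measures corrections (e.g. Greenhouse-Geisser) are not
  implemented; the mixed ANOVA assumes sphericity, trivially satisfied
  for two within levels.
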