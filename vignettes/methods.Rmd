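---
title: "Measurement model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stancekit)
```

This vignette records the measurement model behind stancekit, the meaning
and rationale of every tunable parameter, the scope of the synthetic
generator, and the numerical choices that a user validating or extending
the package should know about.

## Coordinate and angle conventions

Input is the standard 33-point pose topology (BlazePose order) in image
coordinates: origin at the top left, x rightward, y **downward**,
per-landmark confidence in [0, 1]. The z column is preserved through I/O
but never used: single-camera relative depth is not metrically reliable,
so all kinematics are 2D projections into the lateral (sagittal) viewing
plane. This is the central modelling assumption — every angle below is
only meaningful for a subject seen side-on by a fixed, level camera.

Three angle conventions are used consistently:

- **Inter-joint angle**: the angle at a middle landmark between rays to
  two adjacent landmarks (e.g. hip–knee–ankle), in [0°, 180°];
  180° = fully extended. Computed by `joint_angle` from the dot product
  with the cosine clamped to [-1, 1] before `acos` (see *Numerical
  choices*).
- **Flexion**: `180° − inter-joint angle`, so larger = more bent. Knee
  flexions drive the stance rules.
- **Segment inclination**: the unsigned angle of a segment from the image
  vertical (the +y, downward axis), in [0°, 90°+]. Trunk inclination
  `theta_body` is the inclination of the mid-shoulder → mid-hip axis.

Because trunk inclination is unsigned, a separate `lean_forward` flag
(sign of the shoulder offset along the facing direction) records the
direction of any lean; the stance rules need only the magnitude, since
"upright within a tolerance" is symmetric.

Scale is normalised by **trunk length** (mid-shoulder to mid-hip
distance in pixels): foot separation `D_feet` and the reflex displacement
threshold are in trunk lengths, making them invariant to subject size and
camera distance. All derived features are invariant to translation and
uniform scaling of the frame, and mirror consistently under horizontal
reflection (verified by property tests).

## Derived features

- **Facing direction**: the sign of the nose's horizontal offset from the
  mid-hip. An exact tie (within 1e-6 trunk lengths) is an error rather
  than a guess — a lateral view with the nose over the hips means the
  subject is facing the camera, where the planar model does not apply.
- **Front leg**: the ankle displaced farther along the facing direction
  from the mid-hip. A displacement tie returns `"undetermined"`, which
  routes classification into the symmetric (Kiba) branch.
- **Weight-shift proxy `W_back`**: the torso axis (mid-shoulder through
  mid-hip) is extended to the ground line `y = max(ankle_y)`; the
  intersection is expressed as a fraction of the way from the front ankle
  (0) to the back ankle (1), clipped to [0, 1] with an `out_of_base`
  flag. This is a qualitative geometric stand-in for load distribution,
  not a force measurement; it is exact for a rigid trunk over a planted
  base and degrades gracefully with trunk tilt.
- **Invisible big toe**: the forward-stance coaching cue that the front
  knee should hide the big toe from the practitioner's own eye is
  operationalised as a ray test: the line from the front-side eye through
  the front knee is extended to the toe's vertical level; the toe is
  hidden when the ray reaches or passes the toe along the facing
  direction. The eye→knee construction was chosen over a vertical-drop
  test because it matches the cue's line-of-sight geometry and stays
  meaningful when the shin is inclined.
- **Confidence gating**: a frame is reliable for a computation when every
  required joint's confidence is at or above `min_conf` (default 0.5,
  inclusive). Unreliable frames yield `NA` features, classify as
  `"none"`, and never advance the repetition counter — gating is always
  explicit, never silent interpolation.

## Stance rules and their parameters

Classification branches first on symmetry: if
`|F_left − F_right| ≤ eps_flex` the frame is a candidate for Kiba Dachi
only; otherwise for Zenkutsu or Kokutsu only. This makes the three labels
mutually exclusive by construction rather than by precedence ordering.

| Parameter | Default | Role |
|---|---|---|
| `eps_flex_deg` | 5 | symmetry margin on the flexion comparison |
| `T_upright_deg` | 15 | allowed trunk tilt for ZD/KD |
| `D_min` | 0.9 | minimum foot separation (trunk lengths) for ZD |
| `W_min` | 0.6 | minimum `W_back` for KD |
| `F_range_deg` | [30, 90] | knee-flexion window for Kiba |
| `D_kiba_min` | 1.3 | minimum lateral separation for Kiba |

- Zenkutsu Dachi: `F_front > F_back + eps` ∧ `theta_body ≤ T_upright` ∧
  `D_feet ≥ D_min`.
- Kokutsu Dachi: `F_back > F_front + eps` ∧ `theta_body ≤ T_upright` ∧
  `W_back ≥ W_min`.
- Kiba Dachi: both flexions in `F_range` ∧ `D_feet ≥ D_kiba_min`.

All inequality thresholds are inclusive; the flexion dominance comparison
is strict beyond the margin. The defaults are **calibrated on the
package's own synthetic generator** — they sit at round values that
separate the three preset stance regions with wide margins — and are
deliberately exposed as configuration, because real-world values belong
to the user's population and camera setup. `calibrate_thresholds`
performs an exhaustive grid search over a documented lattice
(`stancekit:::calibration_lattice()`), maximising label agreement with
reference labels; ties break deterministically to the first lattice point
in iteration order, so calibration is reproducible.

A sequence-level label (`classify_sequence`) is the majority per-frame
label over reliable frames, reported only if it persists for `k_stable`
consecutive reliable frames (default 5) — a stance is a held posture, so
an unstable majority is reported as `"none"` rather than a guess.

## Smoothing

Three filters are provided, applied per landmark to x and y only
(confidence is data, not signal; z is passthrough):

- moving average and median with a symmetric window (default 5 frames,
  odd), truncated at sequence edges;
- a **causal** one-euro filter (defaults: `min_cutoff` 1 Hz, `beta`
  0.007, `d_cutoff` 1 Hz). The causal form was chosen deliberately: the
  one-euro filter is a real-time filter by design, and keeping it causal
  means offline results match what an on-device implementation would
  produce. The smoothing factor is computed as `alpha = 1 / (1 + tau/dt)`
  with `tau = 1 / (2*pi*cutoff)`; the test suite checks equivalence to an
  independently coded reference using the algebraically equal
  `r/(r+1)` form.

Smoothing matters in practice: at jitter σ = 2 px on a 500 px body, raw
per-frame Kiba classification drops to ≈90% because two independently
jittered knees exceed the 5° symmetry margin in ≈10% of frames, while the
default moving average restores ≈99.7% per-frame accuracy.
`smoothing_ablation` quantifies exactly this effect on any sequence.

## Repetition counting

The counter is a three-state machine (idle → top → bottom → top) over an
angle signal: knee inter-joint angle for squats, elbow for push-ups, with
the left/right pair combined by `min` (conservative: both limbs must
extend) or `mean`. Raw inter-joint angles, not flexions, are used for the
thresholds because "180 = straight" is the natural reading for exercise
depth (squat defaults 160/100, push-up 150/90).

Three guards prevent chatter:

- **Hysteresis dead band**: the gap between `theta_top_deg` and
  `theta_bottom_deg`. Noise of amplitude below half the band can never
  add or remove a repetition (a tested invariant).
- **Dwell** (`min_dwell_frames`, default 2): a state is entered only
  after that many consecutive qualifying frames, rejecting single-frame
  spikes.
- **Refractory period** (`refractory_s`, default 0.3 s): after a counted
  repetition, new bottom entries are ignored briefly, so one deep bounce
  cannot double-count.

Push-up frames additionally require the shoulder–hip–ankle angle to stay
within `T_plank_deg` (default 20°) of straight; sagging-hip frames are
gated out rather than counted. Gated frames never advance the machine.

`evaluate_reps` scores detections against reference completion times by
greedy chronological one-to-one matching within a tolerance window
(default 0.5 s), with the conventions precision = 1 for no detections and
recall = 1 for no references.

## Reaction time

Punch detection tracks the wrist's displacement along the facing
direction from the mid-shoulder, in trunk lengths, with the mean
displacement over the pre-stimulus window (default 0.5 s) subtracted —
so a forward guard position or slow drift cannot trigger detection. The
punch is detected at the first post-stimulus frame whose
baseline-corrected displacement reaches `delta_disp` (default 0.5 trunk
lengths) and stays there for `sustain_frames` (default 2) consecutive
frames. Measured reaction time is therefore quantised by the camera:
the error relative to the true latency always lies in
`[0, (sustain_frames + 1) / fps)`, a bound the acceptance suite verifies
at 15, 30, and 60 fps. No detection within `timeout_s` (default 2 s)
reports a timeout with `rt_s = NA` rather than a fabricated value.

## Agreement statistics

For validating app-derived angles against expert annotations:

- MAE (with the sample SD of absolute errors) and RMSE, no outlier
  exclusion;
- Bland–Altman bias and 95% limits of agreement (`bias ± 1.96 sd`);
- Pearson r with Fisher-z confidence interval;
- ICC(2,1) — two-way random effects, absolute agreement, single measure —
  computed from the ANOVA mean squares, with McGraw–Wong F-based
  confidence limits. The implementation is hand-built (the heavy ICC
  packages are not among the dependencies) and is tested against
  `stats::aov` mean squares as an oracle. Zero between-subject variance
  makes the ICC undefined; the result is flagged `degenerate = TRUE`
  rather than guessed.

The package also bundles a nine-row stance-comparison fixture
(`load_stance_comparison()`): app-detected versus expert stance labels,
side-correctness flags, and knee/shin angles from single-subject lateral
stance holds. Two rows are flagged `parse_ambiguous` because their
transcribed angle digit grouping is typographically ambiguous at the
source; strict angle analyses should exclude them, while the stance and
side labels are unambiguous on all nine rows.

## The synthetic generator

`simulate_stance`, `simulate_squat`, `simulate_pushup`, and
`simulate_punch` build frames by planar forward kinematics from a
parametric skeleton (segment lengths as anthropometric fractions of a
500 px body height). The legs are posed by solving for the thigh angle
(1D root-finding) so that the ankle lands at the required horizontal
offset while the knee flexion is *exactly* the requested value; the
requested trunk tilt, stance width, and hip bias (which sets the true
`W_back`) are likewise exact. Consequently at zero noise every specified
angle is recoverable by the kinematics module to numerical precision —
the basis of the round-trip acceptance tests. Infeasible requests (e.g. a
stance wider than the bent legs can span) raise a generation error
instead of silently clamping.

Noise is layered on top, emulating the dominant failure modes of
single-camera pose estimators: Gaussian per-coordinate jitter, landmark
confidence dropout, and whole-frame left/right keypoint swaps. A seeded
noise model restores the caller's RNG state afterwards, so simulations
are reproducible without disturbing the surrounding program.

Scope and limits: one subject, strictly lateral view, level camera, no
occlusion by other objects, no perspective foreshortening, coincident
left/right hips and shoulders (a true lateral projection), and face,
hand, and foot landmarks placed at fixed plausible offsets rather than
articulated. The generator validates geometry and I/O contracts; it does
not validate pose-estimator behaviour on real video.

## Numerical choices

- `joint_angle` clamps the cosine into [-1, 1] before `acos`, so
  collinear configurations at the edge of floating-point error return
  exactly 0° or 180° instead of `NaN`; degenerate triples (coincident
  vertex) are errors.
- Geometric tie tests (facing, front leg, coincident feet) use a relative
  epsilon of 1e-6 trunk lengths rather than exact equality.
- The one-euro smoothing factor uses the `1/(1 + tau/dt)` form; the test
  oracle uses the equivalent `r/(r+1)` form, so agreement is a genuine
  cross-check rather than code duplication.
- ICC confidence limits use the McGraw–Wong Satterthwaite degrees of
  freedom; the `mse = 0` perfect-agreement case short-circuits to a
  [1, 1] interval instead of dividing by zero.
- Repetition event times are reported at the first frame of the dwell run
  that entered each state, not the frame that confirmed it, so event
  timestamps do not drift with `min_dwell_frames`.

## Reproducibility

The full test suite runs with
`testthat::test_dir("tests/testthat", package = "stancekit",
load_package = "installed")`; `tests/testthat/test-acceptance.R` holds
one block per acceptance criterion, and `scripts/acceptance.R --seed 1
--out results/acceptance.json` recomputes the headline quantities against
the installed package.
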