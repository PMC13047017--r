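# stancekit

Rule-based posture analysis for 33-landmark pose streams: stance
classification for the three fundamental Shotokan karate stances,
hysteresis repetition counting for squats and push-ups, reaction-time
measurement for a punch-on-stimulus task, and the method-agreement
statistics needed to validate such a pipeline against expert annotations.
A forward-kinematics skeleton simulator with ground-truth manifests makes
every part of the pipeline testable offline, without video or a pose
estimator.

The package operates on the standard 33-point pose topology (BlazePose
order) in image coordinates: origin top left, y down, per-landmark
confidence in [0, 1]. The z column is carried through I/O but never used
in kinematics; all angles are 2D sagittal-plane projections from a lateral
camera view.

## What it computes

- **Kinematics** (`extract_features`): knee flexion per side (flexion =
  180° − inter-joint angle), trunk inclination from vertical, shin
  inclinations, foot separation in trunk lengths, a posterior weight-shift
  proxy `W_back` (where the torso axis meets the ground line, as a
  fraction of the base of support), facing direction, front-leg
  identification, and the "invisible big toe" coaching-cue check (the ray
  from the front eye through the front knee reaching past the toe).
- **Stance rules** (`classify_stance`, `classify_sequence`): threshold
  predicates for Zenkutsu Dachi (front knee bent more than rear, upright
  trunk, wide base), Kokutsu Dachi (rear knee bent more, weight shifted
  back), and Kiba Dachi (symmetric flexion over a wide lateral base), with
  a symmetric-versus-asymmetric branch that makes labels mutually
  exclusive and a per-frame predicate trace for interpretability.
  `calibrate_thresholds` grid-searches a documented lattice against
  labelled features.
- **Smoothing** (`smooth_sequence`): moving average, median, or a causal
  one-euro filter over landmark trajectories; `smoothing_ablation`
  reports how smoothing changes the angular features.
- **Repetition counting** (`count_reps`): a Top → Bottom → Top state
  machine with a hysteresis dead band, a dwell requirement, and a
  refractory lockout; push-ups add a plank gate on the
  shoulder–hip–ankle angle. `evaluate_reps` scores detections against
  reference times with greedy one-to-one matching.
- **Reaction time** (`reaction_time`): baseline-corrected forward wrist
  displacement in trunk lengths, with a sustain requirement; resolution is
  quantised by the frame rate.
- **Agreement statistics** (`agreement_report`, `icc_absolute`): MAE,
  RMSE, Bland–Altman bias and limits of agreement, Pearson r with
  Fisher-z CI, and ICC(2,1) with McGraw–Wong confidence limits.
- **Simulator** (`simulate_stance`, `simulate_squat`, `simulate_pushup`,
  `simulate_punch`): plants a planar skeleton at exactly the requested
  joint angles, so zero-noise scenes are recoverable to numerical
  precision, and adds Gaussian jitter, confidence dropout, and left/right
  swap noise with a ground-truth manifest.
- **Sessions and CLI**: an append-only JSONL session store
  (`append_session`, `aggregate_stats`) and a command-line interface
  (`stancekit_cli`; wrapper script in `inst/scripts/stancekit`) with
  verbs `simulate`, `features`, `classify`, `count-reps`, `reflex`,
  `agree`, `stats`.

## Worked example

```r
library(stancekit)

# simulate a noisy back-stance hold and classify it
sim <- simulate_stance(stance_preset("kokutsu")$spec, n_frames = 30,
                       noise = noise_model(jitter_sd_px = 2, seed = 7))
classify_sequence(sim$seq, filter_cfg = filter_config("moving_average"))
#> <stance_classification> summary: kokutsu (30/30 frames reliable)
#>
#> kokutsu
#>      30

# count squat repetitions and score them against the ground truth
squat <- simulate_squat(n_reps = 5)
cfg <- rep_config("squat")
rc <- count_reps(exercise_signal(squat$seq, cfg), cfg)
rc
#> <rep_count> 5 squat repetition(s)
#>   t_top_enter t_bottom t_complete
#> 1       0.000    1.167        2.3
#> 2       2.267    3.167        4.3
#> 3       4.267    5.167        6.3
#> 4       6.267    7.167        8.3
#> 5       8.267    9.167       10.3
evaluate_reps(rc, squat$truth$rep_times)[c("precision", "recall")]
#> $precision
#> [1] 1
#>
#> $recall
#> [1] 1

# reaction time from a simulated punch 0.3 s after the stimulus
punch <- simulate_punch(stimulus_t = 1, true_latency_s = 0.3)
reaction_time(punch$seq, stimulus_t = 1)
#> <reaction_result> RT = 0.333 s (stimulus at 1.000 s)
```

From the shell:

```sh
SK=$(Rscript -e 'cat(system.file("scripts", "stancekit", package = "stancekit"))')
Rscript "$SK" simulate --scenario squat --n-reps 3 --out squat.jsonl
Rscript "$SK" count-reps --in squat.jsonl --exercise squat \
  --reference 2.5,4.5,6.5 --tolerance 0.5
```

## Data formats

Landmark sequences read and write as JSONL (one
`{"t": seconds, "pts": [[x, y, z, conf] × 33]}` record per line) or wide
CSV (`t` plus `<landmark>_{x,y,z,c}` columns); see `read_landmarks` /
`write_landmarks`. Configuration files are JSON or YAML with sections
`thresholds`, `filter`, `rep`, `reflex`, `min_conf` (`load_config`).
Session stores are JSONL, one session summary per line; no raw landmark
data is ever persisted by session commands.

## Notes on scope

Default thresholds are calibrated on the package's synthetic generator
and exposed as configuration; they are not population norms. `W_back` is
a geometric proxy for weight distribution, not a force measurement. All
kinematics assume a single subject viewed laterally by a fixed, level
camera. See the vignette (`vignettes/methods.Rmd`) for the measurement
model, parameter rationale, and the simulator's scope and limits.
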