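# gaitfmg

Per-sample detection of the **stance** (foot on the ground) and **swing**
(foot in the air) phases of walking from multi-channel muscle-deformation
signals — the force-myography-style output of a shank-worn optical band —
without any labeled walking data. The classifier is calibrated entirely
from short static standing postures; a kinematic gating rule then corrects
for the drift between standing and walking signal distributions. The
intended users are researchers in wearable gait analysis who need a
phase detector that can be (re)calibrated on a wearer in about a minute
of standing still.

## Method

Each 50 Hz frame carries a muscle-deformation vector $x \in \mathbb{R}^K$
(nominally $K = 11$ channels), an orientation quaternion and body-frame
gyro rates. The swing probability is logistic,

$$P(\text{swing} \mid x) = \sigma(w^\top x + b), \qquad P > 0.5 \Rightarrow \text{swing},$$

with $(w, b)$ fitted by L2-penalized maximum likelihood on standing-posture
frames alone: seven postures mimicking snapshots of the gait cycle, each
labeled by its phase side (foot-off postures → swing). Ten fixed posture
combinations are supported; condition 9 (six postures, 10 s each — 60 s of
calibration data) is the default.

Because the standing-calibrated boundary is biased on walking data, the
logit is shifted by the anterior angular velocity $g_y$ of the shank
(pitch rate, from quaternion → Euler → rate transform):

$$P = \begin{cases}
\sigma(w^\top x + b + a) & g_y < th_1 \quad \text{(leg swinging forward)}\\
\sigma(w^\top x + b - a) & g_y > th_2\\
\sigma(w^\top x + b) & \text{otherwise,}
\end{cases}$$

with defaults $a = 8$, $th_1 = 0.6$, $th_2 = 0.7$ rad/s, and a reliability
guard that disables the adjustment when $\max|\tan\theta| > 50$ over the
recording. The package also ships the posture-to-phase Euclidean-distance
analysis, sample-based accuracy / per-phase TPR evaluation with
video-to-sensor label alignment, an oracle-tuned RBF-SVM baseline, and a
synthetic gait generator that provides labeled ground truth. See
`vignettes/gait-phase-detection.Rmd` for the full account.

## Worked example

```r
library(gaitfmg)

cfg <- sim_config(seed = 42)
postures <- generate_posture_recordings(cfg, n_per_posture = 500)
walk <- generate_walk(cfg)
walk
#> <gait_recording> walk, 1800 frames x 11 channels @ 50 Hz
#>   labels: 1080 stance / 720 swing

model <- calibrate(postures, condition = 9, n_per_posture = 500)
det <- detect_sequence(walk, model, detection_config())
evaluate_phases(det$phase, walk$labels)
#> <evaluation_result> 1800 frames, accuracy 99.9%
#>   stance n =  1080  TPR = 100.0%  FPR =   0.3%
#>   swing  n =   720  TPR =  99.7%  FPR =   0.0%
```

The 1800 frames are 30 gait cycles at 50 Hz with a 1.5:1 stance:swing
sample ratio; TPRs are per-phase recall, and a phase's false positive rate
is 100 minus the other phase's TPR. With matched standing/walking data the
plain classifier is already near-perfect. Displace the walking frames
toward the swing prototypes (the generator's model of standing/walking
boundary drift) and the adjustment is what saves the day:

```r
walk_drift <- generate_walk(sim_config(seed = 42, boundary_mismatch = 24))
plain    <- detect_sequence(walk_drift, model, detection_config(a = 0))
adjusted <- detect_sequence(walk_drift, model, detection_config())
round(c(plain    = evaluate_phases(plain$phase, walk_drift$labels)$accuracy,
        adjusted = evaluate_phases(adjusted$phase, walk_drift$labels)$accuracy), 1)
#>    plain adjusted
#>     61.6     97.9
```

The posture-similarity analysis shows which standing postures resemble
which phase (here the synthetic prototypes separate cleanly):

```r
head(closest_label_percentages(walk, posture_means(postures)))
#>              posture stance_pct swing_pct
#> 1     back_foot_flat        100         0
#> 2      back_heel_off        100         0
#> 3      back_foot_off          0       100
#> 4    front_foot_flat        100         0
#> 5 front_heel_contact        100         0
#> 6     front_foot_off          0       100
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "gaitfmg.R", package = "gaitfmg")` with subcommands
`simulate`, `calibrate`, `detect`, `posture-analysis`, `evaluate` and
`demo`.

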