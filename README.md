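# fpcontrol

Quantifies the **degree of mediolateral foot placement control** in treadmill
walking: how tightly the placement of each step follows the body's
center-of-mass (CoM) state during the preceding swing phase. It is aimed at
gait and motor-control researchers who record per-belt ground reaction
forces, segment kinematics and hip ab-/adductor EMG, and want a tested,
reproducible implementation of the foot-placement regression analysis —
including a fully synthetic walker so every stage can be verified by
parameter recovery without any experimental data.

## The models

For each step (toe-off → heel strike, time-normalized to 51 phase samples),
foot placement FP — the swing foot's mediolateral position at midstance
relative to the contralateral foot at its midstance (signed step width, leg
frame with lateral positive) — is regressed across steps on the CoM state at
phase *i*:

    FP = β_pos · CoM_pos(i) + β_vel · CoM_vel(i) + ε(i)        (model 1)

with all variables demeaned per trial. R²(i) is the *degree of foot placement
control* at phase *i*; mid-swing (i = 25) and terminal swing (i = 51) are the
phases tested. A second model relates FP2 (foot position at midstance
relative to the CoM at toe-off, z-normalized) to the z-normalized early-swing
(60–80% of the stride) gluteus medius (gm) and adductor longus (al) EMG
features:

    FP2 = β_gm · EMG_gm_swing + β_al · EMG_al_swing + ε        (model 2)

with β_gm > 0 (abductor bursts precede more lateral steps) and β_al < 0
expected. Group inference uses Fisher-transformed R² in a 2 (condition) × 2
(speed) repeated-measures design with within-participant contrasts, optional
JZS Bayes factors, and one-tailed planned post-hocs for directional
hypotheses.

The built-in synthetic walker is a lateral inverted pendulum
(x¨ = (g/ℓ)(x − u)) with a linear step-to-step placement controller
(FP = w₀ + k_pos·y + k_vel·v + noise) — exactly the process model 1 assumes —
plus within-stance CoP excursions clipped to a configurable half-width
(0.005 m emulates a 1 cm ankle-moment-constraining ridge), double-support
force transfer producing a butterfly CoP, target-line stepping for the
foot-placement-constrained condition, and burst-modulated synthetic EMG.
Channels come out at 200 Hz (forces/CoP), 50 Hz (kinematics) and 2 kHz (EMG).

## Worked example

```r
library(fpcontrol)

cfg <- sim_config(n_strides = 100, seed = 42)
cfg
#> <sim_config> steady / normal (belt 1.19 m/s, f 0.90 Hz, 100 strides, seed 42)
#>   controller: k_pos 1.000, k_vel 0.300 s, width 0.120 m, fp noise 0.0020 m
#>   CoP half-width 0.030 m; process noise 0.08 m/s^2

st <- simulate_trial(cfg)           # trial channels + ground truth
an <- analyze_trial(st$trial, n_strides = 100)

an$fp_fit
#> <fp_model_fit> 200 steps
#>   mid-swing (i=25): beta_pos 2.176, beta_vel 0.677, R2 0.962
#>   terminal (i=51):  beta_pos 1.087, beta_vel 0.282, R2 0.980

an$muscle_fit
#> <muscle_model_fit> 200 steps: beta_gm 0.328, beta_al -0.367, R2 0.2417
```

The terminal-swing coefficients recover the generating controller gains
(k_pos = 1.0, k_vel = 0.30 s) to a few percent from the measured channels
alone; the terminal R² of 0.98 reflects the walker's motor-noise level; the
muscle-model signs match the imposed burst coupling (gm positive, al
negative). Condition metrics come from `condition_metrics(an$records)`:
here mean step width 0.120 m (the configured target), variability 0.0146 m,
stride frequency 0.901 Hz (the imposed 0.90 Hz metronome).

Cohort-level use:

```r
p   <- draw_participants(12, seed = 1)
tab <- simulate_cohort(p, conditions = c("steady", "fp_constrained"),
                       speeds = c("normal", "slow"), n_strides = 120, seed = 2)
rm_2x2(tab, "z_ts", c("steady", "fp_constrained"), c("normal", "slow"),
       posthoc_alternative = "less")
```

shows the hypothesized directions: constraining placement to projected lines
lowers the degree of control (more at slow speed — a negative
condition × speed interaction) and lowers step-width variability.

A thin command-line front end is included at `inst/cli/fpcontrol.R`
(`simulate`, `events`, `features`, `fit`, `report`, `all`), operating on
trial directories of delimited tables plus a YAML manifest; see the script
header for usage.

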