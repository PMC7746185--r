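---
title: "Quantifying mediolateral foot placement control: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mediolateral foot placement control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fpcontrol)
```

## The scientific question

During walking, the body behaves laterally like an inverted pendulum pivoting
about the stance foot: between steps the center of mass (CoM) accelerates away
from the support point, and the dominant corrective action is choosing *where
to place the next foot*. The degree of foot placement control is quantified by
regressing, across steps, the mediolateral foot placement FP (the swing foot's
position at midstance relative to the contralateral foot at its midstance) on
the CoM state during the preceding swing:

$$\mathrm{FP} = \beta_{pos}\,\mathrm{CoM}_{pos}(i) + \beta_{vel}\,\mathrm{CoM}_{vel}(i) + \varepsilon(i),$$

at each of 51 phases $i$ of the normalized step (toe-off to heel strike), with
all variables demeaned per trial. The relative explained variance $R^2(i)$ is
the degree of control at phase $i$; mid-swing ($i = 25$) and terminal swing
($i = 51$) are tested. A second model regresses FP2 (foot position at
midstance relative to the CoM at toe-off, z-normalized) on the z-normalized
early-swing (60–80% of the stride) gluteus medius and adductor longus
envelope features: the "active contribution" of hip ab-/adductor activity,
with positive $\beta_{gm}$ and negative $\beta_{al}$ expected.

The package implements this pipeline end to end — event detection,
CoM estimation, step segmentation, EMG conditioning, model fits and
repeated-measures group statistics over a 2 (condition) × 2 (speed) design —
together with a synthetic walker whose ground truth makes every stage
verifiable by parameter recovery.

## The synthetic walker

### Dynamics

Within stance the lateral CoM obeys
$\ddot{x} = \omega^2 (x - u)$, $\omega = \sqrt{g/\ell}$, where $u$ is the
stance-foot CoP. Support switches to the new foot instantly at heel strike;
the gradual double-support load transfer appears only in the force and CoP
channels, not in the dynamics. This is the standard step-to-step
inverted-pendulum abstraction; a dynamically blended support point adds
roughly 0.1 s of phase lag which shrinks the stable controller-gain region so
far that realistic between-participant gain variation becomes impossible.

The trial is integrated cell by cell on the 200 Hz force grid with the exact
propagator of the linear pendulum under piecewise-constant input (the
`cosh`/`sinh` solution, extended to the damped/stiffened case by its
eigendecomposition). There is no discretization error beyond the
piecewise-constant approximation of the within-stance CoP profile, so the
frozen-support trajectory matches the closed form to machine precision.
White acceleration noise (`process_noise_sd`, held per 5 ms cell) represents
unmodeled lateral perturbations, and per-step duration jitter
(`stride_time_jitter_sd`) represents timing variability around the metronome
period.

### The stepping controller

At every heel strike the swinging foot lands, in the leg frame (lateral
positive, so left and right steps pool), at

$$\mathrm{FP} = w_0 + k_{pos}\, y + k_{vel}\, v + \varepsilon_{fp},$$

with $y, v$ the CoM position and velocity relative to the stance foot at that
instant. This is exactly the data-generating process model 1 assumes, which
is what makes gain recovery a meaningful end-to-end oracle. The stable region
of $(k_{pos}, k_{vel})$ is centered on capture-point-like gains: for the
symmetric periodic orbit, stability requires approximately
$k_{vel}\,\omega\sinh(\omega\tau) \in (\cosh(\omega\tau)-1,\ \cosh(\omega\tau)+1)$
at $k_{pos} = 1$, with $\tau$ the step period. Defaults $k_{pos} = 1.0$,
$k_{vel} = 0.30\ \mathrm{s}$ are stable at both speeds for leg lengths around
0.9 m.

The deterministic orbit is known in closed form: with
$\kappa = k_{pos} + k_{vel}\,\omega\tanh(\omega\tau/2)$, the realized step
width is proportional to $w_0 / (2 - \kappa)$. Because the open-loop CoP
profile adds a constant forcing, the constant of proportionality is found
numerically: the realized width is affine in $w_0$, so two short noiseless
probe simulations identify the offset that realizes `nominal_step_width`
exactly. Users therefore specify the *target mean step width*, not the raw
controller offset.

### Within-stance CoP and the ankle-moment constraint

The stance-foot CoP follows an open-loop biphasic profile
`cop_shift_amp * sin(2*pi*phase)`, clipped to `±cop_half_width`
(default 0.03 m; 0.005 m emulates walking on the 1 cm ridge of an
ankle-moment-constraining shoe). The profile is deliberately *not* state
feedback: with feedback CoP, clipping it would change the closed-loop
variance of the CoM-state predictors, so the ankle constraint would alter
the model-1 $R^2$ even with an unchanged stepping controller — contradicting
the constraint's intended orthogonality to placement control. With an
open-loop profile, stepping is the only feedback path and $R^2$ is invariant
to `cop_half_width` by construction.

The `ankle_constrained` preset additionally applies the behavioral
compensations observed under this constraint — target step width × 1.25 and
stride frequency × 1.08 — as imposed conditions, not emergent behavior. Note
that the higher stride frequency shortens stance and thereby slightly
*reduces* the noise amplification that generates predictor variance, so the
cohort-level $R^2$ under the ankle preset is marginally lower than steady
state, not identical. The hypothesis of *tighter* control under the
constraint is therefore assessed one-tailed, and the cohort provides no
support for it.

### The foot-placement constraint

The `fp_constrained` preset mixes the controller output with fixed target
lines at `±nominal_step_width/2` with weight `fp_constraint_weight` (0.5 at
normal speed, 0.8 at slow speed, reflecting that projected lines bind
stepping more effectively in slow walking; how strongly the projection binds
is not empirically established, so the weight is an explicit free
parameter). Pure line stepping cannot stabilize an inverted pendulum — any
useful down-weighting of the stepping feedback diverges — so the preset also
enables a non-stepping control force
$-c\,x - d\,\dot{x}$ (`nonstep_stiffness` = 14 s⁻², `nonstep_damping` = 7
s⁻¹) representing the hip, ankle and push-off strategies that keep a human
walker stable when stepping is constrained. Consequences, in the hypothesized
directions: terminal-swing $R^2$ drops (more at slow speed, where the weight
is higher) and step-width variability drops well below steady state.

### EMG synthesis

Each channel is band-limited carrier noise (50–150 Hz Butterworth band-pass
of white noise, unit variance) amplitude-modulated by a tonic level plus one
Gaussian burst per stride centered at 70% of the stride cycle (early swing:
the swing phase of a leg occupies 60–100% of its own stride). Burst
amplitudes scale with the ensuing step's lateral placement deviation:
$1 + c\,\mathrm{dev}$ for gluteus medius and $1 - c\,\mathrm{dev}$ for
adductor longus (`emg_coupling` $c$ = 4 m⁻¹ by default, giving a muscle-model
$R^2$ around 0.1–0.2 with reliably recoverable signs). Additive wide-band
noise (`emg_noise_sd`) completes the channel. The synthesis exercises the
20 Hz high-pass / rectify / 50 Hz low-pass chain meaningfully but is not a
physiological motor-unit model.

### What the generator does and does not emulate

It emulates: lateral CoM oscillation at two leg-length-normalized belt
speeds; placement linearly driven by CoM state with motor noise; bounded
within-stance CoP excursions; target-line stepping; double-support force
transfer producing a butterfly-shaped combined CoP; a stylized sawtooth
anteroposterior CoP (feet land ahead, are carried back by the belt, roll
heel-to-toe) sufficient for butterfly-based event detection; swing-phase
hip ab-/adductor bursts correlated with step laterality.

It does not emulate: 3D kinematics or marker noise, ankle-moment dynamics
(the constraint is mechanical, via clipping), anteroposterior balance,
fatigue or learning, or physiological EMG spectra. Two quantitative
discrepancies from human data are documented rather than hidden. First, the
point-mass walker recirculates placement noise into CoM-state variance with
a per-step amplification of roughly
$k_{pos}\cosh(\omega\tau) + k_{vel}\,\omega\sinh(\omega\tau) \approx 6$, so
its steady-state terminal-swing $R^2$ (~0.97) is well above the human 0.6–0.8
and, because the amplification grows with stance time, slightly *higher* at
slow speed rather than lower. Passing tests therefore demonstrate pipeline
correctness and directional condition effects, not reproduction of human
$R^2$ magnitudes. Second, the constraint-condition compensations are imposed
by presets, so cohort contrasts verify the analysis chain, not motor
adaptation.

## Analysis-side numerical choices

* **Gait events.** The force-threshold detector uses 5% of body weight by
  default, refines crossings by linear interpolation, and extrapolates the
  loading ramp to zero so the reported time estimates the contact change
  itself rather than the threshold crossing (the crossing lags by
  threshold/slope, about one sample here). The butterfly detector finds
  heel strikes at anteroposterior CoP minima (onset of the forward transfer
  sweep) and toe-offs at the following maxima, assigns the side from the
  mediolateral sweep direction, removes low-prominence reversal pairs
  iteratively, and refines each reversal on the unsmoothed trace because
  smoothing biases an asymmetric vertex toward its shallow limb.
* **Phase convention.** Steps are normalized to 51 samples by linear
  interpolation; the literal 1-based indices are kept, so `i = 25`
  (phase 24/50 = 48%) is mid-swing and `i = 51` terminal swing.
* **Velocity.** `com_velocity` is the forward difference divided by the time
  step with the last value repeated. A forward difference is centered half a
  sample late, so interpolation onto event times uses half-sample-shifted
  timestamps. The *terminal* sample is special: the CoM acceleration jumps
  at heel strike (support transfer), so any estimate that straddles the
  contact is biased by the new support, in proportion to the placement
  itself — which leaks into the regression coefficients. The terminal CoM
  velocity is therefore estimated one-sidedly by a least-squares quartic
  over the last ~0.22 s of pre-contact CoM samples evaluated at heel-strike
  time. The span balances truncation error (dominant in noiseless
  trajectories, favoring short spans and high order) against within-stance
  process noise (favoring longer, averaging spans); 0.22 s keeps the
  noiseless limit exact to <0.3% while holding cohort-level gain-recovery
  bias near 3–4%.
* **Midstance** is the temporal midpoint of stance (configurable). The foot
  is stationary during stance, so placements are insensitive to the exact
  instant — verified as a property over ±10% shifts.
* **Muscle-model alignment.** EMG strides run ipsilateral heel strike to
  heel strike (configurable in principle; this alignment makes the 60–80%
  window the early swing of that leg), and each stride's features are keyed
  to the heel strike that ends it — the placement those features predict.
* **Demeaning and $R^2$.** All model variables are demeaned per
  participant × condition × trial and fitted without intercept;
  `ols_demeaned` checks centering, reports collinear columns by name on rank
  deficiency, and its $R^2$ equals the ordinary centered $R^2$.
* **Fisher transform.** `fisher_transform` defaults to
  $\operatorname{atanh}\sqrt{R^2}$ (the classical Fisher z of the multiple
  correlation); $\operatorname{atanh}(R^2)$ is available via
  `method = "direct"` because the convention is ambiguous in common usage —
  results in this package are stated under the default.
* **Group statistics.** The 2 × 2 repeated-measures analysis reduces each
  effect to one within-participant difference contrast tested with a paired
  t-test; planned constrained-vs-steady post-hocs are one-tailed where the
  hypothesis is directional. The optional JZS Bayes factor uses a Cauchy
  prior with scale $\sqrt{2}/2$ on the standardized effect, computed by
  adaptive quadrature and cross-checked in the tests against a dense
  log-grid trapezoidal oracle. A full Bayesian model-averaging ANOVA is out
  of scope; the frequentist decomposition plus the one-sample BF covers the
  inferential needs of the synthetic cohorts.

## Degenerate inputs and error behavior

Unstable gain combinations are reported with the offending gains and stride
frequency; all-zero force channels, silent belts, undefined CoP spans, NaNs
inside analysis windows, constant features (zero variance), rank-deficient
designs and incomplete 2 × 2 cells each raise specific errors naming the
offender. Pipeline runs quarantine failing trials with their error message
and continue.

## Problem sizes

The test suite and the acceptance script run cohorts of 10–30 synthetic
participants with 100–200 strides per trial (200 strides being the number of
consecutive strides analyzed per trial in the emulated protocol), EMG at
2 kHz where the muscle model is exercised, and 20 seeded trials for event
detection — sizes chosen so the full verification completes in minutes on a
single CPU while keeping every oracle statistically sharp.

## Known limitations

* The walker is a lateral point-mass model; anteroposterior dynamics are
  stylized and vertical dynamics absent.
* Steady-state $R^2$ magnitudes are higher than human values and their speed
  ordering is reversed (see above); condition effects are directional
  emulations.
* The anthropometric default table in `default_anthropometry()` is a
  synthetic placeholder with plausible magnitudes, not a published
  coefficient set; studies should supply their own regression coefficients,
  and all package tests use hand-checkable toy tables.
* The butterfly detector is validated against the force-threshold oracle on
  synthetic butterflies; real-data CoP traces with spin or crossover gait
  may need parameter adjustment (`smooth_n`, `prominence`).
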