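---
title: "Working-memory RNNs with short-term synaptic plasticity: models, analyses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working-memory RNNs with short-term synaptic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Working memory has classically been attributed to attractor dynamics:
stimulus-specific patterns of recurrent spiking that persist through a
memory delay. Cortical recordings complicate this picture — population
spiking often carries little stimulus information late in long delays, yet
behavior stays accurate. Short-term synaptic plasticity (STSP) offers a
complementary substrate: spiking leaves transient "impressions" in synaptic
efficacies that can hold information across gaps with little or no spiking.

`stspwm` implements the computational side of that comparison end to end:
recurrent network models with and without STSP trained on a distracted
delayed-match-to-sample (DMS) task, the population analysis stack used to
characterize them (time-resolved decoding, trajectory distances,
multi-level bootstrap, recovery time constants, LDA state-space
projections), similarity and robustness scores for model comparison, and a
surrogate multi-session recording generator so every stage is testable
without animal data.

# The task

A trial is: fixation (1000 ms) → sample image (500 ms, 1 of 8) → memory
delay (1.0, 1.41, 2.0, 2.83 or 4.0 s, uniform) → test display (500 ms, the
sample plus one uniformly drawn off-target sample image) → a 500 ms
response window. On half the trials a task-irrelevant distractor (1 of 2
images never used as samples) appears for 250 ms centered on the delay
midpoint. Inputs are 11 binary channels (8 samples, 2 distractors, 1
fixation); the fixation input stays on through the end of the test period.
The desired output keeps an output fixation channel at 1 until test onset
and, during the response window, the correct sample channel at 1 with all
other channels at 0.

Time is discretized at dt = 15 ms; epoch durations not divisible by dt are
rounded to the nearest whole step and recorded in the trial's
`epoch_boundaries`. Where the distractor sits "mid-delay" is not fully
determined by the verbal protocol; we center the 250 ms interval on the
delay midpoint (onset = delay start + round((delay − 250)/2 / dt)). The
response window is scored strictly after the test period ends.

# The models

All four families share leaky rate dynamics with membrane time constant
tau = 100 ms (alpha = dt/tau = 0.15), a trainable input map `I_t = W_in
m_t`, a trainable bias, and an affine readout `y = W_out x + c`. Process
noise enters the drive as `sqrt(2/alpha) * sigma_rec * N(0,1)` with
sigma_rec = 0.05 — the standard Euler discretization of
Ornstein–Uhlenbeck noise (the source expression is garbled in print; this
is the dimensionally consistent reading).

**FS-tanh / FS-relu (fixed synapses).**
`x' = (1-alpha) x + alpha phi(W x + I + b + noise)` with phi = tanh or
rectifier. `W` is initialized at SD `0.9/sqrt(n)` — a slightly subcritical
spectral radius (~0.9) under the circular law — and all other parameters at
SD `1/sqrt(n)`.

**PS-pre (presynaptic facilitation/depression).**
Dale's law holds by construction: `W_eff = relu(W_raw) %*% diag(d)` with
`d = +1` for the 80% excitatory and `-1` for the 20% inhibitory units, so
every column of the effective matrix carries its presynaptic sign at every
training step (we read the printed decomposition "W = W+ D" as the matrix
product; a sum could not keep the populations separate). Each presynaptic
unit carries utilization `u` and resource `a` variables:

    du = dt [ (U - u)/tau_u + U (1 - u) x ]
    da = dt [ (1 - a)/tau_a - u a x ]

clamped to [0, 1] after every Euler step, with facilitating kinetics
(tau_a = 0.2 s, tau_u = 1.5 s, U = 0.15) on exactly half of the units and
depressing kinetics (tau_a = 1.5 s, tau_u = 0.2 s, U = 0.45) on the other
half. Time constants are in seconds with dimensionless rates, the scaling
of the model lineage this follows; it makes `tau_u * x` order one, which is
what the closed-form steady states assume. The recurrent drive applies the
per-unit efficacy: `x' = (1-alpha) x + alpha relu(W_eff (u a x) + I + b)`.
At each trial start `x = 0, u = 0, a = 1`. `W_raw` is initialized Gaussian
with SD `1/n` and 50% of entries set to zero.

**PS-hebb (anti-Hebbian plastic weights).**
The recurrent weights themselves are the fast variable, reset to 0 at
trial start, with identity activation:

    x' = (1-alpha) x + alpha (W x + I + b + noise)
    W' = (1 - alpha gamma) W - alpha K o (x x')

with gamma = 1/200 and `o` the elementwise product. The gain matrix is
reparameterized as `K = B'B + 1e-2 O + 1e-2 I` with `B = C^2` elementwise
(training acts on C, initialized uniform on (-0.5, 0.5)), which keeps K
strictly positive entrywise and strictly positive-definite through every
optimizer update — the anti-Hebbian stability construction. We implement
the weight decay factor exactly as printed, `(1 - alpha*gamma)` per step:
during development we also evaluated readings in which gamma acts as a
continuous-time rate in ms^-1 (per-step factors 0.925 and 0.98875); under
those the task is effectively unlearnable at these delays (accuracy stuck
near 0.17 / 0.27), while the printed factor trains into the intended
>90% performance regime, so the printed equation is taken at face value.

# Training

Backpropagation-through-time with Adam (PyTorch-standard moments), L2
weight decay 1e-4 on all trainable parameters, batch size 256, and
learning rates 1e-3 (FS), 0.02 (PS-pre), 0.01 (PS-hebb). The forward and
backward passes are hand-derived and implemented in C++
(RcppArmadillo); the two large-n families run the training pass in single
precision (the analysis/recording path stays in double), and gradients are
verified against finite differences and against a pure-R single-step
reference implementation in the test suite. Variable-length trials are
grouped by delay, one delay per batch, so no padding semantics are needed.

The loss is the mean squared error between output and desired output over
the 500 ms after the test period, averaged over channels, timepoints and
trials. Activity regularization adds `strength * sum(x^2) /
(n_units * n_timepoints)` summed over the whole batch — the stated
normalization does not divide by batch size, and we implement it as
stated. The package default strength is 1e-3: it is the low end of the
standard sweep grid and trained most reliably in our head-to-head probes
(e.g. PS-hebb reached 0.94 held-out accuracy under 1e-3 against 0.66 under
1e-2 at matched budgets). PS-hebb gradients are clipped at global norm 1;
its identity activation makes early training prone to blow-up, and a
`||x||_inf > 1e6` guard aborts divergent trials with a diagnostic.

Process noise during training follows each family's printed dynamics: on
for FS and PS-hebb, off by default for PS-pre (whose update is written
without a noise term); process-noise robustness is probed explicitly at
evaluation time by the comparison module. Training keeps the best
dev-accuracy checkpoint — optimization of the plastic models is visibly
non-monotone late in training — and stops early at 95% dev accuracy. The
epoch loop also accepts a wall-clock cap (`max_seconds`); the acceptance
script and the test-suite cohort use caps (roughly 3–10 minutes per model)
chosen so the whole run fits a modest single-CPU session, and the
accuracies they report are whatever those budgets achieve.

Task accuracy follows the argmax rule: at every timepoint of the response
window the decision is the largest of the 8 sample-output channels,
compared against the true sample; a trial's accuracy is its fraction of
matching timepoints, and ties break to the lowest index. Restricting the
argmax to the sample channels (rather than all 11 outputs) makes the
decision set explicit and puts untrained networks at the task's natural
chance level of 1/8; the fixation channel is still shaped by the loss, it
is just not a decision alternative.

# The analysis stack

All analyses run on `trajectory_tensor` objects (trials x units x time
with labels), whether the source is a model run or the surrogate recording
generator.

- **Smoothing and binning**: Gaussian kernel (default SD 10 ms, reflect
  padding, unit mass) followed by mean-rate bins (default 50 ms).
- **Sample decoding**: one linear SVM (cost = 1, no rescaling) per time
  bin, stratified 10-fold cross-validation, per session, averaged with an
  SE across sessions. Unit subsampling (seeded, without replacement) is
  applied before fitting.
- **Change-from-baseline decoding**: binary classification of each bin's
  population vector against the −400 to −350 ms pre-stimulus window,
  averaged over sample types and sessions.
- **Trajectory distances**: `stim_distance` is the mean Euclidean distance
  between trial-averaged trajectories over all sample pairs
  (non-distractor trials only); `distractor_distance` is the mean over
  samples of the distance between distracted and undistracted averages.
  Optional normalization divides by the mean pre-stimulus distance.
- **Uncertainty**: a non-parametric multi-level bootstrap — resample
  sessions with replacement, then trials within each resampled session,
  B = 1000, percentile intervals — propagating both levels of variability.
- **Recovery time constants**: Levenberg–Marquardt exponential fits on a
  window from the perturbation offset. A Euclidean distance between noisy
  trajectory means has a finite-sample floor that combines with the signal
  in quadrature, and a plain additive exponential fit is biased low by up
  to ~25% at realistic floor-to-amplitude ratios; the default therefore
  fits the exponential on the squared curve (exact under a quadrature
  floor, identical when the floor vanishes), with the plain additive model
  available as an option.
- **State-space structure**: per-epoch LDA projections to 3 discriminants
  (shrinkage ridge on the within-class scatter if singular) and orthogonal
  Procrustes alignment (centered, rotation only) between epochs.
- **Model comparison**: brain-similarity is the Pearson correlation
  between decoding-accuracy curves per delay (model curves linearly
  interpolated onto the reference grid), averaged over delays; constant
  curves have no defined correlation and are excluded with a warning.
  Robustness profiles evaluate accuracy under growing synaptic ablation
  fractions (evaluation-time only, no retraining) or process-noise SDs and
  reduce to the noise-weighted mean `sum(noise * perf) / sum(noise)` — the
  normalization makes a never-degrading model score exactly 1 and scores
  comparable across grids. PS-hebb ablation masks entries of K so ablated
  synapses can never develop weight.
- **Synaptic decoding features**: per-unit (u, a) concatenated for PS-pre
  (plasticity is presynaptic, so per-unit variables carry all synaptic
  information); the flattened plastic weight matrix for PS-hebb, with an
  optional seeded random projection to at most 4096 features.

# The surrogate recording generator

`surrogate_config()` parameterizes a generative stand-in for multi-session
multi-electrode recordings: per-unit baselines (uniform 2–10), a
sample-tuned transient whose amplitude is 1 during the sample and decays
exponentially with a 1 s constant through the delay, a distractor-evoked
common-mode population excursion (norm 8) recovering with a 0.2 s
constant, white trial noise (SD 1.5), a log-normal session gain (SD 0.1),
and rectification at zero. Defaults mirror the recorded preparation the
analyses were built for — 6 sessions of 256 units — with scales chosen so
that sample identity decodes near-perfectly during the sample epoch and
declines toward chance (1/8) over the 4 s delay, and the distractor
excursion stands clear of the finite-trial distance floor so its recovery
constant is identifiable. Because the excursion is common across samples,
the distracted/undistracted distance rises and recovers while stimulus
separation is untouched at first order — the dissociation the analyses
assume.

What the surrogate does *not* emulate: spiking point-process statistics,
oscillations, burst dynamics, electrode geometry, or any interesting
trial-to-trial dynamics beyond white noise and a session gain. Passing
tests on surrogate data therefore validates the analysis *machinery* (and
parameter recovery under the stated generative model), not claims about
real cortex.

# Problem sizes and budgets

The full-scale version of this modelling program sweeps on the order of 2000 trained models over 2^14-trial datasets.
This package's test suite and acceptance script run a reduced protocol as
their own design choice: delays {1.0, 1.41} s, 4096 training trials, 1024
held-out trials, hidden sizes 100 (10 for PS-hebb, whose state count
scales with n^2), one seed per family, and wall-clock-capped training.
Analyses use 45–100 ms bins and subsampled bin grids. The `analysis/`
drivers run the same pipeline at slightly larger sizes and write CSV
tables under `results/`.

# What reproduces at desk scale, and what does not

With the budgets above, the central quantitative claim reproduces: both
plasticity models reach >90% held-out accuracy on distractor and
no-distractor trials (a capped acceptance run reported 94.0–95.1% across
the four model × condition cells). The qualitative decodability pattern
also reproduces cleanly: fixed-synapse models keep sample information in
their rates throughout the delay (late-delay decoding ≈ sample-epoch
decoding), while both plastic models show rate decodability that decays
toward chance with synaptic decodability near 1.0 late in the delay.

The structural-robustness ordering reproduces in its score form: the
noise-weighted robustness score over ablation fractions
{0, 0.1, 0.25, 0.5, 0.75} gives PS-pre 0.36 and PS-hebb 0.31–0.32 above
FS-relu 0.30 and FS-tanh 0.21 on both cohorts we measured, driven by the
plastic models' graceful degradation at 10–25% ablation (e.g. PS-hebb
keeps 0.75 accuracy at 25% ablation where FS-tanh is at 0.35). The
single-point accuracy ordering exactly at 50% ablation does *not*
reproduce for one pair (PS-hebb 0.22 vs FS-relu 0.28 over 8 ablation
patterns). Two mechanisms are visible in the runs: randomly masking
entries of the gain matrix K destroys the symmetry the anti-Hebbian
stability construction rests on, so a fraction of heavily ablated trials
genuinely diverge (scored as task failures); and at its conventional size
of 10 units the PS-hebb network has only 100 recurrent synapses, so 50%
ablation removes capacity far more coarsely than in the 100-unit models.
The PS-hebb margin on the score ordering is thin (~0.02), so that check
sits close to its boundary at this scale.

# Known limitations

- The PS-pre initialization follows the printed recipe (Gaussian SD 1/n,
  half the entries zeroed). Under rectification with a zero subgradient,
  entries that start at or below zero receive no gradient, so roughly 75%
  of the recurrent synapses stay silent; an alternative is an
  all-positive (log-normal) initialization that avoids this. Both were
  probed; the printed recipe is the default.
- With training capped at minutes per model, PS-pre typically lands below
  its asymptotic accuracy; PS-hebb reaches the >90% regime within its
  budget. Longer budgets move PS-pre toward the published performance.
- The brain-similarity reference here is surrogate data, not recordings;
  scores are only meaningful relative to each other.
- Decoding uses libsvm's one-vs-one multiclass scheme, which can differ
  slightly from other linear-SVM multiclass constructions near chance.
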