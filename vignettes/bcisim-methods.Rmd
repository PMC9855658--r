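---
title: "Emulating closed-loop intracortical BCI use: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating closed-loop intracortical BCI use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bcisim` is a model system for studying closed-loop intracortical
brain-computer interface (iBCI) control without implants: finger-joint
kinematics stand in for motor imagery, a trained network emulates the firing
rates a microelectrode array would record from primary motor cortex (M1), and
a standard velocity Kalman filter decodes those rates into cursor motion at a
25 ms tick. This vignette documents the models behind each stage, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## 1. The synthetic study data

The pipeline is exercised end to end on synthetic data whose statistical
structure mirrors what the downstream stages assume about real recordings.

**Neural sessions.** A session (`session_spec()`,
`generate_neural_session()`) is a day's set of simultaneously recorded
neurons — between 23 and 93 — observed over 8-condition center-out trials
segmented from 200 ms before to 800 ms after the go cue on a 25 ms grid
(40 samples). The population is driven by a low-dimensional latent state
$x(t) \in \mathbb{R}^6$ obeying linear rotational dynamics $\dot x = M x$
with $M$ skew-symmetric and block-diagonal: the dominant plane rotates at
`rotation_strength` (default $2\pi$ rad/s, i.e. one cycle per second, the
order of magnitude reported for M1 rotational modes during reaching), and the
remaining planes rotate at odd subharmonics with amplitudes decaying by 0.4
per plane. The reach condition $c$ sets the latent initial phase
$2\pi c / 8$, so the 8 conditions occupy a ring. Rates are read out as
$r(t) = \mathrm{softplus}(B x(t) + b_0)$ with a per-session random $B$
(entries $\mathcal N(0, 8^2)$) and baselines $b_0 \sim U(10, 25)$, giving
non-negative rates mostly between 2 and 60 spikes/s. Trial-to-trial
variability is a random offset to the latent initial condition
(`latent_noise_sd`, default 0.08 against a unit-amplitude dominant plane),
evolved under the same dynamics — noise is therefore *correlated across
neurons*, unlike channel-independent Poisson draws, which matters for how a
Kalman filter experiences it.

With these defaults the generated sessions show the three properties the
validation battery checks on real-like data: 8 PCA clusters in ring order
matching the generator phases, cluster separation well above intra-cluster
spread, and a top jPC plane whose angular frequency recovers
`rotation_strength`.

**Spike smoothing.** `smooth_spike_trains()` converts spike times to rates
with a Gaussian kernel of SD 25 ms truncated at ±2 SD (total support 100 ms)
and renormalised to unit mass; each 25 ms bin receives the exact kernel mass
falling inside it (differences of the truncated CDF), so the time integral of
the rate over the window equals the spike count for spikes away from the
window edges. We chose bin-mass evaluation over sampling the density at bin
centers because the sampled sum mis-states the integral by up to ~3%
depending on the spike's phase relative to the grid.

**Kinematic trials.** A posture set (`posture_set()`) is a rest posture plus
8 target postures in normalized 19-sensor glove coordinates, arranged on a
ring of radius 0.25 in a random 2D plane of sensor space with small
off-plane idiosyncrasies, so repeated movements project to 8 separable PCA
clusters in a ring — mirroring the neural geometry. A trial
(`generate_kinematic_trials()`) is a minimum-jerk transition
($10\tau^3 - 15\tau^4 + 6\tau^5$) from rest to a target over 1.2 s, plus
smooth motor noise: Gaussian white noise low-pass filtered with a 100 ms time
constant (brought to stationarity by a burn-in) and scaled to
`motor_noise_sd` (default 0.02 normalized units, a few percent of the 0.25
movement amplitude — the order of trial-to-trial variability a practiced
subject shows on a data glove). Trials start at rest and end on the target
posture; the pre-movement neural window therefore sees near-rest kinematics.

**What the generator does not emulate.** Real M1 has condition-dependent
*preparatory* activity, non-stationary baselines, neuron dropout within
sessions, and rate distributions far from any softplus-of-Gaussian; the glove
data have sensor-specific calibration drift. Passing tests on this generator
shows the pipeline's statistical machinery is correct and that the
architecture can learn a kinematics-to-rates map with the right geometry —
not that the emulator would reach any particular fidelity on real
recordings. One consequence of the prescribed constant-amplitude rotational
latent is visible in training: conditions differ maximally at the trial start
while the paired kinematics are still at rest, so early-window rates are
inherently unpredictable from kinematics and set a floor on the achievable
validation error (about the first quarter of the window).

## 2. Pairing kinematics with neural trials

`build_trial_matrix()` flattens each trial channel-major into a
`[trials] x [channels x timepoints]` matrix; `project_pca2()` takes the top
two principal components with mean-centering only (no per-feature variance
scaling — the subsequent z-scoring removes scale anyway, and the sign of each
component is fixed by making its largest-magnitude loading positive so
embeddings are reproducible). `pair_trials()` z-scores each modality's 2D
coordinates per condition *separately per modality* (the two planes have
incommensurate units; z-scoring each on its own trials is what makes a
Euclidean cross-modality cost meaningful), forms the pairwise distance matrix
and solves the linear sum assignment problem with the Hungarian method
(`clue::solve_LSAP`). A zero-variance coordinate is mapped to 0 so it
contributes nothing to the cost rather than dividing by zero. Ties are
resolved by the solver's deterministic scan order. `replicate_pairings()`
repeats the procedure once per kinematic subject so each neural trial is
paired with several subjects' movements — teaching the network that
inter-subject kinematic variation is noise, not signal.

## 3. The firing-rate emulator

The emulator is a time-delay network: the input at tick $T_0$ is the
concatenation of the 19-sensor samples at $T_0, T_{-1}, \dots, T_{-4}$
(95 inputs spanning 100 ms of history — roughly the delay window over which
linear and recurrent decoders extract most control-relevant information).
Three shared tanh layers (150, 100, 50) form the kinematics encoder; its
50-dimensional output is a latent space of characteristic neural activations.
Each session owns a readout module — a 30-unit tanh layer and a
rectified-linear output layer sized to that session's neuron count — so the
encoder is trained on all sessions' data while readouts capture
session-specific tuning. All layers carry biases. At trial start, missing
lags are filled with the series' first sample (in closed loop the buffer has
a genuine history, so this affects only trial-start transients).

**Loss and optimizer.** Training minimizes the mean absolute error between
emulated and target rates, in raw spikes/s (not per-neuron normalized — the
choice was open; raw units weight active neurons more, which is what the
decoder ultimately sees). The optimizer is minibatch Adam (batch 1024), an
adaptive first-order method run under the termination contract: a session
visit ends when the full-batch loss-gradient infinity norm falls below
$10^{-6}$ — checked exactly at entry, and through the epoch-accumulated
minibatch gradient thereafter (the accumulated gradient is evaluated at
slightly different weights across the epoch; at the $10^{-6}$ scale the
distinction is immaterial) — or when the iteration budget is exhausted
(`steps_per_visit`, capped at $200\times$ the session's trial count). On
first encounter a readout's output bias is set to the session's mean rates
and its output weights scaled to the per-neuron rate SDs, so optimization
refines the shape of the tuning rather than spending thousands of steps
growing weight magnitudes toward the spikes/s scale. The learning rate
(default $6\times10^{-3}$) decays by 0.85 per round. After the schedule
returns the minimum-error round, a *readout polish* stage freezes the shared
encoder, caches its 50-dimensional outputs, and refines each session's
readout module alone at a small learning rate, averaging the weights over
the final 30% of polish iterations; a readout's polish is kept only when it
improves that session's training MAE. The polish exists because minibatch
optimization of an L1 loss leaves the iterate orbiting a noise ball whose
radius the MAE pays for directly; freezing the encoder makes the remaining
problem small enough to converge properly, and touching only readouts
cannot disturb the cross-session transfer structure.

**Schedule.** One round visits every session once in seeded random order
without replacement, updating the shared encoder and the active readout only;
the round error is the mean across-session MAE. Training stops when the
variance of the last 100 round errors falls below 5% of their mean, or at
`max_rounds` (desk-scale runs use 8 rounds of 700 steps — with three
sessions of 160 trials x 4 subjects this is where validation error has
flattened while staying inside a coffee-break runtime; the convergence-window
rule matters for long schedules). The returned network is the snapshot from
the minimum-error round. An 85/15 train/validation split, stratified by
(session, condition) so every stratum keeps its proportion within one trial,
precedes training.

**Reduced emulators.** `train_emulator(withhold_condition = k)` trains the
identical architecture and schedule on the remaining 7 conditions, producing
the leave-one-posture-out emulators used by the generalization analysis.

## 4. The steady-state velocity Kalman filter

The decoder state is $x_k = [V_x, V_y, 1]$: planar cursor velocity in cm/s
plus a constant offset element that absorbs each neuron's baseline rate, the
standard construction for velocity Kalman filters in iBCI work. The
measurement model $z_k = Hx_k + q_k$, $q_k \sim \mathcal N(0, Q)$ is fit by
ordinary least squares (one row per neuron; $Q$ is the residual covariance);
the state model $x_k = Ax_{k-1} + \omega_k$ is fit by least squares of
consecutive reference velocities with the offset row pinned at $[0, 0, 1]$
and zero offset noise. The steady-state gain iterates the discrete Riccati
recursion from a covariance with zero offset variance until the prior
covariance moves less than $10^{-10}$ (cap $10^5$ iterations), then
$K = P^-H^\top(HP^-H^\top + Q)^{-1}$. $Q$ is regularized by
$10^{-8}\,\overline{\mathrm{diag}(Q)}\,I$ before inversion: at desk-scale
calibration counts the residual covariance can be near-singular. Decoding is
$x_k = A\hat x_{k-1} + K(z_k - HA\hat x_{k-1})$ with the offset element
re-pinned to 1 and position integrating velocity over the 25 ms tick.

**Calibration.** Six 30-trial blocks. In every trial the user executes the
paced 1.5 s posture transition for the displayed target while a pre-defined
straight-line ideal trajectory provides the reference. The reference velocity
is the ideal trajectory's velocity; we gave the straight-line path a
minimum-jerk *speed profile* (zero velocity at both ends) rather than a
constant speed, because the executing hand is at rest at the transition's
endpoints — tying zero reference velocity to rest postures is what lets the
decoder hold the cursor still, and a constant-speed reference would associate
rest-posture rates with full speed. Blocks 1–2 are observation-only; after
block 2 the state model is fit from the references and $(H, Q)$ from all
accumulated (rates, reference-state) pairs; blocks 3–6 additionally display
the decoded cursor and refit after each block on all data so far (whether the
original protocol refit $A, W$ per block is unstated; we refit — the
references are identical across blocks so the effect is nil). No re-aiming
rotation of references is applied. Calibration uses the 4 task targets, whose
directions coincide with 4 of the 8 trained posture directions.

## 5. The closed-loop task

`run_trial()` loops at the 25 ms tick: sample the user's posture, push it
into the 5-tap lag buffer, emulate rates, decode one Kalman step, clamp the
cursor to the 31 x 31 cm workspace. A hit requires the cursor to stay inside
the 5 x 5 cm target square continuously for 500 ms, timed from target entry
(the dwell counter resets fully on exit); a trial times out at 7 s. "Inside"
means the cursor *center* is in the square (configurable to disc-overlap; the
original geometry is unstated). The target distance is set by the Shannon
form of the Fitts index of difficulty, $ID = \log_2(D/W + 1) = 1.2$, giving
$D = 5(2^{1.2}-1) \approx 6.49$ cm. Between trials an untimed return-to-center
phase runs until the cursor is within 1 cm of the center (with a 30 s
failsafe recentering, which a functioning decoder never reaches). The 6.5 s
error-rate criterion and the 7 s timeout are kept as two distinct constants,
as printed in the protocols this emulates.

**The simulated user.** `simulated_user_policy()` stands in for the human:
at each tick it computes the desired direction $d$ from cursor to target,
weights every trained posture by
$\max(0, \cos\angle(d, \mathrm{dir}_j))^p$ (default $p = 4$; higher $p$
commits harder to the nearest posture), blends the posture deviations from
rest with those normalized weights, low-pass filters the command with
$\tau = 150$ ms (a plausible voluntary-movement smoothing constant), adds
Gaussian motor noise and clips to $[0, 1]$. Within 1 cm of the target the
command decays to rest, which (with the zero-velocity calibration reference)
holds the cursor for the dwell. This greedy policy has no learning, no
prediction and no error-corrective strategy beyond pointing at the target —
it is deliberately the simplest controller that can complete the task, so
closed-loop viability results say "the stack is controllable", not "humans
would perform like this".

## 6. The validation battery

**Peri-event averages** (`perievent_average()`): per-(neuron, condition)
trial-averaged traces plus, as a population summary, the SD across all
neuron-condition averages at each timepoint.

**Mantel test** (`mantel_test()`): Pearson correlation of the upper
triangles of two distance matrices; the one-sided p-value is the fraction of
row/column label permutations of the second matrix — including the identity —
with permuted correlation at least the observed one. With $n! \le$
`n_perm` all permutations are enumerated exactly (important at $n = 8$
cluster labels where sampled p-values would be granular); otherwise
`n_perm` − 1 sampled permutations plus the identity are used. Labels of the
cluster-center distance matrix are permuted (whether the original analysis
permuted cluster labels or trial-level distances is unstated; center-label
permutation matches the "ring structure" question being asked).

**jPCA** (`jpca()`): target-averaged rates, cross-condition mean trace
subtracted, projected on the top 6 PCs; state derivatives by central finite
differences on the 25 ms grid; then the skew-symmetric dynamics matrix
minimizing $\|\dot X - MX\|_F$ in closed form over the 15-dimensional
skew-symmetric basis (a small linear least-squares problem — no iterative
optimization). Planes come from eigenvector pairs ordered by
$|\mathrm{Im}\,\lambda|$; the variance captured by a plane is the variance of
the projections over the variance in the 6-PC space. No soft-normalization of
rates is applied before averaging (the flag exists, default off; the variant
used originally is unstated).

**Ellipse fit and generalization** (`fit_ellipse()`,
`generalization_stats()`): the direct least-squares conic fit with the
ellipse constraint $4ac - b^2 = 1$, in its numerically stable partitioned
form, on coordinates centred and scaled for conditioning. For a reduced
emulator, the withheld class's emulated trials are projected into the PCA
plane defined by the 7 training classes and three normalized statistics are
computed: distance of the withheld-cluster center to the ellipse fit to the
7 training centers (divided by the training centers' mean distance to that
ellipse), the intra-cluster variation ratio, and the mean distance to the
two ring-adjacent training centers (divided by the training centers' mean
nearest-neighbor distance); plus a boolean — whether the withheld center's
nearest boundary point falls on the ellipse arc between its two neighbors'
own boundary projections, the arc being chosen as the one free of the other
training classes' projections (falling back to the shorter arc in degenerate
configurations). Point-to-ellipse distance is a 1D minimization over the
boundary parameter with 16 starts at tolerance $10^{-12}$. All three ratios
are scale-invariant by construction.

## 7. Behavioral measures

For each trial, with $Y_i$ the *signed* orthogonal distance of trajectory
point $i$ to the start-to-target line (go cue through trial end, dwell
included; configurable to exclude dwell): movement error ME is the mean of
$|Y_i|$ (a distance, hence unsigned); movement variation MV is the sample SD
$\sqrt{\sum_i (Y_i - \mu_Y)^2 / (N - 1)}$ — the defining equation's index
mismatch (sum to $N$, denominator $k-1$) is resolved as $k = N$ since the
quantity is described as a standard deviation, and signs are kept because a
deviation around a mean forces them to be meaningful. MDC and ODC count sign
flips of the per-tick velocity components perpendicular and parallel to the
line, one count per flip, with a dead band (default $10^{-6}$ cm per tick)
under which a component carries its previous sign — without it, numerical
jitter near zero would count unboundedly. MT is go-cue-to-dwell-completion
time (misses excluded from aggregation); ER is the fraction of trials not
hit within 6.5 s; DR is polyline path length over the straight-line distance
between the first and last cursor positions, which is at least 1 for
distinct endpoints — the original text's remark that DR's maximum is unity
contradicts its own printed definition and is treated as an erratum; the
definition is implemented as printed. All seven are invariant to rigid
motions of the workspace. `metric_correlations()` gives pairwise Pearson
correlations with two-sided p-values; `learning_corrected_session_effect()`
subtracts each visit's across-subject mean score before averaging by
emulator session, isolating session effects from learning.

## 8. Problem sizes, determinism and limitations

The default desk-scale study conditions — 3 sessions of 30/45/60 neurons,
20 trials per condition, 4 replicated kinematic subjects, with one 93-neuron
session for the closed-loop check — keep the full pipeline (training
included) within tens of minutes on one CPU while preserving every
structural property the statistics test. Paper-scale counts (22 sessions,
132+ trials per condition, 25 subjects x 4 visits) are reachable through the
same configuration objects. Every random draw is governed by explicit seeds;
a fixed seed reproduces trained weights, trial logs and metric files
byte-for-byte (wall-clock diagnostics are kept out of written artifacts for
this reason).

Known limitations: the emulator's early-window error floor under the
rotational generator (§1); the greedy simulated user's lack of learning,
so across-visit learning curves exist only as hooks
(`learning_corrected_session_effect()` operates on whatever scores are
supplied); no discrete click/selection classifier; no adaptive decoder
updating during the test phase; and live glove input is an adapter interface
(`user_policy` objects), not a shipped driver.
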