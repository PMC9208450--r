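---
title: "Model and methods: self-organization of the monosynaptic stretch-reflex loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinloop)
```

## The question the simulator addresses

In adult vertebrates, muscle-spindle primary (Ia) afferents connect
monosynaptically and predominantly to the motoneurons of their *own*
muscle — the circuit behind the tendon-jerk reflex. A naive Hebbian account
of how this wiring could be learned runs into a paradox: when a motoneuron
fires, its muscle shortens, which *unloads* the spindle and silences the
very afferent whose synapse should be strengthened.

`spinloop` simulates a resolution based on two developmental facts:

1. **Beta-motoneurons.** A large fraction of vertebrate motoneurons
   innervate both force-producing (extrafusal) fibres and the small
   intrafusal fibres inside the spindle. Activating a βMN therefore
   *excites* the homonymous spindle directly (the fusimotor effect), even
   while the muscle shortens.
2. **Fetal weakness.** Early extrafusal muscle is roughly ten times weaker
   than mature muscle, so spontaneous fetal twitches barely move the limb.
   The fusimotor excitation then dominates the (small) unloading, and
   "fire together, wire together" points the right way.

The simulator closes the full loop — spontaneous motoneuron twitches →
weak muscles → a viscous 1-D body → proprioceptors → learnable synapses
back onto the motoneurons — and asks which 4×4 Ia→motoneuron weight matrix
self-organizes under different muscle strengths, twitch statistics and
sensor models.

## The plant

The body is one-dimensional: a trunk with two limbs, each pulled by an
antagonist pair of muscles (order throughout: LE, LF, RF, RE — left
extensor, left flexor, right flexor, right extensor). Mechanics are
viscosity-dominated, as for small aquatic organisms: limb velocity is
proportional to net force (`velocity = force / damping`, damping 2.0), with
no inertia and hence no overshoot. Muscles are springs with zero rest
length that pull but cannot push: force = `G · MS · A · s`, with `A ∈
[0,1]` the activation, `s ∈ [0,8]` the spring length in world units, `MS`
the muscle-strength fraction (0.1 in the fetal regime) and `G` a gain
calibrated so that one fully activated muscle at `MS = 1` traverses the
full ±4-unit limb range in about 2 s (`calibrate_muscle_gain()`; because
the spring force vanishes as the muscle shortens, the approach to the far
stop is asymptotic and the traverse is scored at 99% of travel). Limbs are
clamped at anatomical stops, at the walls of the world and at limb–limb
contact, with the absorbed force recorded as a contact reaction. The trunk
has stiction — it moves only when braced against both walls with a net
force above 50% of maximal muscle force — so twitching never drifts the
body.

Normalized sensor coordinates: muscle length `L = 0.2 + 0.1·s` (neutral
0.6, range [0.2, 1.0]); muscle velocity `V = L̇ / V_ref` clipped to
[−1, 1], where `V_ref` is the fastest stretch achievable (a fully
activated antagonist at `MS = 1` acting on the longest spring).

## Proprioceptors

Each muscle carries three receptors, all scaled and clipped to [0, 1]
(`spindle_II()`, `spindle_Ia()`, `gto_Ib()`, `spindle_Ia_alpha()`):

* **Spindle II** (length): `II = ((L − 0.2)·1.25 + A) / 2`. The `A` term
  is the static fusimotor bias from βMN co-innervation.
* **Spindle Ia** (velocity + length + fusimotor):
  `Ia = ((1.5 + log10(A + 0.1))·V + A + 0.2·II) / 2`. The
  activation-dependent velocity gain is 0.5 for a passive muscle and
  saturates logarithmically — the dynamic fusimotor effect. Checkpoints: a
  passive muscle at maximal stretch velocity gives 0.25; a maximally
  active muscle at maximal stretch clips at 1; at maximal shortening it
  clips at 0.
* **Ia without fusimotor action** (`spindle_Ia_alpha`): `(L + V)/2`,
  the α-only ablation used in control experiments.
* **Golgi tendon organ Ib** (force): `A·L`, a linear sensor of active
  force. The functional form follows from the plant's spring law (active
  force ∝ activation × length); it is the package's choice where only
  "linear in active force" is constrained.

Clipping is applied to the complete expression, not per term.

## The motoneuron

One rate neuron per muscle stands in for the whole, gap-junction-coupled
motor pool. Synaptic input is summed linearly, smoothed with a fast
exponential filter (gain `K_A = 0.3` per 10 ms step), and divided by a
shunting denominator:

```
P = φ(Σ pre_j · w_j⁺ · S_j, K_A)  /  (k + φ(Σ pre_j · w_j⁺, K_A))
```

with the leak `k = max(0.5, 2 × rolling unsigned sum)`. The rolling
estimate uses the slow gain `K_M = 4×10⁻⁵` (time constant ≈ 250 s), making
the leak a homeostatic background rather than a tracker of individual
twitches; using the fast gain instead (`leak_gain = K_A`) empirically
destroys selective learning because the leak then cancels the very
transients the plasticity needs. All synapses here are excitatory
(`S = +1`); signs are fixed by a static sign matrix, never by the weight.
Muscle activation applies a small hyperpolarizing bias:
`A = max(0, (P⁺ − 0.1)/0.9)`, compensating for the absence of inhibitory
neurons.

A slow trace `P̄ = φ(P⁺, K_M)` represents the neuron's running mean
activity (phosphatase/kinase balance in calcium terms).

### The pacemaker drive and the shunting denominator

Spontaneous twitch drive enters each motoneuron through a fixed,
non-learnable synapse of weight 1. Whether that drive also adds to the
shunting denominator is a genuinely open modelling point, and the package
exposes it (`sim_config(apg_shunt = )`):

* `apg_shunt = FALSE` (default): the drive acts as an **intrinsic
  pacemaker current** — it excites but does not shunt; only sensory
  synapses load the membrane. `P` is clipped to its [−1, 1] range. This is
  the configuration in which a 100%-amplitude twitch can actually drive
  the motoneuron through its full output range, and in which the fetal
  training conditions converge to the selective homonymous matrix within
  20,000 s (exercised end to end by the test suite).
* `apg_shunt = TRUE`: the drive is an ordinary shunting synapse. Output
  then saturates near 0.67 for a full-amplitude twitch; learning is
  qualitatively identical but several-fold slower. The
  playback-attenuation property (routed responses smaller than open-loop
  playback, the signature of leaky integration) is meaningful only in
  this configuration and is tested there.

## Plasticity: the calcium-covariance rule

Initial weights are drawn from N(0.2, 0.16), redrawing below 0.001 so all
start positive and small. Per learnable synapse and step:

```
l  ← clip(φ(pre · w · (hp(P) − P̄), K_L), −1, 1)      K_L = 0.001
c  =  1 − w  if l ≥ 0,   w  otherwise
η  =  clip(0.04 · P̄, 0, 0.001)
w  ← clip(w + l·η·c, −1, 1)
```

`hp(P)` is a first-order high-pass at 0.05 Hz (τ ≈ 3.2 s), modelling the
fast supralinear calcium transient; its difference from `P̄` makes the rule
a covariance: synapses whose presynaptic activity coincides with
postsynaptic transients potentiate, tonically active but uncorrelated
synapses are scaled down (homeostatic synaptic plasticity). The
compensation factor `c` soft-bounds the weights: potentiation stalls as
`w → 1`, and a negative weight (nonfunctional — only `w⁺` is used
downstream) relaxes back toward zero.

**Learning-rate law.** The activity dependence of η is implemented as
`scale · P̄^exponent` with a clamp at 0.001; the default is linear
(`0.04·P̄`). A quartic variant (`P̄⁴·0.01`) is available through
`sim_config(eta_exponent = 4, eta_scale = 0.01)`, but in the fetal regime
the mean activity sits at `P̄ ≈ 0.03–0.2`, so the quartic rate is below
10⁻⁵ and weights cannot traverse their range within a 20,000 s run; the
linear law (which is at its 0.001 clamp whenever `P̄ > 0.025`) is the
reading under which the model's reported dynamics are reproducible.

## Spontaneous activity: the twitch generator

Each motoneuron carries an independent twitch generator. Once per decision
epoch (default 0.2 s) an idle motoneuron starts a twitch with probability
`p`; a twitch is a square pulse with amplitude ~ U(0, 1), duration ~
U(50, 100) ms (presets up to 950–1,000 ms), smoothed by the one-step
exponential filter with gain ~ U(0.5, 0.8), and truncated to zero once it
decays below 1% of its amplitude (the motoneuron is busy until then). At
the default `p = 0.1` this yields ≈0.5 twitches/s per muscle — within the
range of observed fetal per-muscle twitch rates. The epoch length is the
one stochastic-timing constant that observation does not pin down; 0.2 s
was fixed once, before the validation runs were frozen, as the value whose
event rate supports convergence of initially weak synapses within a
20,000 s run. Reduced variants restrict the repertoire:

* `no_cocontraction` — a twitch is cancelled if the same-limb antagonist
  is active at its onset (the trace-level guarantee that antagonist drives
  are never simultaneously positive is tested exhaustively);
* `symmetrical_only` — joint twitches of the mirror pairs LE+RE or LF+RF;
* `in_phase_only` — joint twitches of the contralateral synergist pairs
  LE+RF or LF+RE.

Joint events share a single amplitude/duration/gain draw, emulating
synchronized pools. Deterministic phasic schedules (all 16 binary
activation permutations, or arbitrary scripts) are available via
`phasic_sequence()` / `apg_drive_from_script()` for playback and probe
experiments.

## The closed loop

`run_simulation()` advances, per 10 ms step: (1) plant positions from the
previous activations, with contacts; (2) normalized muscle kinematics;
(3) sensor outputs (the same `A` drives extrafusal force and intrafusal
bias — the βMN assumption); (4) motoneuron integration, plasticity, and
the next activations. The inner loop is compiled (Rcpp); a pure-R
reference engine (`run_simulation_r()`) implements the identical
arithmetic and the test suite checks agreement to 10⁻¹². Runs are
deterministic given the seed, which fixes the initial weights and the
twitch stream; snapshots serialize the full state as JSON at 17
significant digits so that a resumed run is bit-identical to an unbroken
one.

## What the generator emulates — and what it does not

The twitch generator reproduces the *statistics* of spontaneous fetal
motor activity: independent, sparse, randomly sized single-muscle twitches
with fast rise and decay. It does not emulate: correlated multi-muscle
synergies beyond the scripted variants, sensory noise (all sensors are
noiseless functions of the mechanical state), spiking discreteness,
multiple motor units per muscle, gravity or external objects. Passing
tests therefore demonstrate the self-organization principle in a clean
closed loop, not robustness of the mechanism to afferent noise or richer
biomechanics. Two quantitative limits of this implementation are worth
stating plainly:

* **High twitch rates wash out.** Above roughly 3 twitches/s per muscle
  the 0.05 Hz high-pass no longer isolates individual transients and the
  homeostatic term dominates; homonymous end weights then fall well below
  saturation. Selectivity (homonymous ≫ heteronymous) survives across the
  whole preset range `p ∈ {0.1, …, 0.75}` and all three duration ranges —
  that is the form of the robustness claim the test suite asserts.
* **The plant is exactly mirror-symmetric.** Under the joint-pair
  variants the homonymous afferent and the paired partner afferent carry
  identical signals, so their end weights converge to equal values
  (≈0.6/0.6 under both joint variants) rather than to asymmetric pairs;
  an asymmetry would require left–right or extensor–flexor asymmetries in
  the plant that this minimal geometry deliberately omits.

## Numerical choices

* Explicit first-order stepping at `dt = 10 ms`; all filter gains are
  defined per 10 ms step and rescaled as `K' = 1 − (1−K)^(dt'/0.01)` if
  `dt` changes, preserving time constants.
* Contacts are position clamps with the absorbed force reported as the
  reaction; no physics-engine solver state.
* Clipping: sensors to [0,1] after the full expression; `P` to [−1,1];
  `l` to [−1,1]; weights to [−1,1]; drive streams to [0,1].
* Degenerate inputs: zero-probability drive with zero weights is an exact
  fixed point (no drift); a silent neuron (`P̄ = 0`) has learning rate 0.
* Validation problem sizes: training experiments use the full 20,000 s
  (2×10⁶ steps) with n = 3 replicates; the muscle-strength sweep and the
  probability/duration robustness checks use 10,000 s with n = 2, which
  resolves the orderings and crossings they assert while keeping the
  whole suite to a few minutes.

## Experiment presets

* `run_replicates(sim_config(), n = 3)` — fetal training (MS 0.1,
  p 0.1, 50–100 ms twitches): selective homonymous matrix.
* `run_strength_sweep()` — MS 10–100%: homonymous weights decline with
  strength while antagonist weights rise (stronger twitches unload the
  homonymous spindle and stretch the antagonist's), the two group means
  meeting near full strength. In this plant the static fusimotor `A` term
  keeps the homonymous Ia from being silenced completely during strong
  twitches, so at 100% strength the two groups sit close to equality and
  a strict inversion of the scheme is seed-dependent rather than a
  reliable end state (`weight_crossing()` reports both the
  closest-approach grid point and, when present, the strict inversion
  point).
* `run_control("Ia_alpha" | "Ib" | "II")` — sensor ablations: without
  fusimotor action all weights decay (no usable correlation at fetal
  strength); Ib force feedback also wires a strong selective diagonal
  (active force always tracks the homonymous motoneuron); II length
  feedback gives a much weaker but still selective diagonal (large tonic
  baseline, small activation-locked transient).
* `probe_reflex()` — a single 50 ms full-amplitude pulse into one trained
  motoneuron; reports response duration, evoked kinematics and whether
  the antagonist's stretch reflex fires. With diagonal weights the
  response outlasts the pulse (reverberation through the Ia loop), and
  the antagonist response appears only once muscle strength makes the
  evoked stretch fast enough. Scored as "any nonzero antagonist
  activation", that threshold is 30% strength in this implementation,
  though the response stays below 1% amplitude until ~40–50% strength.
* `run_playback()` — scripted schedules with or without the network.
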