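# spinloop

Closed-loop simulation of how the spinal monosynaptic stretch-reflex
circuit can wire itself up during early development, for computational
neuroscientists and motor-control researchers studying activity-dependent
circuit formation.

## The problem

Muscle-spindle primary (Ia) afferents in adult vertebrates project
monosynaptically and predominantly onto the motoneurons of their own
muscle. Pure Hebbian learning seems unable to explain this: firing a
motoneuron shortens its muscle, unloads the spindle, and silences exactly
the afferent whose synapse should strengthen. `spinloop` simulates the
resolution offered by **β-motoneurons** — which innervate intrafusal
(spindle) fibres alongside the weak extrafusal fibres of the fetal stage —
in a minimal but complete sensorimotor loop: a one-dimensional,
viscosity-dominated body with two limbs and four muscles (LE, LF, RF, RE),
proprioceptors (Ia, II, Golgi tendon organ Ib), one rate-coded motoneuron
per muscle, and spontaneous fetal-like twitch generators.

## The model core

Each motoneuron is a linear-summation rate neuron with a shunting leak
(φ is a one-step exponential smoother, `φ(x, K): y ← y(1−K) + xK`):

    P_i = φ(Σ_j P_j⁺ w_ij⁺ S_ij, K_A) / (k_i + φ(Σ_j P_j⁺ w_ij⁺, K_A)),
    k_i = max(0.5, 2 · rolling Σ_j P_j⁺ w_ij⁺),       A_i = ((P_i⁺ − 0.1)/0.9)⁺

Spindle sensors with β-fusimotor action (all outputs clipped to [0, 1]):

    II = ((L − 0.2)·1.25 + A) / 2
    Ia = ((1.5 + log10(A + 0.1))·V + A + 0.2·II) / 2
    Ib = A·L                      Ia_α = (L + V)/2   (fusimotor ablation)

Calcium-covariance plasticity on the 4×4 Ia→MN weight matrix:

    l_ij ← φ(P_j⁺ w_ij (hp(P_i) − P̄_i), K_L)         (learning signal)
    Δw_ij = l_ij · η_i · c_ij,   c_ij = 1−w_ij if l_ij ≥ 0 else w_ij
    η_i = min(0.001, 0.04 · P̄_i),  P̄_i = φ(P_i⁺, K_M),  hp = 0.05 Hz high-pass

Under weak fetal muscles (10% strength) and sparse random twitches, the
fusimotor loop makes each Ia afferent fire with its own motoneuron, and
the weight matrix converges to the adult pattern: a saturated homonymous
diagonal with depressed heteronymous projections.

## Worked example

Train one fetal network for 5,000 s (about 1 s of compute):

```r
library(spinloop)
cfg <- sim_config(duration = 5000)     # MS = 0.1, p = 0.1, 50-100 ms twitches
sim <- run_simulation(cfg, seed = 1)
print(sim)
#> <spinloop_sim> 500000 steps (5000 s), sensor Ia, MS 0.1, seed 1
#> final weights:
#>       LE    LF    RF    RE
#> LE 0.609 0.220 0.208 0.099
#> LF 0.216 0.554 0.134 0.176
#> RF 0.061 0.187 0.784 0.248
#> RE 0.275 0.216 0.196 0.555
summarize_weights(sim)
#>   relationship      mean         sd
#> 1   homonymous 0.6257226 0.10856235
#> 2   antagonist 0.2201331 0.02154990
#> 3     in_phase 0.1653115 0.07152925
#> 4       mirror 0.1735955 0.07638855
```

Rows are motoneurons, columns the muscle of origin of the Ia afferent.
After 5,000 s the homonymous (diagonal) synapses have clearly potentiated
(mean 0.63 from initial ~0.23) while heteronymous synapses are being
depressed; by the full 20,000 s training the diagonal saturates near 1.0
and heteronymous groups fall below 0.1. Other experiments:

```r
run_strength_sweep()                  # homonymous/antagonist vs muscle strength
run_control("Ia_alpha")               # ablate fusimotor action: weights decay
probe_reflex(diag(4), muscle_strength = 0.6)   # stretch-reflex probe
```

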