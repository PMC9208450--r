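Package: spinloop
Title: Self-Organization of the Spinal Monosynaptic Stretch-Reflex Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulator of activity-dependent self-organization of
    muscle-spindle Ia afferent to motoneuron connectivity during early
    development. Couples a one-dimensional viscosity-dominated two-limb
    musculoskeletal plant with antagonist pulling-only muscles to
    proprioceptor transfer functions (spindle Ia with beta-motoneuron
    fusimotor action, spindle II, Golgi tendon organ Ib), a linear-summation
    rate neuron with activity-dependent shunting leak, and a calcium-
    covariance Hebbian plasticity rule. Spontaneous fetal-like muscle
    twitches are produced by configurable stochastic and phasic activity
    pattern generators. Includes experiment presets for muscle-strength
    sweeps, reduced twitch-generator variants, sensor-ablation controls, and
    reflex probe protocols, plus snapshotting and weight-matrix summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
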