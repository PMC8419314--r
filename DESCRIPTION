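Package: naveip
Title: Effective Inhibitor Potency Analysis for Sodium Channel Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Concentration-independent characterization of sodium-channel
    inhibitor mechanism of action from voltage-clamp recordings. Implements
    a composite 17-pulse protocol probing state-dependent onset, recovery
    from inactivation and steady-state inactivation; per-pulse
    concentration-inhibition (Hill) fitting yielding effective inhibitor
    potency curves; resting- and inactivated-state affinity estimation;
    macroscopic washout and millisecond-scale (micro) binding-kinetics
    descriptors; and a Markov channel-plus-drug simulator with
    state-dependent binding, perfusion kinetics and measurement noise that
    serves as the ground-truth generator for validating every stage by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
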