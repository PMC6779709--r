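Package: gaitfes
Title: Personalized Planar Neuromusculoskeletal Gait Models and FES Treatment Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building personalized planar neuromusculoskeletal walking
    models from treadmill gait data (markers, ground reactions, EMG envelopes) and
    for designing functional electrical stimulation (FES) treatments that improve
    propulsive-force symmetry between the legs. Provides EMG-driven Hill-type
    muscle models with rigid tendons, polynomial surrogate musculoskeletal
    geometry, deformable foot-ground contact, muscle-synergy extraction by
    non-negative matrix factorization with missing-channel reconstruction, a
    direct-collocation optimal-control engine built on joint-jerk controls, a
    four-stage model personalization pipeline with verification, and a sequence
    of treatment optimizations that minimize inter-leg anterior-posterior force
    impulse asymmetry under simulated stimulation of two muscles. A virtual
    patient generator with a paretic plantarflexor deficit supplies fully
    ground-truthed synthetic gait trials for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
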