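Package: ticdro
Title: Differential-Reinforcement Engine and Session Analytics for Tic
    Suppression Training
Version: 0.1.0
Authors@R:
    person("Ticdro", "Developers", email = "maintainers@ticdro.dev",
           role = c("aut", "cre"))
Description: A headless re-implementation of a gamified behavior-therapy
    platform for tic disorders: a differential-reinforcement-of-other-behavior
    (DRO) reward engine that pays points for tic-free intervals, a masked
    noncontingent-reward (NCR) control scheduler, a session lifecycle state
    machine with trainer heartbeat timeout and birthdate anonymization, a
    text-based session-log format with bit-exact round-tripping, per-session
    suppression metrics, point-process analytics (Fano-factor fractal scaling,
    reward-timing permutation tests), and a seeded simulator of synthetic tic
    streams so every component can be exercised without human subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
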