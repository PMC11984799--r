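Package: tonewheel
Title: Simulated Auditory Tone-Cloud Decision Tasks with a Steering Wheel
Version: 0.1.0
Authors@R:
    person("DMC", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hardware-free implementation of a head-fixed mouse behavioral
    platform for auditory decision-making: tone-cloud stimulus synthesis,
    quadrature wheel-encoder signal processing, event-driven trial state
    machines for detection, Go/NoGo and two-alternative forced choice (2AFC)
    tasks with fully automated staged training, synthetic mouse agents with
    parameterized psychometric ground truth, signal-detection (d-prime) and
    maximum-likelihood psychometric analysis, and TTL frame-pulse
    synchronization utilities. Sessions run closed-loop on a virtual clock
    so every component is testable end to end without a rig.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
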