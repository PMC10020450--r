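Package: wetcow
Title: Critically Synchronized Wave-Mode Networks for Memory and Shallow Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates weakly evanescent cortical wave (WETCOW) oscillator
    modes, in which each network node carries both an amplitude and a phase
    and the phase difference between nodes gates amplitude growth and phase
    pull.  Provides single-mode amplitude-phase dynamics with closed-form
    criticality and spiking-frequency predictions, coupled multi-mode network
    integration, constructive design and verification of critically
    synchronized memory loops, spike detection and synchronization metrics, a
    dispersion-relation map from anisotropic conductivity tensor fields, a
    leaky integrate-and-fire baseline, seeded synthetic generators, and a
    shallow classifier that encodes patterns as mode excitations and decides
    by synchronization response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
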