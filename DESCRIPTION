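Package: spimsim
Title: Fail-Safe Virtual Light Sheet Fluorescence Microscope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully virtual, fail-safe light sheet fluorescence microscope
    (SPIM) for unsupervised settings such as museum exhibits: a synthetic
    two-channel zebrafish-vasculature phantom served by simulated peripherals
    behind per-device interface contracts, a supervisor state machine with
    automatic re-initialisation, fall-back (simulating) and fatal modes plus a
    watchdog restart loop, debounced seven-button interaction with an LED
    auto-off policy, preview and z-stack acquisition with depth-colour-coded
    back-to-front alpha compositing, and usage telemetry with daily statistics,
    a one-rendering-per-day archive and website data-file export. Fault
    injection makes every error-handling path testable with scripted event
    trains and schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
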