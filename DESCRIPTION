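Package: polardrum
Title: Virtual Intensity-Polarization Optomotor Drum: Stimuli, Polarimetry
    and Gaze-Stabilization Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gaze stabilization and polarization vision in
    aquatic crustaceans with a virtual optomotor drum built from four flat
    intensity-polarization screens. Renders perspective-corrected rotating
    gratings and looming discs in either an intensity or a polarization
    channel; models the screens' Stokes-state encoding, receptor quantum
    catch and polarization distance for a two-channel polarization vision
    system; extracts eye and body responses from marker videos or angle
    traces (nystagmus segmentation, optokinetic and optomotor scoring);
    estimates contrast thresholds with a descending/bisection staircase and
    assembles individual and cohort contrast sensitivity functions; and
    generates synthetic observers, traces, marker videos and polarimetric
    image stacks with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
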