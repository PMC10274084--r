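Package: sfgating
Title: Selectivity-Filter Gating Analysis for Single-Channel Recordings
    and Ion-Channel Simulation Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying potassium-channel selectivity-filter
    gating from two complementary data sources: single-channel patch-clamp
    recordings (50% threshold idealization with Gaussian-filter dead-time
    theory, NPo/Po statistics, Boltzmann open-probability voltage fits,
    all-points amplitude histograms with two-Gaussian and semi-logarithmic
    tail fits) and molecular-dynamics-derived time series (ion permeation
    counting across the filter, binding-site occupancy, negative-log-density
    free-energy profiles, rotamer classification, hydrogen-bond break and
    inactivation event detection, event-aligned probability curves, and
    pKa-shift conversion from deprotonation free energies). Includes
    synthetic-data generators with exact ground truth emulating the
    corresponding recording and simulation conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
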