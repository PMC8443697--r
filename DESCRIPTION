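Package: vsrnoise
Title: Ship Source Levels, Sound Exposure, and Vessel Speed Reduction Noise Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-transit underwater radiated noise from commercial
    ships recorded on a deep single-channel hydrophone with paired AIS
    (Automatic Identification System) tracks. Received levels are computed as
    calibrated 1-Hz power spectral densities, converted to source levels with
    a modified Lloyd's-mirror transmission-loss model (surface-interference
    two-ray model below a crossover frequency, spherical spreading above it),
    and integrated into sound exposure levels over each passage. Group
    comparisons across vessel-speed-reduction program participation (Welch
    t-test; Kruskal-Wallis with Dunn post-hoc tests and Benjamini-Hochberg
    adjustment) quantify the noise reduction achieved by slower transits. A
    synthetic-data module generates summary transit tables and full ship
    passage waveforms so the entire pipeline can be exercised and validated
    without access to archival recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
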