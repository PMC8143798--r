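Package: sacspike
Title: Intra-Saccadic Spike Effects on Microsaccade Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how movement-unrelated superior colliculus
    spiking occurring around microsaccade onset alters microsaccade metrics.
    Includes microsaccade detection from high-resolution eye-position traces,
    event-aligned spike counting and firing-rate estimation, visual-burst
    quantification, linear spike-count-to-amplitude models with trial-count
    level filtering, sliding-eccentricity slope profiles, burst-timing trial
    sorting with consecutive-bin significance, per-amplitude-bin spike time
    courses, efferent-lag estimation by cross-correlation, movement response
    field mapping with two-dimensional Gaussian fits, population
    normalization, and a synthetic session generator with ground truth for
    end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
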