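Package: peakrescue
Title: Joint LC-MS Feature Extraction with MS2-Based Peak Rescue
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint feature extraction for untargeted LC-MS metabolomics and
    exposomics. Combines centWave-style chromatographic peak picking with two
    complementary tiers: rescue of features via their DDA MS2 precursor ions
    (precursor deduplication, novelty check against picked peaks, apex
    relocation, local-noise and consecutive-scan validation) and direct
    extraction of a user-defined targeted compound list. Includes cross-sample
    density grouping with gap filling, MS2 spectral-library annotation by
    dot-product similarity against MSP libraries, calibration-curve limit of
    detection estimation from serial dilutions, and a seeded synthetic DDA
    run generator (mzML plus ground truth) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    withr,
    optparse,
    stats,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
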