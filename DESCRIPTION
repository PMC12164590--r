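Package: comigrate
Title: Complexome Profiling Analysis of BN-PAGE Migration Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of complexome-profiling experiments in which native
    protein complexes are separated along a blue-native PAGE lane, the lane
    is cut into consecutive slices, and proteins are quantified per slice by
    mass spectrometry. Provides anchor-set median-of-ratios sample
    normalization, replicate-averaged migration profiles with max-normalized
    heat-map matrices and hierarchical clustering, per-protein Welch tests on
    lane sums, per-band-window tests, amplitude-adjusted profile distances,
    band-window abundance ratio tables with detection flags and complex-level
    median summaries, and a comigration screen for candidate assembly factors
    that accumulate in early-intermediate band windows in a mutant but not in
    the reference strain. A synthetic BN-PAGE complexome generator with known
    ground truth supports end-to-end testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
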