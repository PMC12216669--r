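Package: eshcoord
Title: Coupling Coordination and Configurational Analysis of Regional
    Economy-Society-Healthcare Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing regional health equity from county-level
    indicator panels. Implements entropy-weight scoring of a 20-indicator
    economy/society/healthcare system, the coupling coordination degree
    (CCD) model with its ten-grade classification, regional and temporal
    disparity summaries, and a complete fuzzy-set Qualitative Comparative
    Analysis (fsQCA) engine: quartile-anchored direct calibration,
    necessity analysis, truth-table construction with frequency,
    consistency and PRI cutoffs, Quine-McCluskey minimization with
    complex, parsimonious and intermediate solutions, core/peripheral
    condition labelling, coverage bookkeeping and robustness scans.
    A synthetic-data generator with plantable ground truth supports
    end-to-end testing, and the published county-by-year CCD matrix for
    Zhejiang Province (2020-2022) ships as a verification fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
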