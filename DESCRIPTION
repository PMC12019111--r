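Package: statedyn
Title: Dynamic Brain-State Analysis for ROI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering and quantifying recurrent brain states
    in regional fMRI time series: motion/nuisance postprocessing with frame
    censoring, k-means clustering with correlation distance and elbow-based
    model selection, dynamic metrics (fractional occupancy, dwell time,
    appearance rate, transition probabilities), paired pharmacological
    contrasts with Benjamini-Hochberg correction, receptor-availability
    correlations at ROI and voxel level with cluster-extent filtering, and
    bootstrap mediation analysis. Includes a synthetic-cohort generator with
    planted Markov state structure, receptor values, and behavior so the whole
    pipeline is testable without access to human imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
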