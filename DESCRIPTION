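Package: relspike
Title: Relational Concept-Neuron Analysis of Human Single-Unit Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and classification of stimulus-selective single units
    ("concept cells") recorded from the human medial temporal lobe during a
    three-condition picture-comparison task, together with the population- and
    pair-level statistics used to characterise relational reactivation of
    concept representations. Implements bin-wise Wilcoxon signed-rank response
    detection with Simes correction and Hedges' g selectivity gates, a
    five-class unit taxonomy, baseline z-normalised population time series with
    cluster-based permutation testing, trial-by-trial cross-correlograms with
    shift-predictor correction, and trial-category-partitioned pairwise rate
    correlations. A synthetic-session generator simulates the full trial
    design of all three task conditions and inhomogeneous-Poisson spike trains
    with planted concept-neuron phenomenology, providing ground truth for
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
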