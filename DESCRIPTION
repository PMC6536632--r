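Package: striocell
Title: Classification of Striatal Neuron Types from Intrinsic
    Electrophysiology and Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering striatal neuron types from whole-cell
    current-clamp recordings and digital reconstructions. Extracts the twelve
    intrinsic electrical properties used to separate tyrosine-hydroxylase-line
    interneurons (THIN), frequency-adapting neurons with spines (FANS) and
    medium-sized spiny neurons (MSN) from current-step sweep tables;
    quantifies spike-frequency, amplitude and duration adaptation with
    exponential fits; computes 23 global morphometric features, Sholl and
    surface-area profiles from SWC reconstructions; and reproduces the
    unsupervised classification stage (standardization, PCA by singular value
    decomposition, Ward agglomerative clustering, silhouette-based choice of
    the number of clusters). Includes synthetic generators for current-step
    recordings, dendritic trees and Gaussian feature cohorts with known
    ground truth so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
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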