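Package: cpdecode
Title: Choice Probability from Correlated Noise and Selective Decoding in
    Multisensory Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for dissociating two causes of
    choice probability (CP) in heading-selective multisensory neurons:
    interneuronal noise correlations structured by tuning similarity versus
    selective readout weights in a maximum-likelihood population decoder.
    Generates cosine-tuned and MSTd-like synthetic populations with
    heterogeneous visual/vestibular congruency, simulates correlated
    single-trial responses with proportional Gaussian noise, decodes fine
    heading discrimination choices, and measures ROC-based choice
    probabilities, neurometric and psychometric thresholds, and optimal
    cue-integration predictions. Includes the companion inferential toolbox:
    major-axis (model II) regression, sequential F-tests for nested
    correlation-structure models, a kernel-density multimodality test,
    rank-dispersion comparison, and a one-dimensional cluster-separation
    index.
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
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
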