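Package: protexplain
Title: Residue-Level Explainability Analysis for Protein Sequence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-attribution analysis for differentiable protein sequence
    models at single-residue resolution. Implements nine attribution operators
    (saliency, deconvolution, guided backpropagation, input-times-gradient,
    DeepLIFT, integrated gradients, LIME, KernelSHAP, GradientSHAP) against a
    small differentiable-model contract, the tensor algebra that collapses
    element-level attributions into residue-on-residue impact matrices for both
    embedding construction and windowed interaction-site prediction, a
    statistical evaluation harness (Mann-Whitney U tests on categorical
    amino-acid properties, Kendall tau tests on numerical ones, distance
    profiles, explanation infidelity, and an RBF-SVM real-versus-random
    separability check), and pass-count summarization of large published
    p-value grids. Ships desk-scale differentiable toy embedder and window
    predictor models with controllable locality and planted property
    sensitivity, plus synthetic sequence generators, so the whole analysis runs
    end-to-end in minutes on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
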