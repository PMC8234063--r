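Package: oligoisotope
Title: Predict Aggregated Isotope Distributions of Average DNA and RNA
    Oligonucleotides from Monoisotopic Mass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the aggregated (nominal-mass) isotope distribution of an
    "average" DNA or RNA oligonucleotide given only its monoisotopic mass. An
    exhaustive in-silico database of nucleotide compositions is enumerated, the
    aggregated isotope distribution of every record is computed with a
    Newton-Girard power-sum recursion (BRAIN), the 21-part isotope compositions
    are mapped to real space with the additive log-ratio transform, and a
    weighted polynomial regression per log-ratio links them to mass. Predictions
    are back-transformed with a modified softmax so probabilities sum to one,
    and centroid masses are reconstructed from average per-isotope mass offsets.
    Includes two goodness-of-fit statistics for scoring observed isotope
    envelopes (a scale-invariant mean squared error in log-ratio space and a
    mean Pearson chi-squared error on intensities), a label-free DNA-versus-RNA
    classifier built on them, synthetic-envelope generators for validation, and
    a command-line interface for batch prediction and scoring.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
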