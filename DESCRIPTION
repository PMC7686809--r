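Package: microstates
Title: Resting-State EEG Microstate Analysis with Moderated Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments resting-state EEG into microstates by polarity-invariant
    atomize-agglomerate hierarchical clustering (AAHC) of topographies at global
    field power (GFP) peaks, selects the number of template maps by the classical
    cross-validation criterion, backfits templates to every sample by global map
    dissimilarity, and derives the standard temporal parameters (duration,
    occurrence, contribution, transition probabilities). A moderation layer
    relates these parameters to behavioral scores via moderated ordinary least
    squares with covariates, incremental-R2 F tests, simple slopes,
    Johnson-Neyman regions of significance, and Benjamini-Hochberg false
    discovery rate control. A synthetic-data module simulates
    microstate-structured EEG (semi-Markov state sequences, alpha-band amplitude
    modulation) and behavioral cohorts with planted moderation effects so that
    every stage of the pipeline can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    signal,
    jsonlite,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
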