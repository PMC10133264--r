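Package: gcflow
Title: Time-Resolved Granger Causality for Trial-Aligned Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing fast directional signal flow between brain
    regions from trial-aligned multichannel intracranial (stereo-EEG)
    recordings. Implements a multi-criterion artifact-rejection pipeline
    (robust bivariate feature outliers, wavelet transient blobs, coherent
    interictal events, trial amplitude outliers, glitches, flat segments),
    broadband-gamma (50-150 Hz) response characterization with
    responsive/selective lead classification, sliding-window vector-
    autoregressive pairwise and conditioned Granger causality at multiple
    sampling delays with trial-permutation surrogate and bootstrap
    normalization, signed connection-strength summaries with
    disappear/maintain/appear/negative typing, via-lead and conditioning
    screens, and half-peak onset-latency estimation with bootstrap
    comparisons. Includes a synthetic generator of coupled vector-
    autoregressive trial tensors with known ground truth for validation.
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
    graphics,
    jsonlite,
    MASS,
    purrr,
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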