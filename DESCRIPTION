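Package: vocalsleep
Title: EEG Responses to Rough Vocalizations Across Wakefulness and Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for auditory polysomnography experiments that
    probe how acoustically rough (screamed) versus neutral vocalizations are
    processed across wakefulness and NREM sleep. Provides acoustic feature
    extraction (roughness from the modulation power spectrum, fundamental
    frequency), EEG preprocessing (filtering, re-referencing, epoching, sleep
    stage labeling, artifact screening), Morlet wavelet time-frequency
    decomposition with inter-trial phase coherence, single-trial regression of
    oscillatory power on stimulus features, and cluster-based permutation
    inference with sum-of-t cluster statistics. A synthetic stimulus and
    polysomnography generator with known ground truth makes every stage
    testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
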