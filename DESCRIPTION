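Package: spatspike
Title: Cell-Type Classification from Spatiotemporal Extracellular Spike Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts waveform, spike-timing, and purely spatial features from
    multichannel extracellular spike recordings and classifies pyramidal (PYR)
    versus parvalbumin-immunoreactive (PV) units. Implements the event-based
    delta-transformation that strips single-channel waveform information from
    multichannel mean waveforms, an 18-feature spatial descriptor set
    (time-based, graph-based, and value-based), chunking data augmentation with
    majority-vote pooling, nested cross-validated random-forest models with
    shuffled-label chance baselines, TreeSHAP feature attribution with
    permutation nulls, cross-region generalization metrics, and a synthetic
    population generator with ground-truth labels so that every stage is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    signal,
    pROC,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
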