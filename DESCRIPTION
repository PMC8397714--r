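Package: molevo
Title: Deep-Learning-Guided Evolutionary Molecular Design in Fingerprint Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Goal-directed de novo molecular design by evolving
    extended-connectivity (ECFP) fingerprint vectors with a genetic
    algorithm. Mutated fingerprints are decoded back to SMILES strings by a
    conditional recurrent (LSTM) language model or a nearest-neighbour
    fallback decoder, scored by a feed-forward neural property predictor or
    an analytic descriptor oracle, and filtered through structural
    blacklists and property windows. Includes an iterative
    generate-label-retrain phase loop for extrapolating beyond the property
    range of the training data, a goal-directed benchmark suite
    (rediscovery and property-satisfaction tasks with score modifiers and
    top-k aggregation), and a seeded fragment-based fixture generator with
    a surrogate property oracle so the whole loop runs at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
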