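Package: seedflank
Title: Seed-Constrained Design and Analysis of Promoter Flanking Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Designs synthetic promoters by fixing expert-chosen motif "seeds"
    (e.g. the bacterial -10/-35 elements, operator sites) and optimising the
    flanking sequence around them. A conditional adversarial generator
    (Wasserstein critic with gradient penalty) learns the distribution of
    flanking sequences compatible with fixed seeds; a convolution-LSTM-DenseNet
    regressor predicts sequence activity and exposes saliency maps and
    penultimate-layer embeddings; a genetic algorithm searches the generator's
    latent space for high-activity designs. A companion analysis suite provides
    k-mer spectra, Levenshtein diversity profiles, pentamer-based DNA shape
    tracks, PWM scanning with exact p-values, and second-promoter detection.
    Includes a synthetic promoter simulator with a known activity oracle so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
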