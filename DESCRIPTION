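Package: softlattice
Title: Soft-Lattice Transformer-CRF Tagger for Chinese Clinical Named
    Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Character-level named entity recognition for Chinese clinical
    text using a word-character lattice. Induces a subword lexicon from raw
    records by byte-pair encoding, scores alternative multi-granularity
    segmentations of a sentence with a term-frequency times category-ratio
    (TF-CR) statistic, flattens the winning segmentation into a
    word-character lattice with relative span positions, encodes the
    lattice with stacked relative-position self-attention layers, and
    decodes per-character BIO tags with an exact linear-chain conditional
    random field (forward algorithm and Viterbi). Includes CoNLL input and
    output, strict-match entity-level evaluation, a seeded synthetic
    clinical-style corpus generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
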