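Package: ocsr
Title: Optical Chemical Structure Recognition with a Windowed-Attention
    Image-to-Sequence Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for optical chemical structure
    recognition (OCSR): generation of synthetic molecule-depiction
    training corpora in four stylistic categories (Kekule and aromatic
    ring forms, each with and without injected substituents and bracket
    atoms), DeepSMILES labelling, deterministic 18:1:1 splits, styled 2D
    depiction rendering with binarization to 224x224 three-channel
    inputs, a character-level tokenizer, a hierarchical window-attention
    image backbone feeding a Transformer encoder-decoder trained with
    either cross-entropy or a multi-label focal loss, and a four-metric
    stratified evaluation protocol (exact match, Tanimoto, BLEU,
    ROUGE-L) with validity rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
SystemRequirements: OpenBabel (the 'obabel' executable on the PATH)
Config/testthat/edition: 3
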