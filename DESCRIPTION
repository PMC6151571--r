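Package: seq2go
Title: Protein Function Prediction by Translating k-mer Sentences into Gene Ontology Code Words
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Casts protein function prediction as machine translation between two
    constructed languages: protein sequences segmented into frequent k-mer "words"
    on one side, and Gene Ontology terms encoded as short base-26 letter codes
    (derived from a deterministic post-order traversal of the ontology graph) on
    the other. Provides an OBO parser and ontology utilities, the k-mer tokenizer,
    an encoder-decoder recurrent translation model with additive attention,
    bucketing and sampled-softmax training, a descendant-expanded model variant
    and a weighted model combiner, a noisy-OR probabilistic baseline,
    propagation-based precision/recall and GO-similarity evaluation, seeded
    synthetic ontology and motif-planted corpus generators, and CAFA-style
    prediction input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
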