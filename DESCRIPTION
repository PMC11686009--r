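Package: oromotopics
Title: Topic Modeling, Categorization and Retrieval for Afaan Oromo Health
    Documents
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Latent Dirichlet allocation for unlabeled health-document
    corpora in Afaan Oromo and other low-resource languages. Provides the
    full pipeline: rule-based text preprocessing tuned to Qubee
    orthography (apostrophe-preserving), token/integer-ID dictionary and
    bag-of-words construction, LDA trained by collapsed Gibbs sampling
    with fold-in inference for unseen documents, held-out perplexity and
    pairwise-Jaccard topic coherence, dominant-topic document
    classification with human-supplied topic labels, document-ID topic
    retrieval and query-based medical-specialist recommendation, plus a
    synthetic-corpus generator with known latent structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
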