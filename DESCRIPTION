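Package: medtopic
Title: Health-Topic Detection in Online Community Messages by Mixture-Model Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects health-related discussion topics in online health-community
    message corpora. Messages are tokenized, stemmed and stripped of
    medically-empty noise, represented by keyword n-gram frequencies together
    with medical-term and UMLS-style semantic-type frequencies, reduced by
    principal components, and clustered with a diagonal-Gaussian mixture model
    fitted by expectation-maximization, the number of clusters chosen by
    cross-validated held-out likelihood. Clusters are summarized by
    TF-IDF-like key-phrase scores and labeled with topic categories (Symptom,
    Complication, Examination, Procedure, Drug) from their dominant semantic
    types. Includes pair-counting external validation (Rand, Jaccard,
    Fowlkes-Mallows), Cohen's kappa, a synthetic labeled-corpus generator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    e1071,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
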