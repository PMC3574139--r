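# medtopic

Health-topic detection for online health-community messages by
mixture-model text clustering.

Patients and caregivers post millions of free-text messages on disease
discussion boards. `medtopic` answers, without supervision, the question
*"what health topics dominate this board?"* — typically symptoms,
examinations, drugs, procedures and complications. It is aimed at health
informatics researchers and at anyone who needs a reproducible, tested
implementation of semantic-type-augmented document clustering for lay
medical text.

## The method

Messages are tokenized, stop words removed, tokens Porter-stemmed, and
medically-empty messages of pure emotional support ("Thank you for your
answer") are filtered out. Each retained message *i* becomes a count vector
over five feature blocks: unigrams, bigrams and trigrams (keyword block,
**F1**) plus matched medical terms and their UMLS-style semantic types
(domain block, **F2**), where terms come from a typed dictionary matched
greedily longest-first over stemmed tokens. After PCA reduction, a
diagonal-covariance Gaussian mixture

  p(x) = Σ_k w_k ∏_j N(x_j; μ_kj, σ_kj²)

is fitted by expectation–maximization; the number of components K is chosen
by 10-fold cross-validation, incrementing K while the mean held-out per-row
log-likelihood strictly improves. Each cluster C_i is summarized by its
top-scoring key phrases,

  score(w, C_i) = f(w, C_i) · log(N / n_w),

with f the term's in-cluster frequency and n_w the number of clusters whose
frequency of w is at least f(w, C_i), and labeled by its dominant semantic
type (sosy → Symptom, dsyn/patf → Complication, diap/lbpr → Examination,
topp → Procedure, phsu → Drug). Clusters sharing a label are merged into
topic groups. Against gold labels the package reports pair-counting
validation — Rand = (SS+DD)/total, Jaccard = SS/(SS+SD+DS),
Fowlkes–Mallows = SS/√((SS+SD)(SS+DS)) — and Cohen's kappa.

A synthetic-corpus generator produces labeled boards with planted topic
structure (typed term sets, background vocabulary, emotional noise
messages), so the whole pipeline is testable end to end without any data
download. See `vignettes/methods.Rmd` for the model details, parameter
rationale and known limitations.

## Worked example

```r
library(medtopic)
sc <- generate_corpus(synthetic_config(n_topics = 3, n_messages = 600, seed = 7))
print(corpus_stats(sc$corpus))
cfg <- pipeline_config(sc$corpus, sc$lexicon, seed = 7,
                       em = em_config(n_init = 2, k_max = 6))
report <- run_pipeline(cfg)
print(report)
```

```
messages: 600  members: 187  messages/member: 3.21
time span: 2004-03-02 to 2012-03-25
read: 600 message(s), 187 member(s)
noise filter: 542 of 600 message(s) retained
match: 10878 term occurrence(s), 30 distinct term(s)
features: 542 x 1621 count matrix
feature blocks F1+F2: 1621 column(s)
pca: 30 component(s) covering 84.2% of variance
clustering: K = 5
topic groups: 3 (Symptom, Complication, Examination)
evaluate (topic groups): Rand 1.000, Jaccard 1.000, FM 1.000 (n = 542)
<run_report> 5 mixture component(s) -> 3 topic group(s), 542 message(s), F1+F2 features
  cluster 1 [Symptom]: dutupa budipa, vemeda, pesu, zuro, gibu
  cluster 2 [Complication]: lanu zurovu, teme givela, zuzala faze, dugo, gokoka
  cluster 3 [Examination]: tato, pape, givo kefi, kutu, mivada
  ...
  Rand 1.000  Jaccard 1.000  FM 1.000  kappa 1.000
```

Reading this: 58 noise messages were filtered; cross-validated likelihood
selected a 5-component mixture whose components map onto 3 semantic topic
groups (`k_mixture = 5`, `k_topics = 3`) — the mixture routinely over-splits
discrete count data, and the semantic-type merge recovers the planted
3-topic structure exactly (Rand 1.0 against the generator's gold labels).
The listed key phrases are the generator's synthetic topic terms, each
ranked by the score above.

Real corpora enter as JSONL (one message object per line: `id`,
`author_id`, `board_id`, `timestamp`, `text`, optional `gold_label`,
`thread_id`) or CSV with the same columns; lexicons as TSV
`term<TAB>type1|type2`. A small packaged lexicon (`toy_lexicon()`) covers
common cancer and diabetes board vocabulary.

## Command line

```sh
Rscript inst/cli/medtopic.R synth --topics 5 --messages 2000 --seed 42 \
    --out corpus.jsonl --lexicon-out lex.tsv
Rscript inst/cli/medtopic.R run --corpus corpus.jsonl --lexicon lex.tsv --out run1
Rscript inst/cli/medtopic.R stats --corpus corpus.jsonl
Rscript inst/cli/medtopic.R evaluate --file labels.tsv --pred cluster --gold topic
```

Exit codes: 0 success, 2 validation error, 1 otherwise.

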