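---
title: "Detecting health topics in online community messages: the medtopic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting health topics in online community messages: the medtopic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtopic)
```

## The problem

Patients and caregivers exchange enormous volumes of free-text messages on
disease discussion boards. Understanding which health topics dominate a board
— symptoms, examinations, drugs, procedures, complications — matters to site
designers, health-information researchers and newcomers trying to orient
themselves. Manual content analysis does not scale, and generic document
clustering struggles with lay medical language. `medtopic` implements an
unsupervised detection method that augments keyword features with medical
domain knowledge: messages are represented both by their n-gram counts and by
the frequencies of the *medical terms* they contain and of the coarse
biomedical *semantic types* (e.g. `sosy` = Sign or Symptom, `phsu` =
Pharmacologic Substance) those terms map to.

## The pipeline

1. **Preprocessing.** Messages are lowercased and tokenized (intra-word
   hyphens and apostrophes preserved, so "x-ray" survives), stop words are
   removed, and tokens are reduced with the Porter stemmer (implemented in
   the package and tested against the algorithm's canonical examples).
   Messages of pure emotional support ("Thank you for your answer") carry no
   medical information; a message is kept only if it has at least
   `noise_min_content_tokens` content tokens *and* at least one
   medical-lexicon match. Filtering is idempotent.

2. **Term matching.** A typed term dictionary stands in for concept mapping
   against a licensed biomedical metathesaurus, which cannot be
   redistributed; the package ships a small lexicon built from hot-topic
   vocabulary of cancer and diabetes boards, and the synthetic generator
   emits its own. Matching is a greedy left-to-right longest-match scan over
   stemmed tokens: at each position the longest dictionary entry wins and the
   scan jumps past it, so matches never overlap. Real concept mappers do
   much more (variants, disambiguation); since downstream features only use
   term and type frequencies, greedy matching is an adequate, fully testable
   surrogate.

3. **Features.** Five blocks: unigram/bigram/trigram counts over content
   tokens (the keyword block, F1) and medical-term plus semantic-type counts
   (the domain block, F2). The semantic-type block is a closed set of 20
   types; a term carrying two types increments both columns. Counts are raw
   occurrence counts — the representation is deliberately simple, and PCA
   centering absorbs scale. n-grams below a document frequency of
   `min_df = 3` are dropped to control vocabulary explosion (the method's
   source material states no threshold; 3 is a conventional floor). n-grams
   are built over the contiguous *content-token* sequence, i.e. they may
   bridge removed stop words; the alternative (respecting gaps) would only
   shrink the vocabulary.

4. **PCA.** Columns are centered (not scaled — the counts share units) and
   components come from an SVD of the centered matrix. Components are
   retained up to a cumulative explained-variance target of 0.95, capped at
   `max_components = 30`: text count matrices have thousands of
   near-noise directions, and a diagonal-Gaussian mixture gains nothing from
   them while the fit slows and destabilizes. Each component's
   largest-magnitude loading is made positive for determinism.

5. **EM clustering.** A diagonal-covariance Gaussian mixture is fitted by
   expectation–maximization: the E step computes per-message posterior
   responsibilities in log space; the M step re-estimates weights, means and
   standard deviations from responsibility-weighted moments, with a
   standard-deviation floor of `1e-6` against degenerate spikes. Means are
   initialized k-means++-style from data rows, with uniform weights and the
   global per-dimension spread; the best of `n_init` restarts by final
   log-likelihood wins. The log-likelihood trace is non-decreasing up to
   numerical slack on every fit — the signature property of EM, and one of
   the package's acceptance checks. The number of components is chosen by
   10-fold cross-validation: starting at K = 1, K is incremented while the
   mean held-out per-row log-likelihood strictly improves (ties favor the
   smaller K). All randomness — initialization, restarts, folds — flows from
   one explicit seed.

6. **Key phrases and topic labels.** For every candidate term (content
   n-grams and matched medical terms) the per-cluster frequency
   f(w, C_i) is tallied, and a TF-IDF-like score ranks cluster-specific
   phrases:

   score(w, C_i) = f(w, C_i) · log(N / n_w),

   where N is the number of clusters and n_w the number of clusters whose
   frequency of w is at least f(w, C_i). A term spread evenly over all
   clusters scores 0; a term exclusive to one cluster scores f · log N.
   *This scoring formula is a reconstruction*: the method's published
   formula image is unreadable in our source material, and the form above is
   the natural reading of its prose definition ("similar to the TF-IDF
   scheme", with f and n_w defined as here). The ≥ in n_w guarantees
   n_w ≥ 1, so the logarithm is always defined. f counts token occurrences;
   a `count = "document"` switch tallies message counts instead.

   Each cluster is then labeled by its dominant semantic type: `sosy` →
   Symptom; `dsyn`/`patf` → Complication; `diap`/`lbpr` → Examination;
   `topp` → Procedure; `phsu` → Drug; anything else → Other. Clusters
   sharing a label are *merged into one topic group* — the "incorporate
   clusters with similar semantic types" step of the original workflow — and
   the pipeline reports both the raw mixture order `k_mixture` and the
   number of topic groups `k_topics`.

7. **Evaluation.** When gold topic labels exist, all unordered message pairs
   are classified as SS/SD/DS/DD (same/different cluster × same/different
   category) and three indices follow: Rand = (SS+DD)/total, Jaccard =
   SS/(SS+SD+DS), Fowlkes–Mallows = SS/√((SS+SD)(SS+DS)). Jaccard and FM
   are defined as 0 when their denominators vanish so degenerate partitions
   do not crash evaluation. Cohen's kappa (unweighted; the categories are
   nominal) measures chance-corrected agreement between two nominal
   labelings; for pipeline reports the cluster partition is first mapped to
   its gold-majority categories so both sides share an alphabet. Evaluation
   is computed on the final merged topic groups, with the unmerged indices
   reported alongside.

## Why the pipeline reports two K values

Cross-validated likelihood selection stops only when extra components no
longer improve held-out density. For genuinely Gaussian clusters it stops at
the true K — the package verifies this on well-separated blobs. Bag-of-words
count data are different: within a topic, *which* terms a message uses and
how many cross-topic terms leak in create real, discrete substructure in the
projected space, so held-out likelihood keeps improving past the number of
planted topics and the mixture order grows until `k_max`. This is a
well-known property of likelihood-based model-order selection on text, and
it is why the original workflow merges clusters with similar semantic types
before interpreting them. `medtopic` makes that step explicit: `k_mixture`
is the cross-validated mixture order; `k_topics` — the number of semantic
topic groups after merging — is the quantity that recovers the planted
topic count on synthetic corpora.

## The synthetic corpus generator

Real board dumps cannot be redistributed, so the package generates labeled
corpora with the statistical structure the pipeline assumes. Each of K
topics owns a disjoint set of typed terms (about a third are two-token
phrases, exercising multiword matching); each non-noise message draws a
topic uniformly and emits `max(1, Poisson(topic_term_rate))` term tokens —
from its own topic with probability `separation`, otherwise from a random
other topic — plus `Poisson(background_rate)` background words; noise
messages combine an emotional phrase with background words and contain no
lexicon term, giving the noise filter realistic prey. Defaults: 5 topics
(one per topic category, with the type profile sosy; dsyn/patf; diap/lbpr;
topp; phsu so labeling can be checked exactly), 2000 messages,
`topic_term_rate = 20` and `background_rate = 40` (≈60 content tokens — a
100–120-word post in which key terms recur, as they do in real posts),
600 background words, 10% noise, separation 0.9. Vocabulary words are
generated as pronounceable syllable strings that are fixed points of the
Porter stemmer, so lexicon and corpus normalize to themselves.

What the generator does *not* emulate: grammar and word order (the pipeline
only consumes counts), thread structure, author behavior, time trends,
misspellings, and the heavy-tailed vocabulary of real forums. Passing tests
therefore demonstrate the pipeline's correctness and its behavior under the
stated generative assumptions — not performance on real MedHelp-scale data.

## Numerical choices and degenerate inputs

* EM tolerance `1e-6` on the log-likelihood improvement, at most 100
  iterations, standard-deviation floor `1e-6`; a component whose total
  responsibility underflows is reseeded from a random data row.
* PCA refuses constant matrices (zero variance) and drops numerically
  zero eigenvalues (relative threshold `1e-12`).
* Ratio rounding in corpus summaries is half-up to 2 decimals, matching how
  such tables are conventionally printed.
* Unparseable timestamps are kept as raw strings and excluded from time
  spans; nothing downstream computes on time.
* Ties in key-phrase ranking break lexicographically; ties in CV selection
  favor the smaller K.

## Problem sizes used by the test suite

The acceptance checks run at the sizes stated in their descriptions: 50
random datasets for EM monotonicity; 200 random labelings (n ≤ 50) for the
pair-counting oracle; 10 seeds × 180 points for blob K recovery; 10 seeds ×
2000 messages (K cycling 3, 4, 5) for end-to-end recovery with
`n_init = 2` restarts and `k_max = 8`; 10 seeds × 800 messages for the
feature-set ablation with K fixed at 5. These sizes keep a full run at desk
scale while leaving the statistical conclusions stable across seeds.

## Known limitations

* The key-phrase score is a reconstruction (see above); any downstream use
  should treat its absolute values as method-internal.
* Greedy longest-match term tagging cannot disambiguate senses and never
  nests matches.
* Diagonal covariance ignores correlations between retained components
  within a cluster (PCA decorrelates globally, not per cluster).
* EM is quadratic-ish in corpus size × components and is intended for desk
  scale, not streaming use.
* With `k_max` reached, `k_mixture` is a lower bound on where CV would have
  stopped; interpretation should rest on `k_topics` and the key phrases.
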