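---
title: "Classifying VTE imaging reports with active learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying VTE imaging reports with active learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vteal)
```

## The problem

Venous thromboembolism (VTE) — deep vein thrombosis (DVT) and pulmonary
embolism (PE) — is routinely confirmed by imaging, but the findings live in
free-text radiology reports. Administrative ICD-10 codes systematically
under-capture imaging-confirmed VTE (in the audited single-institution
corpus this package emulates, only 65.0% of a random sample of VTE-positive
reports carried a VTE-related code), so estimating true prevalence or
building registries requires classifying the report text itself. Expert
annotation is expensive, which motivates two complementary tools:

1. **Pool-based active learning** for the annotation loop: a classifier is
   seeded with 8 labeled reports, and at each query iteration one unlabeled
   report is chosen by a query strategy, labeled, and the model retrained
   from scratch; test-set F1 is recorded after every query.
2. **Small sequence classifiers** (LSTM, 1D-CNNs) for the final model, with
   ADAM, early stopping, and stratified 5-fold cross-validation.

Reports are annotated into seven anatomical classes: *No DVT or PE*, *PE
only*, *Proximal DVT* (inferior vena cava through popliteal vein), *Distal
DVT* (soleal/calf veins), *Thrombophlebitis* (great or small saphenous
veins), *Other DVT* (subclavian, jugular, upper-extremity veins), and *DVT
and PE*. A 6-class scheme drops the dominant negative class.

## The synthetic corpus: a stated world

The original corpus is private single-institution data, so every pipeline
stage here runs against a synthetic template-based generator whose
*composition* matches the published corpus exactly and whose *text* is
plain-English radiology phrasing with class-diagnostic anatomical terms.

* **Class counts.** The default configuration carries the published counts
  (4,751 negative; 75 PE only; 570 proximal DVT; 286 distal DVT; 58
  thrombophlebitis; 11 other DVT; 88 DVT-and-PE; total 5,839, 18.6%
  VTE-positive). Counts are scaled to any `n_reports` by *largest-remainder
  apportionment*, which is deterministic — so the published counts are exact
  acceptance targets rather than sampling expectations. A stochastic
  multinomial allocation would blur them.
* **Modalities** are sampled with weights 2,425 / 69 / 568 / 886 / 1,891
  over the five imaging modalities; demographics follow the published
  margins (50.6% male; age ~ Normal(61.9, 15.1), truncated to 18–100).
* **ICD-10 flags.** VTE-positive reports are flagged "coded" by independent
  Bernoulli draws with probability 0.650. Sampling (rather than
  quota-allocating) the flags means the concordance audit statistic is
  exercised under realistic binomial noise; the deterministic analytic path
  is checked separately via the printed counts (372 coded / 200 uncoded).
* **Text.** Each report is a modality header plus one findings sentence
  drawn from the class's template bank (the compound *DVT and PE* class
  concatenates one PE sentence and one deep-vein sentence, mirroring its
  definition), with lexical slots (anatomy, laterality, hedging). Two dials
  control difficulty: `synonym_rate` (default 0.5), the per-slot probability
  of substituting a synonym for the default wording, and `distractor_rate`
  (default 0.3), the probability of appending a clinically irrelevant
  sentence and, independently, an incidental negative finding. The defaults
  are our one-time judgment of realistic lexical variation in radiology
  reports; with both dials at 0 the corpus is separable by construction (a
  linear term-frequency classifier reaches macro-F1 ≥ 0.95 from 200
  training reports), which the test suite asserts as the "separability
  dial" invariant on a class-balanced 400-report corpus (the imbalanced
  default would leave the smallest class with a single member at that
  size, making the dial test measure the split rather than the generator).
* **What a green test does not establish.** The generator emulates lexical
  class signals only: no Korean-language text (the source corpus's language
  is not stated and bag-of-words pipelines are language-agnostic), no
  institution-specific sectioning, negation scope, or report-length
  distribution, no patient-level structure, and no label noise. Passing
  tests validate the *machinery* — query strategies, training protocols,
  metrics — not clinical performance; the published headline F1 values on
  the private corpus are out of reach by design, and the package makes no
  claim to reproduce them.

The label token itself never appears in rendered text (templates avoid the
"DVT"/"PE" abbreviations and the word "thrombophlebitis"), so no classifier
can cheat by reading its own target; a property test asserts this
non-leakage on every class.

## Embeddings

Three vectorizations mirror the reference pipeline: term frequency (TF), TF-IDF,
and dense document embeddings. The environment ships no word2vec/doc2vec
trainer, so the dense spaces use their count-based equivalents, which also
buy exact determinism:

* **Word vectors** — positive pointwise mutual information (PPMI) over
  symmetric windowed co-occurrence counts (window 5), factorized by
  truncated SVD; skip-gram with negative sampling implicitly factorizes
  this same matrix, so PPMI-SVD is the standard deterministic stand-in. A
  document is the mean of its tokens' vectors; an all-out-of-vocabulary
  document is the zero vector.
* **Document vectors** — latent semantic analysis: truncated SVD of the
  TF-IDF document-term matrix, with unseen documents projected onto the
  fitted basis.

Both accept (and ignore) `seed` and `epochs` for interface parity with
stochastic trainers; sign indeterminacy of the SVD is removed by a fixed
convention (largest-magnitude loading positive). IDF uses the smoothed form
`ln((1+N)/(1+df)) + 1`: strictly positive (sparsity patterns survive
reweighting) and defined for unseen tokens. Vocabulary is always fitted on
the training pool only. Cosine similarity follows the usual closed form
with one convention: a zero-norm vector has similarity 0 to everything —
the quotient is undefined there, and 0 marks the document as maximally
novel, the conservative choice for similarity-based querying.

## Query strategies

Ten strategy names are exposed: `random`; the three uncertainty
functionals on the model posterior (`least_confidence` = 1 − top
probability, `margin` = 1 − (top1 − top2), `entropy` with natural log —
the base only rescales, never reranks); `length_words` (most tokens);
`word_similarity` and `tfidf_similarity` (lowest mean cosine similarity to
the labeled set = most novel); and the three combined
`wordsim_{least_confidence,margin,entropy}` strategies.

Two points were genuinely open and are package decisions:

* **Similarity aggregation.** "Lowest cosine similarity to already-learned
  samples" does not say how to aggregate over the labeled set. The default
  is the *mean* (stable to outlying labeled points); `min` is available via
  `strategy_spec(similarity_aggregate = "min")`.
* **Combining per-class similarity with uncertainty.** The combined
  strategy computes, for each candidate, its average cosine similarity to
  the labeled members of each class, then needs a rule to feed that vector
  into an uncertainty functional. We shift the vector to be non-negative
  (subtract its minimum) and L1-normalize it into a pseudo-posterior before
  applying the functional. This preserves the class ordering, always yields
  a valid distribution, and reduces to "ambiguous between classes ⇒ most
  queried": a candidate equidistant from all classes maps to the uniform
  distribution, which maximizes all three functionals. With a single
  labeled class the pseudo-posterior is degenerate, so the strategy falls
  back to plain novelty selection with a warning.

Ties are broken by lowest pool index by default (reproducibility); a
random tie-break drawing from the context's RNG stream is available. Every
score-based strategy is tested against an independent brute-force
reimplementation on pools of ≤ 50.

## The active-learning loop

`run_experiment()` splits the corpus once (8:2), fixes the test set, fits
the feature space on the training pool only, and runs epochs with seeds
`master_seed + e`. Within an epoch, the 8 seed reports are drawn uniformly
(the protocol does not stratify the seed), so early labeled sets routinely
miss classes: classifiers fit on the classes present, absent classes get
probability 0, and the 0/0 convention in precision/recall/F1 keeps the
trajectory defined from iteration 0. The budget is either a fraction of
the training pool (default 0.5, the reference protocol) or an absolute labeled
count (learning curves are conventionally compared at a fixed query iteration, which an
absolute count budget exposes directly); both are supported and neither is asserted
as the "true" horizon. Models are retrained from scratch each iteration —
the model state is a pure function of the labeled set and the epoch seed,
which a test verifies by refitting offline.

No random-forest, SVM, or boosting package exists in the target
environment, so the four classifier families are implemented in-package:
bagged gini CART trees with per-node feature subsampling (compiled, tree-
averaged leaf distributions as probabilities); one-vs-rest L2-regularized
squared-hinge linear SVM by full-batch subgradient descent; the same
objective by pegasos-style SGD; and multinomial gradient boosting with
shallow compiled regression trees and the standard multinomial leaf
update. The SVMs expose probabilities as a softmax over decision values —
monotone in each decision value with rows summing to 1, which is all the
uncertainty functionals require; these are not calibrated posteriors, and
the learning curves should be read accordingly.

## Sequence classifiers

The four architectures (`lstm`, `cnn1d`, `multikernel_cnn1d`,
`multikernel_cnn1d_pretrained`) are implemented directly in vectorized R
(no deep-learning framework ships with the environment): a trainable
embedding table with a pinned zero pad row, a single LSTM layer read out at
the last non-pad position, or 1D convolutions with ReLU and max-over-time
pooling — kernel widths {3,4,5} with equal filter counts concatenated, the
canonical multi-kernel text-CNN design (the reference protocol does not specify the
kernels). "Pretrained" means the embedding table is initialized from word
vectors trained on the training fold itself (so the test suite needs no
download); external GloVe-format text files are also accepted.

Training follows the stated protocol: tokenize, encode to exactly 256
indices (right-pad, truncate from the end), up to 50 epochs of ADAM,
early-stopped when validation accuracy fails to improve on its running
best by ≥ 1e-4 for 2 consecutive epochs, inside stratified 5-fold
cross-validation. The validation set is a stratified 10% of each fold's
training portion — the protocol monitors validation accuracy but never
defines the validation split, so this is a package decision. Defaults
(embedding 64, hidden 64, 32 filters/kernel, batch 32, learning rate 0.01)
keep 2,000-document training in minutes on one CPU. Sequences are
processed only to the longest non-pad position in each batch, which is
mathematically identical to processing all 256 positions (pad steps are
masked) but much faster on short reports.

## Evaluation conventions

Precision, recall and F1 follow the standard one-vs-rest closed forms with
0/0 → 0. The aggregate default is **macro** F1; the reference protocol never names its
averaging, and under 81%-negative imbalance the choice is material — micro
(= accuracy for single-label multiclass) and support-weighted averaging are
both available, and absolute comparisons with the published curves are out
of scope for exactly this reason. Per-fold and per-iteration F1 are macro
averages over the classes present in that evaluation set (truth or
predictions): at n = 2,000 the 11-member class scales to ~4 members and
some CV folds contain none of it, and scoring a class that cannot appear
as 0 would measure the split, not the model. Classes present but never
predicted still score 0. Composition percentages are rounded half-up to
one decimal on the published denominators (modalities and VTE presence
over all reports; VTE subclasses over positives only).

## Numerical and degenerate-input choices

* Largest-remainder ties broken by class position; allocation always sums
  exactly to `n_reports`.
* `encode_batch` drops out-of-vocabulary tokens (the vocabulary is a
  training-fold artifact); an empty or all-OOV document becomes an all-pad
  row and flows through both architectures.
* A class with one member is forced into the training partition of a
  stratified split, with a warning; a class with fewer members than folds
  degrades stratification with a warning.
* RNG isolation: generator and query streams are self-contained
  (`rng_stream`), so library code never perturbs the caller's `.Random.seed`;
  all training randomness funnels through explicit seeds, and per-epoch
  seeds are `master_seed + epoch`.

## Known limitations

* Synthetic text is far easier than hospital prose: no negation-scope
  traps, abbreviation ambiguity, or cross-institution style drift. Learning
  curves here rise much faster than they would on real reports.
* The SVM probability mechanism is uncalibrated (softmax over margins).
* The dense embeddings are count-based equivalents, not SGD word2vec/
  doc2vec; on corpora of this size the practical difference is small, but
  it is a substitution.
* Transformer fine-tuning is a plug-in contract only
  (`plugin_transformer_interface()`); no pretrained weights are shipped,
  and the published BERT-family results are not reproducible here.
* Inference timing is hardware-dependent; the harness records the machine
  descriptor and asserts only ordering (a 10×-larger model is slower), not
  absolute values.
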