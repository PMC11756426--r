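---
title: "Methods: exemplar expansion and evaluation for stigmatizing-language detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exemplar expansion and evaluation for stigmatizing-language detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stigmatext)
```

## The problem and the unit of analysis

Stigmatizing language in clinical notes — wording that casts a patient as
difficult, doubts their credibility, or restates marginalizing
descriptors — is sparse, nuanced and expensive to annotate. The unit of
analysis throughout this package is the *exemplar*: a contiguous span of
one to three sentences from the free-text portion of a note, labeled with
one of five stigmatizing categories, one positive/preferred category, or
the negative-case label `none`. Exemplars are short enough to annotate
and classify reliably, and long enough to carry the context that
distinguishes, say, a neutral "declines epidural" from a loaded
"refuses repeatedly".

Two structural assumptions follow from this choice. First, every
classifier in the package is a single-label multi-class model over the
seven-value label set; annotated spans carry exactly one category.
Second, all span bookkeeping (gold annotations, retrieval candidates,
ground-truth tables of the synthetic corpus) is done in sentence
coordinates over a note's free text, so the deterministic sentence
segmenter is load-bearing and is tested for exact content preservation.

## Expansion by verified semantic retrieval

The core procedure enlarges a small human-annotated gold standard at low
annotation cost:

1. Notes never used for annotation (but of the same seven types) are
   normalized, segmented, and decomposed into all 1–3-sentence windows.
   Windows never cross free-text block boundaries, since blocks are
   independent narrative units.
2. Gold exemplars are sampled as queries — stratified
   proportional-to-size over the six substantive categories with
   largest-remainder rounding, so rare categories are represented in
   proportion to their prevalence.
3. Every query retrieves its `top_k` most cosine-similar windows from the
   embedded pool. Search is exact: each query is scored against every
   window, and ties break by pool insertion order so results are
   reproducible. With `n_queries = 250` and `top_k = 5` (the defaults)
   the review queue has exactly 1250 rows.
4. A human (or, in tests, a simulated verifier with configurable error
   rate) accepts or rejects each candidate, optionally correcting the
   proposed category. Accepted candidates become exemplars with
   provenance `expansion_verified`; identical windows retrieved by
   several queries collapse to one, keeping the highest similarity.

No minimum-similarity threshold is applied before review: verification is
the quality gate, and a threshold would silently truncate recall for rare
categories whose nearest neighbours are farther away.

### The embedding backend

The default backend is a hashed character n-gram bag: the text is padded
with `#`, every character 3-, 4- and 5-gram is hashed with 32-bit FNV-1a
modulo the dimension (default 512), and the counts are L2-normalized.
This backend is deterministic, dependency-free and cheap, and it ranks
close paraphrases highly because word-level edits leave most character
n-grams intact. It does *not* model synonymy or semantics — "declines"
and "refuses" share almost no n-grams — which is exactly the capability a
pretrained sentence-transformer would add. The backend interface accepts
a `sentence_transformer` configuration for that purpose, but encoding
with it requires external model weights and therefore raises a capability
error in this installation; nothing in the package or its tests depends
on it. Because embeddings are unit-norm, cosine equals the dot product;
empty text embeds to the zero vector and its cosine is defined as 0 so
that degenerate inputs never propagate NaN.

## Dataset construction

Balanced modeling sets pair each positive exemplar with one negative
(`ratio = 1`). Negatives are windows drawn only from notes containing no
gold or verified span, matched to the positives on the two observable
"length and context" covariates: the sentence-width histogram is matched
exactly (largest-remainder scaling for other ratios), and the note-type
histogram within one item per type, relaxing to other types with a
warning only when a type's eligible windows run out. A hard deficit in a
width stratum is an error that names the missing count, not a silent
shortfall.

Initial and expanded sets are split 60/20/20 *separately*, stratified by
category with largest-remainder rounding within each stratum (so each
part's category proportions deviate from the target fractions by less
than one item), and then combined part-wise into the enhanced splits.
Splitting before combining keeps the initial test items identifiable and
prevents expanded items from leaking into the initial model's training
pool. Strata smaller than three items go entirely to train with a
warning — a three-way split of two items cannot respect any fractions.
Negatives are sampled before splitting, so the `none` stratum is split
like any other. On the published balanced set sizes (1926 and 1004, with
the published category counts) this procedure reproduces the published
enhanced training size of 1757 exactly; the validation/test sizes come
out 590/583 against the published 586/587, because the original
per-stratum rounding rule is not published. Only the training size is
asserted, at a documented tolerance of ±3.

## Classifiers

Text is normalized (HTML entities, clinical abbreviations on whole-token
boundaries, case folding), tokenized into maximal letter/digit runs, and
featurized as unigrams plus adjacent bigrams — bigrams capture the short
phrases ("poor effort", "late registrant") that carry much of the signal.
TF-IDF uses the smoothed form `tf · (ln((1+N)/(1+df)) + 1)` with
L2-normalized rows; chi-squared feature selection scores each nonnegative
feature by `Σ (O − E)²/E` over class-wise feature sums, keeping by
default every feature with a positive score (the selection size is
otherwise a tunable).

Three classical learners stand behind one specification object: a
support vector machine (`e1071`), a decision tree (`rpart`) and a random
forest (`ranger`). Sample weights are inverse class frequency normalized
to mean one; the SVM backend accepts class weights rather than sample
weights, and since inverse-frequency weights are constant within class
the per-class mean weight is passed — an exact reformulation, not an
approximation. Cross-validation is stratified 5-fold (per-class fold
counts within one), and hyperparameter search is sequential model-based:
a seeded random design, then a random-forest surrogate whose per-tree
prediction spread drives an expected-improvement acquisition over sampled
candidates. If the surrogate cannot be fitted the search degrades to
seeded random sampling and records that in the result's `method` field.
Default spaces: SVM `C ∈ [10⁻², 10³]` (log) with linear/RBF kernels;
tree depth `[2, 64]`; forest size `[50, 500]` × depth `[2, 64]`.

The fine-tuning adapter implements the same fit/predict contract for
encoder-plus-linear-head models with the recipe lr = 3e-5, batch 16,
4 epochs and a global gradient-norm cap of 1.0, returning the
best-validation-accuracy checkpoint. For offline testing the encoder is
`tiny_random`: a frozen hashed-n-gram embedding passed through a seeded
random projection with tanh. Only the linear head is trained; this
exercises every mechanism the recipe specifies (minibatching, per-step
clipping — asserted from the recorded per-step gradient norms — descent,
determinism, checkpoint selection) without pretrained weights. First-token
style pooling questions do not arise because the tiny encoder emits a
single pooled vector per text.

## Evaluation

Per-category precision, recall and F1 use the 0/0 → 0 convention; the
macro average is the unweighted mean over the six substantive categories
only, matching the convention of reporting tables that list six category
rows whose mean equals the printed macro row. The negative class
participates in the confusion matrix but not in the macro average.

Uncertainty comes from bootstrap resampling of test items (B = 1000,
uniform with replacement; stratified resampling is available behind a
flag). A replicate that lacks a category in its resampled truth has
undefined metrics for that category; these are recorded as missing and
excluded from that replicate's macro average. Intervals are BCa: bias
correction `z₀` from the replicate distribution (with half-weight for
replicates equal to the point estimate), acceleration `a` from a
leave-one-out jackknife over test items, and empirical replicate
quantiles at the adjusted levels. Degenerate replicate distributions
collapse to a point interval; zero jackknife variance falls back to the
percentile interval with a flag; a category entirely absent from the test
set yields an `NA` interval marked `undefined` rather than an error.

Paired model comparison uses the Wilcoxon signed-rank test with zero
differences dropped and midranks for ties: exact enumeration of all 2ⁿ
sign assignments for n ≤ 12 tie-free pairs, otherwise the normal
approximation with tie and continuity corrections. All-zero differences
are a flagged "no test" outcome, not a p-value. Relative improvements are
reported as `100·(enhanced − initial)/initial` rounded half-away-from-zero
to the nearest integer, the same convention as all displayed percentages
(two decimals for table proportions).

## The synthetic corpus: what it emulates and what it does not

The generator produces notes of the seven obstetric types with 2–3
structured sections and a free-text body of 5–8 routine narrative
sentences; gold exemplars are rendered from a phrase bank of ≥10 templates
per category (seeded from the published category descriptions and
exemplars), planted contiguously into annotated notes with exact
character and sentence offsets recorded in a ground-truth table. Each
gold exemplar receives, with probability `paraphrase_rate` (default 0.5),
a paraphrased twin — the same template re-rendered with about half of its
alternation choices switched and numeric slots kept — planted only in
unannotated notes, which is what gives retrieval something true to find.
Noise imitates the named preprocessing hazards: "patient" → "pt.",
HTML-entity quotes, random upper-casing, applied to filler sentences at
configurable rates. Default prevalences mirror the published imbalance
(roughly 41/15/10/7/5/21 percent across the six categories), scaled so
the default 600-note benchmark carries about 150 gold exemplars.

Passing tests on this corpus demonstrate that the machinery is correct
and that the expansion→enhancement effect is directionally reproduced on
separable template data. They do not demonstrate clinical realism: real
notes have far larger vocabulary, correlated topics, annotator noise and
genuinely ambiguous category boundaries, so absolute synthetic scores
(macro F1 near 0.9) are not predictions of real-data performance, where
published macro F1 lies around 0.7–0.8. On the default benchmark the
planted-paraphrase top-5 recall of the hashed backend is about 0.9
(0.914 at the benchmark seed; ~0.86–0.91 across other generator seeds),
reflecting competition among near-duplicate renders of a shared template
— a failure mode real paraphrases share.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
600-note benchmarks for retrieval properties, 150–400-note corpora for
end-to-end pipeline checks (five seeds for the directional-gain
property), B = 1000 bootstraps where the interval itself is under test
and B = 50–200 in smoke tests, 500 simulations for BCa coverage of the
mean of an exponential(1) sample of size 50. Quantile type 6 is used for
empirical bootstrap quantiles. Seeds are explicit arguments everywhere;
every randomized operation restores the caller's RNG state, and stage
seeds inside `run_pipeline()` derive from the single master seed.

## Known limitations

* The default embedding is lexical; retrieval of semantically similar but
  lexically disjoint exemplars requires plugging in a sentence-transformer
  backend and its weights.
* The sentence segmenter is rule-based with a small protected-abbreviation
  list; clinical text with unusual punctuation will over- or under-split,
  which shifts window boundaries.
* Exemplars are single-label; notes whose spans plausibly carry two
  categories must be resolved at annotation time.
* The matched-negative design controls length and note-type only; it does
  not control topical content, so a negative can be topically close to a
  positive.
* The fine-tuning adapter trains a linear head over a frozen encoder; full
  encoder fine-tuning requires an external deep-learning runtime and
  pretrained weights, outside this package's scope.
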