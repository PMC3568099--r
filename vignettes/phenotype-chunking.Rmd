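---
title: "Recognizing phenotype descriptions in free text: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing phenotype descriptions in free text: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Statements such as *bell-shaped thorax*, *hitchhiker thumb* or *flattening
and squaring of the metacarpal heads* describe qualitative aspects —
often abnormalities — of anatomical entities. They are how skeletal
phenotypes are reported in figure captions, clinical summaries and case
reports, and extracting them is the prerequisite for downstream work such
as genotype–phenotype correlation or ontology population. The task is
harder than classic gene/protein tagging for several reasons: the same
token can name an anatomical entity or a quality (*radial*, *long*),
abbreviations abound (*L4-S1*), hedging and qualifiers blur boundaries
(*appear to affect*, *subtle flattening*), and descriptions have complex
internal structure — canonical quality–entity pairs, verb-linked and
conjunction-chained forms, and nesting.

`phenochunk` frames recognition as BIO sequence labeling over tokens:
each token receives `B` (begins a phenotype description), `I` (inside
one) or `O` (outside). Decoded maximal `B I*` runs are the predicted
spans, and systems are compared by entity-level exact-match precision,
recall and F1 under stratified ten-fold cross-validation. Because
expert-annotated corpora in this domain are scarce, the package also
ships a synthetic caption generator that reproduces the structural
statistics of such corpora, so the full pipeline is testable end to end.

## The ensemble

Four divergent chunkers share one contract (`chunker_spec()`,
`train_chunker()`, `predict_labels()`/`predict_spans()`):

* **`crf_a`, `crf_b`** — linear-chain conditional random fields. With
  label set $\mathcal{Y}=\{B,I,O\}$ and per-token sparse indicator
  features $\mathbf{f}(x_t)$, the model is
  $$p(y_{1:T}\mid x_{1:T}) \propto \exp\Big(\sum_t
  \mathbf{w}_{y_t}\!\cdot\!\mathbf{f}(x_t) + \sum_t A_{y_{t-1},y_t}\Big),$$
  fitted by maximizing the L2-penalized log-likelihood (penalty
  $\lVert\mathbf{w}\rVert^2/2C$) with L-BFGS over an exact
  forward–backward gradient, and decoded by Viterbi. The two variants
  differ in the regularization constant — $C=1$ for `crf_a`, $C=3.5$ for
  `crf_b` — and, under the presets, in their context features.
* **`svm_ovo`, `svm_ova`** — margin-based (SVM-style) token classifiers
  emulating forward-parsing chunkers: binary max-margin separators
  trained with averaged passive-aggressive (PA-I) updates on the hinge
  loss, composed either one-vs-one or one-vs-all over the three BIO
  classes, and decoded greedily left to right with the previous
  *predicted* label added as a feature. The default degree-2 polynomial
  kernel is realized as an explicit feature map: all pairwise
  conjunctions of a token's active features (previous-label indicator
  included) hashed into a fixed 2^19-dimensional slice of the weight
  vector. A `kernel = "linear"` option drops the conjunction map for
  very large corpora.

These are deliberately *divergent* re-implementations of the classic
CRF/SVM chunking toolchain, not wrappers around any particular historical
tool; exact score parity with specific packages is a non-goal. What the
ensemble needs is diversity plus a shared feature battery, and that is
what the presets provide.

### Feature battery

`feature_config()` assembles four families per token:

* *simple*: character prefixes and suffixes of length $1..n$ (default
  $n=5$, matching the worked examples `f fl fla flat flatt` /
  `g ng ing ning ening` for *flattening*), plus lemma and part-of-speech
  from two providers — a rule-based shallow-NLP tagger with a
  fine-grained Penn-style tagset, and a bundled table lexicon with a
  coarse tagset whose deliberately partial coverage maps missing words to
  the `@` sentinel (so the model sees exactly the uninformative-feature
  effect a thin lexicon produces);
* *morphological*: punctuation flag, vowel pattern (`--a--e-i--`),
  digit pattern (`L*`, or the standard value `no*` when no digit is
  present), shape (`Aaaaaaaaaa`) and run-length-compressed brief shape
  (`Aa`);
* *dictionary*: one membership flag per gazetteer — four generic lists
  (ordinals, conjunctions, connectives, coordinates) and two
  domain-specific excerpts in the style of anatomy/quality ontology term
  dumps, with a loader for full user-supplied lists. Matching is
  case-folded exact unigram lookup, with no stemming;
* *token contexts*: n-grams over a symmetric window of $w$ tokens on
  each side ($w \in 1..5$): $2w+1$ unigrams, the $2w$ adjacent bigrams,
  or the $2w-1$ adjacent trigrams, with `<PAD>` at sequence boundaries.

Two genuinely open design points are resolved as follows. "Window of
size $n$" is read as $w$ neighbours on each side (a symmetric window of
$2w+1$ tokens), the standard chunking construction; and bigram/trigram
contexts are *adjacent* tuples within the window rather than all
combinations, bounding feature growth. The affix depth $n=5$ is inferred
from the five printed prefixes/suffixes of the worked example.

`preset_spec()` captures the best per-backend configurations: all simple
and morphological features and the generic dictionaries for everyone;
token bigrams with window 3 for `crf_a`; bigrams with window 3 plus
unigrams with window 5 for `crf_b`; unigrams with window 5 for the SVMs.
`with_domain_dicts = TRUE` adds the anatomy/quality gazetteers.

### Aggregation

Predictions of the individual chunkers are combined two ways:

* **Span-set algebra** (`span_union()`, `span_intersection()`,
  `evaluate_expr()`): predictions become sets of exact
  `(caption, start, end)` triples; union keeps everything either system
  found (recall can only rise), intersection keeps only identical spans
  (precision rises). Overlapping-but-unequal spans are distinct members —
  set identity is exact, and no merging policy is applied. Arbitrary
  union/intersection expression trees over the four classifiers are
  supported.
* **Majority voting with veto** (`majority_vote_veto()`): token-level
  voting over the four aligned BIO sequences. A label wins if it has the
  strictly highest count and at least 50% of the votes; on a tie at the
  top — possible with four voters — or when nothing reaches the
  threshold, the designated veto owner's label wins, read literally: the
  veto owner prevails even when it voted a third label. Voting operates
  on tokens rather than spans because the voters emit aligned label
  sequences; note that with four voters and three labels a *complete*
  four-way disagreement is impossible at token level (pigeonhole), which
  is asserted in the test suite. The voted sequence passes through
  `repair_bio()` — any `I` that does not continue a span is rewritten to
  `B` — so it always decodes.

### Evaluation

Scoring is entity-level exact match: a predicted span counts only if its
boundaries equal a gold span's. This is the stricter of the two common
conventions; it fits a task definition in which descriptions "should be
complete" for downstream semantic processing, where a truncated span is
of little use. A partial-overlap criterion is available behind a flag
for diagnostics only. Cross-validation (`cross_validate()`,
`cv_predictions()` + `score_cv()`) stratifies captions by gold-span
count (bins 0, 1–2, 3–5, 6+), shuffles within bins under the seed and
deals round-robin, so fold sizes differ by at most one and each bin is
spread evenly; reported metrics are the arithmetic mean of per-fold
metrics (macro averaging over folds, not pooled micro counts — both
conventions are defensible, and the fold-averaged one matches
"average across the folds" reporting). Two ablation protocols retrain
with each feature unit alone (`ablate_single()`) or removed
(`ablate_leave_one_out()`), the units being individual simple and
morphological features, each context specification, and the generic and
domain dictionary groups.

## The synthetic corpus generator

`synth_corpus()` builds annotated captions from templates — not from a
language model — so every generated phenomenon is deterministic,
inspectable and seedable. Defaults emulate the structure of a manually
annotated figure-caption corpus: a Poisson number of spans per caption
with mean 4, span lengths averaging 5 tokens (capped at 31, minimum 1
via one-token condition terms such as *platyspondyly*), a mix of
canonical (45%), verb-linked (20%), conjunction-chained (20%) and nested
(15%) forms, hedges and vertebral-level abbreviations at 15% each, and a
30% share of distractor (non-phenotype) sentences. Spans never open with
an article, and verb-linked forms keep the linking verb inside the span,
mirroring the annotation conventions of such corpora. Captions come out
at roughly 40–45 tokens; the sentence-count and distractor proportions
of real corpora are unpublished beyond rough figures, so these preset
values are stated assumptions.

Three study presets matter for validation:

* `separable` — spans are fully determined by a gazetteer-visible
  pattern (quality terms followed by an anatomy term, or
  "*nominal-quality* of the *anatomy*"), span vocabulary never occurs
  outside spans, and the between-span connector is fixed so the span
  grammar stays unambiguous. Any competent backend should score near
  1.0; this is a separability sanity check, not a benchmark.
* `hard` — plants the domain's confusable tokens in both roles
  (*radial* metaphysis vs. *radial* view; *long* bones vs. *long*
  history), lets anatomy words appear in distractor sentences, and
  raises hedge/abbreviation rates. Scores drop materially relative to
  `separable`.
* `planted` — single-token spans drawn from a 300-term synthetic marker
  gazetteer embedded in unrelated filler vocabulary, with both
  vocabularies random strings; only gazetteer membership generalizes
  across folds, making the expected ablation ranking unambiguous.

What passing tests on these corpora does **not** show: generated
captions have a closed vocabulary a few hundred words wide, far less
lexical and syntactic variety than real figure captions, no OCR noise,
no genuinely unseen span heads at test time (except in `planted`), and
gold annotations that are consistent by construction rather than by
expert judgment. Results on synthetic presets validate the machinery —
feature extraction, training, decoding, aggregation, scoring — and the
relative orderings one can derive analytically; they do not predict
absolute scores on real corpora, where open vocabulary and genuine
annotation ambiguity make the task substantially harder than any
closed-vocabulary synthetic preset.

## Numerical choices

* CRF optimization: L-BFGS-B, at most 60 iterations, `factr = 1e8`,
  zero initialization (the objective is convex, so the fit is
  deterministic). On representative corpora the objective is flat after
  roughly 50 iterations; the cap trades a fraction of a percent of
  likelihood for substantially less compute, with no measurable score
  change.
* PA-I updates: aggressiveness cap `C = 1`, 5 shuffled epochs (xorshift
  RNG seeded from the spec seed), averaged weights; binary subproblems
  missing a class degenerate to constant classifiers for the present
  class.
* Hashed conjunction map: 2^19 slots; collisions are rare at the
  feature counts involved (tens of active features per token) and act
  as mild regularization.
* Tie-breaks are all deterministic: one-vs-one prediction breaks vote
  ties by summed margins, then label order; one-vs-all takes the first
  maximal margin.
* Degenerate inputs: empty captions featurize to empty sequences and
  predict empty label vectors; features unseen at training are dropped
  at prediction; `prf()` flags zero-denominator metrics instead of
  dividing by zero; stand-off spans not aligned to token boundaries are
  snapped outward to the smallest covering token interval with a
  warning; structurally invalid BIO output is repaired (`I` after `O`
  becomes `B`) rather than rejected, since classifier and voting output
  must always decode.

## Problem sizes used in validation

The package's own end-to-end checks run the separable and hard presets
at 1,000 captions with ten-fold stratified cross-validation for all four
backends, and the ablation protocols on a 160-caption planted corpus
with four folds — sizes chosen so the full suite exercises every code
path at corpus scale while remaining comfortably runnable on one CPU.
`scripts/acceptance.R` re-runs the same pipeline from scratch and writes
the resulting metrics as JSON.

## Known limitations

* The lemma/POS providers are intentionally lightweight; a production
  system would plug a full morphological analyser and a licensed
  lexicon into the provider contract.
* The bundled anatomy/quality gazetteers are small curated excerpts;
  full ontology term dumps can be loaded via `load_dictionary()` but are
  not shipped.
* The SVM backends' greedy decoding with a previous-label feature is a
  stand-in for richer structured SVM decoding; like the original
  forward-parsing chunkers it can propagate an early labeling mistake
  through a span.
* Set-algebra aggregation treats partial overlaps as distinct spans; no
  span-merging policy is provided, by design.
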