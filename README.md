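# phenochunk

Recognition of skeletal phenotype descriptions in free text — statements
like *bell-shaped thorax*, *hitchhiker thumb* or *flattening and squaring
of the metacarpal heads* that describe qualities (often abnormalities) of
anatomical entities. Such descriptions carry the phenotypic content of
figure captions, clinical summaries and case reports, and recognizing
them is the prerequisite for genotype–phenotype analysis and phenotype
ontology population. The package is aimed at biomedical text-mining
practitioners who need a transparent, fully seedable named-entity
pipeline for this entity class, and at anyone who wants to study
classifier-ensemble aggregation for chunking tasks under controlled
conditions.

## What it does

Recognition is cast as BIO sequence labeling: each token is tagged
`B` (begins a phenotype description), `I` (inside) or `O` (outside), and
maximal `B I*` runs decode to predicted spans. Four divergent chunkers
share one contract:

* two **linear-chain CRFs** (`crf_a`, `crf_b`), differing in L2
  regularization (C = 1 vs C = 3.5) and context features, fitted by
  L-BFGS over exact forward–backward gradients and decoded by Viterbi;
* two **margin-based (SVM-style) token chunkers** (`svm_ovo`,
  `svm_ova`), one-vs-one and one-vs-all over the three labels, trained
  with averaged passive-aggressive updates, with a hashed explicit
  degree-2 interaction map standing in for the polynomial kernel, and
  greedy left-to-right decoding with the previous predicted label as a
  feature.

All four consume a configurable battery of features per token: character
affixes (n = 1..5), lemma and part-of-speech from two providers,
orthographic shapes (`Aaaaaaaaaa` → `Aa`, vowel and digit patterns),
gazetteer membership flags (generic lists plus anatomy/quality
excerpts), and token n-gram contexts in symmetric windows.

Predictions are combined by **span-set algebra** — union ("keep
everything", raises recall) and intersection ("keep only agreed spans",
raises precision) over exact `(caption, start, end)` triples, composable
into expression trees — or by **token-level majority voting with veto**:
a label needs a strict majority reaching 50% of the four votes; ties and
threshold failures go to the designated veto owner. Systems are scored
by entity-level exact-match precision/recall/F1 under stratified
ten-fold cross-validation (folds balanced by span count per caption),
with single-feature and leave-one-out ablation protocols.

Because expert-annotated corpora for this entity class are scarce, a
template-based synthetic generator (`synth_corpus()`) produces annotated
caption corpora with the right structure — ~4 spans per caption
averaging 5 tokens (range 1–31), canonical/verb-linked/conjoined/nested
forms, hedges, abbreviations, distractor sentences — plus a provably
`separable` preset, an ambiguity-laden `hard` preset, and a `planted`
gazetteer-signal preset for ablation sanity checks.

## Worked example

```r
library(phenochunk)

corpus <- synth_corpus(200, seed = 42, preset = "paperlike")
corpus_stats(corpus)
#> Corpus statistics
#>   captions: 200   tokens: 8613   phenotype spans: 806
#>   tokens/caption: 43.06   spans/caption: 4.03
#>   tokens/span: 5.02   span length range: [1, 20]

model <- train_chunker(preset_spec("crf_a"), corpus)
cap <- caption("demo",
  "Radiograph shows bell-shaped thorax and short ribs. Same patient as in figure 2.")
predict_spans(model, cap)
#>   start end
#> 1     2   7
```

The predicted span covers tokens 2–7 (0-based, half-open):
*bell-shaped thorax and short ribs* — the chunker has tagged the
conjoined quality–entity chain as one description, following the
conjunction-chained forms it saw in training, and has left the opener
and the distractor sentence outside. Cross-validating the same
configuration:

```r
cross_validate(corpus, preset_spec("crf_a"), k = 5, seed = 1)
#> <cv_result> crf_a  (5 folds)
#>   mean P 93.65%  R 88.79%  F1 91.15%
```

which reads: averaged over five held-out folds, 93.65% of predicted
spans exactly matched a gold span (precision), 88.79% of gold spans were
recovered with exact boundaries (recall), F1 91.15%. Ensembles are
scored from shared fold predictions without retraining:

```r
specs <- sapply(c("crf_a", "svm_ova"), preset_spec, simplify = FALSE)
cvp <- cv_predictions(corpus, specs, k = 5, seed = 1)
score_cv(cvp, list("union", "crf_a", "svm_ova"))   # recall up
score_cv(cvp, vote_config(c("crf_a", "svm_ova", "crf_a", "svm_ova"),
                          veto_owner = "crf_a"))
```

A thin command-line front end (`inst/cli/phenochunk.R`) exposes the same
pipeline as `synth`, `stats`, `evaluate`, `compare` and `ablate`
commands driven by a YAML experiment config.

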