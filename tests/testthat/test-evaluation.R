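test_that("exact span matching counts tp/fp/fn correctly", {
  gold <- data.frame(start = c(0L, 5L), end = c(2L, 6L))
  pred <- data.frame(start = c(0L, 8L), end = c(2L, 9L))
  expect_equal(match_spans(gold, pred), c(tp = 1L, fp = 1L, fn = 1L))
  expect_equal(match_spans(gold, gold), c(tp = 2L, fp = 0L, fn = 0L))
  none <- data.frame(start = integer(0), end = integer(0))
  expect_equal(match_spans(gold, none), c(tp = 0L, fp = 0L, fn = 2L))
})

test_that("exact matching agrees with naive pairwise comparison", {
  set.seed(21)
  for (rep in 1:200) {
    g <- random_span_set(6, caps = "c")[, c("start", "end")]
    p <- random_span_set(6, caps = "c")[, c("start", "end")]
    tp <- 0L
    for (i in seq_len(nrow(g)))
      for (j in seq_len(nrow(p)))
        if (g$start[i] == p$start[j] && g$end[i] == p$end[j]) tp <- tp + 1L
    expect_equal(match_spans(g, p),
                 c(tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp))
  }
})

test_that("the overlap criterion gives partial credit for boundary misses", {
  gold <- data.frame(start = 0L, end = 3L)
  pred <- data.frame(start = 1L, end = 2L)
  expect_equal(match_spans(gold, pred)[["tp"]], 0L)
  expect_equal(match_spans(gold, pred, criterion = "overlap")[["tp"]], 1L)
})

test_that("precision/recall/F1 follow the standard definitions", {
  m <- prf(1, 1, 1)
  expect_equal(c(m$precision, m$recall, m$f1), c(0.5, 0.5, 0.5))
  m2 <- prf(2, 0, 0)
  expect_equal(c(m2$precision, m2$recall, m2$f1), c(1, 1, 1))
  m0 <- prf(0, 0, 0)
  expect_equal(m0$f1, 0)
  expect_true(m0$degenerate)
  expect_error(prf(-1, 0, 0), "non-negative")
})

test_that("F1 lies between min and max of precision and recall", {
  set.seed(5)
  for (rep in 1:300) {
    m <- prf(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    if (m$precision + m$recall > 0) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("stratified folds partition the corpus with balanced sizes and strata", {
  co <- synth_corpus(97, seed = 31, preset = "paperlike")
  fa <- stratified_folds(co, k = 10, seed = 2)
  expect_setequal(names(fa$assignment), names(co))
  sizes <- tabulate(fa$assignment, nbins = 10)
  expect_lte(max(sizes) - min(sizes), 1L)
  # per-fold stratum composition within one caption of the even share
  for (b in levels(fa$strata)) {
    members <- fa$assignment[fa$strata == b]
    if (!length(members)) next
    per_fold <- tabulate(members, nbins = 10)
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  expect_identical(stratified_folds(co, 10, 2)$assignment, fa$assignment)
  expect_error(stratified_folds(co, 98), "exceeds")
  co20 <- synth_corpus(20, seed = 1, preset = "separable")
  expect_true(all(tabulate(stratified_folds(co20, 10)$assignment, 10) == 2))
})

test_that("cross-validation is deterministic and fold means are arithmetic", {
  co <- synth_corpus(40, seed = 12, preset = "separable")
  r1 <- cross_validate(co, preset_spec("svm_ova", TRUE), k = 4, seed = 3)
  r2 <- cross_validate(co, preset_spec("svm_ova", TRUE), k = 4, seed = 3)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_equal(r1$mean$f1, mean(r1$per_fold$f1))
  expect_equal(r1$mean$precision, mean(r1$per_fold$precision))
  expect_equal(nrow(r1$per_fold), 4L)
})

test_that("a memorizable separable corpus is solved perfectly under CV", {
  co <- synth_corpus(40, seed = 12, preset = "separable")
  r <- cross_validate(co, preset_spec("crf_a", TRUE), k = 4, seed = 3)
  expect_equal(r$mean$f1, 1.0)
})

test_that("shared fold predictions score single systems and ensembles consistently", {
  co <- synth_corpus(40, seed = 22, preset = "hard")
  specs <- list(crf_a = preset_spec("crf_a", TRUE),
                svm_ova = preset_spec("svm_ova", TRUE))
  cvp <- cv_predictions(co, specs, k = 4, seed = 9)
  single <- score_cv(cvp, "crf_a")
  expect_identical(
    single$per_fold,
    cross_validate(co, preset_spec("crf_a", TRUE), k = 4, seed = 9)$per_fold)
  uni <- score_cv(cvp, list("union", "crf_a", "svm_ova"))
  inter <- score_cv(cvp, list("intersect", "crf_a", "svm_ova"))
  # per-fold set monotonicity carries over to recall
  expect_true(all(uni$per_fold$recall >=
                  pmax(single$per_fold$recall,
                       score_cv(cvp, "svm_ova")$per_fold$recall) - 1e-12))
  expect_true(all(inter$per_fold$recall <= single$per_fold$recall + 1e-12))
  vote <- score_cv(cvp, vote_config(c("crf_a", "svm_ova", "crf_a", "svm_ova"),
                                    veto_owner = "crf_a"))
  expect_true(is.finite(vote$mean$f1))
})

test_that("ablation reports cover every unit of the base configuration", {
  co <- synth_corpus(60, seed = 17, preset = "separable")
  base <- chunker_spec(
    "svm_ova",
    feature_config(enabled = c("prefix", "suffix", "shape"), affix_n = 3,
                   context_specs = list(context_spec("uni", 1)),
                   dictionaries = c("conjunctions", "anatomy")),
    seed = 1)
  rep_single <- ablate_single(base, co, k = 3, seed = 5)
  expect_setequal(names(rep_single$rows),
                  c("prefix", "suffix", "shape", "token_uni1",
                    "dict_generic", "dict_domain"))
  expect_equal(rep_single$mode, "single_feature")
  rep_loo <- ablate_leave_one_out(base, co, k = 3, seed = 5)
  expect_setequal(names(rep_loo$rows), names(rep_single$rows))
  # reproducible per seed
  rep2 <- ablate_leave_one_out(base, co, k = 3, seed = 5)
  expect_identical(ablation_table(rep_loo), ablation_table(rep2))
})
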