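test_that("span union keeps everything, intersection only shared triples", {
  a <- span_set(c("c1", "c1"), c(0, 5), c(2, 6))
  b <- span_set(c("c1", "c1"), c(5, 8), c(6, 9))
  u <- span_union(a, b)
  expect_equal(nrow(u), 3L)
  expect_equal(u$start, c(0L, 5L, 8L))
  i <- span_intersection(a, b)
  expect_equal(nrow(i), 1L)
  expect_equal(i$start, 5L)
  # overlapping-but-unequal spans are distinct members
  ov <- span_union(span_set("c1", 0, 3), span_set("c1", 1, 3))
  expect_equal(nrow(ov), 2L)
  # identity / idempotence
  expect_equal(span_union(a, span_set()), a)
  expect_equal(span_intersection(a, a), a)
})

test_that("set operations are commutative, associative and idempotent", {
  set.seed(99)
  for (rep in 1:40) {
    a <- random_span_set(); b <- random_span_set(); c <- random_span_set()
    expect_equal(span_union(a, b), span_union(b, a))
    expect_equal(span_intersection(a, b), span_intersection(b, a))
    expect_equal(span_union(span_union(a, b), c),
                 span_union(a, span_union(b, c)))
    expect_equal(span_intersection(span_intersection(a, b), c),
                 span_intersection(a, span_intersection(b, c)))
    expect_equal(span_union(a, a), a)
    expect_equal(span_intersection(a, a), a)
  }
})

test_that("ensemble expressions match a naive set evaluator", {
  # independent evaluator over plain key-string sets
  naive <- function(expr, preds) {
    if (is.character(expr))
      return(with(preds[[expr]], paste(caption_id, start, end)))
    args <- lapply(expr[-1], naive, preds = preds)
    Reduce(if (expr[[1]] == "union") union else intersect, args)
  }
  set.seed(7)
  ids <- c("m1", "m2", "m3", "m4")
  ops <- c("union", "intersect")
  for (rep in 1:30) {
    preds <- setNames(lapply(ids, function(i) random_span_set()), ids)
    expr <- list(sample(ops, 1),
                 list(sample(ops, 1), sample(ids, 1), sample(ids, 1)),
                 sample(ids, 1))
    got <- evaluate_expr(expr, preds)
    expect_setequal(with(got, paste(caption_id, start, end)),
                    naive(expr, preds))
  }
  expect_identical(evaluate_expr("m1", list(m1 = span_set("c", 1, 2))),
                   span_set("c", 1, 2))
  expect_error(evaluate_expr("nope", list()), "no predictions")
})

test_that("union never hurts recall; intersection never helps it", {
  score <- function(pred, gold) {
    tp <- sum(with(pred, paste(caption_id, start, end)) %in%
              with(gold, paste(caption_id, start, end)))
    if (nrow(gold) == 0) return(NA_real_)
    tp / nrow(gold)
  }
  set.seed(13)
  for (rep in 1:1000) {
    gold <- random_span_set(8)
    if (nrow(gold) == 0) next
    a <- random_span_set(8); b <- random_span_set(8)
    expect_gte(score(span_union(a, b), gold),
               max(score(a, gold), score(b, gold)))
    expect_lte(score(span_intersection(a, b), gold),
               min(score(a, gold), score(b, gold)))
  }
})

test_that("majority voting with veto matches a brute-force oracle on all patterns", {
  # independent restatement of the rule: strict top count reaching
  # ceil(threshold * 4) wins, otherwise the veto owner's label
  oracle <- function(votes, veto_label) {
    counts <- table(factor(votes, levels = c("B", "I", "O")))
    top <- names(counts)[counts == max(counts)]
    if (max(counts) >= 2 && length(top) == 1) top else veto_label
  }
  voters <- c("m1", "m2", "m3", "m4")
  patterns <- expand.grid(rep(list(c("B", "I", "O")), 4),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(patterns), 81L)
  for (veto in voters) {
    cfg <- vote_config(voters, veto_owner = veto)
    for (r in seq_len(nrow(patterns))) {
      votes <- as.character(unlist(patterns[r, ]))
      got <- majority_vote_veto(
        setNames(as.list(votes), voters), cfg)
      want <- repair_bio(oracle(votes, votes[match(veto, voters)]))
      expect_identical(got, want)
    }
  }
})

test_that("a 2-2 tie goes to the veto owner's label", {
  cfg <- vote_config(c("m1", "m2", "m3", "m4"), veto_owner = "m1")
  expect_identical(
    majority_vote_veto(list(m1 = "B", m2 = "B", m3 = "O", m4 = "O"), cfg),
    "B")
  # the rule is literal: the veto owner's label wins even when it voted
  # the third label
  cfg4 <- vote_config(c("m1", "m2", "m3", "m4"), veto_owner = "m4")
  expect_identical(
    majority_vote_veto(list(m1 = "B", m2 = "B", m3 = "O", m4 = "O"), cfg4),
    "O")
})

test_that("complete four-way disagreement is impossible over three labels", {
  # pigeonhole: some label always gets >= 2 of 4 votes, so token-level
  # voting never reaches the no-votes-at-all case
  patterns <- expand.grid(rep(list(c("B", "I", "O")), 4),
                          stringsAsFactors = FALSE)
  max_count <- apply(patterns, 1, function(v) max(table(v)))
  expect_true(all(max_count >= 2))
})

test_that("voting validates its inputs", {
  cfg <- vote_config(c("m1", "m2", "m3", "m4"))
  expect_error(majority_vote_veto(list(m1 = "B"), cfg), "missing")
  expect_error(majority_vote_veto(
    list(m1 = c("B", "I"), m2 = "B", m3 = "B", m4 = "B"), cfg),
    "length")
  expect_error(vote_config(c("a", "b"), veto_owner = "z"), "veto_owner")
  expect_identical(
    majority_vote_veto(list(m1 = character(0), m2 = character(0),
                            m3 = character(0), m4 = character(0)), cfg),
    character(0))
})

test_that("voted sequences are repaired to decodable BIO", {
  cfg <- vote_config(c("m1", "m2", "m3", "m4"), veto_owner = "m1")
  seqs <- list(m1 = c("O", "I"), m2 = c("O", "I"), m3 = c("O", "I"),
               m4 = c("B", "I"))
  expect_identical(majority_vote_veto(seqs, cfg), c("O", "B"))
})
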