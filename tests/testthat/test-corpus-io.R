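test_that("tokenize splits words and punctuation, keeping internal hyphens", {
  expect_equal(tokenize("short ribs.")$text, c("short", "ribs", "."))
  expect_equal(tokenize("bell-shaped thorax")$text, c("bell-shaped", "thorax"))
  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(nrow(tokenize("   ")), 0L)
  expect_equal(tokenize("L4-S1, severe")$text, c("L4-S1", ",", "severe"))
})

test_that("token offsets re-slice the original text", {
  for (txt in c("short ribs.", "bell-shaped  thorax and L4-S1!",
                "a, b  - c")) {
    tok <- tokenize(txt)
    expect_equal(substring(txt, tok$start + 1L, tok$end), tok$text)
  }
})

test_that("spans_to_bio marks span starts B, insides I, rest O", {
  expect_equal(spans_to_bio(tiny_caption()), c("B", "I", "O", "O"))
  cap0 <- caption("c", "no annotation here")
  expect_equal(spans_to_bio(cap0), rep("O", 3))
  adj <- caption("c", "short ribs",
                 spans = data.frame(start = c(0L, 1L), end = c(1L, 2L)))
  expect_equal(spans_to_bio(adj), c("B", "B"))
})

test_that("overlapping gold spans are rejected", {
  expect_error(
    caption("c", "one two three",
            spans = data.frame(start = c(0L, 1L), end = c(2L, 3L))),
    "overlap")
})

test_that("bio_to_spans decodes runs and repairs orphan I labels", {
  expect_equal(bio_to_spans(c("B", "I", "O", "B")),
               data.frame(start = c(0L, 3L), end = c(2L, 4L)))
  expect_equal(bio_to_spans(c("O", "I", "I")),
               data.frame(start = 1L, end = 3L))
  expect_error(bio_to_spans(c("B", "X")), "unknown BIO label")
})

test_that("BIO round-trip is the identity on valid captions", {
  set.seed(11)
  for (i in 1:200) {
    cap <- random_caption(paste0("c", i))
    expect_identical(bio_to_spans(spans_to_bio(cap)), cap$spans)
  }
})

test_that("decoding then re-encoding equals repair, exhaustively to length 8", {
  for (len in c(1L, 3L, 8L)) {
    for (labels in all_bio_sequences(len)) {
      rep1 <- repair_bio(labels)
      expect_identical(repair_bio(rep1), rep1)  # idempotent
      cap <- labelled_caption(labels)           # builds via bio_to_spans
      expect_identical(spans_to_bio(cap), rep1)
    }
  }
})

test_that("CoNLL files round-trip tokens, labels and caption boundaries", {
  co <- pheno_corpus(list(tiny_caption("a"),
                          labelled_caption(c("O", "B", "I"), "b")))
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(co, path)
  back <- read_conll(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$tokens$text, co[[i]]$tokens$text)
    expect_equal(spans_to_bio(back[[i]]), spans_to_bio(co[[i]]))
  }
  # writer output is stable byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".conll")
  write_conll(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("CoNLL reader rejects malformed input with a line number", {
  path <- withr::local_tempfile(fileext = ".conll")
  writeLines(c("tok\tB", "lonely"), path)
  expect_error(read_conll(path), "line 2")
  writeLines(c("tok\tB", "tok\tX"), path)
  expect_error(read_conll(path), "label 'X'")
  writeLines(c("", "", ""), path)
  expect_length(read_conll(path), 0L)
})

test_that("stand-off JSON round-trips text and token spans", {
  co <- synth_corpus(12, seed = 5, preset = "paperlike")
  path <- withr::local_tempfile(fileext = ".json")
  write_standoff(co, path)
  back <- read_standoff(path)
  expect_equal(length(back), length(co))
  for (id in names(co)) {
    expect_identical(back[[id]]$text, co[[id]]$text)
    expect_identical(back[[id]]$spans, co[[id]]$spans)
  }
})

test_that("stand-off character spans map to tokens, snapping outward", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(captions = list(
    list(id = "c1", text = "short ribs",
         spans = list(list(start = 0, end = 10)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_identical(read_standoff(path)[[1]]$spans,
                   data.frame(start = 0L, end = 2L))
  doc$captions[[1]]$spans <- list(list(start = 1, end = 4))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_warning(back <- read_standoff(path), "snapped")
  expect_identical(back[[1]]$spans, data.frame(start = 0L, end = 1L))
  doc$captions[[1]]$spans <- list(list(start = 3, end = 99))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(suppressWarnings(read_standoff(path)), "outside")
})

test_that("corpus_stats counts and means are exact", {
  c1 <- labelled_caption(c("B", "I", "O", "O", "O", "O", "O", "O", "O", "O"))
  c2 <- labelled_caption(c("B", "I", "I", "I", "O", "O"), "c2")
  st <- corpus_stats(pheno_corpus(list(c1, c2)))
  expect_equal(st$n_captions, 2L)
  expect_equal(st$n_tokens, 16L)
  expect_equal(st$n_spans, 2L)
  expect_equal(st$mean_tokens_per_span, 3)
  expect_equal(st$min_span_len, 2L)
  expect_equal(st$max_span_len, 4L)
  expect_warning(
    st0 <- corpus_stats(pheno_corpus(list(labelled_caption(c("O", "O"))))),
    "no spans")
  expect_equal(st0$n_spans, 0L)
  expect_true(is.na(st0$mean_tokens_per_span))
})

test_that("corpus_stats agrees exactly with the generator's own ledger", {
  co <- synth_corpus(80, seed = 3, preset = "paperlike")
  led <- gen_ledger(co)
  st <- corpus_stats(co)
  expect_equal(st$n_captions, nrow(led))
  expect_equal(st$n_tokens, sum(led$n_tokens))
  expect_equal(st$n_spans, sum(led$n_spans))
  expect_equal(st$mean_spans_per_caption, mean(led$n_spans))
})
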