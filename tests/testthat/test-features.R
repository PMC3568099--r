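test_that("affix features of 'flattening' at n = 5 match the worked example", {
  v <- extract_simple("flattening", n = 5)
  expect_equal(unname(v[paste0("p", 1:5)]),
               c("f", "fl", "fla", "flat", "flatt"))
  expect_equal(unname(v[paste0("s", 1:5)]),
               c("g", "ng", "ing", "ning", "ening"))
})

test_that("affixes truncate at the token length", {
  v <- extract_simple("ab", n = 5)
  expect_equal(unname(v[c("p1", "p2")]), c("a", "ab"))
  expect_false("p3" %in% names(v))
  expect_equal(sum(grepl("^p[0-9]+$", names(v))), 2L)  # min(n, len)
  expect_equal(sum(grepl("^s[0-9]+$", names(v))), 2L)
})

test_that("tokens absent from the secondary lexicon yield the @ sentinel", {
  v <- extract_simple("L4")
  expect_equal(unname(v["lemma_secondary"]), "@")
  expect_equal(unname(v["pos_secondary"]), "@")
  v2 <- extract_simple("ribs")
  expect_equal(unname(v2["lemma_secondary"]), "rib")
  expect_equal(unname(v2["pos_secondary"]), "noun")
})

test_that("morphological features reproduce the worked examples", {
  v <- extract_morph("flattening")
  expect_equal(unname(v["vowels"]), "--a--e-i--")
  vF <- extract_morph("Flattening")
  expect_equal(unname(vF["shape"]), "Aaaaaaaaaa")
  expect_equal(unname(vF["brief_shape"]), "Aa")
  expect_equal(unname(extract_morph("thorax")["digits"]), "no*")
  vL <- extract_morph("L4")
  expect_equal(unname(vL[c("digits", "shape", "brief_shape")]),
               c("L*", "A0", "A0"))
  expect_equal(unname(extract_morph("bell-shaped")["punct"]), "1")
  expect_equal(unname(extract_morph("ribs")["punct"]), "0")
})

test_that("brief shape is the run-length compression of shape, vowels keep length", {
  set.seed(42)
  alphabet <- c(letters, LETTERS, 0:9, "-", ".")
  for (i in 1:200) {
    tok <- paste(sample(alphabet, sample.int(12, 1), replace = TRUE),
                 collapse = "")
    v <- extract_morph(tok)
    r <- rle(strsplit(v[["shape"]], "")[[1]])
    expect_identical(v[["brief_shape"]], paste(r$values, collapse = ""))
    expect_equal(nchar(v[["vowels"]]), nchar(tok))
    if (grepl("[0-9]", tok)) expect_equal(nchar(v[["digits"]]), nchar(tok))
  }
})

test_that("dictionary features flag case-folded unigram membership", {
  dicts <- bundled_dictionaries(c("conjunctions", "coordinates", "anatomy",
                                  "quality"))
  expect_equal(unname(extract_dict("and", dicts)["dict_conjunctions"]), "1")
  expect_equal(unname(extract_dict("Left", dicts)["dict_coordinates"]), "1")
  v <- extract_dict("thorax", dicts)
  expect_equal(unname(v["dict_anatomy"]), "1")
  expect_equal(unname(v["dict_quality"]), "0")
})

test_that("context windows tag neighbours by offset and pad at boundaries", {
  toks <- c("short", "and", "wide", "ribs")
  v <- extract_context(toks, 2, context_spec("uni", 1))
  expect_equal(unname(v), c("short", "and", "wide"))
  expect_equal(names(v), c("uni1[-1]", "uni1[+0]", "uni1[+1]"))
  v0 <- extract_context(toks, 1, context_spec("uni", 1))
  expect_equal(unname(v0["uni1[-1]"]), "<PAD>")
  expect_error(extract_context(toks, 9, context_spec("uni", 1)),
               "out of range")
})

test_that("bigram/trigram contexts enumerate adjacent tuples in the window", {
  toks <- c("short", "and", "wide", "ribs", "with", "cupping")
  # independent brute-force enumeration of adjacent pairs inside the window
  brute_pairs <- function(i, w) {
    offs <- -w:(w - 1)
    at <- function(o) {
      j <- i + o
      if (j < 1 || j > length(toks)) "<PAD>" else toks[j]
    }
    vapply(offs, function(o) paste(at(o), at(o + 1), sep = "|"), "")
  }
  for (i in seq_along(toks)) {
    for (w in 1:3) {
      v <- extract_context(toks, i, context_spec("bi", w))
      expect_equal(unname(v), brute_pairs(i, w))
      expect_length(v, 2 * w)
      expect_length(extract_context(toks, i, context_spec("tri", w)),
                    2 * w - 1)
      expect_length(extract_context(toks, i, context_spec("uni", w)),
                    2 * w + 1)
    }
  }
})

test_that("featurize_sequence emits exactly the enabled families, deterministically", {
  cap <- tiny_caption()
  fc <- feature_config(enabled = "shape")
  fv <- featurize_sequence(cap, fc)
  expect_length(fv, nrow(cap$tokens))
  expect_true(all(vapply(fv, length, integer(1)) == 1L))
  expect_true(all(vapply(fv, names, character(1)) == "shape"))
  # enabling a family twice is idempotent
  fc2 <- feature_config(enabled = c("shape", "shape"))
  expect_identical(featurize_sequence(cap, fc2), fv)
  # determinism across calls under a full config
  full <- preset_spec("crf_b", TRUE)$feature_config
  expect_identical(featurize_sequence(cap, full),
                   featurize_sequence(cap, full))
  expect_error(feature_config(enabled = "nope"), "unknown feature")
})
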