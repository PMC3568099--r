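# Template-based generator of annotated figure-caption corpora. Templates,
# not a language model: every linguistic phenomenon the generator emulates
# (canonical quality-entity pairs, verb-linked and conjunction-chained
# forms, nesting, hedges, abbreviations, distractor sentences) is a
# separate, seedable mechanism.

SPAN_ANATOMY <- c("thorax", "ribs", "clavicles", "femur", "tibia", "fibula",
                  "humerus", "radius", "ulna", "metacarpals", "metatarsals",
                  "phalanges", "vertebrae", "pelvis", "skull", "mandible",
                  "scapula", "sternum", "epiphyses", "metaphyses",
                  "diaphyses", "hands", "feet", "fingers", "thumbs", "toes",
                  "knees", "elbows", "wrists", "ankles")
SPAN_QUALITY <- c("short", "broad", "wide", "narrow", "thin", "thick",
                  "flattened", "flattening", "irregular", "hypoplastic",
                  "dysplastic", "sclerotic", "osteopenic", "bowed",
                  "widened", "shortened", "elongated", "enlarged", "cupped",
                  "flared", "squared", "rounded", "bell-shaped",
                  "cone-shaped", "hitchhiker", "trident", "stippled",
                  "fragmented", "absent", "fused", "delayed", "decreased",
                  "increased", "small", "large")
SPAN_VERBS <- c("appear", "appears", "is", "are", "seem", "seems")
# nominal qualities used in nested "X of the Y" forms; all in the quality
# gazetteer
NOMINAL_QUALITY <- c("flattening", "shortening", "widening", "narrowing",
                     "thickening", "bowing", "cupping", "flaring",
                     "squaring", "sclerosis", "hypoplasia", "dysplasia",
                     "fragmentation", "fusion", "angulation",
                     "irregularity")
# condition terms that form complete one-token phenotype descriptions
SOLO_PHENO <- c("platyspondyly", "brachydactyly", "arachnodactyly",
                "clinodactyly", "polydactyly", "syndactyly")
HEDGES <- c("subtle", "mild", "possible", "apparent", "slight")
ABBREVS <- c("L1", "L2", "L3", "L4", "L5", "S1", "C2", "C7",
             "T4", "T8", "T12", "L4-S1", "C2-C7", "T4-T8")
OPENER_VOCAB <- list(
  c("radiograph", "shows"),
  c("the", "film", "shows"),
  c("note", "the"),
  c("ap", "view", "obtained", "at", "birth", "shows"),
  c("there", "is"),
  c("the", "image", "demonstrates"))
DISTRACTOR_SENTENCES <- list(
  c("figure", "obtained", "at", "the", "age", "of", "NUM", "years", "."),
  c("same", "patient", "as", "in", "figure", "NUM", "."),
  c("arrows", "indicate", "the", "region", "of", "interest", "."),
  c("clinical", "photograph", "of", "the", "patient", "at", "NUM",
    "months", "."),
  c("panel", "b", "shows", "the", "corresponding", "image", "."),
  c("the", "examination", "was", "performed", "at", "NUM", "years", "."))
HARD_DISTRACTORS <- list(
  c("lateral", "view", "of", "the", "chest", "at", "NUM", "years", "."),
  c("the", "patient", "has", "a", "long", "history", "of", "pain", "."),
  c("radial", "view", "of", "the", "hand", "."),
  c("note", "the", "normal", "appearance", "of", "the", "spine", "."),
  c("irregular", "margins", "are", "a", "common", "artifact", "."),
  c("image", "of", "the", "skull", "for", "comparison", "."))

#' Generator configuration
#'
#' Defaults mirror the corpus structure the package emulates: about four
#' phenotype descriptions per caption, five tokens per description (range
#' 1..31), multi-sentence captions with non-phenotype distractor text, and
#' a mix of canonical, verb-linked, conjunction-chained and nested span
#' forms with occasional hedges and abbreviations.
#'
#' @param n_captions Number of captions to generate.
#' @param mean_spans_per_caption Poisson mean of gold spans per caption.
#' @param span_length_target Target mean tokens per span.
#' @param max_span_len Hard span-length cap.
#' @param form_mix Named proportions (summing to 1) of span forms
#'   `canonical`, `verb`, `conj`, `nested`.
#' @param distractor_rate Expected share of distractor (non-phenotype)
#'   sentences per caption.
#' @param abbreviation_rate Probability an anatomical mention is replaced
#'   by a vertebral-level style abbreviation (`L4`, `C2-C7`, ...).
#' @param hedge_rate Probability a span carries a hedge/qualifier token.
#' @param seed Generation seed; everything downstream is deterministic.
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(n_captions,
                       mean_spans_per_caption = 4,
                       span_length_target = 5,
                       max_span_len = 31L,
                       form_mix = c(canonical = 0.45, verb = 0.2,
                                    conj = 0.2, nested = 0.15),
                       distractor_rate = 0.3,
                       abbreviation_rate = 0.15,
                       hedge_rate = 0.15,
                       seed = 1L) {
  stopifnot(n_captions >= 1, mean_spans_per_caption >= 0,
            span_length_target >= 1, span_length_target <= max_span_len)
  form_mix <- form_mix[c("canonical", "verb", "conj", "nested")]
  if (any(is.na(form_mix)) || any(form_mix < 0) ||
      abs(sum(form_mix) - 1) > 1e-8)
    stop("form_mix must give non-negative proportions summing to 1 for ",
         "canonical/verb/conj/nested")
  rates <- c(distractor_rate, abbreviation_rate, hedge_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(n_captions = as.integer(n_captions),
                 mean_spans_per_caption = mean_spans_per_caption,
                 span_length_target = span_length_target,
                 max_span_len = as.integer(max_span_len),
                 form_mix = form_mix,
                 distractor_rate = distractor_rate,
                 abbreviation_rate = abbreviation_rate,
                 hedge_rate = hedge_rate,
                 seed = as.integer(seed)),
            class = "gen_config")
}

#' Generator lexicons
#'
#' Word lists the caption templates draw from: anatomical entities and
#' qualities (each a subset of the bundled anatomy/quality gazetteers, so
#' dictionary features can see generated spans), metaphorical quality
#' terms, linking verbs, hedges, abbreviations, and non-phenotype
#' distractor vocabulary. Anatomy and quality lists are disjoint.
#'
#' @param preset Lexicon flavour; `"hard"` adds ambiguous usage (terms like
#'   "radial" and "long" appearing both inside and outside phenotype
#'   descriptions).
#' @return A named list of character vectors, class `synth_lexicons`.
#' @export
synth_lexicons <- function(preset = c("paperlike", "separable", "hard",
                                      "planted")) {
  preset <- match.arg(preset)
  lx <- list(anatomy = SPAN_ANATOMY, quality = SPAN_QUALITY,
             nominals = NOMINAL_QUALITY, solo = SOLO_PHENO,
             metaphors = grep("-", SPAN_QUALITY, value = TRUE,
                              fixed = TRUE),
             verbs = SPAN_VERBS, hedges = HEDGES, abbrevs = ABBREVS,
             openers = OPENER_VOCAB, distractors = DISTRACTOR_SENTENCES)
  if (preset == "separable") {
    lx$anatomy <- SPAN_ANATOMY[1:20]
    lx$quality <- SPAN_QUALITY[1:20]
    lx$nominals <- NOMINAL_QUALITY[1:8]
    lx$solo <- NULL  # keep the separable span grammar minimal
  } else if (preset == "hard") {
    lx$distractors <- c(DISTRACTOR_SENTENCES, HARD_DISTRACTORS)
    lx$quality <- unique(c(lx$quality, "long", "lateral", "normal"))
    lx$anatomy_compounds <- list(c("long", "bones"), c("radial", "heads"),
                                 c("vertebral", "bodies"))
  } else if (preset == "planted") {
    words <- random_words(700, seed = 99991L)
    lx <- list(markers = words[1:300], filler = words[301:700])
  }
  structure(lx, class = "synth_lexicons", preset = preset)
}

random_words <- function(n, min_len = 6L, max_len = 9L, seed = 1L) {
  with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      w <- vapply(sample(min_len:max_len, n, replace = TRUE), function(l)
        paste(sample(letters, l, replace = TRUE), collapse = ""),
        character(1))
      out <- unique(c(out, w))
    }
    out[seq_len(n)]
  })
}

# expected core span length under the form mix; used to set the extension
# continuation probability so generated spans hit span_length_target
EXT_MEAN_LEN <- 8 / 3   # extensions average: "of the A"=3, "and A"=2, "and Q A"=3
core_len <- function(form_mix) {
  sum(form_mix * c(canonical = 2.4, verb = 3.4, conj = 4, nested = 4))
}

ext_prob <- function(config) {
  m <- max(0, (config$span_length_target - core_len(config$form_mix)) /
             EXT_MEAN_LEN)
  m / (1 + m)
}

draw <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

make_span_tokens <- function(config, lex, form) {
  A <- function() draw(lex$anatomy)
  Q <- function() draw(lex$quality)
  if (form == "canonical" && !is.null(lex$solo) && stats::runif(1) < 0.1)
    return(draw(lex$solo))
  toks <- switch(form,
    canonical = c(if (stats::runif(1) < 0.4) Q(), Q(), A()),
    verb = c(A(), draw(lex$verbs), if (stats::runif(1) < 0.4) Q(), Q()),
    conj = if (stats::runif(1) < 0.5) c(Q(), "and", Q(), A())
           else c(Q(), A(), "and", A()),
    nested = c(draw(lex$nominals), "of", "the", A()))
  if (!is.null(lex$anatomy_compounds) && stats::runif(1) < 0.2) {
    comp <- lex$anatomy_compounds[[sample.int(length(lex$anatomy_compounds),
                                              1)]]
    toks <- c(draw(lex$quality), comp)
  }
  if (stats::runif(1) < config$hedge_rate)
    toks <- c(draw(lex$hedges), toks)
  p <- ext_prob(config)
  while (stats::runif(1) < p && length(toks) <= config$max_span_len - 3L) {
    ext <- switch(sample.int(3L, 1L),
                  c("of", "the", A()), c("and", A()), c("and", Q(), A()))
    toks <- c(toks, ext)
  }
  if (stats::runif(1) < config$abbreviation_rate)
    toks[length(toks)] <- draw(lex$abbrevs)
  toks[seq_len(min(length(toks), config$max_span_len))]
}

fill_num <- function(toks) {
  toks[toks == "NUM"] <- as.character(draw(1:14, sum(toks == "NUM")))
  toks
}

# assemble one sentence holding `spans` span token vectors; returns tokens
# plus span boundaries relative to the sentence
make_pheno_sentence <- function(span_list, lex) {
  toks <- character(0)
  starts <- integer(0); ends <- integer(0)
  # in the separable preset "and" only ever occurs inside spans, so the
  # between-span connector is fixed to "with" to keep the span grammar
  # unambiguous
  connectors <- if (identical(attr(lex, "preset"), "separable")) "with"
                else c("and", "with")
  if (stats::runif(1) < 0.6)
    toks <- fill_num(lex$openers[[sample.int(length(lex$openers), 1L)]])
  for (j in seq_along(span_list)) {
    if (j > 1L) toks <- c(toks, draw(connectors))
    if (stats::runif(1) < 0.3) toks <- c(toks, "the")  # leading article, outside
    starts <- c(starts, length(toks))
    toks <- c(toks, span_list[[j]])
    ends <- c(ends, length(toks))
  }
  list(tokens = c(toks, "."), start = starts, end = ends)
}

#' Generate one caption
#'
#' Draws a caption from the current RNG state (callers wanting
#' reproducibility should use [generate_corpus()], which seeds from its
#' config). Gold spans never include leading articles; verb-linked forms
#' keep the linking verb inside the span.
#'
#' @param config A [gen_config()].
#' @param lex A [synth_lexicons()].
#' @param id Caption id.
#' @return A [caption()], with attribute `forms` recording the span forms
#'   drawn.
#' @export
generate_caption <- function(config, lex = synth_lexicons(), id = "cap1") {
  if (identical(attr(lex, "preset"), "planted"))
    return(generate_planted_caption(lex, id))
  n_spans <- if (config$distractor_rate >= 1) 0L
             else min(stats::rpois(1, config$mean_spans_per_caption), 12L)
  forms <- if (n_spans)
    draw_forms(config$form_mix, n_spans) else character(0)
  spans <- lapply(forms, function(f) make_span_tokens(config, lex, f))

  sentences <- list()
  i <- 1L
  while (i <= n_spans) {
    take <- if (i < n_spans && stats::runif(1) < 0.25) 2L else 1L
    sentences[[length(sentences) + 1L]] <-
      make_pheno_sentence(spans[i:(i + take - 1L)], lex)
    i <- i + take
  }
  # distractor_rate is the target share of non-phenotype sentences:
  # n_dis / (n_pheno + n_dis) ~= rate
  n_pheno <- length(sentences)
  rate <- config$distractor_rate
  n_dis <- if (rate >= 1) draw(2:4)
           else min(6L, as.integer(round(n_pheno * rate / (1 - rate))))
  if (n_spans == 0L) n_dis <- max(n_dis, 1L)
  for (d in seq_len(n_dis)) {
    toks <- fill_num(lex$distractors[[sample.int(length(lex$distractors),
                                                 1L)]])
    sentences[[length(sentences) + 1L]] <-
      list(tokens = toks, start = integer(0), end = integer(0))
  }
  if (length(sentences) > 1L)
    sentences <- sentences[sample.int(length(sentences))]

  toks <- character(0); starts <- integer(0); ends <- integer(0)
  for (s in sentences) {
    starts <- c(starts, s$start + length(toks))
    ends <- c(ends, s$end + length(toks))
    toks <- c(toks, s$tokens)
  }
  cap <- caption(id, build_text(toks),
                 spans = if (length(starts))
                   data.frame(start = starts, end = ends) else NULL)
  attr(cap, "forms") <- forms
  cap
}

draw_forms <- function(form_mix, n) {
  names(form_mix)[sample.int(4L, n, replace = TRUE, prob = form_mix)]
}

generate_planted_caption <- function(lex, id) {
  n_spans <- draw(1:2)
  toks <- character(0); starts <- integer(0); ends <- integer(0)
  for (s in seq_len(n_spans)) {
    pre <- draw(lex$filler, draw(2:5))
    toks <- c(toks, pre)
    starts <- c(starts, length(toks))
    toks <- c(toks, draw(lex$markers))
    ends <- c(ends, length(toks))
    toks <- c(toks, draw(lex$filler, draw(1:3)))
  }
  toks <- c(toks, ".")
  cap <- caption(id, build_text(toks),
                 spans = data.frame(start = starts, end = ends))
  attr(cap, "forms") <- rep("planted", n_spans)
  cap
}

# join tokens into caption text (no space before sentence punctuation);
# tokenize() recovers exactly these tokens
build_text <- function(toks) {
  if (!length(toks)) return("")
  sep <- ifelse(toks %in% c(".", ",", ";"), "", " ")[-1]
  paste0(toks[1], paste0(c(sep, ""), c(toks[-1], ""), collapse = ""))
}

#' Generate an annotated corpus
#'
#' Deterministic per `config$seed`. The returned corpus carries a
#' generation ledger (attribute `"gen_ledger"`, see [gen_ledger()])
#' recording each caption's true span count and the span forms drawn, for
#' downstream assertions.
#'
#' @param config A [gen_config()].
#' @param lex A [synth_lexicons()].
#' @return A [pheno_corpus()].
#' @export
generate_corpus <- function(config, lex = synth_lexicons()) {
  stopifnot(inherits(config, "gen_config"))
  captions <- with_seed(config$seed, {
    lapply(seq_len(config$n_captions), function(i)
      generate_caption(config, lex, sprintf("cap%05d", i)))
  })
  ledger <- data.frame(
    caption_id = vapply(captions, `[[`, character(1), "id"),
    n_tokens = vapply(captions, function(cp) nrow(cp$tokens), integer(1)),
    n_spans = vapply(captions, function(cp) nrow(cp$spans), integer(1)),
    forms = vapply(captions, function(cp)
      paste(attr(cp, "forms"), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  corpus <- pheno_corpus(captions,
                         provenance = sprintf(
                           "synthetic preset=%s seed=%d n=%d",
                           attr(lex, "preset"), config$seed,
                           config$n_captions))
  attr(corpus, "gen_ledger") <- ledger
  corpus
}

#' @rdname generate_corpus
#' @param corpus A generated corpus.
#' @return `gen_ledger`: the generation bookkeeping data frame.
#' @export
gen_ledger <- function(corpus) attr(corpus, "gen_ledger")

#' Generate a corpus from a named preset
#'
#' Three study presets plus one diagnostic one:
#'
#' * `"paperlike"` — the default configuration: ~4 spans per caption
#'   averaging 5 tokens, mixed span forms, hedges, abbreviations,
#'   distractor sentences.
#' * `"separable"` — spans are fully determined by a gazetteer-visible
#'   pattern (quality terms followed by an anatomy term, or
#'   "quality of the anatomy"), and span vocabulary never occurs outside
#'   spans; any competent backend should solve it almost perfectly.
#' * `"hard"` — adds ambiguous usage: terms such as "radial", "long" and
#'   "lateral" occur both within phenotype descriptions and in distractor
#'   roles, anatomy words appear outside spans, and complex forms abound.
#' * `"planted"` — spans are single tokens from a 300-term synthetic
#'   marker gazetteer embedded in unrelated filler vocabulary; the marker
#'   dictionary is registered as `"markers"` for use in feature configs.
#'   Only the gazetteer generalizes across folds, which makes this the
#'   reference corpus for ablation sanity checks.
#'
#' @param n_captions,seed Passed to [gen_config()].
#' @param preset Preset name.
#' @param ... Further [gen_config()] overrides.
#' @return A [pheno_corpus()] with generation ledger.
#' @export
synth_corpus <- function(n_captions, seed = 1L,
                         preset = c("paperlike", "separable", "hard",
                                    "planted"), ...) {
  preset <- match.arg(preset)
  lex <- synth_lexicons(preset)
  defaults <- switch(preset,
    paperlike = list(),
    separable = list(form_mix = c(canonical = 0.7, verb = 0, conj = 0,
                                  nested = 0.3),
                     span_length_target = 3.2, hedge_rate = 0,
                     abbreviation_rate = 0, distractor_rate = 0.4),
    hard = list(distractor_rate = 0.5, hedge_rate = 0.25,
                abbreviation_rate = 0.25),
    planted = list(mean_spans_per_caption = 1.5))
  args <- utils::modifyList(defaults, list(...))
  config <- do.call(gen_config,
                    c(list(n_captions = n_captions, seed = seed), args))
  if (preset == "planted")
    register_dictionary(structure(list(name = "markers",
                                       terms = lex$markers),
                                  class = "dictionary"))
  generate_corpus(config, lex)
}
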