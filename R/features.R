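SIMPLE_FEATURES <- c("prefix", "suffix", "lemma_primary", "lemma_secondary",
                     "pos_primary", "pos_secondary")
MORPH_FEATURES <- c("punct", "vowels", "digits", "shape", "brief_shape")
ABSENT_SENTINEL <- "@"
PAD_TOKEN <- "<PAD>"

#' Declarative per-token feature configuration
#'
#' Selects which of the four feature families are computed for each token:
#' simple features (character affixes plus lemma and part-of-speech from two
#' lexicon providers), morphological features (orthographic token shapes),
#' dictionary features (gazetteer membership flags) and token contexts
#' (n-grams of neighbouring tokens in a symmetric window).
#'
#' @param enabled Character vector of simple/morphological feature names to
#'   enable. Known names: `r paste(c(SIMPLE_FEATURES, MORPH_FEATURES), collapse = ", ")`.
#' @param affix_n Maximum affix length: prefixes and suffixes of 1..`affix_n`
#'   characters are emitted (shorter tokens emit fewer). Default 5.
#' @param context_specs List of context specifications, each created by
#'   [context_spec()] (gram in `uni`/`bi`/`tri`, window half-width 1..5).
#' @param dictionaries Character vector of dictionary names (see
#'   [load_dictionary()]); each contributes one membership flag per token.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(enabled = c(SIMPLE_FEATURES, MORPH_FEATURES),
                           affix_n = 5L,
                           context_specs = list(),
                           dictionaries = character(0)) {
  enabled <- unique(as.character(enabled))
  unknown <- setdiff(enabled, c(SIMPLE_FEATURES, MORPH_FEATURES))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  affix_n <- as.integer(affix_n)
  stopifnot(affix_n >= 1L)
  context_specs <- lapply(context_specs, function(cs) {
    if (!inherits(cs, "context_spec")) cs <- context_spec(cs[[1]], cs[[2]])
    cs
  })
  structure(list(enabled = enabled, affix_n = affix_n,
                 context_specs = context_specs,
                 dictionaries = unique(as.character(dictionaries))),
            class = "feature_config")
}

#' @rdname feature_config
#' @param gram N-gram order of the context feature: `"uni"`, `"bi"` or
#'   `"tri"`.
#' @param w Window half-width in tokens (1..5): the window covers offsets
#'   `-w..+w` around the current token.
#' @export
context_spec <- function(gram = c("uni", "bi", "tri"), w) {
  gram <- match.arg(gram)
  w <- as.integer(w)
  if (w < 1L || w > 5L) stop("context window half-width must be in 1..5")
  structure(list(gram = gram, w = w), class = "context_spec")
}

context_label <- function(cs) paste0(cs$gram, cs$w)

#' @export
print.feature_config <- function(x, ...) {
  ctx <- vapply(x$context_specs, context_label, character(1))
  cat("<feature_config>\n",
      " enabled: ", paste(x$enabled, collapse = ", "), "\n",
      " affix_n: ", x$affix_n, "\n",
      " contexts: ", if (length(ctx)) paste(ctx, collapse = ", ") else "none",
      "\n  dictionaries: ",
      if (length(x$dictionaries)) paste(x$dictionaries, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

provider_cache <- new.env(parent = emptyenv())

#' Default lemma/POS providers
#'
#' @return List with `primary` ([nlp_provider()]) and `secondary`
#'   ([lexicon_provider()]), cached across calls.
#' @export
default_providers <- function() {
  if (is.null(provider_cache$providers))
    provider_cache$providers <- list(primary = nlp_provider(),
                                     secondary = lexicon_provider())
  provider_cache$providers
}

# ---- morphological primitives (vectorized over token texts) ----

morph_vowels <- function(texts) gsub("[^AEIOUaeiou]", "-", texts)

morph_digits <- function(texts) {
  out <- gsub("[0-9]", "*", texts)
  out[!grepl("[0-9]", texts)] <- "no*"
  out
}

morph_shape <- function(texts) {
  out <- gsub("[[:upper:]]", "A", texts)
  out <- gsub("[[:lower:]]", "a", out)
  gsub("[0-9]", "0", out)
}

morph_brief_shape <- function(texts) gsub("(.)\\1+", "\\1", morph_shape(texts))

morph_punct <- function(texts) ifelse(grepl("[[:punct:]]", texts), "1", "0")

# ---- feature-column builder -------------------------------------------
# Returns a character matrix (tokens x features) with NA marking features
# absent for a token (affixes longer than the token). Shared by the
# user-facing extractors and the ML featurization path.
feature_columns <- function(texts, config, providers, dictionaries) {
  n <- length(texts)
  if (n == 0L) return(matrix(character(0), nrow = 0, ncol = 0))
  cols <- list()
  en <- config$enabled
  len <- nchar(texts)
  if ("prefix" %in% en) {
    for (i in seq_len(config$affix_n)) {
      v <- substr(texts, 1L, i)
      v[len < i] <- NA
      cols[[paste0("p", i)]] <- v
    }
  }
  if ("suffix" %in% en) {
    for (i in seq_len(config$affix_n)) {
      v <- substr(texts, len - i + 1L, len)
      v[len < i] <- NA
      cols[[paste0("s", i)]] <- v
    }
  }
  sentinel <- function(v) ifelse(is.na(v) | !nzchar(v), ABSENT_SENTINEL, v)
  if ("lemma_primary" %in% en)
    cols$lemma_primary <- sentinel(providers$primary$lemma(texts))
  if ("lemma_secondary" %in% en)
    cols$lemma_secondary <- sentinel(providers$secondary$lemma(texts))
  if ("pos_primary" %in% en)
    cols$pos_primary <- sentinel(providers$primary$pos(texts))
  if ("pos_secondary" %in% en)
    cols$pos_secondary <- sentinel(providers$secondary$pos(texts))
  if ("punct" %in% en) cols$punct <- morph_punct(texts)
  if ("vowels" %in% en) cols$vowels <- morph_vowels(texts)
  if ("digits" %in% en) cols$digits <- morph_digits(texts)
  if ("shape" %in% en) cols$shape <- morph_shape(texts)
  if ("brief_shape" %in% en) cols$brief_shape <- morph_brief_shape(texts)
  lower <- tolower(texts)
  for (dn in config$dictionaries) {
    d <- dictionaries[[dn]]
    if (is.null(d)) stop("dictionary '", dn, "' not supplied")
    cols[[paste0("dict_", dn)]] <- ifelse(lower %in% d$terms, "1", "0")
  }
  for (cs in config$context_specs) {
    w <- cs$w
    padded <- c(rep(PAD_TOKEN, w), texts, rep(PAD_TOKEN, w))
    at <- function(o) padded[seq_len(n) + w + o]
    lab <- context_label(cs)
    if (cs$gram == "uni") {
      for (o in -w:w)
        cols[[sprintf("%s[%+d]", lab, o)]] <- at(o)
    } else if (cs$gram == "bi") {
      for (o in -w:(w - 1L))
        cols[[sprintf("%s[%+d,%+d]", lab, o, o + 1L)]] <-
          paste(at(o), at(o + 1L), sep = "|")
    } else {
      for (o in -w:(w - 2L))
        cols[[sprintf("%s[%+d,%+d,%+d]", lab, o, o + 1L, o + 2L)]] <-
          paste(at(o), at(o + 1L), at(o + 2L), sep = "|")
    }
  }
  if (!length(cols))
    return(matrix(character(0), nrow = n, ncol = 0))
  matrix(unlist(cols, use.names = FALSE), nrow = n,
         dimnames = list(NULL, names(cols)))
}

#' Per-token feature extractors
#'
#' Single-token views of the four feature families. [featurize_sequence()]
#' computes the same features for a whole caption at once and is what the
#' chunkers use.
#'
#' `extract_simple` emits prefixes `p1..pn` and suffixes `s1..sn`
#' (truncated at the token length) and lemma/part-of-speech values from the
#' primary and secondary providers; an absent lookup is represented by the
#' sentinel `"@"`. `extract_morph` emits orthographic features: `punct`
#' (contains punctuation), `vowels` (consonants replaced by `-`), `digits`
#' (digits replaced by `*`, or the standard value `no*` when the token has
#' no digit), `shape` (upper `A` / lower `a` / digit `0`) and `brief_shape`
#' (shape with runs of equal characters compressed). `extract_dict` emits
#' one `0`/`1` membership flag per dictionary (case-folded exact unigram
#' match). `extract_context` emits n-grams of window tokens with offset
#' tags; positions outside the sequence yield the `"<PAD>"` sentinel.
#'
#' @param token Token text (character scalar).
#' @param providers List with `primary` and `secondary` lexicon providers;
#'   see [default_providers()].
#' @param n Maximum affix length.
#' @param dictionaries Named list of `dictionary` objects.
#' @param texts Character vector of the caption's token texts.
#' @param i Position of the current token in `texts` (1-based).
#' @param spec A [context_spec()].
#' @return Named character vector of feature values.
#' @export
extract_simple <- function(token, providers = default_providers(), n = 5L) {
  cfg <- feature_config(enabled = SIMPLE_FEATURES, affix_n = n)
  m <- feature_columns(token, cfg, providers, list())
  v <- m[1L, ]
  v[!is.na(v)]
}

#' @rdname extract_simple
#' @export
extract_morph <- function(token) {
  cfg <- feature_config(enabled = MORPH_FEATURES)
  feature_columns(token, cfg, NULL, list())[1L, ]
}

#' @rdname extract_simple
#' @export
extract_dict <- function(token, dictionaries) {
  cfg <- feature_config(enabled = character(0),
                        dictionaries = names(dictionaries))
  feature_columns(token, cfg, NULL, dictionaries)[1L, ]
}

#' @rdname extract_simple
#' @export
extract_context <- function(texts, i, spec) {
  i <- as.integer(i)
  if (i < 1L || i > length(texts)) stop("token index out of range")
  cfg <- feature_config(enabled = character(0), context_specs = list(spec))
  feature_columns(texts, cfg, NULL, list())[i, ]
}

#' Compute feature vectors for every token of a caption
#'
#' Assembles exactly the feature families enabled in `config`, in a
#' deterministic order, one named vector per token.
#'
#' @param x A [caption()].
#' @param config A [feature_config()].
#' @param providers Primary/secondary lexicon providers
#'   ([default_providers()]).
#' @param dictionaries Named list of loaded dictionaries; by default the
#'   ones named in `config` are loaded from the bundled files.
#' @return List (one element per token) of named character feature vectors.
#' @export
featurize_sequence <- function(x, config,
                               providers = default_providers(),
                               dictionaries = NULL) {
  stopifnot(inherits(x, "caption"), inherits(config, "feature_config"))
  if (is.null(dictionaries) && length(config$dictionaries))
    dictionaries <- bundled_dictionaries(config$dictionaries)
  m <- feature_columns(x$tokens$text, config, providers, dictionaries)
  lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    v[!is.na(v)]
  })
}

# Flattened "name=value" encoding used by the learners: one character vector
# of active feature strings per token.
featurize_flat <- function(texts, config, providers, dictionaries) {
  m <- feature_columns(texts, config, providers, dictionaries)
  if (!ncol(m)) return(rep(list(character(0)), length(texts)))
  nm <- colnames(m)
  lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    keep <- !is.na(v)
    paste0(nm[keep], "=", v[keep])
  })
}

# Featurize a whole corpus: list over captions of lists over tokens of
# active-feature string vectors.
featurize_corpus <- function(corpus, config,
                             providers = default_providers(),
                             dictionaries = NULL) {
  if (is.null(dictionaries) && length(config$dictionaries))
    dictionaries <- bundled_dictionaries(config$dictionaries)
  lapply(corpus, function(cp)
    featurize_flat(cp$tokens$text, config, providers, dictionaries))
}
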