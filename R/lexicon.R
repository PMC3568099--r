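#' Lexicon providers
#'
#' A lexicon provider supplies per-token lemma and part-of-speech lookups
#' behind a uniform contract: a list with vectorized functions
#' `lemma(texts)` and `pos(texts)`, each returning a character vector with
#' `NA` for tokens the provider has no entry for. Lookups are deterministic.
#' Two providers ship with the package:
#'
#' * [nlp_provider()] — a rule-based shallow-NLP stand-in: a suffix-stripping
#'   lemmatizer and a heuristic tagger over a fine-grained Penn-style tagset
#'   (`NN`, `NNS`, `NNP`, `VBG`, `VBN`, `JJ`, `CD`, ...). It is total: it
#'   always returns a value.
#' * [lexicon_provider()] — a table lookup against a bundled synthetic
#'   general-English lexicon with a coarse tagset (`noun`, `verb`, `adj`,
#'   ...). Its coverage is intentionally partial; missing words return `NA`,
#'   which the feature extractor renders as the `"@"` sentinel.
#'
#' @name lexicon_providers
NULL

#' @rdname lexicon_providers
#' @return A provider list with elements `name`, `lemma`, `pos`.
#' @export
nlp_provider <- function() {
  lemma <- function(texts) {
    out <- tolower(texts)
    # plural / 3rd-person -s, -es, -ies
    out <- sub("(?<=[a-z])ies$", "y", out, perl = TRUE)
    out <- sub("(?<=[sxz])es$|(?<=[cs]h)es$", "", out, perl = TRUE)
    out <- sub("(?<=[a-z])s$(?<!ss$)", "", out, perl = TRUE)
    # -ing / -ed with doubled-consonant collapse ("flattening" -> "flatten")
    out <- sub("(?<=([b-df-hj-np-tv-z]))\\1ing$", "\\1", out, perl = TRUE)
    out <- sub("(?<=[a-z]{3})ing$", "", out, perl = TRUE)
    out <- sub("(?<=([b-df-hj-np-tv-z]))\\1ed$", "\\1", out, perl = TRUE)
    out <- sub("(?<=[a-z]{3})ed$", "", out, perl = TRUE)
    out
  }
  pos <- function(texts) {
    lt <- tolower(texts)
    out <- rep("NN", length(texts))
    out[grepl("^[[:punct:]]+$", texts)] <- "PUNCT"
    out[grepl("^[0-9]+([.,][0-9]+)?$", texts)] <- "CD"
    out[grepl("^[0-9]+(st|nd|rd|th)$", lt)] <- "JJ"
    out[lt %in% c("the", "a", "an", "this", "that", "these", "those",
                  "no", "all", "both", "each", "some")] <- "DT"
    out[lt %in% c("and", "or", "but", "nor", "either", "neither")] <- "CC"
    out[lt %in% c("of", "in", "on", "at", "to", "with", "without", "from",
                  "by", "into", "between", "through", "during", "under",
                  "over", "above", "below", "near", "per", "within",
                  "along", "across", "toward", "towards")] <- "IN"
    out[lt %in% c("is", "are", "was", "were", "be", "been", "has", "have",
                  "had")] <- "VB"
    verbish <- out == "NN"
    out[verbish & grepl("(ate|ise|ize|fy)s?$", lt)] <- "VBZ"
    out[out == "NN" & grepl("ing$", lt) & nchar(lt) > 4] <- "VBG"
    out[out == "NN" & grepl("ed$", lt) & nchar(lt) > 3] <- "VBN"
    out[out == "NN" & grepl("ly$", lt) & nchar(lt) > 3] <- "RB"
    out[out == "NN" & grepl("(ous|ic|al|ar|ive|able|ible|ile|oid)$", lt)] <- "JJ"
    out[out == "NN" & grepl("-", texts, fixed = TRUE)] <- "JJ"
    plural <- out == "NN" & grepl("(?<!s)s$", lt, perl = TRUE)
    out[plural] <- "NNS"
    out[out == "NN" & grepl("^[A-Z]", texts) ] <- "NNP"
    out
  }
  list(name = "nlp", lemma = lemma, pos = pos)
}

#' @rdname lexicon_providers
#' @param path Optional path to a lexicon TSV (`word<TAB>lemma<TAB>pos`,
#'   `#` comments ignored); defaults to the bundled synthetic excerpt.
#' @export
lexicon_provider <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lexicon",
                        "english_lexicon_synthetic.tsv",
                        package = "phenochunk", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed lexicon file: expected word<TAB>lemma<TAB>pos")
  tab <- data.frame(word = vapply(parts, `[[`, "", 1L),
                    lemma = vapply(parts, `[[`, "", 2L),
                    pos = vapply(parts, `[[`, "", 3L),
                    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab$word), , drop = FALSE]
  lookup <- function(col) {
    force(col)
    function(texts) tab[[col]][match(tolower(texts), tab$word)]
  }
  list(name = "lexicon", lemma = lookup("lemma"), pos = lookup("pos"))
}
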