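#' Construct a caption
#'
#' A caption is the basic annotated unit: a free-text figure caption, its
#' tokenization, and the gold phenotype-description spans over the tokens.
#' Token and span intervals are 0-based and half-open throughout the package.
#'
#' @param id Unique caption identifier (character scalar).
#' @param text Raw caption text (UTF-8 character scalar).
#' @param spans Gold spans: a data frame with integer columns `start` and
#'   `end` (0-based, half-open token indices), or `NULL` for no spans.
#' @param tokens Optional pre-computed tokenization as returned by
#'   [tokenize()]; computed from `text` when omitted.
#' @return An object of class `caption`: a list with elements `id`, `text`,
#'   `tokens` (data frame `text`, `start`, `end` in characters) and `spans`
#'   (data frame `start`, `end` in tokens, sorted, non-overlapping).
#' @export
caption <- function(id, text, spans = NULL, tokens = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(text), length(text) == 1L)
  if (is.null(tokens)) tokens <- tokenize(text)
  spans <- normalize_spans(spans, nrow(tokens))
  structure(list(id = id, text = text, tokens = tokens, spans = spans),
            class = "caption")
}

normalize_spans <- function(spans, n_tokens) {
  if (is.null(spans) || (is.data.frame(spans) && nrow(spans) == 0L)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  stopifnot(is.data.frame(spans), all(c("start", "end") %in% names(spans)))
  spans <- data.frame(start = as.integer(spans$start),
                      end   = as.integer(spans$end))
  if (any(spans$start >= spans$end))
    stop("invalid span: start must be < end (half-open token interval)")
  if (any(spans$start < 0L) || any(spans$end > n_tokens))
    stop("span token indices out of range for caption with ", n_tokens,
         " tokens")
  spans <- spans[order(spans$start), , drop = FALSE]
  rownames(spans) <- NULL
  if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)]))
    stop("gold spans overlap")
  spans
}

#' Construct a corpus
#'
#' @param captions List of [caption()] objects with unique ids.
#' @param provenance Free-text metadata recorded with the corpus.
#' @return An object of class `pheno_corpus` (a list of captions with a
#'   `provenance` attribute).
#' @export
pheno_corpus <- function(captions, provenance = "") {
  stopifnot(is.list(captions),
            all(vapply(captions, inherits, logical(1), "caption")))
  ids <- vapply(captions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("caption ids are not unique")
  names(captions) <- ids
  structure(captions, class = "pheno_corpus", provenance = provenance)
}

#' @export
print.pheno_corpus <- function(x, ...) {
  st <- corpus_stats(x)
  cat(sprintf("<pheno_corpus> %d captions, %d tokens, %d phenotype spans\n",
              st$n_captions, st$n_tokens, st$n_spans))
  invisible(x)
}

#' @export
print.caption <- function(x, ...) {
  cat(sprintf("<caption %s> %d tokens, %d spans: %s\n",
              x$id, nrow(x$tokens), nrow(x$spans),
              substr(x$text, 1, 60)))
  invisible(x)
}

#' Tokenize caption text
#'
#' Splits text into word and punctuation tokens with character offsets.
#' Alphanumeric runs form tokens; hyphens internal to a word stay attached
#' ("bell-shaped" is one token); every other non-space character becomes a
#' token of its own. Offsets are 0-based half-open, so
#' `substr(text, start + 1, end)` recovers each token.
#'
#' @param text Character scalar (may be empty).
#' @return Data frame with columns `text`, `start`, `end`; zero rows for
#'   empty or all-whitespace input.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) {
    return(data.frame(text = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*|[^[:space:]]", text,
                perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(text = substring(text, start + 1L, start + len),
             start = start, end = start + as.integer(len),
             stringsAsFactors = FALSE)
}

#' Convert gold spans to a BIO label sequence
#'
#' @param x A [caption()].
#' @return Character vector over `{"B","I","O"}`, one label per token: `B`
#'   on the first token of each span, `I` inside, `O` elsewhere.
#' @export
spans_to_bio <- function(x) {
  stopifnot(inherits(x, "caption"))
  n <- nrow(x$tokens)
  labels <- rep("O", n)
  sp <- x$spans
  if (nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      labels[sp$start[i] + 1L] <- "B"
      if (sp$end[i] - sp$start[i] > 1L)
        labels[(sp$start[i] + 2L):sp$end[i]] <- "I"
    }
  }
  labels
}

#' Decode a BIO label sequence into spans
#'
#' Maximal `B I*` runs become spans. An `I` with no preceding `B` or `I`
#' (sequence-initial or after `O`) is repaired to `B` first — classifier or
#' voting output can be structurally invalid and must still be decodable.
#'
#' @param labels Character vector over `{"B","I","O"}`.
#' @return Data frame of spans (`start`, `end`, 0-based half-open token
#'   indices), sorted and non-overlapping.
#' @export
bio_to_spans <- function(labels) {
  labels <- repair_bio(labels)
  n <- length(labels)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (labels[i] == "B") {
      j <- i + 1L
      while (j <= n && labels[j] == "I") j <- j + 1L
      starts <- c(starts, i - 1L); ends <- c(ends, j - 1L)
      i <- j
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

#' Repair a structurally invalid BIO sequence
#'
#' Rewrites any `I` that does not continue a span (sequence-initial, or
#' following `O`) to `B`. Idempotent; the result always decodes cleanly.
#'
#' @param labels Character vector over `{"B","I","O"}`.
#' @return Repaired label vector of the same length.
#' @export
repair_bio <- function(labels) {
  if (!length(labels)) return(character(0))
  if (!all(labels %in% c("B", "I", "O")))
    stop("unknown BIO label: ",
         paste(unique(setdiff(labels, c("B", "I", "O"))), collapse = ", "))
  bad <- labels == "I" & c("O", labels[-length(labels)]) == "O"
  labels[bad] <- "B"
  labels
}

#' Corpus summary statistics
#'
#' Counts and means describing a corpus: captions, tokens, phenotype spans,
#' tokens per caption, spans per caption, tokens per span, and the span
#' length range.
#'
#' @param corpus A [pheno_corpus()].
#' @return A list of class `corpus_stats`. Means over spans are `NA` (with a
#'   warning) when the corpus holds no spans; all means are `NA` for an
#'   empty corpus.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "pheno_corpus"))
  n_cap <- length(corpus)
  tok <- vapply(corpus, function(cp) nrow(cp$tokens), integer(1))
  nsp <- vapply(corpus, function(cp) nrow(cp$spans), integer(1))
  span_len <- unlist(lapply(corpus, function(cp) cp$spans$end - cp$spans$start),
                     use.names = FALSE)
  if (n_cap == 0L) warning("empty corpus: means are undefined")
  else if (sum(nsp) == 0L) warning("corpus has no spans: span means are undefined")
  structure(list(
    n_captions = n_cap,
    n_tokens = sum(tok),
    n_spans = sum(nsp),
    mean_tokens_per_caption = if (n_cap) mean(tok) else NA_real_,
    mean_spans_per_caption = if (n_cap) mean(nsp) else NA_real_,
    mean_tokens_per_span = if (length(span_len)) mean(span_len) else NA_real_,
    min_span_len = if (length(span_len)) min(span_len) else NA_integer_,
    max_span_len = if (length(span_len)) max(span_len) else NA_integer_
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, digits = 2, ...) {
  cat("Corpus statistics\n")
  cat(sprintf("  captions: %d   tokens: %d   phenotype spans: %d\n",
              x$n_captions, x$n_tokens, x$n_spans))
  cat(sprintf("  tokens/caption: %.*f   spans/caption: %.*f\n",
              digits, x$mean_tokens_per_caption,
              digits, x$mean_spans_per_caption))
  cat(sprintf("  tokens/span: %.*f   span length range: [%s, %s]\n",
              digits, x$mean_tokens_per_span,
              x$min_span_len, x$max_span_len))
  invisible(x)
}
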