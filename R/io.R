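#' Write a corpus in CoNLL two-column format
#'
#' One `token<TAB>label` line per token (labels from the BIO scheme), blank
#' line between captions. Character offsets are not stored; on re-reading,
#' text is reconstructed by joining tokens with single spaces.
#'
#' @param corpus A [pheno_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  stopifnot(inherits(corpus, "pheno_corpus"))
  blocks <- vapply(corpus, function(cp) {
    paste(paste(cp$tokens$text, spans_to_bio(cp), sep = "\t"),
          collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")  # fixed newlines for byte-identical output
  on.exit(close(con))
  writeLines(paste(blocks, collapse = "\n\n"), con = con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from CoNLL two-column format
#'
#' @param path Input file; UTF-8, `token<TAB>label` lines with labels in
#'   `{B,I,O}`, blank line between captions.
#' @param id_prefix Captions are assigned ids `<id_prefix><k>` in file order.
#' @return A [pheno_corpus()].
#' @export
read_conll <- function(path, id_prefix = "c") {
  lines <- readLines(path, encoding = "UTF-8")
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)])) # block index per line
  captions <- list()
  k <- 0L
  for (g in split(seq_along(lines), grp)) {
    g <- g[!blank[g]]
    if (!length(g)) next
    parts <- strsplit(lines[g], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop("malformed CoNLL line ", g[bad[1]], ": expected 2 tab-separated ",
           "columns, got ", lengths(parts)[bad[1]])
    toks <- vapply(parts, `[[`, character(1), 1L)
    labels <- vapply(parts, `[[`, character(1), 2L)
    if (!all(labels %in% c("B", "I", "O")))
      stop("unknown label '", setdiff(labels, c("B", "I", "O"))[1],
           "' at line ", g[which(!labels %in% c("B", "I", "O"))[1]])
    k <- k + 1L
    text <- paste(toks, collapse = " ")
    ends <- cumsum(nchar(toks) + 1L) - 1L
    tokens <- data.frame(text = toks, start = ends - nchar(toks),
                         end = ends, stringsAsFactors = FALSE)
    captions[[k]] <- caption(paste0(id_prefix, k), text,
                             spans = bio_to_spans(labels), tokens = tokens)
  }
  pheno_corpus(captions, provenance = paste("read_conll:", path))
}

#' Write a corpus as stand-off JSON
#'
#' Format: `{"captions":[{"id","text","spans":[{"start","end"}]}]}` with
#' character offsets, 0-based half-open, over the raw caption text.
#'
#' @param corpus A [pheno_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(corpus, path) {
  stopifnot(inherits(corpus, "pheno_corpus"))
  caps <- lapply(unname(corpus), function(cp) {
    sp <- cp$spans
    spans <- lapply(seq_len(nrow(sp)), function(i) {
      list(start = cp$tokens$start[sp$start[i] + 1L],
           end = cp$tokens$end[sp$end[i]])
    })
    list(id = cp$id, text = cp$text, spans = spans)
  })
  jsonlite::write_json(list(captions = caps), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a corpus from stand-off JSON
#'
#' Character-offset spans are mapped to token intervals. A span whose
#' boundaries fall inside tokens is snapped outward to the smallest covering
#' token interval, with a warning.
#'
#' @param path Input JSON file (see [write_standoff()] for the schema).
#' @return A [pheno_corpus()].
#' @export
read_standoff <- function(path) {
  doc <- jsonlite::read_json(path)
  captions <- lapply(doc$captions, function(cap) {
    text <- cap$text
    tokens <- tokenize(text)
    nsp <- length(cap$spans)
    start <- integer(nsp); end <- integer(nsp)
    for (i in seq_len(nsp)) {
      cs <- as.integer(cap$spans[[i]]$start)
      ce <- as.integer(cap$spans[[i]]$end)
      if (cs < 0L || ce > nchar(text) || cs >= ce)
        stop("caption ", cap$id, ": character span [", cs, ",", ce,
             ") outside text of length ", nchar(text))
      ts <- which(tokens$end > cs)[1]
      te <- max(which(tokens$start < ce))
      if (is.na(ts) || !is.finite(te) || ts > te)
        stop("caption ", cap$id, ": span [", cs, ",", ce,
             ") covers no token")
      if (tokens$start[ts] != cs || tokens$end[te] != ce)
        warning("caption ", cap$id, ": span [", cs, ",", ce,
                ") not aligned to token boundaries; snapped outward",
                call. = FALSE)
      start[i] <- ts - 1L; end[i] <- te
    }
    caption(cap$id, text, spans = data.frame(start = start, end = end),
            tokens = tokens)
  })
  pheno_corpus(captions, provenance = paste("read_standoff:", path))
}
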