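#' Span sets
#'
#' A span set treats a system's predictions over a corpus as a set of exact
#' `(caption_id, start, end)` triples — the representation the set-algebra
#' aggregation operates on. Overlapping but unequal spans are distinct
#' members.
#'
#' @param caption_id Character vector of caption ids.
#' @param start,end Integer vectors of 0-based half-open token indices.
#' @return An object of class `span_set` (a de-duplicated data frame with
#'   columns `caption_id`, `start`, `end`).
#' @export
span_set <- function(caption_id = character(0), start = integer(0),
                     end = integer(0)) {
  df <- data.frame(caption_id = as.character(caption_id),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start >= df$end))
    stop("invalid span: start must be < end")
  df <- unique(df)
  df <- df[order(df$caption_id, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("span_set", "data.frame")
  df
}

span_keys <- function(s) paste(s$caption_id, s$start, s$end, sep = "\r")

#' @rdname span_set
#' @param spans_by_caption Named list (caption id -> span data frame with
#'   `start`/`end`), e.g. per-caption [predict_spans()] output.
#' @export
spans_to_set <- function(spans_by_caption) {
  n <- vapply(spans_by_caption, nrow, integer(1))
  span_set(rep.int(names(spans_by_caption), n),
           unlist(lapply(spans_by_caption, `[[`, "start"), use.names = FALSE),
           unlist(lapply(spans_by_caption, `[[`, "end"), use.names = FALSE))
}

#' @rdname span_set
#' @param corpus A [pheno_corpus()]; its gold spans become the set.
#' @export
gold_span_set <- function(corpus) {
  stopifnot(inherits(corpus, "pheno_corpus"))
  spans_to_set(lapply(corpus, `[[`, "spans"))
}

#' Set algebra over predictions
#'
#' `span_union` keeps every span found by either system (the "maintain
#' everything" operator, raising recall); `span_intersection` keeps only
#' spans identical in both (raising precision). Membership is by exact
#' triple identity.
#'
#' @param a,b `span_set` objects.
#' @return A `span_set`.
#' @export
span_union <- function(a, b) {
  stopifnot(inherits(a, "span_set"), inherits(b, "span_set"))
  span_set(c(a$caption_id, b$caption_id), c(a$start, b$start),
           c(a$end, b$end))
}

#' @rdname span_union
#' @export
span_intersection <- function(a, b) {
  stopifnot(inherits(a, "span_set"), inherits(b, "span_set"))
  keep <- span_keys(a) %in% span_keys(b)
  span_set(a$caption_id[keep], a$start[keep], a$end[keep])
}

#' Evaluate an ensemble set expression
#'
#' Expressions are nested lists over classifier identifiers with operators
#' `"union"` and `"intersect"`, e.g.
#' `list("intersect", list("union", "crf_a", "svm_ova"),
#'       list("union", "crf_b", "svm_ovo"))`.
#' A bare character identifier is a leaf referencing `predictions`.
#'
#' @param expr Expression tree (nested list / character leaf).
#' @param predictions Named list of `span_set` objects, one per classifier.
#' @return The resulting `span_set`.
#' @export
evaluate_expr <- function(expr, predictions) {
  if (is.character(expr) && length(expr) == 1L) {
    out <- predictions[[expr]]
    if (is.null(out)) stop("no predictions for classifier '", expr, "'")
    return(out)
  }
  if (!is.list(expr) || length(expr) < 3L)
    stop("malformed ensemble expression")
  op <- expr[[1]]
  args <- lapply(expr[-1], evaluate_expr, predictions = predictions)
  out <- args[[1]]
  for (k in seq_along(args)[-1]) {
    out <- switch(op,
                  union = span_union(out, args[[k]]),
                  intersect = ,
                  intersection = span_intersection(out, args[[k]]),
                  stop("unknown set operator '", op, "'"))
  }
  out
}

#' Configure majority voting with veto
#'
#' @param voters Ordered classifier ids (the four ensemble members).
#' @param veto_owner The voter whose label wins on a tie or when no label
#'   reaches the threshold. Defaults to the first voter.
#' @param threshold Winning fraction of votes, in (0, 1]; default 0.5
#'   ("50% or more votes").
#' @return An object of class `vote_config`.
#' @export
vote_config <- function(voters = BACKENDS, veto_owner = voters[1],
                        threshold = 0.5) {
  voters <- as.character(voters)
  if (!veto_owner %in% voters) stop("veto_owner must be one of the voters")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  structure(list(voters = voters, veto_owner = veto_owner,
                 threshold = threshold), class = "vote_config")
}

#' Token-level majority voting with veto
#'
#' For each token, the label with the strictly highest vote count wins,
#' provided it reaches the threshold (`ceiling(threshold * n_voters)`
#' votes). When two labels tie at the top, or no label reaches the
#' threshold, the veto owner's label wins — even if the veto owner voted a
#' third label. The voted sequence is passed through [repair_bio()] so it
#' always decodes.
#'
#' @param label_seqs Named list of aligned BIO label sequences, one per
#'   voter in `config$voters`.
#' @param config A [vote_config()].
#' @return A repaired BIO label sequence.
#' @export
majority_vote_veto <- function(label_seqs, config = vote_config()) {
  stopifnot(inherits(config, "vote_config"))
  missing <- setdiff(config$voters, names(label_seqs))
  if (length(missing))
    stop("missing label sequences for voter(s): ",
         paste(missing, collapse = ", "))
  seqs <- label_seqs[config$voters]
  n <- unique(lengths(seqs))
  if (length(n) != 1L) stop("voter label sequences differ in length")
  if (n == 0L) return(character(0))
  for (s in seqs) if (!all(s %in% BIO_LABELS))
    stop("labels must be drawn from {B, I, O}")
  nv <- length(config$voters)
  need <- ceiling(config$threshold * nv)
  veto <- seqs[[config$veto_owner]]
  m <- matrix(unlist(seqs, use.names = FALSE), ncol = nv)
  out <- character(n)
  for (i in seq_len(n)) {
    counts <- c(B = sum(m[i, ] == "B"), I = sum(m[i, ] == "I"),
                O = sum(m[i, ] == "O"))
    top <- max(counts)
    winners <- names(counts)[counts == top]
    out[i] <- if (top >= need && length(winners) == 1L) winners else veto[i]
  }
  repair_bio(out)
}
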