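# run code under a temporary RNG state so package functions never disturb
# the caller's random stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Match predicted against gold spans in one caption
#'
#' The default criterion is exact boundary identity: a predicted span
#' counts as a true positive only if its `(start, end)` equals a gold
#' span's. A partial-overlap criterion (any token shared, each span matched
#' at most once) is available for diagnostics.
#'
#' @param gold,pred Span data frames (`start`, `end`) for one caption.
#' @param criterion `"exact"` (default) or `"overlap"`.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
match_spans <- function(gold, pred, criterion = c("exact", "overlap")) {
  criterion <- match.arg(criterion)
  ng <- nrow(gold); np <- nrow(pred)
  if (criterion == "exact") {
    tp <- sum(paste(pred$start, pred$end) %in% paste(gold$start, gold$end))
  } else {
    used <- rep(FALSE, ng)
    tp <- 0L
    for (i in seq_len(np)) {
      hit <- which(!used & gold$start < pred$end[i] & pred$start[i] < gold$end)
      if (length(hit)) { used[hit[1]] <- TRUE; tp <- tp + 1L }
    }
  }
  c(tp = as.integer(tp), fp = as.integer(np - tp), fn = as.integer(ng - tp))
}

#' Precision, recall and F1 from match counts
#'
#' @param tp,fp,fn Non-negative counts.
#' @return An object of class `eval_metrics`: list with `precision`,
#'   `recall`, `f1` (fractions in `[0,1]`), the counts, and `degenerate`
#'   (`TRUE` when a zero denominator forced a metric to 0).
#' @export
prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  degenerate <- FALSE
  p <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  f <- if (p + r > 0) 2 * p * r / (p + r) else { degenerate <- TRUE; 0 }
  structure(list(precision = p, recall = r, f1 = f,
                 tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), degenerate = degenerate),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("P %.2f%%  R %.2f%%  F1 %.2f%%  (tp %d, fp %d, fn %d)%s\n",
              100 * x$precision, 100 * x$recall, 100 * x$f1,
              x$tp, x$fp, x$fn,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Captions are binned by gold-span count (0, 1–2, 3–5, 6+), shuffled
#' within each bin under the seed, and dealt round-robin across the `k`
#' folds (the deal continues across bins, so fold sizes differ by at most
#' one and every bin is spread evenly).
#'
#' @param corpus A [pheno_corpus()].
#' @param k Number of folds (default 10).
#' @param seed Shuffling seed.
#' @return Object of class `fold_assignment`: list with `k`, `seed` and
#'   `assignment` (named integer vector, caption id -> fold in 1..k).
#' @export
stratified_folds <- function(corpus, k = 10L, seed = 1L) {
  stopifnot(inherits(corpus, "pheno_corpus"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > length(corpus))
    stop("k = ", k, " exceeds the number of captions (", length(corpus), ")")
  nsp <- vapply(corpus, function(cp) nrow(cp$spans), integer(1))
  bin <- cut(nsp, breaks = c(-1, 0, 2, 5, Inf),
             labels = c("0", "1-2", "3-5", "6+"))
  ids <- names(corpus)
  ordered <- with_seed(seed, {
    unlist(lapply(levels(bin), function(b) {
      members <- ids[bin == b]
      if (length(members) > 1L) sample(members) else members
    }), use.names = FALSE)
  })
  assignment <- stats::setNames(((seq_along(ordered) - 1L) %% k) + 1L,
                                ordered)[ids]
  structure(list(k = k, seed = as.integer(seed),
                 assignment = assignment, strata = stats::setNames(bin, ids)),
            class = "fold_assignment")
}

# ---- shared cross-validation machinery --------------------------------

# internal: fit a backend on pre-featurized data (flat feature lists +
# 0-based integer labels), skipping re-featurization
train_encoded <- function(spec, flat, y) {
  vocab <- unique(unlist(flat, use.names = FALSE))
  enc <- encode_feats(flat, vocab)
  hp <- spec$hyperparams
  if (startsWith(spec$backend, "crf")) {
    n_par <- 3L * length(vocab) + 12L
    cache <- new.env(parent = emptyenv())
    fn <- function(p) {
      r <- crf_nll_grad(p, enc$feats, enc$tok_ptr, enc$seq_ptr, y,
                        length(vocab), hp$C)
      cache$p <- p; cache$g <- r$grad
      r$value
    }
    gr <- function(p) {
      if (!identical(p, cache$p)) fn(p)
      cache$g
    }
    fit <- stats::optim(numeric(n_par), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = hp$maxit, factr = 1e8))
    model <- list(par = fit$par)
  } else {
    model <- svm_train_cpp(enc$feats, enc$tok_ptr, enc$seq_ptr, y,
                           length(vocab),
                           scheme = if (spec$backend == "svm_ovo") 0L else 1L,
                           poly2 = hp$kernel == "poly2",
                           C = hp$C, epochs = hp$epochs,
                           hash_dim = hp$hash_dim, seed = spec$seed)
  }
  structure(list(spec = spec, vocab = vocab, model = model),
            class = "trained_chunker")
}

#' Held-out predictions for every fold and chunker
#'
#' Runs the expensive part of cross-validation once: for each fold, each
#' chunker is trained on the other `k - 1` folds and predicts BIO labels on
#' the held-out captions. The result can then be scored for any individual
#' chunker, set expression or voting configuration with [score_cv()]
#' without retraining. Captions are featurized once per distinct feature
#' configuration.
#'
#' @param corpus A [pheno_corpus()].
#' @param specs Named list of [chunker_spec()]s (names are the classifier
#'   ids used by ensemble expressions and vote configs).
#' @param k,seed Fold count and stratification seed (see
#'   [stratified_folds()]).
#' @param folds Optional pre-computed [stratified_folds()] assignment.
#' @return Object of class `cv_predictions`.
#' @export
cv_predictions <- function(corpus, specs, k = 10L, seed = 1L, folds = NULL) {
  stopifnot(inherits(corpus, "pheno_corpus"), is.list(specs),
            length(specs) >= 1L, !is.null(names(specs)))
  if (is.null(folds)) folds <- stratified_folds(corpus, k, seed)
  stopifnot(inherits(folds, "fold_assignment"))
  ids <- names(corpus)

  cfg_keys <- vapply(specs, function(s)
    paste(deparse(s$feature_config), collapse = ""), character(1))
  flat_by_cfg <- list()
  for (u in unique(cfg_keys)) {
    spec_u <- specs[[which(cfg_keys == u)[1]]]
    flat_by_cfg[[u]] <- featurize_corpus(corpus, spec_u$feature_config)
  }
  gold_bio <- lapply(corpus, spans_to_bio)
  y_all <- lapply(gold_bio, function(l) match(l, BIO_LABELS) - 1L)

  fold_labels <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test_ids <- ids[folds$assignment == f]
    train_ids <- ids[folds$assignment != f]
    fold_labels[[f]] <- lapply(specs, function(spec) {
      key <- paste(deparse(spec$feature_config), collapse = "")
      flat <- flat_by_cfg[[key]]
      model <- train_encoded(spec, flat[train_ids],
                             unlist(y_all[train_ids], use.names = FALSE))
      test_flat <- flat[test_ids]
      enc <- encode_feats(test_flat, model$vocab)
      yhat <- BIO_LABELS[decode_encoded(model, enc) + 1L]
      n_tok <- vapply(test_flat, length, integer(1))
      out <- rep(list(character(0)), length(test_ids))
      names(out) <- test_ids
      if (length(yhat)) {
        filled <- split(yhat, rep.int(seq_along(n_tok), n_tok))
        out[as.integer(names(filled))] <- filled
      }
      out
    })
  }
  structure(list(folds = folds,
                 classifiers = names(specs),
                 labels = fold_labels,
                 gold = lapply(corpus, `[[`, "spans")),
            class = "cv_predictions")
}

#' Score cross-validated predictions for a system
#'
#' @param cvp A [cv_predictions()] result.
#' @param system One of: a classifier id (character scalar) naming a single
#'   chunker; an ensemble set expression (see [evaluate_expr()]); or a
#'   [vote_config()].
#' @param criterion Span-matching criterion, see [match_spans()].
#' @return Object of class `cv_result`: `per_fold` data frame (fold, tp,
#'   fp, fn, precision, recall, f1) and `mean` (arithmetic mean of the
#'   per-fold metrics).
#' @export
score_cv <- function(cvp, system, criterion = "exact") {
  stopifnot(inherits(cvp, "cv_predictions"))
  k <- cvp$folds$k
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    lab <- cvp$labels[[f]]
    test_ids <- names(lab[[1]])
    pred_spans <- if (inherits(system, "vote_config")) {
      stats::setNames(lapply(test_ids, function(id) {
        bio_to_spans(majority_vote_veto(lapply(lab, `[[`, id), system))
      }), test_ids)
    } else if (is.character(system) || is.list(system)) {
      sets <- lapply(lab, function(per_cap) spans_to_set(
        lapply(per_cap, bio_to_spans)))
      s <- evaluate_expr(system, sets)
      stats::setNames(lapply(test_ids, function(id) {
        sub <- s[s$caption_id == id, c("start", "end"), drop = FALSE]
        rownames(sub) <- NULL
        sub
      }), test_ids)
    } else stop("unsupported system definition")
    counts <- rowSums(vapply(test_ids, function(id)
      match_spans(cvp$gold[[id]], pred_spans[[id]], criterion),
      integer(3)))
    m <- prf(counts["tp"], counts["fp"], counts["fn"])
    rows[[f]] <- data.frame(fold = f, tp = m$tp, fp = m$fp, fn = m$fn,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(system = system_label(system),
                 per_fold = per_fold,
                 mean = list(precision = mean(per_fold$precision),
                             recall = mean(per_fold$recall),
                             f1 = mean(per_fold$f1))),
            class = "cv_result")
}

system_label <- function(system) {
  if (inherits(system, "vote_config"))
    return(paste0("vote[veto=", system$veto_owner, "]"))
  if (is.character(system)) return(system)
  op <- switch(system[[1]], union = " ∪ ", " ∩ ")
  paste0("(", paste(vapply(system[-1], system_label, character(1)),
                    collapse = op), ")")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s  (%d folds)\n", x$system, nrow(x$per_fold)))
  cat(sprintf("  mean P %.2f%%  R %.2f%%  F1 %.2f%%\n",
              100 * x$mean$precision, 100 * x$mean$recall, 100 * x$mean$f1))
  invisible(x)
}

#' Stratified k-fold cross-validation of a chunking system
#'
#' Convenience wrapper around [cv_predictions()] + [score_cv()]: for each
#' fold, every needed chunker is trained on the remaining folds, the system
#' (single chunker, set expression or voting ensemble) predicts on the
#' held-out captions, and entity-level exact-match metrics are computed;
#' the reported metrics are the arithmetic mean across folds.
#'
#' @param corpus A [pheno_corpus()].
#' @param system Either a single [chunker_spec()], or a list
#'   `list(chunkers = <named list of specs>, combine = <expression or
#'   vote_config>)` (omit `combine` to score the single named chunker).
#' @param k,seed Fold count and stratification seed.
#' @param criterion Span-matching criterion, see [match_spans()].
#' @return A `cv_result`.
#' @export
cross_validate <- function(corpus, system, k = 10L, seed = 1L,
                           criterion = "exact") {
  if (inherits(system, "chunker_spec")) {
    specs <- stats::setNames(list(system), system$backend)
    combine <- system$backend
  } else {
    stopifnot(is.list(system), !is.null(system$chunkers))
    specs <- system$chunkers
    combine <- system$combine
    if (is.null(combine)) {
      if (length(specs) != 1L)
        stop("combine must be given when multiple chunkers are defined")
      combine <- names(specs)[1]
    }
  }
  cvp <- cv_predictions(corpus, specs, k = k, seed = seed)
  score_cv(cvp, combine, criterion = criterion)
}

# ---- ablation protocols ----------------------------------------------

# decompose a spec's feature configuration into ablation units
ablation_units <- function(spec) {
  fc <- spec$feature_config
  units <- list()
  for (f in fc$enabled) units[[f]] <- list(kind = "atomic", value = f)
  for (cs in fc$context_specs)
    units[[paste0("token_", context_label(cs))]] <-
      list(kind = "context", value = cs)
  gen <- intersect(fc$dictionaries, GENERIC_DICTS)
  dom <- intersect(fc$dictionaries, DOMAIN_DICTS)
  other <- setdiff(fc$dictionaries, c(GENERIC_DICTS, DOMAIN_DICTS))
  if (length(gen)) units$dict_generic <- list(kind = "dicts", value = gen)
  if (length(dom)) units$dict_domain <- list(kind = "dicts", value = dom)
  for (d in other)
    units[[paste0("dict_", d)]] <- list(kind = "dicts", value = d)
  units
}

unit_spec <- function(spec, unit, mode) {
  fc <- spec$feature_config
  if (mode == "only") {
    enabled <- character(0); ctx <- list(); dicts <- character(0)
  } else {
    enabled <- fc$enabled; ctx <- fc$context_specs; dicts <- fc$dictionaries
  }
  if (unit$kind == "atomic") {
    enabled <- if (mode == "only") unit$value else setdiff(enabled, unit$value)
  } else if (unit$kind == "context") {
    if (mode == "only") ctx <- list(unit$value)
    else ctx <- Filter(function(cs)
      context_label(cs) != context_label(unit$value), ctx)
  } else {
    dicts <- if (mode == "only") unit$value else setdiff(dicts, unit$value)
  }
  chunker_spec(spec$backend,
               feature_config(enabled = enabled, affix_n = fc$affix_n,
                              context_specs = ctx, dictionaries = dicts),
               hyperparams = spec$hyperparams, seed = spec$seed)
}

run_ablation <- function(base, corpus, k, seed, mode) {
  stopifnot(inherits(base, "chunker_spec"))
  units <- ablation_units(base)
  if (length(units) < 2L)
    stop("ablation requires a base configuration with at least 2 features")
  rows <- lapply(names(units), function(un) {
    cross_validate(corpus, unit_spec(base, units[[un]], mode),
                   k = k, seed = seed)
  })
  names(rows) <- names(units)
  structure(list(mode = if (mode == "only") "single_feature"
                 else "leave_one_out",
                 backend = base$backend, rows = rows),
            class = "ablation_report")
}

#' Feature ablation protocols
#'
#' `ablate_single` retrains the chunker with each feature unit of the base
#' configuration enabled on its own; `ablate_leave_one_out` retrains with
#' each unit removed from the base configuration. Units are the individual
#' simple/morphological features, each token-context specification, the
#' generic dictionaries as a group, the domain dictionaries as a group, and
#' any other dictionary individually.
#'
#' @param base A [chunker_spec()] whose configuration defines the units.
#' @param corpus A [pheno_corpus()].
#' @param k,seed Cross-validation parameters.
#' @return An `ablation_report`: `mode` and named `rows` of `cv_result`s.
#' @export
ablate_single <- function(base, corpus, k = 10L, seed = 1L)
  run_ablation(base, corpus, k, seed, "only")

#' @rdname ablate_single
#' @export
ablate_leave_one_out <- function(base, corpus, k = 10L, seed = 1L)
  run_ablation(base, corpus, k, seed, "remove")

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("<ablation_report> %s, backend %s\n", x$mode, x$backend))
  print(ablation_table(x), row.names = FALSE)
  invisible(x)
}

#' @rdname ablate_single
#' @param report An `ablation_report`.
#' @return `ablation_table`: data frame (feature, precision, recall, f1 as
#'   percentages) sorted by F1.
#' @export
ablation_table <- function(report) {
  stopifnot(inherits(report, "ablation_report"))
  df <- data.frame(
    feature = names(report$rows),
    precision = 100 * vapply(report$rows, function(r) r$mean$precision, 0),
    recall = 100 * vapply(report$rows, function(r) r$mean$recall, 0),
    f1 = 100 * vapply(report$rows, function(r) r$mean$f1, 0),
    row.names = NULL)
  df[order(-df$f1), ]
}
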