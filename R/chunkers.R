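BACKENDS <- c("crf_a", "crf_b", "svm_ovo", "svm_ova")
BIO_LABELS <- c("B", "I", "O")

#' Specify a chunker
#'
#' A chunker spec binds a sequence-labeling backend to a feature
#' configuration and hyperparameters. Four backends are available:
#'
#' * `crf_a`, `crf_b` — linear-chain conditional random fields differing in
#'   L2 regularization (`C = 1` and `C = 3.5` respectively) and, under the
#'   presets, in feature configuration.
#' * `svm_ovo`, `svm_ova` — margin-based (SVM-style) token classifiers with
#'   a degree-2 polynomial interaction map, decoded greedily left-to-right
#'   with the previous predicted label as a feature; `svm_ovo` decomposes
#'   the three BIO classes one-vs-one, `svm_ova` one-vs-all.
#'
#' @param backend One of `"crf_a"`, `"crf_b"`, `"svm_ovo"`, `"svm_ova"`.
#' @param feature_config A [feature_config()].
#' @param hyperparams Named list overriding backend defaults. CRF: `C`
#'   (regularization constant), `maxit` (L-BFGS iterations, default 60).
#'   SVM: `kernel` (`"poly2"` default, or `"linear"` for large corpora),
#'   `C` (update aggressiveness cap, default 1), `epochs` (default 5),
#'   `hash_dim` (size of the interaction hash space, default 2^19).
#' @param seed Integer seed controlling any training-time randomness
#'   (example-order shuffling in the SVM backends; the CRF fit is
#'   deterministic regardless).
#' @return An object of class `chunker_spec`.
#' @export
chunker_spec <- function(backend, feature_config, hyperparams = list(),
                         seed = 1L) {
  backend <- match.arg(backend, BACKENDS)
  stopifnot(inherits(feature_config, "feature_config"))
  defaults <- switch(backend,
    crf_a = list(C = 1.0, maxit = 60L),
    crf_b = list(C = 3.5, maxit = 60L),
    svm_ovo = ,
    svm_ova = list(kernel = "poly2", degree = 2L, C = 1.0, epochs = 5L,
                   hash_dim = 2L^19L))
  hp <- utils::modifyList(defaults, hyperparams)
  if (startsWith(backend, "svm") && !hp$kernel %in% c("poly2", "linear"))
    stop("svm kernel must be 'poly2' or 'linear'")
  structure(list(backend = backend, feature_config = feature_config,
                 hyperparams = hp, seed = as.integer(seed)),
            class = "chunker_spec")
}

#' Preset chunker specifications
#'
#' Reproduces the best-performing per-backend feature combinations: every
#' preset enables all simple and morphological features plus the four
#' generic dictionaries; `crf_a` adds token bigrams with window 3, `crf_b`
#' adds token bigrams with window 3 and token unigrams with window 5, and
#' the two SVM backends add token unigrams with window 5.
#'
#' @param name Backend name (see [chunker_spec()]).
#' @param with_domain_dicts Also enable the domain-specific anatomy and
#'   quality gazetteers.
#' @param seed Training seed.
#' @return A [chunker_spec()].
#' @export
preset_spec <- function(name, with_domain_dicts = FALSE, seed = 1L) {
  name <- match.arg(name, BACKENDS)
  ctx <- switch(name,
    crf_a = list(context_spec("bi", 3)),
    crf_b = list(context_spec("bi", 3), context_spec("uni", 5)),
    svm_ovo = ,
    svm_ova = list(context_spec("uni", 5)))
  dicts <- GENERIC_DICTS
  if (with_domain_dicts) dicts <- c(dicts, DOMAIN_DICTS)
  fc <- feature_config(enabled = c(SIMPLE_FEATURES, MORPH_FEATURES),
                       affix_n = 5L, context_specs = ctx,
                       dictionaries = dicts)
  chunker_spec(name, fc, seed = seed)
}

#' @export
print.chunker_spec <- function(x, ...) {
  cat("<chunker_spec>", x$backend, "seed", x$seed, "\n")
  print(x$feature_config)
  invisible(x)
}

# ---- sparse encoding shared by both backends --------------------------

# flat: list over captions of list over tokens of active-feature strings.
# Returns 0-based CSR arrays; features absent from `vocab` are dropped.
encode_feats <- function(flat, vocab) {
  n_tok_per_cap <- vapply(flat, length, integer(1))
  per_tok <- unlist(lapply(flat, lengths), use.names = FALSE)
  if (is.null(per_tok)) per_tok <- integer(0)
  strings <- unlist(flat, use.names = FALSE)
  ids <- match(strings, vocab)
  keep <- !is.na(ids)
  n_tok <- length(per_tok)
  if (n_tok) {
    grp <- rep.int(seq_len(n_tok), per_tok)
    kept_counts <- tabulate(grp[keep], nbins = n_tok)
  } else kept_counts <- integer(0)
  list(feats = as.integer(ids[keep] - 1L),
       tok_ptr = as.integer(c(0L, cumsum(kept_counts))),
       seq_ptr = as.integer(c(0L, cumsum(n_tok_per_cap))))
}

#' Train a chunker
#'
#' Featurizes the corpus under the spec's [feature_config()], builds the
#' training feature vocabulary, and fits the backend. Training is
#' deterministic given the spec (including its seed) and the corpus.
#'
#' @param spec A [chunker_spec()].
#' @param corpus A [pheno_corpus()] with at least one caption containing at
#'   least one token.
#' @return An object of class `trained_chunker`.
#' @export
train_chunker <- function(spec, corpus) {
  stopifnot(inherits(spec, "chunker_spec"), inherits(corpus, "pheno_corpus"))
  if (!length(corpus)) stop("cannot train on an empty corpus")
  flat <- featurize_corpus(corpus, spec$feature_config)
  labels <- unlist(lapply(corpus, spans_to_bio), use.names = FALSE)
  if (!length(labels)) stop("corpus has no tokens")
  y <- match(labels, BIO_LABELS) - 1L
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

#' @export
print.trained_chunker <- function(x, ...) {
  cat("<trained_chunker>", x$spec$backend, "-",
      length(x$vocab), "features\n")
  invisible(x)
}

# decode an encoded batch with a trained model -> integer labels
decode_encoded <- function(model, enc) {
  hp <- model$spec$hyperparams
  if (startsWith(model$spec$backend, "crf")) {
    crf_viterbi(model$model$par, enc$feats, enc$tok_ptr, enc$seq_ptr,
                length(model$vocab))
  } else {
    svm_predict_cpp(model$model$W, model$model$pos_n, model$model$neg_n,
                    enc$feats, enc$tok_ptr, enc$seq_ptr, length(model$vocab),
                    scheme = if (model$spec$backend == "svm_ovo") 0L else 1L,
                    poly2 = hp$kernel == "poly2", hash_dim = hp$hash_dim)
  }
}

# batch prediction over a corpus: list of label sequences, one per caption
predict_corpus_labels <- function(model, corpus) {
  stopifnot(inherits(model, "trained_chunker"))
  flat <- featurize_corpus(corpus, model$spec$feature_config)
  enc <- encode_feats(flat, model$vocab)
  yhat <- BIO_LABELS[decode_encoded(model, enc) + 1L]
  n_tok <- vapply(flat, length, integer(1))
  split_at <- rep.int(seq_along(n_tok), n_tok)
  out <- rep(list(character(0)), length(corpus))
  if (length(yhat)) {
    filled <- split(yhat, split_at)
    out[as.integer(names(filled))] <- filled
  }
  names(out) <- names(corpus)
  out
}

#' Predict BIO labels for a caption
#'
#' @param model A [train_chunker()] result.
#' @param x A [caption()].
#' @return Character label sequence over `{"B","I","O"}`, one per token.
#' @export
predict_labels <- function(model, x) {
  stopifnot(inherits(model, "trained_chunker"), inherits(x, "caption"))
  predict_corpus_labels(model, pheno_corpus(list(x)))[[1]]
}

#' Predict phenotype-description spans for a caption
#'
#' Composition of [predict_labels()] and [bio_to_spans()] (structurally
#' invalid label sequences are repaired before decoding).
#'
#' @inheritParams predict_labels
#' @return Data frame of spans (`start`, `end`), sorted, non-overlapping.
#' @export
predict_spans <- function(model, x) {
  bio_to_spans(predict_labels(model, x))
}

#' Save / load a trained chunker
#'
#' The model state is written as a single RDS file with a JSON sidecar
#' (`<path>.json`) recording the spec (backend, features, hyperparameters,
#' seed) for provenance. A reloaded model yields identical predictions.
#'
#' @param model A `trained_chunker`.
#' @param path Destination file.
#' @return `save_chunker`: `path`, invisibly. `load_chunker`: the model.
#' @export
save_chunker <- function(model, path) {
  stopifnot(inherits(model, "trained_chunker"))
  saveRDS(model, path)
  sp <- model$spec
  side <- list(
    backend = sp$backend,
    seed = sp$seed,
    hyperparams = sp$hyperparams,
    features = list(
      enabled = sp$feature_config$enabled,
      affix_n = sp$feature_config$affix_n,
      contexts = vapply(sp$feature_config$context_specs, context_label,
                        character(1)),
      dictionaries = sp$feature_config$dictionaries),
    n_features = length(model$vocab))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_chunker
#' @export
load_chunker <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_chunker"))
  model
}
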