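# Small in-code fixtures shared across test files.

# caption with known tokens and spans
tiny_caption <- function(id = "c1") {
  caption(id, "bell-shaped thorax and clavicles",
          spans = data.frame(start = 0L, end = 2L))
}

# a caption whose tokens are t1..tn with the given BIO labels
labelled_caption <- function(labels, id = "c1") {
  toks <- paste0("t", seq_along(labels))
  caption(id, paste(toks, collapse = " "),
          spans = bio_to_spans(labels))
}

# random valid caption for property checks (uses the caller's RNG)
random_caption <- function(id, max_tokens = 12L) {
  n <- sample.int(max_tokens, 1L)
  labels <- character(n)
  i <- 1L
  while (i <= n) {
    if (runif(1) < 0.35) {
      len <- sample.int(min(3L, n - i + 1L), 1L)
      labels[i] <- "B"
      if (len > 1L) labels[(i + 1L):(i + len - 1L)] <- "I"
      i <- i + len
    } else {
      labels[i] <- "O"
      i <- i + 1L
    }
  }
  labelled_caption(labels, id)
}

# all BIO label sequences of the given length
all_bio_sequences <- function(len) {
  grid <- do.call(expand.grid, rep(list(c("B", "I", "O")), len))
  lapply(seq_len(nrow(grid)), function(i)
    as.character(unlist(grid[i, ], use.names = FALSE)))
}

# random span set over a small universe of captions/positions
random_span_set <- function(n_max = 6L, caps = c("c1", "c2")) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  if (n == 0L) return(span_set())
  start <- sample.int(8L, n, replace = TRUE) - 1L
  span_set(sample(caps, n, replace = TRUE), start,
           start + sample.int(3L, n, replace = TRUE))
}

backend_names <- function() c("crf_a", "crf_b", "svm_ovo", "svm_ova")
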