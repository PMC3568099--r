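GENERIC_DICTS <- c("ordinals", "conjunctions", "connectives", "coordinates")
DOMAIN_DICTS <- c("anatomy", "quality")

dict_registry <- new.env(parent = emptyenv())

#' Register an in-memory dictionary
#'
#' Makes a dictionary resolvable by name wherever a [feature_config()]
#' refers to dictionaries, taking precedence over the bundled files of the
#' same name. Used, e.g., by the planted-signal corpus preset to expose its
#' marker gazetteer.
#'
#' @param dict A `dictionary` object (see [load_dictionary()]).
#' @return The dictionary, invisibly.
#' @export
register_dictionary <- function(dict) {
  stopifnot(inherits(dict, "dictionary"))
  assign(dict$name, dict, envir = dict_registry)
  invisible(dict)
}

dict_file <- function(name) {
  fname <- switch(name,
                  anatomy = "anatomy_excerpt.txt",
                  quality = "quality_excerpt.txt",
                  paste0(name, ".txt"))
  system.file("extdata", "dicts", fname, package = "phenochunk",
              mustWork = TRUE)
}

#' Load a gazetteer dictionary
#'
#' Dictionaries are unigram term lists used as lookup features during
#' tagging: one term per line, UTF-8, `#` comment lines ignored, terms
#' lower-cased on load.
#'
#' @param name Dictionary name. The bundled dictionaries are the four
#'   generic ones (`ordinals`, `conjunctions`, `connectives`,
#'   `coordinates`) plus two domain-specific excerpts (`anatomy`, FMA-style;
#'   `quality`, PATO-style). Ignored when `path` is given.
#' @param path Optional path to a user-supplied term list (e.g. a full
#'   anatomy or quality term dump) loaded under `name`.
#' @return An object of class `dictionary`: list with `name` and `terms`
#'   (character set).
#' @export
load_dictionary <- function(name, path = NULL) {
  if (is.null(path) && exists(name, envir = dict_registry))
    return(get(name, envir = dict_registry))
  if (is.null(path)) path <- dict_file(name)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  terms <- tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
  terms <- unique(terms)
  if (!length(terms)) stop("dictionary '", name, "' is empty")
  if (any(grepl("[[:space:]]", terms)))
    stop("dictionary '", name, "' contains multi-token terms; only unigrams ",
         "are supported")
  structure(list(name = name, terms = terms), class = "dictionary")
}

#' Load a set of bundled dictionaries
#'
#' @param names Character vector of bundled dictionary names; defaults to
#'   the four generic dictionaries plus the two domain excerpts.
#' @return Named list of `dictionary` objects.
#' @export
bundled_dictionaries <- function(names = c(GENERIC_DICTS, DOMAIN_DICTS)) {
  stats::setNames(lapply(names, load_dictionary), names)
}
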