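#' Assemble the lexicons used by the feature extractors
#'
#' Bundles the protein gazetteer, the interactor-term lexicon (each term
#' with the part-of-speech tag expected for it) and the three negation
#' phrase lists (pre-, post- and pseudo-negation). All entries are
#' lower-cased and de-duplicated; every list must be non-empty.
#'
#' @param gazetteer Character vector of protein names (multi-word allowed).
#' @param interactors Named character vector: names are interactor terms
#'   (stemmed form), values their POS tags (e.g. `c(bind = "VB")`).
#' @param negation_pre Phrases that negate a following finding.
#' @param negation_post Phrases that negate a preceding finding.
#' @param negation_pseudo Phrases that look like negations but are not
#'   reliable triggers; they block, rather than produce, negations.
#' @return An object of class `ppi_lexicons`.
#' @export
lexicons <- function(gazetteer, interactors, negation_pre,
                     negation_post, negation_pseudo) {
  check_nonempty <- function(x, what) {
    if (length(x) == 0L) stop(what, " lexicon is empty", call. = FALSE)
  }
  check_nonempty(gazetteer, "gazetteer")
  check_nonempty(interactors, "interactor")
  check_nonempty(negation_pre, "pre-negation")
  check_nonempty(negation_post, "post-negation")
  check_nonempty(negation_pseudo, "pseudo-negation")
  if (is.null(names(interactors)) || any(!nzchar(names(interactors)))) {
    stop("`interactors` must be a named vector term -> POS", call. = FALSE)
  }
  ints <- interactors[!duplicated(tolower(names(interactors)))]
  names(ints) <- tolower(names(ints))
  structure(
    list(
      gazetteer = unique(tolower(gazetteer)),
      interactors = vapply(ints, as.character, character(1L)),
      negation_pre = unique(tolower(negation_pre)),
      negation_post = unique(tolower(negation_post)),
      negation_pseudo = unique(tolower(negation_pseudo))
    ),
    class = "ppi_lexicons"
  )
}

#' @export
print.ppi_lexicons <- function(x, ...) {
  cat("<ppi_lexicons> gazetteer:", length(x$gazetteer),
      "| interactors:", length(x$interactors),
      "| negation pre/post/pseudo:", length(x$negation_pre),
      length(x$negation_post), length(x$negation_pseudo), "\n")
  invisible(x)
}

#' Load lexicons from plain-text files
#'
#' The gazetteer and negation files hold one entry per line; the
#' interactor file holds `term<TAB>POS` pairs. Blank lines and lines
#' starting with `#` are skipped.
#'
#' @param gazetteer,interactors,negation_pre,negation_post,negation_pseudo
#'   File paths.
#' @return A `ppi_lexicons` object.
#' @export
read_lexicons <- function(gazetteer, interactors, negation_pre,
                          negation_post, negation_pseudo) {
  read_list <- function(path) {
    x <- trimws(readLines(path, encoding = "UTF-8"))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  ints_raw <- read_list(interactors)
  parts <- strsplit(ints_raw, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("interactor file: expected 'term<TAB>POS' on every line",
         call. = FALSE)
  }
  ints <- vapply(parts, `[`, character(1L), 2L)
  names(ints) <- vapply(parts, `[`, character(1L), 1L)
  lexicons(
    gazetteer = read_list(gazetteer),
    interactors = ints,
    negation_pre = read_list(negation_pre),
    negation_post = read_list(negation_post),
    negation_pseudo = read_list(negation_pseudo)
  )
}

#' Built-in demonstration lexicons
#'
#' A compact lexicon set sufficient to exercise every feature extractor:
#' a gazetteer of bacterial and human protein names, a stemmed
#' interactor-term lexicon with POS tags (verbs such as *bind*,
#' *phosphorylate*; nominals such as *interaction*, *response*), and
#' NegEx-style pre-, post- and pseudo-negation phrase lists. The
#' synthetic corpus generator draws from these by default.
#'
#' @param extra_proteins Optional additional gazetteer entries.
#' @return A `ppi_lexicons` object.
#' @export
default_lexicons <- function(extra_proteins = character()) {
  gaz <- c(
    "GerE", "ykuD", "SigK", "SigK factor", "CotD", "SpoIIID", "p53",
    "MDM2", "BRCA1", "RAD51", "TP53", "AKT1", "EGFR", "GRB2", "SOS1",
    "RAS", "RAF1", "MEK1", "ERK2", "STAT3", "JAK2", "renin",
    "aldosterone", "CheA", "CheY", "FliM", "LexA", "RecA", "UmuD",
    extra_proteins
  )
  ints <- c(
    bind = "VB", activate = "VB", inhibit = "VB", phosphorylate = "VB",
    interact = "VB", associate = "VB", regulate = "VB", suppress = "VB",
    stimulate = "VB", repress = "VB", recruit = "VB", cleave = "VB",
    ubiquitinate = "VB", acetylate = "VB",
    interaction = "NN", association = "NN", complex = "NN",
    response = "NN", binding = "NN", activation = "NN",
    inhibition = "NN", phosphorylation = "NN"
  )
  pre <- c("no", "not", "without", "absence of", "lack of", "failed to",
           "neither", "never", "cannot", "denies", "ruled out",
           "no evidence of")
  post <- c("was ruled out", "were ruled out", "was not observed",
            "were not observed", "was absent", "were absent",
            "could not be detected", "unlikely")
  pseudo <- c("no increase", "no further", "not only", "no change in",
              "not necessarily", "gram negative", "not certain if")
  lexicons(gaz, ints, pre, post, pseudo)
}
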