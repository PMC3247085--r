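#' Tokenize a sentence
#'
#' Splits text into word and punctuation tokens. Maximal runs of
#' alphanumeric characters (plus internal nothing -- hyphens, slashes and
#' other punctuation are isolated as their own single-character tokens)
#' form word tokens; every non-alphanumeric, non-whitespace character
#' becomes its own token. Character offsets are retained so each token can
#' be mapped back to its position in the original string.
#'
#' @param text A single non-empty character string.
#' @return An object of class `ppi_tokens`: a list with components
#'   `tokens` (character vector), `start` (0-based character offset of
#'   each token in `text`) and `text` (the input). `length()` returns the
#'   number of tokens.
#' @examples
#' tokenize("GerE binds ykuD.")$tokens
#' tokenize("p53-mediated response")$tokens
#' @export
tokenize <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("`text` must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text)[[1L]]
  if (m[1L] == -1L) stop("`text` contains no tokens", call. = FALSE)
  toks <- regmatches(text, list(m))[[1L]]
  structure(
    list(tokens = toks, start = as.integer(m) - 1L, text = text),
    class = "ppi_tokens"
  )
}

#' @export
length.ppi_tokens <- function(x) length(x$tokens)

#' @export
print.ppi_tokens <- function(x, ...) {
  cat("<ppi_tokens> ", length(x$tokens), " tokens: ",
      paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Construct a sentence record
#'
#' The basic corpus unit: raw text, its tokens, optional protein-mention
#' spans and a label. Mention spans are half-open `[start, end)` intervals
#' over 0-based token indices; they must lie in bounds and must not
#' overlap.
#'
#' @param id Sentence identifier (string).
#' @param text Sentence text.
#' @param proteins Optional list of `c(start, end)` half-open token spans.
#' @param label One of `"pos"`, `"neg"`, `"unk"`.
#' @return An object of class `ppi_sentence`.
#' @export
sentence <- function(id, text, proteins = NULL, label = "unk") {
  label <- match.arg(label, c("pos", "neg", "unk"))
  tok <- tokenize(text)
  proteins <- validate_spans(proteins, length(tok$tokens))
  structure(
    list(id = as.character(id), text = text, tokens = tok,
         protein_mentions = proteins, label = label),
    class = "ppi_sentence"
  )
}

validate_spans <- function(spans, n_tokens) {
  if (is.null(spans) || length(spans) == 0L) return(list())
  spans <- lapply(spans, function(s) as.integer(s[1:2]))
  ok <- vapply(spans, function(s) {
    s[1L] >= 0L && s[2L] > s[1L] && s[2L] <= n_tokens
  }, logical(1L))
  if (!all(ok)) stop("protein mention span out of bounds", call. = FALSE)
  spans <- spans[order(vapply(spans, `[`, integer(1L), 1L))]
  starts <- vapply(spans, `[`, integer(1L), 1L)
  ends <- vapply(spans, `[`, integer(1L), 2L)
  if (any(starts[-1L] < ends[-length(ends)])) {
    stop("protein mention spans overlap", call. = FALSE)
  }
  spans
}

#' @export
print.ppi_sentence <- function(x, ...) {
  cat("<ppi_sentence> id=", x$id, " label=", x$label, " mentions=",
      length(x$protein_mentions), "\n  ", x$text, "\n", sep = "")
  invisible(x)
}

label_to_num <- function(label) {
  switch(label, pos = 1, neg = -1, unk = NA_real_)
}

#' Read a sentence corpus from JSON lines
#'
#' One JSON object per line with fields `id`, `text`, optional `proteins`
#' (list of half-open token spans) and `label` (`"pos"`, `"neg"` or
#' `"unk"`); extra fields (e.g. a generator's `template`) are kept as
#' attributes.
#'
#' @param path Path to a JSONL file.
#' @return A list of `ppi_sentence` objects.
#' @seealso [write_corpus()], [make_sentences()]
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    s <- sentence(rec$id, rec$text,
                  proteins = if (!is.null(rec$proteins) && length(rec$proteins)) {
                    if (is.matrix(rec$proteins)) {
                      lapply(seq_len(nrow(rec$proteins)), function(i) rec$proteins[i, ])
                    } else rec$proteins
                  },
                  label = if (is.null(rec$label)) "unk" else rec$label)
    extra <- setdiff(names(rec), c("id", "text", "proteins", "label"))
    for (nm in extra) attr(s, nm) <- rec[[nm]]
    s
  })
}

#' Write a sentence corpus to JSON lines
#'
#' Fields are emitted in the fixed order `id`, `text`, `proteins`,
#' `label` (plus any attributes set by a generator), so repeated writes of
#' the same corpus are byte-identical.
#'
#' @param corpus List of `ppi_sentence` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(s) {
    rec <- list(id = s$id, text = s$text,
                proteins = lapply(s$protein_mentions, as.integer),
                label = s$label)
    tmpl <- attr(s, "template")
    if (!is.null(tmpl)) rec$template <- tmpl
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
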