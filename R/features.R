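# Feature extraction: the nine lexico-syntactic features computed per
# sentence (negation, protein count, interactor name/POS/position,
# positional counts, link-path status).

is_punct_token <- function(tok) grepl("^[^[:alnum:]]$", tok)

# Tokens transparent to the negation window: coordination and punctuation.
NEG_DELIMS <- c(",", ";", "and", "or")

# Find all occurrences of a multi-token phrase in a token vector
# (case-insensitive). Returns a list of half-open 0-based spans.
match_phrase <- function(tokens_lc, phrase) {
  ptoks <- tolower(tokenize(phrase)$tokens)
  np <- length(ptoks)
  n <- length(tokens_lc)
  if (np > n) return(list())
  hits <- list()
  for (i in seq_len(n - np + 1L)) {
    if (all(tokens_lc[i:(i + np - 1L)] == ptoks)) {
      hits[[length(hits) + 1L]] <- c(i - 1L, i - 1L + np)
    }
  }
  hits
}

# NegEx-style distance between a negation phrase and a finding, counted in
# "terms" rather than raw tokens: punctuation and the coordinating tokens
# ",", ";", "and", "or" are transparent, and each complete coordinated
# segment between the phrase and the finding counts as a single unit (a
# coordinated conjunct plays the role of one multi-word concept). Words in
# the finding's own segment count individually.
negex_distance <- function(tokens_lc, from, to) {
  if (to < from) return(Inf)
  if (to == from) return(0L)
  idx <- seq.int(from, to - 1L) + 1L  # 1-based R indices
  toks <- tokens_lc[idx]
  delim <- toks %in% NEG_DELIMS
  word <- !delim & !is_punct_token(toks)
  # split at delimiters: segment id per position
  seg <- cumsum(delim)
  seg[delim] <- NA
  segs <- split(word, seg)
  n_seg <- length(segs)
  if (n_seg == 0L) return(0L)
  complete <- if (n_seg > 1L) segs[-n_seg] else list()
  n_complete <- sum(vapply(complete, any, logical(1L)))
  n_complete + sum(segs[[n_seg]])
}

span_contains <- function(outer, inner) {
  outer[1L] <= inner[1L] && inner[2L] <= outer[2L]
}

#' Detect negated findings in a sentence
#'
#' A NegEx-style rule detector. Findings are the sentence's protein
#' mentions plus any interactor-lexicon terms it contains. A finding is
#' negated when a pre-negation phrase precedes it, or a post-negation
#' phrase follows it, within `window` units; pseudo-negation phrases are
#' matched first and block any negation phrase nested inside them. The
#' window is counted NegEx-fashion in *terms*: punctuation and the
#' coordinating tokens `","`, `";"`, `"and"`, `"or"` are transparent and
#' each complete coordinated segment between trigger and finding counts
#' as one unit, so a negation reaches across an enumerated list the way
#' the original rule set reaches across multi-word concepts.
#'
#' @param sent A `ppi_sentence`. If it carries no protein mentions,
#'   [count_proteins()] is applied first.
#' @param lex A `ppi_lexicons` object.
#' @param window Maximum distance (in window units) between a negation
#'   phrase and the finding it negates. Default 5.
#' @return A list with `is_negated` (logical scalar) and `negated`, a
#'   data frame of negated findings (`term`, `start`, `end`, `trigger`,
#'   `status`); spans are half-open 0-based token spans.
#' @export
detect_negation <- function(sent, lex, window = 5L) {
  stopifnot(inherits(sent, "ppi_sentence"), inherits(lex, "ppi_lexicons"))
  if (length(sent$protein_mentions) == 0L) {
    sent <- count_proteins(sent, lex)$sentence
  }
  toks_lc <- tolower(sent$tokens$tokens)

  pseudo <- unlist(lapply(lex$negation_pseudo, match_phrase,
                          tokens_lc = toks_lc), recursive = FALSE)
  blocked <- function(span) {
    any(vapply(pseudo, span_contains, logical(1L), inner = span))
  }
  get_triggers <- function(phrases) {
    hits <- unlist(lapply(phrases, match_phrase, tokens_lc = toks_lc),
                   recursive = FALSE)
    if (is.null(hits)) hits <- list()
    hits[!vapply(hits, blocked, logical(1L))]
  }
  pre <- get_triggers(lex$negation_pre)
  post <- get_triggers(lex$negation_post)

  findings <- sent$protein_mentions
  for (i in seq_along(toks_lc)) {
    if (stem_lookup(toks_lc[i], lex$interactors)$found) {
      findings[[length(findings) + 1L]] <- c(i - 1L, i)
    }
  }
  findings <- unique(findings)

  out <- list()
  for (f in findings) {
    trig <- NULL
    for (p in pre) {
      if (negex_distance(toks_lc, p[2L], f[1L]) <= window) { trig <- p; break }
    }
    if (is.null(trig)) {
      for (p in post) {
        if (negex_distance(toks_lc, f[2L], p[1L]) <= window) { trig <- p; break }
      }
    }
    if (!is.null(trig)) {
      out[[length(out) + 1L]] <- data.frame(
        term = paste(sent$tokens$tokens[(f[1L] + 1L):f[2L]], collapse = " "),
        start = f[1L], end = f[2L],
        trigger = paste(toks_lc[(trig[1L] + 1L):trig[2L]], collapse = " "),
        status = "negated", stringsAsFactors = FALSE
      )
    }
  }
  negated <- if (length(out)) do.call(rbind, out) else
    data.frame(term = character(), start = integer(), end = integer(),
               trigger = character(), status = character(),
               stringsAsFactors = FALSE)
  list(is_negated = nrow(negated) > 0L, negated = negated)
}

#' Count protein mentions by gazetteer matching
#'
#' Greedy left-to-right longest-match of gazetteer entries against the
#' token sequence (case-insensitive); matches never overlap, and at each
#' position the longest gazetteer entry wins (so "SigK factor" beats
#' "SigK" when both are listed). The resolved spans are written back into
#' the sentence's `protein_mentions` unless it already carries gold spans.
#'
#' @param sent A `ppi_sentence`.
#' @param lex A `ppi_lexicons`.
#' @param use_gold If `TRUE` (default) and the sentence already has
#'   mention spans, those are kept and simply counted.
#' @return A list with `count` and the updated `sentence`.
#' @export
count_proteins <- function(sent, lex, use_gold = TRUE) {
  stopifnot(inherits(sent, "ppi_sentence"), inherits(lex, "ppi_lexicons"))
  if (length(lex$gazetteer) == 0L) stop("empty gazetteer", call. = FALSE)
  if (use_gold && length(sent$protein_mentions) > 0L) {
    return(list(count = length(sent$protein_mentions), sentence = sent))
  }
  toks_lc <- tolower(sent$tokens$tokens)
  gaz_tok <- lapply(lex$gazetteer, function(g) tolower(tokenize(g)$tokens))
  gaz_len <- lengths(gaz_tok)
  ord <- order(-gaz_len)  # longest entries first
  gaz_tok <- gaz_tok[ord]
  gaz_len <- gaz_len[ord]
  n <- length(toks_lc)
  spans <- list()
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (k in seq_along(gaz_tok)) {
      L <- gaz_len[k]
      if (i + L - 1L > n) next
      if (all(toks_lc[i:(i + L - 1L)] == gaz_tok[[k]])) { matched <- L; break }
    }
    if (matched > 0L) {
      spans[[length(spans) + 1L]] <- c(i - 1L, i - 1L + matched)
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  sent$protein_mentions <- spans
  list(count = length(spans), sentence = sent)
}

# Conservative suffix-stripping candidates for a token, most specific
# first; never shortens below 3 characters. Designed to preserve the POS
# of interaction terms (no Porter-style aggressive conflation).
stem_candidates <- function(token) {
  t <- tolower(token)
  cand <- t
  add <- function(x) if (nchar(x) >= 3L && !(x %in% cand)) cand <<- c(cand, x)
  n <- nchar(t)
  if (grepl("ies$", t) && n > 4L) add(sub("ies$", "y", t))
  if (grepl("(s|x|z|ch|sh)es$", t)) add(sub("es$", "", t))
  if (grepl("s$", t) && !grepl("ss$", t)) add(sub("s$", "", t))
  if (grepl("ed$", t) && n > 4L) {
    base <- sub("ed$", "", t)
    add(base)
    add(paste0(base, "e"))
    if (grepl("([^aeiou])\\1$", base)) add(sub(".$", "", base))
  }
  if (grepl("ing$", t) && n > 5L) {
    base <- sub("ing$", "", t)
    add(base)
    add(paste0(base, "e"))
    if (grepl("([^aeiou])\\1$", base)) add(sub(".$", "", base))
  }
  cand
}

# Look a token up in the interactor lexicon via its stem candidates.
stem_lookup <- function(token, interactors) {
  for (cand in stem_candidates(token)) {
    if (cand %in% names(interactors)) {
      return(list(found = TRUE, stem = cand, pos = interactors[[cand]]))
    }
  }
  list(found = FALSE, stem = NA_character_, pos = NA_character_)
}

#' Find the interactor term of a sentence
#'
#' Each token is conservatively stemmed (plural/-ed/-ing stripping with
#' doubling and e-restoration candidates, never below three characters)
#' and looked up in the interactor lexicon. When several tokens match,
#' the first match lying strictly between the leftmost and rightmost
#' protein mention is preferred; otherwise the first match anywhere.
#'
#' @inheritParams detect_negation
#' @return A list with `name` (stemmed term or `NA`), `pos` (lexicon POS
#'   tag or `NA`), `position` (0-based character offset of the matched
#'   token in the text, `-1L` when absent) and `token_index`.
#' @export
find_interactor <- function(sent, lex) {
  stopifnot(inherits(sent, "ppi_sentence"), inherits(lex, "ppi_lexicons"))
  toks <- sent$tokens$tokens
  hits <- list()
  for (i in seq_along(toks)) {
    lk <- stem_lookup(toks[i], lex$interactors)
    if (lk$found) hits[[length(hits) + 1L]] <- list(i = i, lk = lk)
  }
  if (length(hits) == 0L) {
    return(list(name = NA_character_, pos = NA_character_,
                position = -1L, token_index = -1L))
  }
  pick <- hits[[1L]]
  m <- sent$protein_mentions
  if (length(m) >= 2L) {
    first_end <- m[[1L]][2L]
    last_start <- m[[length(m)]][1L]
    between <- Filter(function(h) {
      (h$i - 1L) >= first_end && (h$i - 1L) < last_start
    }, hits)
    if (length(between)) pick <- between[[1L]]
  }
  list(name = pick$lk$stem, pos = pick$lk$pos,
       position = sent$tokens$start[pick$i],
       token_index = pick$i - 1L)
}

#' Positional features relative to protein mentions
#'
#' Counts of tokens strictly between the outermost protein mentions,
#' strictly before the first mention, and strictly after the last. Any
#' quantity that is undefined -- fewer than two mentions for the
#' in-between count, a mention at the sentence edge, or no mention at
#' all -- is reported as the sentinel `-1`.
#'
#' @param sent A `ppi_sentence` whose mentions have been resolved.
#' @return A list `n_words_between`, `n_left_words`, `n_right_words`.
#' @export
positional_features <- function(sent) {
  stopifnot(inherits(sent, "ppi_sentence"))
  m <- sent$protein_mentions
  n <- length(sent$tokens$tokens)
  if (length(m) == 0L) {
    return(list(n_words_between = -1L, n_left_words = -1L,
                n_right_words = -1L))
  }
  first <- m[[1L]]
  last <- m[[length(m)]]
  between <- if (length(m) >= 2L) last[1L] - first[2L] else -1L
  left <- if (first[1L] > 0L) first[1L] else -1L
  right <- if (n - last[2L] > 0L) n - last[2L] else -1L
  list(n_words_between = as.integer(between),
       n_left_words = as.integer(left),
       n_right_words = as.integer(right))
}

#' Built-in link-path heuristic
#'
#' Stand-in for a grammatical link parser: reports a link path between
#' the two outermost protein mentions when an interactor term occurs
#' strictly between them and no sentence-boundary punctuation (`.` or
#' `;`) intervenes.
#'
#' @param lex A `ppi_lexicons` supplying the interactor terms.
#' @return A provider function `function(sent) TRUE/FALSE/NA` for
#'   [link_path_status()].
#' @export
heuristic_link_provider <- function(lex) {
  force(lex)
  function(sent) {
    m <- sent$protein_mentions
    if (length(m) < 2L) return(NA)
    lo <- m[[1L]][2L]
    hi <- m[[length(m)]][1L]
    if (hi <= lo) return(FALSE)
    toks <- sent$tokens$tokens[(lo + 1L):hi]
    if (any(toks %in% c(".", ";"))) return(FALSE)
    any(vapply(toks, function(tk) stem_lookup(tolower(tk), lex$interactors)$found,
               logical(1L)))
  }
}

#' Link-path status between the outermost protein mentions
#'
#' Delegates to a pluggable provider; sentences with fewer than two
#' mentions, and provider failures, yield `NA`.
#'
#' @param sent A `ppi_sentence` with resolved mentions.
#' @param provider A function `sentence -> TRUE/FALSE/NA`, e.g.
#'   [heuristic_link_provider()].
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
link_path_status <- function(sent, provider) {
  if (length(sent$protein_mentions) < 2L) return(NA)
  res <- tryCatch(provider(sent), error = function(e) {
    warning("link-path provider failed: ", conditionMessage(e),
            call. = FALSE)
    NA
  })
  if (!is.logical(res) || length(res) != 1L) NA else res
}

#' Extract the nine-feature record for one sentence
#'
#' Composes negation detection, gazetteer protein counting, interactor
#' lookup, positional counts and the link-path provider into the fixed
#' nine-field record used by the classifiers. Deterministic given
#' sentence, lexicons and provider.
#'
#' @inheritParams detect_negation
#' @param provider Link-path provider; defaults to
#'   [heuristic_link_provider()] over `lex`.
#' @return A one-row data frame of class `ppi_features` with columns
#'   `is_negated`, `n_proteins`, `interactor_name`, `interactor_pos`,
#'   `interactor_position`, `n_words_between`, `n_left_words`,
#'   `n_right_words`, `link_path`.
#' @export
extract_features <- function(sent, lex, provider = heuristic_link_provider(lex),
                             window = 5L) {
  cp <- count_proteins(sent, lex)
  sent <- cp$sentence
  neg <- detect_negation(sent, lex, window = window)
  int <- find_interactor(sent, lex)
  pos <- positional_features(sent)
  lp <- link_path_status(sent, provider)
  rec <- data.frame(
    is_negated = neg$is_negated,
    n_proteins = as.integer(cp$count),
    interactor_name = int$name,
    interactor_pos = int$pos,
    interactor_position = as.integer(int$position),
    n_words_between = pos$n_words_between,
    n_left_words = pos$n_left_words,
    n_right_words = pos$n_right_words,
    link_path = lp,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("ppi_features", "data.frame")
  rec
}

#' Extract features for a whole corpus
#'
#' @param corpus List of `ppi_sentence` objects.
#' @inheritParams extract_features
#' @return A `ppi_features` data frame, one row per sentence, with the
#'   sentence ids as `id` column and numeric labels (`+1`/`-1`/`NA`) as
#'   `label` attribute.
#' @export
extract_features_corpus <- function(corpus, lex,
                                    provider = heuristic_link_provider(lex),
                                    window = 5L) {
  rows <- lapply(corpus, extract_features, lex = lex, provider = provider,
                 window = window)
  out <- do.call(rbind, rows)
  out <- cbind(id = vapply(corpus, function(s) s$id, character(1L)), out)
  class(out) <- c("ppi_features", "data.frame")
  attr(out, "label") <- vapply(corpus, function(s) label_to_num(s$label),
                               numeric(1L))
  out
}
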