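# Tokenization, lexicons, negation, NER, interactor, positional and
# link-path feature extraction.

test_that("tokenizer splits words and punctuation deterministically", {
  expect_equal(tokenize("GerE binds ykuD.")$tokens,
               c("GerE", "binds", "ykuD", "."))
  expect_equal(tokenize("p53-mediated response")$tokens,
               c("p53", "-", "mediated", "response"))
  expect_error(tokenize(""), "non-empty")
  expect_error(tokenize("   "), "non-empty")
  # offsets map tokens back into the text
  tk <- tokenize("p53-mediated response")
  expect_equal(substring(tk$text, tk$start + 1, tk$start + nchar(tk$tokens)),
               tk$tokens)
})

test_that("corpus JSONL round-trips byte-stably", {
  corp <- make_sentences(sentence_spec(n_sentences = 12, seed = 7))
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, p1)
  back <- read_corpus(p1)
  write_corpus(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(vapply(back, function(s) s$label, character(1)),
               vapply(corp, function(s) s$label, character(1)))
  expect_equal(back[[3]]$protein_mentions, corp[[3]]$protein_mentions)
})

test_that("negation triggers within the window and not beyond it", {
  lex <- toy_lexicons()
  # finding 5 units after the trigger: negated
  s5 <- sentence("s5", "not here here here here here GerE moved")
  expect_true(detect_negation(s5, lex)$is_negated)
  # finding 6 plain tokens after the only pre-negation phrase: not negated
  s6 <- sentence("s6", "not here here here here here here GerE moved")
  expect_false(detect_negation(s6, lex)$is_negated)
  # no trigger anywhere
  s0 <- sentence("s0", "GerE binds ykuD strongly")
  res0 <- detect_negation(s0, lex)
  expect_false(res0$is_negated)
  expect_equal(nrow(res0$negated), 0L)
  # post-negation phrase after a finding
  sp <- sentence("sp", "binding of GerE was not observed")
  expect_true(detect_negation(sp, lex)$is_negated)
})

test_that("negation is case-insensitive and pseudo-phrases block triggers", {
  lex <- toy_lexicons()
  expect_true(detect_negation(sentence("c", "NOT a partner of GerE"),
                              lex)$is_negated)
  expect_true(detect_negation(sentence("c2", "No binding by GerE"),
                              lex)$is_negated)
  # "no increase" is a pseudo phrase: its "no" must not negate
  sps <- sentence("ps", "no increase of GerE was seen")
  expect_false(detect_negation(sps, lex)$is_negated)
})

test_that("gazetteer NER counts non-overlapping longest matches", {
  lex <- toy_lexicons()
  s <- sentence("g1", "GerE binds ykuD")
  res <- count_proteins(s, lex)
  expect_equal(res$count, 2L)
  expect_equal(res$sentence$protein_mentions, list(c(0L, 1L), c(2L, 3L)))
  # longest match wins: "SigK factor" over "SigK"
  s2 <- count_proteins(sentence("g2", "the SigK factor is required"), lex)
  expect_equal(s2$count, 1L)
  expect_equal(s2$sentence$protein_mentions, list(c(1L, 3L)))
  # no hits
  expect_equal(count_proteins(sentence("g3", "nothing to see here"),
                              lex)$count, 0L)
})

test_that("NER equals brute-force greedy longest-match enumeration", {
  lex <- lexicons(gazetteer = c("aa", "bb", "aa bb", "cc"),
                  interactors = c(bind = "VB"),
                  negation_pre = "no", negation_post = "none seen",
                  negation_pseudo = "no increase")
  vocab <- c("aa", "bb", "cc", "dd", "ee")
  brute <- function(toks, entries) {
    ent <- lapply(entries, function(e) strsplit(e, " ")[[1]])
    spans <- list()
    i <- 1
    while (i <= length(toks)) {
      lens <- vapply(ent, function(e) {
        if (i + length(e) - 1 <= length(toks) &&
            identical(toks[i:(i + length(e) - 1)], e)) length(e) else 0L
      }, integer(1))
      if (max(lens) > 0) {
        spans[[length(spans) + 1]] <- c(i - 1L, i - 1L + max(lens))
        i <- i + max(lens)
      } else i <- i + 1
    }
    spans
  }
  set.seed(42)
  for (trial in 1:25) {
    toks <- sample(vocab, sample(3:10, 1), replace = TRUE)
    s <- sentence("t", paste(toks, collapse = " "))
    got <- count_proteins(s, lex, use_gold = FALSE)
    want <- brute(toks, lex$gazetteer)
    expect_equal(got$sentence$protein_mentions, want)
    expect_equal(got$count, length(want))
  }
})

test_that("interactor lookup stems conservatively and prefers in-between matches", {
  lex <- toy_lexicons()
  s <- count_proteins(sentence("i1", "A binds B"), lex)$sentence
  res <- find_interactor(s, lex)
  expect_equal(res$name, "bind")
  expect_equal(res$pos, "VB")
  expect_equal(res$position, 2L)  # 0-based char offset of "binds"
  # no interactor token at all
  miss <- find_interactor(sentence("i2", "GerE and ykuD cooperate"), lex)
  expect_equal(miss$name, NA_character_)
  expect_equal(miss$position, -1L)
  # match between mentions preferred over an earlier match outside them
  s3 <- count_proteins(sentence("i3", "response of A binds B"), lex)$sentence
  expect_equal(find_interactor(s3, lex)$name, "bind")
  # stemming variants resolve to the lexicon entry
  expect_true(ppispotter:::stem_lookup("binding", lex$interactors)$found)
  expect_true(ppispotter:::stem_lookup("bound", lex$interactors)$found == FALSE)
  expect_equal(ppispotter:::stem_lookup("responses", lex$interactors)$pos, "NN")
})

test_that("positional features use -1 sentinels for undefined quantities", {
  lex <- toy_lexicons()
  s <- count_proteins(sentence("p1", "GerE binds ykuD in vitro"), lex)$sentence
  expect_equal(positional_features(s),
               list(n_words_between = 1L, n_left_words = -1L,
                    n_right_words = 2L))
  # no mentions at all
  s0 <- sentence("p0", "one two three")
  expect_equal(positional_features(s0),
               list(n_words_between = -1L, n_left_words = -1L,
                    n_right_words = -1L))
  # one mention at token 3 of 10
  s1 <- sentence("p2", "w0 w1 w2 GerE w4 w5 w6 w7 w8 w9",
                 proteins = list(c(3L, 4L)))
  expect_equal(positional_features(s1),
               list(n_words_between = -1L, n_left_words = 3L,
                    n_right_words = 6L))
})

test_that("positional identity holds for two single-token mentions", {
  lex <- toy_lexicons()
  set.seed(11)
  for (trial in 1:10) {
    n <- sample(4:12, 1)
    toks <- paste0("w", seq_len(n))
    pos <- sort(sample(n, 2))
    toks[pos] <- c("GerE", "ykuD")
    s <- count_proteins(sentence("t", paste(toks, collapse = " ")), lex,
                        use_gold = FALSE)$sentence
    pf <- positional_features(s)
    left <- max(pf$n_left_words, 0)
    right <- max(pf$n_right_words, 0)
    expect_equal(left + 1 + pf$n_words_between + 1 + right, n)
  }
})

test_that("link-path heuristic needs an interactor between unbroken mentions", {
  lex <- toy_lexicons()
  prov <- heuristic_link_provider(lex)
  mk <- function(txt) count_proteins(sentence("l", txt), lex,
                                     use_gold = FALSE)$sentence
  expect_true(link_path_status(mk("GerE binds ykuD"), prov))
  expect_false(link_path_status(mk("GerE is small ; ykuD too"), prov))
  expect_true(is.na(link_path_status(mk("GerE alone here"), prov)))
  # provider failure degrades to NA with a warning
  bad <- function(sent) stop("boom")
  expect_warning(res <- link_path_status(mk("GerE binds ykuD"), bad),
                 "provider failed")
  expect_true(is.na(res))
})

test_that("extract_features composes the nine fields deterministically", {
  lex <- toy_lexicons()
  rec <- extract_features(sentence("f1", "GerE binds ykuD ."), lex)
  expect_s3_class(rec, "ppi_features")
  expect_equal(names(rec),
               c("is_negated", "n_proteins", "interactor_name",
                 "interactor_pos", "interactor_position",
                 "n_words_between", "n_left_words", "n_right_words",
                 "link_path"))
  expect_equal(unname(unlist(rec[c("is_negated", "n_proteins")])),
               c(0, 2))
  expect_equal(rec$interactor_name, "bind")
  expect_equal(rec$interactor_pos, "VB")
  expect_equal(rec$interactor_position, 5L)
  expect_equal(rec$n_words_between, 1L)
  expect_equal(rec$n_left_words, -1L)
  expect_equal(rec$n_right_words, 1L)
  expect_true(rec$link_path)
  # purity: identical inputs, identical record
  expect_identical(rec, extract_features(sentence("f1", "GerE binds ykuD ."),
                                         lex))
  # nothing matches: sentinels and missings throughout
  rec0 <- extract_features(sentence("f0", "nothing matches here"), lex)
  expect_false(rec0$is_negated)
  expect_equal(rec0$n_proteins, 0L)
  expect_true(is.na(rec0$interactor_name))
  expect_equal(rec0$interactor_position, -1L)
  expect_equal(rec0$n_words_between, -1L)
  expect_true(is.na(rec0$link_path))
})

test_that("encoder standardizes with training statistics only", {
  lex <- default_lexicons()
  corp <- make_sentences(sentence_spec(n_sentences = 40, seed = 5), lex)
  fr <- extract_features_corpus(corp, lex)
  enc <- fit_encoder(fr[1:30, ])
  X_tr <- encode_features(enc, fr[1:30, ])
  X_te <- encode_features(enc, fr[31:40, ])
  expect_equal(ncol(X_tr), ncol(X_te))
  # no leakage: encoding test rows with an encoder fitted on them differs
  enc_leaky <- fit_encoder(fr[31:40, ])
  expect_false(identical(enc$stats, enc_leaky$stats))
  # identical records encode to identical rows
  X2 <- encode_features(enc, fr[c(3, 3), ])
  expect_identical(X2[1, ], X2[2, ])
  # sentinel -1 passes through its indicator, standardized value zeroed
  i <- which(fr$n_left_words == -1)[1]
  expect_equal(unname(X_tr[i, "n_left_words_z"]), 0)
  expect_equal(unname(encode_features(enc, fr[i, , drop = FALSE])[1, "n_left_words_undef"]), 1)
  # unknown POS tags map to OTHER with a warning
  fr_bad <- fr[1, , drop = FALSE]
  fr_bad$interactor_pos <- "XYZ"
  expect_warning(Xb <- encode_features(enc, fr_bad), "OTHER")
  expect_equal(unname(Xb[1, "pos_OTHER"]), 1)
})
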