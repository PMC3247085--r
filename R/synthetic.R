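# Synthetic data: cluster-structured numeric datasets (the SSL cluster
# assumption made literal) and templated PPI-like sentence corpora, so
# every pipeline stage can be exercised without external corpora.

#' Specification for cluster-structured numeric data
#'
#' @param centers Matrix of cluster centers, one row per cluster.
#' @param sigmas Per-cluster standard deviation (recycled).
#' @param class_of_cluster Label (`+1`/`-1`) of each cluster; each class
#'   needs at least one cluster.
#' @param n_labeled,n_unlabeled,n_test Set sizes.
#' @param label_flip_noise Probability in `[0, 0.5)` of flipping a
#'   point's recorded label.
#' @param seed Integer seed.
#' @return An object of class `ppi_cluster_spec`.
#' @export
cluster_spec <- function(centers = rbind(c(2, 0), c(-2, 0)),
                         sigmas = 0.5,
                         class_of_cluster = c(1, -1),
                         n_labeled = 2L, n_unlabeled = 100L, n_test = 0L,
                         label_flip_noise = 0, seed = 1L) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == length(class_of_cluster),
            all(class_of_cluster %in% c(-1, 1)),
            any(class_of_cluster > 0), any(class_of_cluster < 0),
            n_labeled >= 0, n_unlabeled >= 0, n_test >= 0,
            label_flip_noise >= 0, label_flip_noise < 0.5)
  sigmas <- rep_len(sigmas, nrow(centers))
  structure(list(centers = centers, sigmas = sigmas,
                 class_of_cluster = class_of_cluster,
                 n_labeled = as.integer(n_labeled),
                 n_unlabeled = as.integer(n_unlabeled),
                 n_test = as.integer(n_test),
                 label_flip_noise = label_flip_noise,
                 seed = as.integer(seed)),
            class = "ppi_cluster_spec")
}

# allocate n points across clusters, stratified by class and spread
# round-robin across the clusters of each class
allocate_clusters <- function(spec, n, need_both = FALSE) {
  if (n == 0L) return(integer(0))
  classes <- c(1, -1)
  per_class <- c(ceiling(n / 2), floor(n / 2))
  if (need_both && n >= 2L && any(per_class == 0L)) {
    stop("cannot stratify: need at least one point per class", call. = FALSE)
  }
  out <- integer(0)
  for (ci in seq_along(classes)) {
    cl_ids <- which(spec$class_of_cluster == classes[ci])
    out <- c(out, rep_len(cl_ids, per_class[ci]))
  }
  out
}

#' Generate cluster-structured labeled / unlabeled / test sets
#'
#' Draws isotropic Gaussian points around each cluster center, with the
#' class stratification split evenly across the two classes (and
#' round-robin over each class's clusters). Gold labels are retained for
#' the unlabeled set so oracles and transductive evaluation can use
#' them. Fully deterministic per seed.
#'
#' @param spec A [cluster_spec()].
#' @return A list with elements `labeled`, `unlabeled`, `test`, each a
#'   list `(X, y)`; `unlabeled$y` holds the gold labels.
#' @export
make_clusters <- function(spec) {
  stopifnot(inherits(spec, "ppi_cluster_spec"))
  if (spec$n_labeled >= 2L) {
    # labeled set must be stratifiable
    allocate_clusters(spec, spec$n_labeled, need_both = TRUE)
  }
  set.seed(spec$seed)
  draw <- function(n, need_both = FALSE) {
    cl <- allocate_clusters(spec, n, need_both)
    d <- ncol(spec$centers)
    X <- matrix(0, n, d)
    for (i in seq_len(n)) {
      X[i, ] <- spec$centers[cl[i], ] + stats::rnorm(d, 0, spec$sigmas[cl[i]])
    }
    y <- spec$class_of_cluster[cl]
    if (spec$label_flip_noise > 0 && n > 0L) {
      flip <- stats::runif(n) < spec$label_flip_noise
      y[flip] <- -y[flip]
    }
    # shuffle so class blocks are not positional
    ord <- sample.int(n)
    list(X = X[ord, , drop = FALSE], y = y[ord])
  }
  list(labeled = draw(spec$n_labeled, need_both = spec$n_labeled >= 2L),
       unlabeled = draw(spec$n_unlabeled),
       test = draw(spec$n_test))
}

#' Specification for a templated synthetic sentence corpus
#'
#' Positive templates place an interactor term between two protein
#' names; negative templates either lack an interactor or negate the
#' interaction with a pre-negation phrase. Slots: `{P1}`, `{P2}`
#' (proteins), `{INT}` (inflected interactor), `{NEGPRE}` (pre-negation
#' phrase).
#'
#' @param n_sentences Corpus size.
#' @param positive_fraction Fraction of positive sentences, in (0, 1).
#' @param templates Named list with character vectors `positive` and
#'   `negative`; at least one negative template must contain `{NEGPRE}`.
#' @param seed Integer seed.
#' @return An object of class `ppi_sentence_spec`.
#' @export
sentence_spec <- function(n_sentences = 100L, positive_fraction = 0.4,
                          templates = default_templates(), seed = 1L) {
  stopifnot(n_sentences >= 1L,
            positive_fraction > 0, positive_fraction < 1,
            length(templates$positive) >= 1L,
            length(templates$negative) >= 1L)
  if (!any(grepl("{NEGPRE}", templates$negative, fixed = TRUE))) {
    stop("at least one negative template must use the {NEGPRE} slot",
         call. = FALSE)
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 positive_fraction = positive_fraction,
                 templates = templates, seed = as.integer(seed)),
            class = "ppi_sentence_spec")
}

#' Default sentence templates
#'
#' @return A list with `positive` and `negative` template vectors.
#' @export
default_templates <- function() {
  list(
    positive = c(
      "{P1} {INT} {P2} in vitro .",
      "we found that {P1} directly {INT} {P2} .",
      "{P1} specifically {INT} the promoter of {P2} .",
      "these results show that {P1} {INT} {P2} during sporulation ."
    ),
    negative = c(
      "{P1} and {P2} were purified from cell extracts .",
      "{P1} was detected in the same fraction as {P2} .",
      "{NEGPRE} evidence that {P1} {INT} {P2} was found .",
      "there was {NEGPRE} indication that {P1} {INT} {P2} .",
      "{P1} localized to the membrane whereas {P2} did not ."
    )
  )
}

# inflect a stemmed interactor to third-person singular
inflect_interactor <- function(stem) {
  if (grepl("(s|x|z|ch|sh)$", stem)) paste0(stem, "es") else paste0(stem, "s")
}

#' Generate a synthetic sentence corpus
#'
#' Fills the templates with protein names sampled from the gazetteer and
#' interactor terms from the interactor lexicon (verbs are inflected so
#' the stemmer is exercised). The gold label comes from the template
#' class, gold protein mention spans are recorded, and the template id
#' is kept on each sentence. Deterministic per seed.
#'
#' @param spec A [sentence_spec()].
#' @param lex A `ppi_lexicons` (default [default_lexicons()]).
#' @return A list of `ppi_sentence` objects, labels set to
#'   `"pos"`/`"neg"`, each carrying a `template` attribute.
#' @export
make_sentences <- function(spec, lex = default_lexicons()) {
  stopifnot(inherits(spec, "ppi_sentence_spec"), inherits(lex, "ppi_lexicons"))
  set.seed(spec$seed)
  n_pos <- round(spec$n_sentences * spec$positive_fraction)
  n_neg <- spec$n_sentences - n_pos
  # use single-token gazetteer names so mention spans are one token wide
  prots <- lex$gazetteer[!grepl(" ", lex$gazetteer)]
  verbs <- names(lex$interactors)[lex$interactors == "VB"]
  pre <- lex$negation_pre[!grepl(" ", lex$negation_pre)]
  labels <- c(rep("pos", n_pos), rep("neg", n_neg))
  kinds <- c(rep("positive", n_pos), rep("negative", n_neg))
  ord <- sample.int(spec$n_sentences)
  labels <- labels[ord]; kinds <- kinds[ord]

  out <- vector("list", spec$n_sentences)
  for (i in seq_len(spec$n_sentences)) {
    pool <- spec$templates[[kinds[i]]]
    ti <- sample.int(length(pool), 1L)
    tmpl <- pool[ti]
    ps <- sample(prots, 2L)
    fill <- c(P1 = ps[1L], P2 = ps[2L],
              INT = inflect_interactor(sample(verbs, 1L)),
              NEGPRE = sample(pre, 1L))
    text <- tmpl
    for (slot in names(fill)) {
      text <- gsub(paste0("{", slot, "}"), fill[[slot]], text, fixed = TRUE)
    }
    if (grepl("\\{[A-Z0-9]+\\}", text)) {
      stop("unfilled template slot in: ", tmpl, call. = FALSE)
    }
    toks <- tokenize(text)$tokens
    spans <- lapply(which(tolower(toks) %in% tolower(ps)),
                    function(j) c(j - 1L, j))
    s <- sentence(sprintf("syn-%04d", i), text, proteins = spans,
                  label = labels[i])
    attr(s, "template") <- paste0(kinds[i], "-", ti)
    out[[i]] <- s
  }
  out
}
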