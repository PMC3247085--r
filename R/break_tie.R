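# Pool-based active learning by breaking ties: query the unlabeled
# instances whose two class probabilities are closest.

#' Breaking-ties uncertainty scores
#'
#' For binary classification the gap between the two class probabilities
#' is `|P(+1) - P(-1)| = |2 p - 1|`; the smaller the gap, the closer the
#' instance is to a tie between the classes and the more informative an
#' expert label for it is.
#'
#' @param p Positive-class probabilities over the pool, each in `[0, 1]`.
#' @return Numeric vector of tie scores in `[0, 1]`.
#' @export
tie_scores <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  abs(2 * p - 1)
}

#' Select active-learning queries by breaking ties
#'
#' Returns the `k` pool instances with the smallest tie scores; ties on
#' the score are broken by ascending pool index so selection is
#' deterministic.
#'
#' @param p Positive-class probabilities over the pool.
#' @param k Query budget (>= 0). If `k` exceeds the pool size the whole
#'   pool is returned with a warning.
#' @return An object of class `ppi_query_batch`: list with `indices`
#'   (1-based pool indices, ordered by increasing tie score) and
#'   `tie_scores` (matching scores, non-decreasing).
#' @export
select_queries <- function(p, k) {
  s <- tie_scores(p)
  if (!is.numeric(k) || length(k) != 1L || k < 0) {
    stop("k must be a non-negative scalar", call. = FALSE)
  }
  k <- as.integer(k)
  if (k > length(s)) {
    warning("budget exceeds pool size; returning the whole pool",
            call. = FALSE)
    k <- length(s)
  }
  ord <- order(s, seq_along(s))
  idx <- ord[seq_len(k)]
  structure(list(indices = idx, tie_scores = s[idx]),
            class = "ppi_query_batch")
}

#' @export
print.ppi_query_batch <- function(x, ...) {
  cat("<ppi_query_batch>", length(x$indices), "queries; tie scores in [",
      if (length(x$indices)) format(min(x$tie_scores), digits = 3) else "-",
      ",",
      if (length(x$indices)) format(max(x$tie_scores), digits = 3) else "-",
      "]\n")
  invisible(x)
}

#' Partition a pool by classification confidence
#'
#' High-confidence instances are those with `P(+1) >= theta` or
#' `P(+1) <= 1 - theta`; they receive the machine label `sign(2p - 1)`.
#' The rest form the fuzzy set that active learning draws queries from.
#' The two index sets always partition the pool exactly.
#'
#' @param p Positive-class probabilities over the pool.
#' @param theta Confidence threshold in `(0.5, 1]` (default 0.9).
#' @return A list with `fuzzy` (indices), `high_conf` (indices) and
#'   `machine_labels` (labels for `high_conf`, in `{+1, -1}`).
#' @export
split_by_confidence <- function(p, theta = 0.9) {
  s <- tie_scores(p)  # validates range
  if (theta <= 0.5 || theta > 1) {
    stop("theta must lie in (0.5, 1]", call. = FALSE)
  }
  hi <- which(p >= theta | p <= 1 - theta)
  list(fuzzy = setdiff(seq_along(p), hi),
       high_conf = hi,
       machine_labels = ifelse(p[hi] >= 0.5, 1, -1))
}

#' Gold-label oracle for simulations
#'
#' Wraps a vector of gold labels as a query oracle; every call is
#' counted so labeling cost can be audited after a run.
#'
#' @param labels Vector of labels in `{+1, -1}`, one per pool instance.
#' @return An object of class `ppi_oracle`: call it as
#'   `oracle$query(indices)`; read `oracle$calls()` for the cumulative
#'   number of labels requested.
#' @export
gold_oracle <- function(labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  n_calls <- 0L
  structure(list(
    query = function(indices) {
      if (any(indices < 1L | indices > length(labels))) {
        stop("oracle index out of range", call. = FALSE)
      }
      n_calls <<- n_calls + length(indices)
      labels[indices]
    },
    calls = function() n_calls
  ), class = "ppi_oracle")
}

#' Interactive stdin oracle
#'
#' Prompts on the console for a `+`/`-` label for each queried sentence;
#' intended for the command-line tool's `--interactive` mode.
#'
#' @param texts Character vector of sentence texts, one per pool index.
#' @return A `ppi_oracle`.
#' @export
stdin_oracle <- function(texts) {
  n_calls <- 0L
  structure(list(
    query = function(indices) {
      n_calls <<- n_calls + length(indices)
      vapply(indices, function(i) {
        repeat {
          ans <- trimws(readline(sprintf("[%d] %s\n  interaction? [+/-]: ",
                                         i, texts[i])))
          if (ans %in% c("+", "p", "y")) return(1)
          if (ans %in% c("-", "n")) return(-1)
        }
      }, numeric(1L))
    },
    calls = function() n_calls
  ), class = "ppi_oracle")
}
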