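# Weighted linear soft-margin SVM, solved in the dual by sequential
# minimal optimization (maximal-violating-pair working set selection),
# with the intercept recovered by exact 1-D minimization of the primal.

# log(1 + exp(z)) without overflow
log1pexp <- function(z) {
  out <- numeric(length(z))
  hi <- z > 35
  out[hi] <- z[hi]
  out[!hi] <- log1p(exp(z[!hi]))
  out
}

hinge <- function(t) pmax(0, 1 - t)

# Exact minimizer over b of sum_i U_i * hinge(y_i * (f_i + b)).
# The objective is convex piecewise linear with breakpoints y_i - f_i;
# flat stretches are resolved to their midpoint for determinism.
optimal_bias <- function(f, y, U) {
  keep <- U > 0
  f <- f[keep]; y <- y[keep]; U <- U[keep]
  if (!length(f)) return(0)
  cpts <- y - f
  ord <- order(cpts)
  cs <- cpts[ord]
  Us <- U[ord]
  target <- sum(U[y > 0])
  cum <- cumsum(Us)
  tol <- 1e-12 * max(1, target)
  k <- which(cum >= target - tol)[1L]
  if (is.na(k)) return(cs[length(cs)])
  if (abs(cum[k] - target) <= tol && k < length(cs)) {
    (cs[k] + cs[k + 1L]) / 2
  } else {
    cs[k]
  }
}

#' Train a weighted linear soft-margin SVM
#'
#' Minimizes `0.5 * ||w||^2 + C * sum_i s_i * max(0, 1 - y_i (w.x_i + b))`
#' over `(w, b)`, where `s_i` are optional non-negative per-sample
#' weights. The dual is solved by sequential minimal optimization with
#' maximal-violating-pair selection; iteration continues until the
#' relative duality gap drops below `tol` (so the reported solution is a
#' certified optimum of the convex objective up to that gap). The
#' intercept is the exact minimizer of the primal in `b` given `w`. The
#' solver is deterministic: identical inputs give identical models.
#'
#' @param X Numeric matrix, one row per training example.
#' @param y Labels in `{+1, -1}`.
#' @param C Penalty constant (> 0) trading training error against margin.
#' @param weights Per-sample non-negative weights (default all 1).
#' @param tol Relative duality-gap tolerance (default `1e-6`).
#' @param alpha_init Optional warm-start dual variables (clipped to the
#'   feasible box and projected onto the equality constraint).
#' @param max_iter Hard cap on SMO iterations.
#' @return An object of class `ppi_svm`: list with `w`, `b`, `C`,
#'   `alpha`, `iterations`, `gap` (relative duality gap at termination).
#' @export
train_linear_svm <- function(X, y, C = 1, weights = NULL, tol = 1e-6,
                             alpha_init = NULL, max_iter = 1000000L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("C must be a positive scalar", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || length(weights) != n) {
    stop("weights must be non-negative, one per row", call. = FALSE)
  }
  eff <- weights > 1e-12
  if (length(unique(y[eff])) < 2L) {
    stop("training data must contain both classes (with positive weight)",
         call. = FALSE)
  }
  U <- C * weights

  K <- tcrossprod(X)  # linear kernel
  alpha <- if (is.null(alpha_init)) rep(0, n) else pmin(pmax(alpha_init, 0), U)
  # project warm start back onto sum(alpha * y) = 0 by scaling down the
  # over-weighted side (always feasible since alphas shrink toward 0)
  drift <- sum(alpha * y)
  if (abs(drift) > 1e-12) {
    side <- y == sign(drift)
    tot <- sum(alpha[side])
    if (tot > abs(drift)) {
      alpha[side] <- alpha[side] * (tot - abs(drift)) / tot
    } else {
      alpha <- rep(0, n)
    }
  }

  # primal value of the warm start: the solver must never hand back a
  # worse primal than it was started from (block-descent guarantee)
  primal_of <- function(a) {
    w <- as.vector(crossprod(X, a * y))
    f <- as.vector(X %*% w)
    b <- optimal_bias(f, y, U)
    list(w = w, b = b, f = f,
         value = 0.5 * sum(w^2) + sum(U * hinge(y * (f + b))))
  }
  start <- primal_of(alpha)
  alpha_start <- alpha

  G <- as.vector(K %*% (alpha * y)) * y - 1  # dual gradient
  eps_mvp <- 1e-3
  iter <- 0L
  repeat {
    repeat {
      if (iter >= max_iter) break
      up <- (y > 0 & alpha < U - 1e-15) | (y < 0 & alpha > 1e-15)
      lo <- (y < 0 & alpha < U - 1e-15) | (y > 0 & alpha > 1e-15)
      if (!any(up) || !any(lo)) break
      v <- -y * G
      i <- which(up)[which.max(v[up])]
      j <- which(lo)[which.min(v[lo])]
      m <- v[i]; M <- v[j]
      if (m - M <= eps_mvp) break
      quad <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (quad <= 1e-12) quad <- 1e-12
      delta <- (m - M) / quad
      # box clipping preserving sum(alpha*y) = 0
      dmax_i <- if (y[i] > 0) U[i] - alpha[i] else alpha[i]
      dmax_j <- if (y[j] > 0) alpha[j] else U[j] - alpha[j]
      delta <- min(delta, dmax_i, dmax_j)
      if (delta <= 0) break
      alpha[i] <- alpha[i] + y[i] * delta
      alpha[j] <- alpha[j] - y[j] * delta
      G <- G + (y * delta) * (K[, i] - K[, j])
      iter <- iter + 1L
    }
    w <- as.vector(crossprod(X, alpha * y))
    f <- as.vector(X %*% w)
    b <- optimal_bias(f, y, U)
    primal <- 0.5 * sum(w^2) + sum(U * hinge(y * (f + b)))
    dual <- sum(alpha) - 0.5 * sum(w^2)
    gap <- (primal - dual) / max(1, abs(primal))
    if (gap <= tol || iter >= max_iter || eps_mvp < 1e-14) break
    eps_mvp <- eps_mvp / 100
  }
  if (gap > tol) {
    warning(sprintf("SMO stopped at relative duality gap %.3g (tol %.3g)",
                    gap, tol), call. = FALSE)
  }
  if (primal > start$value) {
    alpha <- alpha_start
    w <- start$w
    b <- start$b
    dual <- sum(alpha) - 0.5 * sum(w^2)
    gap <- (start$value - dual) / max(1, abs(start$value))
  }
  structure(list(w = w, b = b, C = C, alpha = alpha,
                 iterations = iter, gap = gap),
            class = "ppi_svm")
}

#' @export
print.ppi_svm <- function(x, ...) {
  cat("<ppi_svm> d =", length(x$w), "| C =", x$C,
      "| ||w|| =", format(sqrt(sum(x$w^2)), digits = 5),
      "| gap =", format(x$gap, digits = 3), "\n")
  invisible(x)
}

#' SVM decision value
#'
#' The affine score `w . x + b` for one vector or each row of a matrix.
#'
#' @param model A `ppi_svm`.
#' @param x Numeric vector of length `d`, or an `n x d` matrix.
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "ppi_svm"))
  if (is.matrix(x)) {
    if (ncol(x) != length(model$w)) stop("dimension mismatch", call. = FALSE)
    as.vector(x %*% model$w) + model$b
  } else {
    if (length(x) != length(model$w)) stop("dimension mismatch", call. = FALSE)
    sum(model$w * x) + model$b
  }
}

#' @export
predict.ppi_svm <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  f <- decision_value(object, newdata)
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' Margin-normalized decision score
#'
#' The decision value divided by `||w||`: the signed geometric distance
#' of `x` from the separating hyperplane. Invariant to a joint rescaling
#' of `(w, b)`.
#'
#' @inheritParams decision_value
#' @return Numeric vector of normalized scores.
#' @export
normalized_score <- function(model, x) {
  nw <- sqrt(sum(model$w^2))
  if (nw <= 0) stop("zero weight vector: normalized score undefined",
                    call. = FALSE)
  decision_value(model, x) / nw
}

#' Fit the sigmoid probability calibration
#'
#' Maps margin-normalized scores to positive-class probabilities through
#' `P(+1 | x) = 1 / (1 + exp(A * s(x)))` with a single fitted slope
#' `A < 0` and no intercept, so a point exactly on the decision boundary
#' always receives probability 0.5. `A` maximizes the regularized
#' log-likelihood with the usual smoothed targets `(N+ + 1)/(N+ + 2)` for
#' positives and `1/(N- + 2)` for negatives, and is constrained to
#' `[-50, -1e-6]` to keep probabilities finite and orientation fixed.
#'
#' @param model A trained `ppi_svm`.
#' @param X Training matrix. @param y Labels in `{+1,-1}`.
#' @return An object of class `ppi_calibration` with elements `A` and
#'   `B` (always 0).
#' @export
fit_calibration <- function(model, X, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop("calibration requires both classes", call. = FALSE)
  }
  s <- normalized_score(model, as.matrix(X))
  npos <- sum(y > 0)
  nneg <- sum(y < 0)
  t <- ifelse(y > 0, (npos + 1) / (npos + 2), 1 / (nneg + 2))
  nll <- function(A) {
    z <- A * s
    # p = 1/(1+exp(z)); -[t log p + (1-t) log(1-p)]
    sum(t * log1pexp(z) + (1 - t) * log1pexp(-z))
  }
  opt <- stats::optimize(nll, interval = c(-50, -1e-6),
                         tol = .Machine$double.eps^0.5)
  A <- opt$minimum
  for (edge in c(-50, -1e-6)) if (nll(edge) < nll(A)) A <- edge
  structure(list(A = A, B = 0), class = "ppi_calibration")
}

#' @export
print.ppi_calibration <- function(x, ...) {
  cat("<ppi_calibration> A =", format(x$A, digits = 6), " B = 0\n")
  invisible(x)
}

#' Calibrated class probabilities
#'
#' Binary class-membership probabilities from the fitted sigmoid over the
#' margin-normalized score; the pair always sums to exactly 1 and a
#' boundary point gets (0.5, 0.5).
#'
#' @param model A `ppi_svm`. @param calib A `ppi_calibration`.
#' @param x Vector or matrix of inputs.
#' @return A matrix with columns `pos` and `neg`.
#' @export
class_probability <- function(model, calib, x) {
  stopifnot(inherits(calib, "ppi_calibration"))
  s <- normalized_score(model, x)
  p <- 1 / (1 + exp(calib$A * s))
  cbind(pos = p, neg = 1 - p)
}

#' Persist a model (with optional calibration) as flat JSON
#'
#' @param model A `ppi_svm`. @param path Output path.
#' @param calib Optional `ppi_calibration` (adds field `A`).
#' @export
write_model <- function(model, path, calib = NULL) {
  doc <- list(w = model$w, b = model$b, C = model$C)
  if (!is.null(calib)) doc$A <- calib$A
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path JSON file path.
#' @return A list with `model` (`ppi_svm`) and `calibration` (or `NULL`).
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  model <- structure(list(w = as.numeric(doc$w), b = doc$b, C = doc$C,
                          alpha = NULL, iterations = NA_integer_, gap = NA_real_),
                     class = "ppi_svm")
  calib <- if (!is.null(doc$A)) {
    structure(list(A = doc$A, B = 0), class = "ppi_calibration")
  }
  list(model = model, calibration = calib)
}
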