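# Deterministic-annealing semi-supervised SVM: minimize the
# entropy-regularized transductive objective over (w, b) and soft labels
# p while lowering the temperature T, alternating exact block updates.

bernoulli_entropy <- function(p) {
  # elementwise -p log p - (1-p) log(1-p), with 0 log 0 = 0
  term <- function(q) ifelse(q > 0, -q * log(q), 0)
  term(p) + term(1 - p)
}

sym_kl <- function(p, q, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  q <- pmin(pmax(q, eps), 1 - eps)
  sum((p - q) * (log(p / (1 - p)) - log(q / (1 - q))))
}

#' Annealing schedule for the DA semi-supervised SVM
#'
#' The outer loop solves a sequence of problems at temperatures
#' `T0 > T0/R > ... >= T_min` (the floor itself is always included as the
#' final temperature), each warm-started from the previous solution.
#'
#' @param T0 Initial temperature (> 0). High temperatures make the
#'   entropy term dominate, so soft labels start near 0.5.
#' @param R Cooling factor (> 1); each outer step divides T by R.
#' @param T_min Temperature floor (> 0).
#' @param inner_tol Convergence threshold on the symmetrized KL
#'   divergence between consecutive soft-label vectors within a fixed-T
#'   inner loop.
#' @param inner_max Cap on inner iterations per temperature.
#' @param entropy_tol Outer stopping threshold on the total soft-label
#'   entropy; `NULL` (default) resolves to `1e-6 * |U|` at run time.
#' @return An object of class `ppi_schedule`.
#' @export
annealing_schedule <- function(T0 = 10, R = 1.5, T_min = 1e-4,
                               inner_tol = 1e-6, inner_max = 50L,
                               entropy_tol = NULL) {
  stopifnot(T0 > 0, R > 1, T_min > 0, T_min <= T0,
            inner_tol > 0, inner_max >= 1L,
            is.null(entropy_tol) || entropy_tol > 0)
  structure(list(T0 = T0, R = R, T_min = T_min, inner_tol = inner_tol,
                 inner_max = as.integer(inner_max),
                 entropy_tol = entropy_tol),
            class = "ppi_schedule")
}

temperature_sequence <- function(schedule) {
  Ts <- schedule$T0 / schedule$R^(0:ceiling(log(schedule$T0 / schedule$T_min) /
                                              log(schedule$R)))
  Ts <- Ts[Ts > schedule$T_min]
  c(Ts, schedule$T_min)
}

#' Free energy of the annealed transductive objective
#'
#' The expected transductive SVM objective minus `T` times the Shannon
#' entropy of the soft labels:
#' `0.5 ||w||^2 + C sum_L H1(y_i f_i) + C* sum_U [p_j H1(f_j) +
#' (1 - p_j) H1(-f_j)] - T sum_U S(p_j)`, with hinge loss
#' `H1(t) = max(0, 1 - t)` and Bernoulli entropy `S`.
#'
#' @param model A `ppi_svm` (only `w`, `b` are used).
#' @param p Soft labels for the unlabeled rows, each in `[0, 1]`.
#' @param T Temperature (>= 0).
#' @param X_l,y_l Labeled data (matrix and `{+1,-1}` labels); may be
#'   empty.
#' @param X_u Unlabeled data matrix (rows matching `p`); may be empty.
#' @param C Penalty on labeled hinge losses.
#' @param Cstar Penalty on unlabeled expected hinge losses.
#' @return The free energy (scalar).
#' @export
free_energy <- function(model, p, T, X_l, y_l, X_u, C = 1, Cstar = 1) {
  if (T < 0) stop("temperature must be non-negative", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("soft labels must lie in [0,1]", call. = FALSE)
  obj <- 0.5 * sum(model$w^2)
  if (length(y_l)) {
    f_l <- decision_value(model, as.matrix(X_l))
    obj <- obj + C * sum(hinge(y_l * f_l))
  }
  if (length(p)) {
    f_u <- decision_value(model, as.matrix(X_u))
    obj <- obj + Cstar * sum(p * hinge(f_u) + (1 - p) * hinge(-f_u)) -
      T * sum(bernoulli_entropy(p))
  }
  obj
}

#' Closed-form soft-label update
#'
#' The exact per-instance minimizer of the free energy in `p` at fixed
#' `(w, b)`: with `g_j = C* (H1(f_j) - H1(-f_j))`,
#' `p_j = 1 / (1 + exp(g_j / T))`. With a class-balance target `r`, a
#' common offset `nu` is found by bisection so that
#' `mean(p) = r` to within `1e-8`, giving
#' `p_j = 1 / (1 + exp((g_j - nu) / T))`.
#'
#' @param model A `ppi_svm`.
#' @param X_u Unlabeled data matrix.
#' @param T Temperature (> 0; at `T = 0` use [round_labels()]).
#' @param Cstar Unlabeled penalty.
#' @param balance Optional target mean of `p` in (0, 1), or `NULL`.
#' @return Numeric vector of soft labels.
#' @export
update_soft_labels <- function(model, X_u, T, Cstar = 1, balance = NULL) {
  if (T <= 0) stop("T must be positive (round labels at T = 0)",
                   call. = FALSE)
  if (is.null(X_u) || nrow(as.matrix(X_u)) == 0L) return(numeric(0))
  f <- decision_value(model, as.matrix(X_u))
  g <- Cstar * (hinge(f) - hinge(-f))
  if (is.null(balance)) return(stats::plogis(-g / T))
  stopifnot(balance > 0, balance < 1)
  mean_p <- function(nu) mean(stats::plogis(-(g - nu) / T))
  lo <- min(g) - T * 40
  hi <- max(g) + T * 40
  mid <- (lo + hi) / 2
  for (it in 1:500) {
    mid <- (lo + hi) / 2
    if (abs(mean_p(mid) - balance) <= 1e-9) break
    if (mean_p(mid) < balance) lo <- mid else hi <- mid
  }
  stats::plogis(-(g - mid) / T)
}

#' Weighted SVM block update for fixed soft labels
#'
#' The exact minimizer of the free energy in `(w, b)` at fixed `p`: each
#' unlabeled point enters the weighted SVM twice, once with label `+1`
#' and weight `C* p_j` and once with label `-1` and weight
#' `C* (1 - p_j)`; labeled points carry weight `C`.
#'
#' @inheritParams free_energy
#' @param alpha_init Optional warm start passed to [train_linear_svm()]
#'   (length `|L| + 2 |U|`, labeled rows first, then the `+1` and `-1`
#'   unlabeled duplicates).
#' @return A `ppi_svm` trained on the expanded weighted problem.
#' @export
weighted_train <- function(X_l, y_l, X_u, p, C = 1, Cstar = 1,
                           alpha_init = NULL) {
  X_l <- as.matrix(X_l)
  have_u <- !is.null(X_u) && nrow(as.matrix(X_u)) > 0L
  if (!have_u) {
    return(train_linear_svm(X_l, y_l, C = 1,
                            weights = rep(C, length(y_l))))
  }
  X_u <- as.matrix(X_u)
  stopifnot(length(p) == nrow(X_u))
  X <- rbind(X_l, X_u, X_u)
  y <- c(y_l, rep(1, nrow(X_u)), rep(-1, nrow(X_u)))
  s <- c(rep(C, length(y_l)), Cstar * p, Cstar * (1 - p))
  train_linear_svm(X, y, C = 1, weights = s, alpha_init = alpha_init)
}

#' Round soft labels to hard labels
#'
#' `sign(2p - 1)` with the exact tie `p = 0.5` resolved to `+1`.
#'
#' @param p Soft labels in `[0, 1]`.
#' @return Labels in `{+1, -1}`.
#' @export
round_labels <- function(p) ifelse(p >= 0.5, 1, -1)

#' Deterministic-annealing semi-supervised SVM
#'
#' Minimizes the entropy-regularized transductive SVM objective by
#' alternating exact block updates -- a weighted SVM solve in `(w, b)`
#' and the closed-form soft-label update in `p` -- inside an outer loop
#' that lowers the temperature geometrically, warm-starting each
#' temperature at the previous solution. A fixed-T inner loop stops when
#' the symmetrized KL divergence between consecutive soft-label vectors
#' falls below `inner_tol` (the convergence monitor on consecutive `p`)
#' or after `inner_max` iterations; the outer loop stops when the total
#' soft-label entropy falls below `entropy_tol` or the temperature floor
#' is reached. Among the states recorded at the end of each temperature,
#' the one minimizing the entropy-free transductive objective (the
#' `T -> 0` limit of the free energy) is returned, since free energies
#' at different temperatures are not directly comparable.
#'
#' @inheritParams free_energy
#' @param schedule An [annealing_schedule()].
#' @param p_init Initial soft labels (default all 0.5).
#' @param balance Optional class-balance target for the soft-label mean
#'   (`NULL`, the default, disables the constraint; `TRUE` uses the
#'   labeled-set positive fraction; a number in (0,1) is used directly).
#' @return An object of class `ppi_da_state`: list with `model`
#'   (`ppi_svm`), `p` (soft labels of the returned best state), `labels`
#'   (`round_labels(p)`), `T` (temperature of the returned state),
#'   `free_energy`, `entropy`, `p_final`/`T_final` (the state at the end
#'   of the schedule, where soft labels have hardened), and `trace` (a
#'   data frame with one row per block update: `outer`, `T`, `inner`,
#'   `step`, `free_energy`, `entropy`, `kl_prev`).
#' @export
anneal <- function(X_l, y_l, X_u, schedule = annealing_schedule(),
                   C = 1, Cstar = 1, p_init = NULL, balance = NULL) {
  stopifnot(inherits(schedule, "ppi_schedule"))
  X_l <- as.matrix(X_l)
  have_u <- !is.null(X_u) && nrow(as.matrix(X_u)) > 0L
  if (have_u) X_u <- as.matrix(X_u)
  n_u <- if (have_u) nrow(X_u) else 0L

  trace <- list()
  push <- function(outer, T, inner, step, fe, ent, kl) {
    trace[[length(trace) + 1L]] <<- data.frame(
      outer = outer, T = T, inner = inner, step = step,
      free_energy = fe, entropy = ent, kl_prev = kl)
  }

  if (!have_u) {
    model <- weighted_train(X_l, y_l, NULL, numeric(0), C = C)
    fe <- free_energy(model, numeric(0), 0, X_l, y_l, NULL, C, Cstar)
    push(1L, schedule$T0, 1L, "train", fe, 0, NA_real_)
    return(structure(list(model = model, p = numeric(0),
                          labels = numeric(0), T = schedule$T0,
                          free_energy = fe, entropy = 0,
                          p_final = numeric(0), T_final = schedule$T0,
                          trace = do.call(rbind, trace)),
                     class = "ppi_da_state"))
  }

  r <- NULL
  if (isTRUE(balance)) r <- mean(y_l > 0) else if (is.numeric(balance)) r <- balance
  entropy_tol <- if (is.null(schedule$entropy_tol)) 1e-6 * n_u else
    schedule$entropy_tol

  p <- if (is.null(p_init)) rep(0.5, n_u) else {
    stopifnot(length(p_init) == n_u, all(p_init >= 0 & p_init <= 1))
    as.numeric(p_init)
  }
  Ts <- temperature_sequence(schedule)
  alpha <- NULL
  best <- NULL
  best_obj <- Inf
  model <- NULL
  for (outer in seq_along(Ts)) {
    T <- Ts[outer]
    for (inner in seq_len(schedule$inner_max)) {
      cand <- weighted_train(X_l, y_l, X_u, p, C = C, Cstar = Cstar,
                             alpha_init = alpha)
      # monotone block descent: only accept the (w, b) update if it does
      # not increase the free energy at the current (p, T); the solver's
      # finite duality gap could otherwise nudge it up near convergence
      if (is.null(model) ||
          free_energy(cand, p, T, X_l, y_l, X_u, C, Cstar) <=
            free_energy(model, p, T, X_l, y_l, X_u, C, Cstar)) {
        model <- cand
        alpha <- model$alpha
      }
      fe <- free_energy(model, p, T, X_l, y_l, X_u, C, Cstar)
      if (!is.finite(fe)) stop("non-finite free energy at T = ", T,
                               call. = FALSE)
      push(outer, T, inner, "train", fe, sum(bernoulli_entropy(p)), NA_real_)
      p_new <- update_soft_labels(model, X_u, T, Cstar = Cstar, balance = r)
      kl <- sym_kl(p, p_new)
      fe <- free_energy(model, p_new, T, X_l, y_l, X_u, C, Cstar)
      push(outer, T, inner, "labels", fe, sum(bernoulli_entropy(p_new)), kl)
      p <- p_new
      if (kl < schedule$inner_tol) break
    }
    # entropy-free transductive objective: comparable across temperatures
    obj <- free_energy(model, p, 0, X_l, y_l, X_u, C, Cstar)
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(model = model, p = p, T = T)
    }
    if (sum(bernoulli_entropy(p)) < entropy_tol) break
  }
  structure(list(model = best$model, p = best$p,
                 labels = round_labels(best$p), T = best$T,
                 free_energy = free_energy(best$model, best$p, best$T,
                                           X_l, y_l, X_u, C, Cstar),
                 entropy = sum(bernoulli_entropy(best$p)),
                 p_final = p, T_final = T,
                 trace = do.call(rbind, trace)),
            class = "ppi_da_state")
}

#' @export
print.ppi_da_state <- function(x, ...) {
  cat("<ppi_da_state> |U| =", length(x$p), "| T =", format(x$T, digits = 4),
      "| free energy =", format(x$free_energy, digits = 6),
      "| entropy =", format(x$entropy, digits = 4), "\n")
  invisible(x)
}

#' Write a DA trace as TSV
#' @param state A `ppi_da_state`. @param path Output path.
#' @export
write_trace <- function(state, path) {
  utils::write.table(state$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
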