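# Deterministic-annealing semi-supervised SVM: free energy, block
# updates, annealing loop.

toy_model <- function(w, b) {
  structure(list(w = w, b = b, C = 1), class = "ppi_svm")
}

test_that("free energy reproduces the hand-computed toy value", {
  m <- toy_model(1, 0)
  # labeled x=+2 (y=+1) has zero hinge; unlabeled x=0 sits on the
  # boundary: expected hinge 1, entropy log 2 at p = 0.5
  fe <- free_energy(m, p = 0.5, T = 1, X_l = matrix(2, 1, 1), y_l = 1,
                    X_u = matrix(0, 1, 1), C = 1, Cstar = 1)
  expect_equal(fe, 1.5 - log(2), tolerance = 1e-12)
  # no unlabeled data: exactly the supervised objective
  fe0 <- free_energy(m, numeric(0), 0, matrix(c(2, -0.5), 2, 1), c(1, 1),
                     NULL, C = 2)
  expect_equal(fe0, 0.5 + 2 * (1.5), tolerance = 1e-12)
  # hard labels kill the entropy term regardless of T
  feh <- function(T) free_energy(m, c(0, 1), T, matrix(2, 1, 1), 1,
                                 matrix(c(0.5, -0.5), 2, 1))
  expect_equal(feh(0.01), feh(100))
  expect_error(free_energy(m, 0.5, -1, matrix(2, 1, 1), 1,
                           matrix(0, 1, 1)), "non-negative")
})

test_that("soft-label update is the exact per-coordinate minimizer", {
  set.seed(17)
  m <- toy_model(c(0.8, -0.4), 0.2)
  X_u <- matrix(rnorm(40), 20, 2)
  for (T in c(0.3, 1, 5)) {
    p <- update_soft_labels(m, X_u, T, Cstar = 1.3)
    f <- decision_value(m, X_u)
    grid <- seq(0, 1, by = 1e-4)
    S <- function(q) ifelse(q > 0 & q < 1,
                            -q * log(q) - (1 - q) * log(1 - q), 0)
    for (j in seq_len(5)) {
      obj <- 1.3 * (grid * max(0, 1 - f[j]) +
                      (1 - grid) * max(0, 1 + f[j])) - T * S(grid)
      expect_lt(abs(p[j] - grid[which.min(obj)]), 1e-4)
    }
  }
  # boundary point is a perfect tie
  expect_equal(update_soft_labels(toy_model(1, 0), matrix(0, 1, 1), T = 1),
               0.5)
  expect_error(update_soft_labels(m, X_u, T = 0), "positive")
})

test_that("entropy dominates at high temperature", {
  set.seed(2)
  m <- toy_model(c(2, -1), 0.5)
  p <- update_soft_labels(m, matrix(rnorm(60), 30, 2), T = 1e6)
  expect_lt(max(abs(p - 0.5)), 1e-3)
})

test_that("balance constraint pins the soft-label mean", {
  set.seed(12)
  m <- toy_model(c(1.5, 0.3), -0.2)
  X_u <- matrix(rnorm(80), 40, 2)
  for (r in c(0.25, 0.5, 0.71)) {
    p <- update_soft_labels(m, X_u, T = 0.5, balance = r)
    expect_equal(mean(p), r, tolerance = 1e-8)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("weighted training collapses to supervised under hard or neutral p", {
  set.seed(8)
  X_l <- rbind(c(2, 0), c(-2, 0))
  y_l <- c(1, -1)
  # p = 0.5 on a symmetric within-margin cloud: unlabeled pulls cancel
  # (the expected hinge is flat inside the margin)
  Xs <- matrix(rnorm(40) * 0.3, 20, 2)
  X_u <- rbind(Xs, -Xs)
  m_half <- weighted_train(X_l, y_l, X_u, rep(0.5, 40))
  m_sup <- train_linear_svm(X_l, y_l, C = 1)
  expect_equal(decision_value(m_half, X_l), decision_value(m_sup, X_l),
               tolerance = 1e-3)
  # hard p: identical to supervised training on the union
  p_hard <- rep(c(1, 0), 10)
  m_hard <- weighted_train(X_l, y_l, Xs, p_hard, C = 1, Cstar = 1)
  m_union <- train_linear_svm(rbind(X_l, Xs), c(y_l, ifelse(p_hard > 0.5, 1, -1)))
  expect_equal(decision_value(m_hard, Xs), decision_value(m_union, Xs),
               tolerance = 1e-4)
})

test_that("each block update decreases the free energy", {
  set.seed(6)
  d <- separated_data(6)
  p <- runif(100, 0.3, 0.7)
  T <- 2
  m1 <- weighted_train(d$labeled$X, d$labeled$y, d$unlabeled$X, p)
  fe1 <- free_energy(m1, p, T, d$labeled$X, d$labeled$y, d$unlabeled$X)
  p2 <- update_soft_labels(m1, d$unlabeled$X, T)
  fe2 <- free_energy(m1, p2, T, d$labeled$X, d$labeled$y, d$unlabeled$X)
  expect_lte(fe2, fe1 + 1e-9)
  m2 <- weighted_train(d$labeled$X, d$labeled$y, d$unlabeled$X, p2,
                       alpha_init = m1$alpha)
  fe3 <- free_energy(m2, p2, T, d$labeled$X, d$labeled$y, d$unlabeled$X)
  expect_lte(fe3, fe2 + 1e-9)
})

test_that("annealing with no unlabeled data is the supervised model", {
  set.seed(10)
  X <- matrix(rnorm(24), 12, 2)
  y <- ifelse(X[, 1] > 0, 1, -1)
  st <- anneal(X, y, NULL)
  sup <- train_linear_svm(X, y, C = 1)
  expect_equal(decision_value(st$model, X), decision_value(sup, X),
               tolerance = 1e-6)
  expect_equal(nrow(st$trace), 1L)
  expect_length(st$p, 0)
})

test_that("annealing recovers the generating clusters and hardens labels", {
  d <- separated_data(1)
  st <- anneal(d$labeled$X, d$labeled$y, d$unlabeled$X)
  expect_gte(mean(st$labels == d$unlabeled$y), 0.95)
  # final soft labels pushed to the corners of [0,1]
  expect_lt(max(pmin(st$p_final, 1 - st$p_final)), 1e-3)
  # entropy shrinks along the outer loop once inner loops converge
  ent_end <- vapply(split(st$trace, st$trace$outer),
                    function(g) g$entropy[nrow(g)], numeric(1))
  expect_lt(ent_end[length(ent_end)], ent_end[1])
})

test_that("rounding soft labels breaks the exact tie upward", {
  expect_equal(round_labels(c(0.9, 0.1, 0.5)), c(1, -1, 1))
})

test_that("annealing schedule is strictly decreasing and floored", {
  sch <- annealing_schedule(T0 = 10, R = 1.5, T_min = 1e-4)
  Ts <- ppispotter:::temperature_sequence(sch)
  expect_true(all(diff(Ts) < 0))
  expect_equal(Ts[1], 10)
  expect_equal(Ts[length(Ts)], 1e-4)
  expect_error(annealing_schedule(R = 1), "R > 1")
})
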