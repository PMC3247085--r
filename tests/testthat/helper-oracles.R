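# Shared fixtures and independent oracles for the test suite.

# Independent convex-QP solution of the weighted SVM objective
# 0.5||w||^2 + sum_i U_i hinge(y_i f_i): solve the dual with kernlab's
# interior-point solver, recover w, and pick b by exact 1-D primal
# minimization (re-derived here, independent of the package's SMO path).
qp_svm_oracle <- function(X, y, C = 1, weights = rep(1, nrow(X))) {
  n <- nrow(X)
  U <- C * weights
  K <- tcrossprod(X)
  H <- (y %*% t(y)) * K
  sol <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-10, n),
                       A = matrix(y, 1), b = 0, l = rep(0, n), u = U,
                       r = 0, sigf = 9, maxiter = 400)
  a <- kernlab::primal(sol)
  w <- colSums(a * y * X)
  f <- as.vector(X %*% w)
  # brute-force b on a fine grid around the hinge breakpoints
  cand <- sort(unique(c(y - f, 0)))
  cand <- unique(sort(c(cand, (head(cand, -1) + tail(cand, -1)) / 2)))
  obj <- vapply(cand, function(b) {
    0.5 * sum(w^2) + sum(U * pmax(0, 1 - y * (f + b)))
  }, numeric(1))
  list(w = w, b = cand[which.min(obj)], f = f + cand[which.min(obj)])
}

# overlapping-clusters study fixture
overlap_data <- function(seed, n_unlabeled = 200, n_test = 200) {
  make_clusters(cluster_spec(centers = rbind(c(1, 0), c(-1, 0)),
                             sigmas = 0.8, n_labeled = 4,
                             n_unlabeled = n_unlabeled, n_test = n_test,
                             seed = seed))
}

# well-separated two-Gaussian fixture
separated_data <- function(seed, n_unlabeled = 100) {
  make_clusters(cluster_spec(centers = rbind(c(2, 0), c(-2, 0)),
                             sigmas = 0.5, n_labeled = 2,
                             n_unlabeled = n_unlabeled, seed = seed))
}

test_f1 <- function(model, X, y) {
  suppressWarnings(prf(y, ifelse(decision_value(model, X) >= 0, 1, -1))[["f1"]])
}

# tiny lexicon set for hand-computable feature examples
toy_lexicons <- function() {
  lexicons(
    gazetteer = c("GerE", "ykuD", "SigK", "SigK factor", "A", "B"),
    interactors = c(bind = "VB", response = "NN"),
    negation_pre = c("no", "not"),
    negation_post = c("was not observed"),
    negation_pseudo = c("no increase")
  )
}
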