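# The combined learner and its baselines: reductions, partitions,
# oracle accounting.

test_that("with no budget and no pool, btda, bt and supervised coincide", {
  set.seed(20)
  X <- matrix(rnorm(24), 12, 2)
  y <- ifelse(X[, 1] + 0.2 * rnorm(12) > 0, 1, -1)
  empty <- matrix(numeric(0), 0, 2)
  o <- gold_oracle(1)
  cfg <- run_config("btda", budget = 0L)
  sup <- run_supervised(X, y, run_config("svm"))
  bt <- run_bt(X, y, empty, o, run_config("bt", budget = 0L))
  bd <- run_btda(X, y, empty, o, cfg)
  probe <- matrix(rnorm(10), 5, 2)
  expect_equal(decision_value(bt$model, probe),
               decision_value(sup$model, probe), tolerance = 1e-6)
  expect_equal(decision_value(bd$model, probe),
               decision_value(sup$model, probe), tolerance = 1e-6)
  expect_equal(o$calls(), 0L)
})

test_that("bt with budget zero equals supervised even with a pool", {
  d <- overlap_data(3, n_test = 0)
  o <- gold_oracle(d$unlabeled$y)
  bt <- run_bt(d$labeled$X, d$labeled$y, d$unlabeled$X, o,
               run_config("bt", budget = 0L))
  sup <- run_supervised(d$labeled$X, d$labeled$y)
  expect_equal(decision_value(bt$model, d$unlabeled$X),
               decision_value(sup$model, d$unlabeled$X), tolerance = 1e-6)
  expect_equal(o$calls(), 0L)
})

test_that("partition stays disjoint and conserves the pool", {
  d <- overlap_data(5, n_test = 0)
  o <- gold_oracle(d$unlabeled$y)
  cfg <- run_config("btda", budget = 15L, rounds = 2L)
  bd <- run_btda(d$labeled$X, d$labeled$y, d$unlabeled$X, o, cfg)
  part <- bd$partition
  pool_sets <- c(part$S_k, part$S_u, part$S_h)
  expect_equal(sort(pool_sets), seq_len(nrow(d$unlabeled$X)))
  expect_equal(anyDuplicated(pool_sets), 0L)
  expect_equal(o$calls(), 30L)
  expect_equal(length(part$S_k), 30L)
})

test_that("oracle call count equals the configured budget", {
  d <- overlap_data(9, n_test = 0)
  o <- gold_oracle(d$unlabeled$y)
  bt <- run_bt(d$labeled$X, d$labeled$y, d$unlabeled$X, o,
               run_config("bt", budget = 10L))
  expect_equal(o$calls(), 10L)
  expect_equal(bt$report$oracle_calls, 10L)
})

test_that("bt queries are the brute-force smallest-tie instances", {
  d <- overlap_data(7, n_test = 0)
  # one round: the queried set must match a direct recomputation from
  # the same supervised model
  sup <- run_supervised(d$labeled$X, d$labeled$y)
  probs <- class_probability(sup$model, sup$calibration,
                             d$unlabeled$X)[, "pos"]
  sp <- split_by_confidence(probs, 0.9)
  fuzzy <- sp$fuzzy
  want <- fuzzy[order(abs(2 * probs[fuzzy] - 1), seq_along(fuzzy))][1:10]
  o <- gold_oracle(d$unlabeled$y)
  bt <- run_bt(d$labeled$X, d$labeled$y, d$unlabeled$X, o,
               run_config("bt", budget = 10L))
  expect_setequal(bt$partition$S_k, want)
})

test_that("random sampling is seeded and reduces to supervised at budget 0", {
  d <- overlap_data(11, n_test = 0)
  o1 <- gold_oracle(d$unlabeled$y)
  o2 <- gold_oracle(d$unlabeled$y)
  cfg <- run_config("rs", budget = 12L, seed = 99L)
  r1 <- run_rs(d$labeled$X, d$labeled$y, d$unlabeled$X, o1, cfg)
  r2 <- run_rs(d$labeled$X, d$labeled$y, d$unlabeled$X, o2, cfg)
  expect_identical(r1$partition$S_k, r2$partition$S_k)
  expect_equal(r1$model$w, r2$model$w)
  r0 <- run_rs(d$labeled$X, d$labeled$y, d$unlabeled$X,
               gold_oracle(d$unlabeled$y),
               run_config("rs", budget = 0L, seed = 1L))
  sup <- run_supervised(d$labeled$X, d$labeled$y)
  expect_equal(decision_value(r0$model, d$unlabeled$X),
               decision_value(sup$model, d$unlabeled$X), tolerance = 1e-6)
  # whole-pool budget labels everything
  rall <- run_rs(d$labeled$X, d$labeled$y, d$unlabeled$X,
                 gold_oracle(d$unlabeled$y),
                 run_config("rs", budget = nrow(d$unlabeled$X), seed = 1L))
  expect_length(rall$partition$S_u, 0)
})

test_that("cluster-then-label propagates pure cluster labels", {
  # two tight clusters, one labeled point each: pseudo-labels must all
  # match the generating cluster
  d <- make_clusters(cluster_spec(centers = rbind(c(3, 0), c(-3, 0)),
                                  sigmas = 0.3, n_labeled = 2,
                                  n_unlabeled = 60, seed = 13))
  cfg <- run_config("cluster", seed = 5L, k_clusters = 2L)
  cl <- run_cluster(d$labeled$X, d$labeled$y, d$unlabeled$X, cfg)
  expect_equal(cl$pseudo_labels, d$unlabeled$y)
  # determinism under the same seed
  cl2 <- run_cluster(d$labeled$X, d$labeled$y, d$unlabeled$X, cfg)
  expect_identical(cl$assignment, cl2$assignment)
  # k = 1: everything takes the majority label of the labeled set
  d1 <- make_clusters(cluster_spec(n_labeled = 4, n_unlabeled = 20,
                                   seed = 3))
  c1 <- run_cluster(d1$labeled$X, d1$labeled$y, d1$unlabeled$X,
                    run_config("cluster", seed = 2L, k_clusters = 1L))
  expect_length(unique(c1$pseudo_labels), 1L)
})

test_that("btda exploits high-confidence probabilities and reports them", {
  d <- overlap_data(2, n_test = 0)
  o <- gold_oracle(d$unlabeled$y)
  bd <- run_btda(d$labeled$X, d$labeled$y, d$unlabeled$X, o,
                 run_config("btda", budget = 10L))
  expect_s3_class(bd$da_state, "ppi_da_state")
  expect_equal(bd$report$oracle_calls, 10L)
  expect_false(is.null(bd$report$partition_sizes))
  # the DA ran over S_h union S_u
  expect_length(bd$da_state$p,
                length(bd$partition$S_h) + length(bd$partition$S_u))
})

test_that("stochastic methods refuse to run without a seed", {
  expect_error(run_config("rs"), "seed")
  expect_error(run_config("cluster"), "seed")
})
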