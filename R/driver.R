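# The combined break-tie / deterministic-annealing learner and its
# comparison methods (supervised, random sampling, cluster-then-label,
# break-tie active learning).

#' Run configuration for the learners
#'
#' Collects every tunable of the five methods in one validated object;
#' the configuration is echoed verbatim into every report so runs are
#' auditable.
#'
#' @param method One of `"svm"`, `"rs"`, `"cluster"`, `"bt"`, `"btda"`.
#' @param C Labeled-data penalty (> 0). @param Cstar Unlabeled-data
#'   penalty (> 0).
#' @param rounds Number of active-learning rounds.
#' @param budget Oracle queries per round.
#' @param theta Confidence threshold for the fuzzy / high-confidence
#'   split, in (0.5, 1].
#' @param schedule An [annealing_schedule()] for the DA stage.
#' @param seed Integer seed; mandatory for the stochastic methods
#'   (`"rs"`, `"cluster"`).
#' @param balance Class-balance option forwarded to [anneal()].
#' @param k_clusters Number of k-means clusters for `"cluster"`.
#' @param post_da If `TRUE`, `"rs"` and `"cluster"` feed their augmented
#'   labeled set into a DA stage as well (off by default).
#' @param cstar_scale How the driver scales the unlabeled penalty before
#'   the DA stage: `"labeled_ratio"` (default) multiplies `Cstar` by
#'   `|L| / |U|` so the total unlabeled influence matches the total
#'   labeled influence regardless of pool size (the usual per-point
#'   normalization of the unlabeled loss in annealed transductive SVMs);
#'   `"none"` uses `Cstar` as given.
#' @return An object of class `ppi_config` (a validated list).
#' @export
run_config <- function(method = c("btda", "svm", "rs", "cluster", "bt"),
                       C = 1, Cstar = 1, rounds = 1L, budget = 20L,
                       theta = 0.9, schedule = annealing_schedule(),
                       seed = NULL, balance = NULL, k_clusters = 2L,
                       post_da = FALSE,
                       cstar_scale = c("labeled_ratio", "none")) {
  cstar_scale <- match.arg(cstar_scale)
  method <- match.arg(method)
  stopifnot(C > 0, Cstar > 0, rounds >= 0L, budget >= 0L,
            theta > 0.5, theta <= 1, inherits(schedule, "ppi_schedule"),
            k_clusters >= 1L)
  if (method %in% c("rs", "cluster") && is.null(seed)) {
    stop("methods 'rs' and 'cluster' are stochastic: a seed is required",
         call. = FALSE)
  }
  structure(list(method = method, C = C, Cstar = Cstar,
                 rounds = as.integer(rounds), budget = as.integer(budget),
                 theta = theta, schedule = schedule, seed = seed,
                 balance = balance, k_clusters = as.integer(k_clusters),
                 post_da = isTRUE(post_da), cstar_scale = cstar_scale),
            class = "ppi_config")
}

effective_cstar <- function(config, n_labeled, n_unlabeled) {
  if (config$cstar_scale == "labeled_ratio" && n_unlabeled > 0L) {
    config$Cstar * n_labeled / n_unlabeled
  } else {
    config$Cstar
  }
}

config_echo <- function(config) {
  out <- unclass(config)
  out$schedule <- unclass(out$schedule)
  out
}

new_partition <- function(n_labeled, n_pool) {
  structure(list(S_t = seq_len(n_labeled),
                 S_k = integer(0),
                 S_u = seq_len(n_pool),
                 S_h = integer(0)),
            class = "ppi_partition")
}

#' @export
print.ppi_partition <- function(x, ...) {
  cat("<ppi_partition> |S_t| =", length(x$S_t), "| |S_k| =", length(x$S_k),
      "| |S_u| =", length(x$S_u), "| |S_h| =", length(x$S_h), "\n")
  invisible(x)
}

base_report <- function(config, oracle_calls = 0L, partition = NULL) {
  list(config = config_echo(config), oracle_calls = oracle_calls,
       partition_sizes = if (!is.null(partition)) {
         lapply(partition[c("S_t", "S_k", "S_u", "S_h")], length)
       })
}

#' Supervised baseline
#'
#' Trains the calibrated linear SVM on the initially labeled set alone.
#'
#' @param X_l,y_l Labeled data.
#' @param config A `ppi_config`.
#' @return A list with `model`, `calibration` and `report`.
#' @export
run_supervised <- function(X_l, y_l, config = run_config("svm")) {
  model <- train_linear_svm(as.matrix(X_l), y_l, C = config$C)
  calib <- fit_calibration(model, as.matrix(X_l), y_l)
  list(model = model, calibration = calib,
       report = base_report(config))
}

# Shared break-tie active-learning rounds (steps 1-3 of the combined
# algorithm). Returns the final supervised model, the partition over the
# pool and, for the DA stage, the last confidence split.
al_rounds <- function(X_l, y_l, X_pool, oracle, config) {
  part <- new_partition(length(y_l), nrow(X_pool))
  y_k <- numeric(0)
  model <- NULL; calib <- NULL; split <- NULL
  probs <- rep(0.5, nrow(X_pool))
  for (round in seq_len(max(1L, config$rounds))) {
    X_cur <- rbind(as.matrix(X_l), X_pool[part$S_k, , drop = FALSE])
    y_cur <- c(y_l, y_k)
    model <- train_linear_svm(X_cur, y_cur, C = config$C)
    calib <- fit_calibration(model, X_cur, y_cur)
    pool_rest <- setdiff(seq_len(nrow(X_pool)), part$S_k)
    if (!length(pool_rest)) break
    probs[pool_rest] <- class_probability(model, calib,
                                          X_pool[pool_rest, , drop = FALSE])[, "pos"]
    split <- split_by_confidence(probs[pool_rest], theta = config$theta)
    part$S_h <- pool_rest[split$high_conf]
    part$S_u <- pool_rest[split$fuzzy]
    if (config$rounds == 0L || config$budget == 0L) break
    if (round > config$rounds) break
    fuzzy <- pool_rest[split$fuzzy]
    if (!length(fuzzy)) {
      message("no fuzzy instances left to query; skipping round ", round)
      next
    }
    batch <- select_queries(probs[fuzzy],
                            min(config$budget, length(fuzzy)))
    queried <- fuzzy[batch$indices]
    y_new <- oracle$query(queried)
    part$S_k <- c(part$S_k, queried)
    y_k <- c(y_k, y_new)
    part$S_u <- setdiff(part$S_u, queried)
    part$S_h <- setdiff(part$S_h, queried)
  }
  # final supervised model on S_t union S_k
  X_cur <- rbind(as.matrix(X_l), X_pool[part$S_k, , drop = FALSE])
  y_cur <- c(y_l, y_k)
  model <- train_linear_svm(X_cur, y_cur, C = config$C)
  calib <- fit_calibration(model, X_cur, y_cur)
  pool_rest <- setdiff(seq_len(nrow(X_pool)), part$S_k)
  if (length(pool_rest)) {
    probs[pool_rest] <- class_probability(model, calib,
                                          X_pool[pool_rest, , drop = FALSE])[, "pos"]
    split <- split_by_confidence(probs[pool_rest], theta = config$theta)
    part$S_h <- pool_rest[split$high_conf]
    part$S_u <- pool_rest[split$fuzzy]
  }
  list(model = model, calibration = calib, partition = part,
       y_k = y_k, probs = probs)
}

#' Break-tie active-learning SVM
#'
#' Runs `rounds` rounds of breaking-ties querying (train, calibrate,
#' query the `budget` most tied pool instances, add the expert labels)
#' and returns the supervised SVM trained on the initial plus
#' oracle-labeled data. With budget 0 this reduces exactly to
#' [run_supervised()].
#'
#' @inheritParams run_supervised
#' @param X_pool Unlabeled pool matrix.
#' @param oracle A `ppi_oracle` supplying labels for queried indices.
#' @return A list with `model`, `calibration`, `partition`, `report`.
#' @export
run_bt <- function(X_l, y_l, X_pool, oracle, config = run_config("bt")) {
  al <- al_rounds(as.matrix(X_l), y_l, as.matrix(X_pool), oracle, config)
  list(model = al$model, calibration = al$calibration,
       partition = al$partition,
       report = base_report(config, oracle$calls(), al$partition))
}

#' Combined break-tie / deterministic-annealing SVM
#'
#' The full combined algorithm: per round, a calibrated supervised SVM is
#' trained on the current labeled set, the pool is split into fuzzy and
#' high-confidence instances, and the most tied fuzzy instances are sent
#' to the oracle. After the last round a deterministic-annealing
#' semi-supervised SVM is trained with labeled set `S_t U S_k` and
#' unlabeled set `S_h U S_u`; rather than discarding the instances the
#' supervised stage classified with high confidence, their calibrated
#' machine probabilities seed the soft labels (the remaining pool starts
#' at 0.5), so the annealer exploits them.
#'
#' @inheritParams run_bt
#' @return A list with `model` (the DA model), `calibration` (from the
#'   final supervised stage), `da_state`, `partition`, `report`.
#' @export
run_btda <- function(X_l, y_l, X_pool, oracle, config = run_config("btda")) {
  X_l <- as.matrix(X_l)
  X_pool <- as.matrix(X_pool)
  if (length(unique(y_l)) < 2L) {
    stop("initial labeled set must contain both classes", call. = FALSE)
  }
  if (nrow(X_pool) == 0L) {
    sup <- run_supervised(X_l, y_l, config)
    return(list(model = sup$model, calibration = sup$calibration,
                da_state = NULL,
                partition = new_partition(length(y_l), 0L),
                report = base_report(config)))
  }
  al <- al_rounds(X_l, y_l, X_pool, oracle, config)
  part <- al$partition
  unl_idx <- c(part$S_h, part$S_u)
  p_init <- c(al$probs[part$S_h], rep(0.5, length(part$S_u)))
  X_lab <- rbind(X_l, X_pool[part$S_k, , drop = FALSE])
  da <- anneal(X_lab, c(y_l, al$y_k),
               X_pool[unl_idx, , drop = FALSE],
               schedule = config$schedule, C = config$C,
               Cstar = effective_cstar(config, nrow(X_lab), length(unl_idx)),
               p_init = p_init,
               balance = config$balance)
  model <- da$model
  degenerate <- length(da$labels) > 0L &&
    length(unique(da$labels)) == 1L
  if (degenerate) {
    # the known transductive-SVM failure mode: every unlabeled point
    # assigned to one class; keep the active-learning stage's model
    warning("annealing degenerated to a one-class labeling; ",
            "falling back to the break-tie model", call. = FALSE)
    model <- al$model
  }
  list(model = model, calibration = al$calibration, da_state = da,
       degenerate = degenerate, partition = part,
       report = base_report(config, oracle$calls(), part))
}

#' Random-sampling baseline
#'
#' Labels a uniformly sampled (seeded) subset of the pool through the
#' oracle and trains the supervised SVM on the union; the naive
#' alternative to breaking-ties query selection. With `post_da = TRUE`
#' in the config, the augmented labeled set additionally feeds a DA
#' stage over the remaining pool.
#'
#' @inheritParams run_bt
#' @return A list with `model`, `calibration`, `partition`, `report`.
#' @export
run_rs <- function(X_l, y_l, X_pool, oracle, config = run_config("rs", seed = 1L)) {
  X_l <- as.matrix(X_l)
  X_pool <- as.matrix(X_pool)
  part <- new_partition(length(y_l), nrow(X_pool))
  k <- min(config$budget * max(1L, config$rounds), nrow(X_pool))
  set.seed(config$seed)
  chosen <- sort(sample.int(nrow(X_pool), k))
  y_k <- if (k) oracle$query(chosen) else numeric(0)
  part$S_k <- chosen
  part$S_u <- setdiff(part$S_u, chosen)
  X_cur <- rbind(X_l, X_pool[chosen, , drop = FALSE])
  y_cur <- c(y_l, y_k)
  model <- train_linear_svm(X_cur, y_cur, C = config$C)
  calib <- fit_calibration(model, X_cur, y_cur)
  da <- NULL
  if (config$post_da && length(part$S_u)) {
    da <- anneal(X_cur, y_cur, X_pool[part$S_u, , drop = FALSE],
                 schedule = config$schedule, C = config$C,
                 Cstar = effective_cstar(config, nrow(X_cur),
                                         length(part$S_u)),
                 balance = config$balance)
    model <- da$model
  }
  list(model = model, calibration = calib, da_state = da, partition = part,
       report = base_report(config, oracle$calls(), part))
}

#' Cluster-then-label baseline
#'
#' Runs seeded k-means (k-means++-free base R `kmeans` with multiple
#' restarts) on the labeled and unlabeled features jointly; each cluster
#' takes the majority label of its labeled members (a cluster with no
#' labeled member takes the label of the nearest labeled point to its
#' centroid), every unlabeled point receives its cluster's pseudo-label,
#' and a supervised SVM is trained on all points.
#'
#' @inheritParams run_supervised
#' @param X_pool Unlabeled pool matrix.
#' @return A list with `model`, `calibration`, `pseudo_labels`,
#'   `assignment`, `report`.
#' @export
run_cluster <- function(X_l, y_l, X_pool, config = run_config("cluster", seed = 1L)) {
  X_l <- as.matrix(X_l)
  X_pool <- as.matrix(X_pool)
  X_all <- rbind(X_l, X_pool)
  k <- min(config$k_clusters, nrow(X_all))
  set.seed(config$seed)
  km <- stats::kmeans(X_all, centers = k, nstart = 10L, iter.max = 100L)
  lab_idx <- seq_along(y_l)
  cluster_label <- numeric(k)
  for (cl in seq_len(k)) {
    members <- intersect(which(km$cluster == cl), lab_idx)
    if (length(members)) {
      maj <- sum(y_l[members] > 0) - sum(y_l[members] < 0)
      if (maj == 0) {
        warning("cluster ", cl, " has tied labeled members; ",
                "falling back to nearest labeled point", call. = FALSE)
      }
      cluster_label[cl] <- if (maj > 0) 1 else if (maj < 0) -1 else NA
    } else {
      cluster_label[cl] <- NA
    }
    if (is.na(cluster_label[cl])) {
      d2 <- colSums((t(X_l) - km$centers[cl, ])^2)
      cluster_label[cl] <- y_l[which.min(d2)]
    }
  }
  pseudo <- cluster_label[km$cluster[-lab_idx]]
  if (nrow(X_pool) == 0L) pseudo <- numeric(0)
  model <- train_linear_svm(X_all, c(y_l, pseudo), C = config$C)
  # heavily conflicting pseudo-labels can collapse the model to w = 0,
  # where the margin-normalized calibration is undefined
  calib <- tryCatch(fit_calibration(model, X_all, c(y_l, pseudo)),
                    error = function(e) {
                      warning("calibration unavailable: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
  list(model = model, calibration = calib, pseudo_labels = pseudo,
       assignment = km$cluster, report = base_report(config))
}
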