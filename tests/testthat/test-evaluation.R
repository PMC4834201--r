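test_that("balancing keeps the minority class whole and equalizes counts", {
  ids <- sprintf("c%02d", 1:14)
  lab <- stats::setNames(c(rep("POSITIVE", 10), rep("NEGATIVE", 4)), ids)
  sub <- balance_dataset(lab, seed = 3)
  expect_equal(unname(label_counts <- table(lab[sub])),
               unname(table(c(rep("n", 4), rep("p", 4)))))
  expect_true(all(ids[11:14] %in% sub))  # minority retained in full

  even <- stats::setNames(rep(c("POSITIVE", "NEGATIVE"), 5), sprintf("e%d", 1:10))
  expect_setequal(balance_dataset(even, seed = 1), names(even))

  expect_identical(balance_dataset(lab, seed = 42), balance_dataset(lab, seed = 42))
  diffs <- vapply(1:20, function(s) {
    !setequal(balance_dataset(lab, seed = s), balance_dataset(lab, seed = 1000 + s))
  }, logical(1))
  expect_gt(mean(diffs), 0.5)

  expect_error(balance_dataset(stats::setNames(rep("POSITIVE", 3), letters[1:3])),
               "NEGATIVE")
})

test_that("confusion metrics follow their definitions", {
  # tp=9 fn=1 tn=8 fp=2 -> sens 0.90 spec 0.80 BA 0.85
  truth <- c(rep(1, 10), rep(0, 10))
  pred_pos <- c(rep(TRUE, 9), FALSE, rep(FALSE, 8), TRUE, TRUE)
  ids <- sprintf("c%02d", 1:20)
  P <- matrix(0, 20, 20, dimnames = list(ids, ids)); diag(P) <- 1
  # wire a proximity matrix that forces exactly these predictions: each
  # compound's sole neighbor carries the intended call
  carriers <- sprintf("x%02d", 1:20)
  allids <- c(ids, carriers)
  P <- matrix(0, 40, 40, dimnames = list(allids, allids)); diag(P) <- 1
  for (i in 1:20) P[ids[i], carriers[i]] <- P[carriers[i], ids[i]] <- 0.9
  lab <- stats::setNames(
    c(ifelse(truth == 1, "POSITIVE", "NEGATIVE"),
      ifelse(pred_pos, "POSITIVE", "NEGATIVE")),
    allids)
  rep <- loo_evaluate(P, NULL, lab, read_across_config(k = 1, min_weight = 0.5),
                      ids = ids)
  expect_equal(unname(rep$confusion), c(9, 2, 8, 1))  # tp fp tn fn
  expect_equal(rep$sensitivity, 0.9)
  expect_equal(rep$specificity, 0.8)
  expect_equal(rep$balanced_accuracy, 0.85)
  expect_equal(rep$n_non_evaluable, 0)
})

test_that("mechanism-driven endpoints are recovered far above chance", {
  ds <- generate_dataset(synthetic_config(n_compounds = 80, n_assays = 40,
                                          n_mechanisms = 4,
                                          assays_per_mechanism = 10,
                                          label_mechanisms = 1:2, seed = 101))
  P <- compute_rf_proximity(ds$activity, proximity_config(n_trees = 200, seed = 101))
  rep <- loo_evaluate(P, NULL, ds$labels, read_across_config(k = 5))
  expect_gt(rep$balanced_accuracy, 0.8)
  sig <- permutation_significance(P, NULL, ds$labels, read_across_config(k = 5),
                                  n_perm = 999, seed = 101)
  expect_lte(sig$p_value, 0.01)
  expect_equal(sig$observed_ba, rep$balanced_accuracy)
})

test_that("permutation p-values respect the estimator floor", {
  ds <- generate_dataset(preset("two-cluster", seed = 55))
  P <- compute_rf_proximity(ds$activity, proximity_config(n_trees = 100, seed = 55))
  sig <- permutation_significance(P, NULL, ds$labels, read_across_config(k = 3),
                                  n_perm = 49, seed = 55)
  expect_gte(sig$p_value, 1 / 50)
  expect_lte(sig$p_value, 1)
  expect_length(sig$perm_ba, 49)
})

test_that("fast permutation path agrees with naively re-run evaluations", {
  ds <- generate_dataset(synthetic_config(n_compounds = 40, n_assays = 20,
                                          n_mechanisms = 2,
                                          assays_per_mechanism = 10, seed = 88,
                                          label_mechanisms = 1))
  P <- compute_rf_proximity(ds$activity, proximity_config(n_trees = 100, seed = 88))
  cfg <- read_across_config(k = 4)
  lab <- ds$labels
  set.seed(202)
  for (i in 1:5) {
    perm_lab <- stats::setNames(sample(unname(lab)), names(lab))
    naive <- loo_evaluate(P, NULL, perm_lab, cfg)
    W <- babra:::prediction_weight_matrix(P, NULL, perm_lab, cfg, rownames(P))
    a <- babra:::label_to_numeric(perm_lab[colnames(W)])
    fast <- babra:::ba_from_weights(W, a, babra:::label_to_numeric(perm_lab),
                                    cfg$call_cutoff)
    expect_equal(fast, naive$balanced_accuracy, tolerance = 1e-12)
  }
})

test_that("binomial cross-check broadly agrees with permutation significance", {
  ds <- generate_dataset(preset("two-cluster", seed = 7))
  P <- compute_rf_proximity(ds$activity, proximity_config(n_trees = 150, seed = 7))
  rep <- loo_evaluate(P, NULL, ds$labels, read_across_config(k = 3))
  p_binom <- binomial_significance(rep)
  sig <- permutation_significance(P, NULL, ds$labels, read_across_config(k = 3),
                                  n_perm = 199, seed = 7)
  expect_lt(p_binom, 0.01)
  expect_lt(sig$p_value, 0.05)
})

test_that("parameter sweep enumerates the grid and applies declared tie-breaks", {
  ds <- generate_dataset(preset("two-cluster", seed = 29))
  P <- compute_rf_proximity(ds$activity, proximity_config(n_trees = 150, seed = 29))
  sw <- parameter_sweep(P, NULL, ds$labels, k_grid = c(1, 2, 3, 3),
                        tau_grid = c(0, 0, 0.1), modes = "babra")
  expect_equal(nrow(sw$grid), 6L)  # duplicates removed: 3 k x 2 tau
  expect_true(sw$selected$balanced_accuracy == max(sw$grid$balanced_accuracy))
  # ties prefer the smallest k, then the largest tau
  best <- sw$grid[sw$grid$balanced_accuracy == max(sw$grid$balanced_accuracy), ]
  expect_equal(sw$selected$k, min(best$k))
  best_k <- best[best$k == min(best$k), ]
  expect_equal(sw$selected$tau, max(best_k$tau))
})
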