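test_that("resolve_missing imputes column medians and can flag missingness", {
  M <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  imp <- resolve_missing(M, "median-impute")
  expect_equal(imp["b", "x"], 2)  # median of (1, 3)
  expect_false(anyNA(imp))

  aug <- resolve_missing(M, "indicator-augment")
  expect_equal(ncol(aug), 4L)
  expect_equal(unname(aug[, "x_missing"]), c(0, 1, 0))

  M[, "y"] <- NA
  expect_error(resolve_missing(M), "'y'")
})

test_that("synthetic class preserves marginals but destroys dependence", {
  # degenerate marginal: constant column stays constant
  M <- cbind(a = rep(3, 5), b = 1:5)
  rownames(M) <- sprintf("c%d", 1:5)
  syn <- generate_synthetic_class(M, seed = 1)
  expect_true(all(syn[, "a"] == 3))
  # resampling contract: synthetic values come from the original column
  expect_true(all(syn[, "b"] %in% M[, "b"]))
  expect_error(generate_synthetic_class(cbind(a = c(1, NA))), "missing")

  # two perfectly correlated columns decorrelate under marginal resampling
  set.seed(5)
  x <- stats::rnorm(2000)
  M2 <- cbind(u = x, v = 2 * x + 1)
  rownames(M2) <- sprintf("c%d", 1:2000)
  syn2 <- generate_synthetic_class(M2, seed = 11)
  expect_lt(abs(stats::cor(syn2[, "u"], syn2[, "v"])), 0.08)
})

test_that("forest terminal assignments have the right shape and determinism", {
  M <- random_activity(10, 4, missing_rate = 0, seed = 2)
  cfg <- proximity_config(n_trees = 30, seed = 5)
  a1 <- fit_unsupervised_forest(M, cfg)
  a2 <- fit_unsupervised_forest(M, cfg)
  expect_equal(dim(a1), c(10L, 30L))
  expect_identical(unclass(a1), unclass(a2))

  # identical rows follow identical paths in every tree
  M2 <- matrix(rep(c(1, 0, 2), each = 2), 2, 3,
               dimnames = list(c("p", "q"), c("f1", "f2", "f3")))
  a3 <- fit_unsupervised_forest(M2, proximity_config(n_trees = 20, seed = 1))
  expect_true(all(a3["p", ] == a3["q", ]))
})

test_that("proximity counting matches hand arithmetic and a brute-force oracle", {
  # 2 compounds co-terminal in 3 of 4 trees -> 0.75
  assign <- matrix(c(1, 1,
                     2, 2,
                     3, 3,
                     4, 9), 2, 4, dimnames = list(c("x", "y"), NULL))
  P <- proximity_from_assignments(assign)
  expect_equal(P["x", "y"], 0.75)
  expect_equal(diag(P), c(x = 1, y = 1))

  # independent O(T n^2) recount on random assignments (n = 8, T = 25)
  set.seed(17)
  A <- matrix(sample.int(5, 8 * 25, replace = TRUE), 8, 25,
              dimnames = list(sprintf("c%d", 1:8), NULL))
  P2 <- proximity_from_assignments(A)
  brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    brute[i, j] <- sum(A[i, ] == A[j, ]) / 25
  }
  diag(brute) <- 1
  expect_equal(unname(P2), brute)
})

test_that("rf proximity is symmetric, bounded, unit-diagonal and deterministic", {
  for (seed in 1:3) {
    M <- random_activity(12, 6, missing_rate = 0.1, seed = seed)
    P <- compute_rf_proximity(M, proximity_config(n_trees = 50, seed = seed))
    expect_true(isSymmetric(P))
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(diag(P)), rep(1, 12))
  }
  M <- random_activity(8, 4, seed = 9)
  cfg <- proximity_config(n_trees = 40, seed = 4)
  expect_identical(compute_rf_proximity(M, cfg), compute_rf_proximity(M, cfg))
})

test_that("duplicate compounds are maximally proximate", {
  M <- matrix(c(1, 1, 0.5, 0.5, 2, 2), 2, 3,
              dimnames = list(c("dup1", "dup2"), c("f1", "f2", "f3")))
  P <- compute_rf_proximity(M, proximity_config(n_trees = 25, seed = 3))
  expect_equal(unname(P), matrix(1, 2, 2))
})

test_that("proximity is invariant to input row permutation", {
  M <- random_activity(15, 5, missing_rate = 0.05, seed = 21)
  cfg <- proximity_config(n_trees = 60, seed = 8)
  P <- compute_rf_proximity(M, cfg)
  perm <- sample(nrow(M))
  P_perm <- compute_rf_proximity(M[perm, ], cfg)
  expect_identical(P_perm[rownames(P), colnames(P)], P)
})

test_that("well-separated bioactivity clusters have higher within-cluster proximity", {
  ds <- generate_dataset(preset("two-cluster", seed = 13))
  P <- compute_rf_proximity(ds$activity, proximity_config(n_trees = 200, seed = 13))
  mech <- ds$truth$mechanism[rownames(P)]
  same <- outer(mech, mech, "==") & upper.tri(P)
  diff <- outer(mech, mech, "!=") & upper.tri(P)
  expect_gt(mean(P[same]), mean(P[diff]))
})

test_that("cluster separation in proximity degrades as call noise grows", {
  sep <- vapply(c(0.02, 0.15, 0.35), function(noise) {
    cfg <- synthetic_config(n_compounds = 60, n_assays = 20, n_mechanisms = 2,
                            assays_per_mechanism = 10, flip_noise = noise,
                            missing_rate = 0, label_mechanisms = 1,
                            fp_length = 64, fp_informative_bits = 8,
                            seed = 31)
    ds <- generate_dataset(cfg)
    P <- compute_rf_proximity(ds$activity,
                              proximity_config(n_trees = 150, seed = 31))
    mech <- ds$truth$mechanism[rownames(P)]
    mean(P[outer(mech, mech, "==") & upper.tri(P)]) -
      mean(P[outer(mech, mech, "!=") & upper.tri(P)])
  }, numeric(1))
  expect_true(all(diff(sep) <= 0))
})

test_that("OOB-only proximity stays a valid similarity", {
  M <- random_activity(10, 5, missing_rate = 0, seed = 6)
  P <- compute_rf_proximity(M, proximity_config(n_trees = 100, seed = 6,
                                                oob_only = TRUE))
  expect_true(isSymmetric(P))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(diag(P)), rep(1, 10))
})
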