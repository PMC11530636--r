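test_that("feature ranking recovers a planted dominant feature", {
  # age depends only on t_d; the other features are noise
  set.seed(5)
  n <- 150
  coh <- data.frame(subject_id = 1:n,
                    t_d = runif(n, 12, 20), b_a = runif(n, 60, 110),
                    volume = runif(n, 1500, 3500),
                    total_length = runif(n, 250, 450))
  coh$age <- 4 * coh$t_d + rnorm(n, 0, 1)
  coh$weight <- runif(n, 40, 90)
  rk <- rank_feature_importance(coh, "age", seed = 2)
  expect_identical(rk$feature[1], "t_d")
  expect_gt(rk$score[1], 0.5)
  expect_true(all(rk$score >= 0))
  expect_equal(sum(rk$score), 1, tolerance = 1e-12)
  expect_true(is.finite(attr(rk, "rmse")))
})

test_that("feature ranking handles degenerate inputs", {
  coh <- generate_cohort(60, seed = 3)
  # single feature: that feature gets the whole score
  rk1 <- rank_feature_importance(coh, "age", features = "t_d")
  expect_identical(rk1$feature, "t_d")
  expect_equal(rk1$score, 1)
  # constant feature: zero score plus a warning
  coh$b_a <- 80
  expect_warning(rk2 <- rank_feature_importance(coh, "age", seed = 2),
                 "constant")
  expect_equal(rk2$score[rk2$feature == "b_a"], 0)
  expect_error(rank_feature_importance(coh[1:10, ], "age"), "20")
})

test_that("cohorts built from the phenotype anchors rank t_d then b_a", {
  coh <- generate_cohort(300, seed = 9)
  rk <- rank_feature_importance(coh, "age", seed = 1)
  expect_identical(rk$feature[1:2], c("t_d", "b_a"))
})

test_that("feature ranking is stable across seeds on informative data", {
  tops <- vapply(1:20, function(s) {
    coh <- generate_cohort(250, seed = s)
    rank_feature_importance(coh, "age", seed = s)$feature[1]
  }, character(1))
  expect_gte(mean(tops == "t_d"), 0.95)
})

test_that("kernel k-means recovers nine planted clusters exactly", {
  gb <- grid_blobs()
  km <- fit_kernel_kmeans(gb$X, k = 9, seed = 4)
  expect_equal(adjusted_rand(km$assignments, gb$truth), 1)
  expect_true(all(diff(km$objective) <= 1e-9))
  # permutation invariance: same partition on shuffled rows
  set.seed(1)
  p <- sample(nrow(gb$X))
  km2 <- fit_kernel_kmeans(gb$X[p, ], k = 9, seed = 4)
  expect_equal(adjusted_rand(km2$assignments, gb$truth[p]), 1)
})

test_that("kernel k-means edge cases behave", {
  gb <- grid_blobs(n_per = 5)
  km1 <- fit_kernel_kmeans(gb$X, k = 1, seed = 1)
  expect_true(all(km1$assignments == 1))
  same <- matrix(1, 10, 2)
  expect_error(fit_kernel_kmeans(same, k = 2, seed = 1), "identical")
  km0 <- fit_kernel_kmeans(same, k = 1, seed = 1)
  expect_true(all(km0$assignments == 1))
  expect_lt(kernel_kmeans_objective(km0), 1e-12)
  expect_error(fit_kernel_kmeans(gb$X[1:5, ], k = 9), "at least")
})

test_that("agreement with an independent kernel k-means implementation", {
  skip_if_not_installed("kernlab")
  # three well-separated blobs (the reference implementation is unreliable
  # at larger k, aborting on empty interim clusters)
  set.seed(3)
  X3 <- rbind(cbind(rnorm(40, 0, .3), rnorm(40, 0, .3)),
              cbind(rnorm(40, 6, .3), rnorm(40, 0, .3)),
              cbind(rnorm(40, 3, .3), rnorm(40, 5, .3)))
  km <- fit_kernel_kmeans(X3, k = 3, seed = 2, normalize = FALSE)
  kk <- NULL
  for (s in 1:10) {
    set.seed(s)
    kk <- tryCatch(
      kernlab::kkmeans(X3, centers = 3, kernel = "rbfdot",
                       kpar = list(sigma = 1 / (2 * km$sigma^2))),
      error = function(e) NULL)
    if (!is.null(kk)) break
  }
  skip_if(is.null(kk), "reference kernel k-means did not converge")
  expect_equal(adjusted_rand(km$assignments, kk@.Data), 1)
})

test_that("grid labels and representatives follow the tertile convention", {
  gb <- grid_blobs()
  km <- fit_kernel_kmeans(gb$X, k = 9, seed = 4)
  lab <- label_clusters_and_select(km, gb$X)
  # bijection onto the nine names on the symmetric grid
  expect_setequal(lab$label,
                  c("ss", "sm", "sb", "ms", "mm", "mb", "bs", "bm", "bb"))
  # "bs" sits in the top tertile of the first coordinate and the bottom
  # tertile of the second
  bs <- lab[lab$label == "bs", ]
  expect_gte(rank(lab$centroid_1)[lab$label == "bs"], 7)
  expect_lte(rank(lab$centroid_2)[lab$label == "bs"], 3)
  # representative equals the brute-force kernel-space argmin
  K <- km$K
  for (c in seq_len(9)) {
    idx <- which(km$assignments == c)
    d2 <- vapply(idx, function(i)
      K[i, i] - 2 * mean(K[i, idx]) + mean(K[idx, idx]), numeric(1))
    expect_identical(lab$representative[c], idx[which.min(d2)])
  }
  expect_false(any(lab$flagged))
})
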