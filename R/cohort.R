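#' Synthetic morphometry cohort
#'
#' Generates a cohort table of lower-airway morphometric parameters with
#' age, weight and sex, for exercising the feature-ranking and clustering
#' tools. Trachea diameter and carina angle are drawn around the nine
#' phenotype-cluster anchors (see [phenotype_clusters()]); age and weight
#' are generated with a configurable dependence on the morphometry so the
#' ground-truth feature importance is known.
#'
#' @param n subjects.
#' @param seed RNG seed.
#' @param age_coef coefficients of the standardized (t_d, b_a, volume,
#'   total_length) in the age model (defaults make t_d dominant and b_a a
#'   close second, the ordering reported for real cohorts).
#' @param noise_sd residual sd of the age/weight models.
#' @return data.frame with subject_id, t_d, b_a, volume, total_length, age,
#'   weight, sex.
#' @export
generate_cohort <- function(n = 200, seed = 1L,
                            age_coef = c(t_d = 6, b_a = 3, volume = 0,
                                         total_length = 0),
                            noise_sd = 2) {
  set.seed(seed)
  anchors <- phenotype_clusters()
  k <- sample.int(nrow(anchors), n, replace = TRUE)
  t_d <- stats::rnorm(n, anchors$t_d[k], anchors$t_d_sd[k])
  b_a <- stats::rnorm(n, anchors$b_a[k], anchors$b_a_sd[k])
  volume <- stats::rnorm(n, 2500 + 100 * (t_d - 16), 350)
  total_length <- stats::rnorm(n, 350 + 5 * (t_d - 16), 30)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  lin <- age_coef["t_d"] * zs(t_d) + age_coef["b_a"] * zs(b_a) +
    age_coef["volume"] * zs(volume) + age_coef["total_length"] * zs(total_length)
  age <- pmax(2, 40 + lin + stats::rnorm(n, 0, noise_sd))
  weight <- pmax(10, 70 + 1.2 * lin + stats::rnorm(n, 0, 1.5 * noise_sd))
  data.frame(subject_id = seq_len(n), t_d = t_d, b_a = b_a,
             volume = volume, total_length = total_length,
             age = age, weight = weight,
             sex = sample(c("M", "F"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Rank morphometric features by predictive importance
#'
#' Random-forest regression of `age` or `weight` on the four morphometric
#' features (t_d, b_a, volume, total_length); importances are the
#' increase-in-node-purity scores, clipped at zero and normalized to sum to
#' one. A held-out root-mean-squared error (25% split) is reported
#' alongside.
#'
#' @param cohort a cohort table (see [generate_cohort()]); rows with missing
#'   feature or target values are an error.
#' @param target `"age"` or `"weight"`.
#' @param features feature columns to rank (default the four morphometric
#'   parameters present in the table).
#' @param seed RNG seed (forest and split).
#' @param ntree forest size (default 500).
#' @return data.frame sorted by decreasing `score` (non-negative, summing
#'   to 1), with the held-out RMSE in attribute `"rmse"`.
#' @export
rank_feature_importance <- function(cohort, target = c("age", "weight"),
                                    features = intersect(
                                      c("t_d", "b_a", "volume", "total_length"),
                                      names(cohort)),
                                    seed = 1L, ntree = 500) {
  target <- match.arg(target)
  if (length(features) < 1) stopf("no feature columns found")
  dat <- cohort[, c(features, target)]
  if (anyNA(dat)) stopf("missing values in features or target")
  if (nrow(dat) < 20) stopf("need at least 20 complete rows")
  const <- vapply(dat[features], function(x) stats::sd(x) == 0, logical(1))
  if (any(const))
    warning("constant feature(s) carry no information: ",
            paste(features[const], collapse = ", "))
  set.seed(seed)
  idx <- sample.int(nrow(dat), floor(0.75 * nrow(dat)))
  fml <- stats::as.formula(paste(target, "~",
                                 paste(features, collapse = " + ")))
  fit <- randomForest::randomForest(fml, data = dat[idx, , drop = FALSE],
                                    ntree = ntree, importance = FALSE)
  pred <- stats::predict(fit, dat[-idx, , drop = FALSE])
  rmse <- sqrt(mean((pred - dat[[target]][-idx])^2))
  imp_mat <- randomForest::importance(fit)
  imp <- stats::setNames(imp_mat[, 1], rownames(imp_mat))
  imp[features[const]] <- 0
  imp <- pmax(imp, 0)
  score <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  out <- data.frame(feature = names(score), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rmse") <- rmse
  out
}

# RBF kernel matrix with bandwidth sigma (k(x,y) = exp(-|x-y|^2 / (2 sigma^2)))
rbf_kernel <- function(X, sigma) {
  d2 <- as.matrix(stats::dist(X))^2
  exp(-d2 / (2 * sigma^2))
}

#' Kernelized k-means clustering
#'
#' k-means in the feature space induced by a radial-basis-function kernel on
#' z-score-normalized inputs. Kernel-space distances are computed from the
#' kernel matrix; centers are implicit cluster means. Initialization is
#' k-means++-style seeding in kernel space with a fixed seed; Lloyd
#' iterations monotonically decrease the kernel k-means objective and stop
#' at assignment convergence or `max_iter`.
#'
#' @param points numeric matrix or data.frame (rows = subjects; typically
#'   the two most informative features, t_d and b_a).
#' @param k number of clusters (default 9).
#' @param sigma RBF bandwidth on the normalized scale; default is the
#'   median pairwise distance heuristic.
#' @param seed RNG seed.
#' @param max_iter iteration cap (default 100).
#' @param n_start number of k-means++ restarts; the partition with the
#'   lowest final objective is kept (default 10).
#' @param normalize z-score the columns (default TRUE); the per-feature
#'   means/sds are stored for reuse.
#' @return object of class `kernel_kmeans`: cluster `assignments`,
#'   `objective` trace, `sigma`, normalization parameters, `k`, `seed`.
#' @export
fit_kernel_kmeans <- function(points, k = 9, sigma = NULL, seed = 1L,
                              max_iter = 100, n_start = 10, normalize = TRUE) {
  X <- as.matrix(points)
  n <- nrow(X)
  if (n < k) stopf("need at least k = %d points, got %d", k, n)
  ctr <- if (normalize) colMeans(X) else rep(0, ncol(X))
  scl <- if (normalize) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(scl == 0)) {
    if (k > 1 && all(scl == 0)) stopf("all points identical: cannot form %d clusters", k)
    scl[scl == 0] <- 1
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (is.null(sigma)) {
    dd <- stats::dist(Z)
    sigma <- stats::median(dd[dd > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  check_positive(sigma, "sigma")
  K <- rbf_kernel(Z, sigma)
  one_run <- function(run_seed) {
    set.seed(run_seed)
    # k-means++ seeding in kernel feature space: d2(i,j) = K_ii + K_jj - 2 K_ij
    seeds <- integer(k)
    seeds[1] <- sample.int(n, 1)
    d2min <- diag(K) + K[seeds[1], seeds[1]] - 2 * K[, seeds[1]]
    if (k > 1) for (j in 2:k) {
      w <- pmax(d2min, 0)
      seeds[j] <- if (sum(w) == 0) sample.int(n, 1)
                  else sample.int(n, 1, prob = w)
      d2j <- diag(K) + K[seeds[j], seeds[j]] - 2 * K[, seeds[j]]
      d2min <- pmin(d2min, d2j)
    }
    assign <- apply(vapply(seeds, function(s) diag(K) - 2 * K[, s], numeric(n)),
                    1, which.min)
    obj_trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      # kernel distances to implicit centroids
      D <- matrix(Inf, n, k)
      for (c in seq_len(k)) {
        idx <- which(assign == c)
        if (length(idx) == 0) next
        Kc <- K[, idx, drop = FALSE]
        D[, c] <- diag(K) - 2 * rowMeans(Kc) +
          mean(K[idx, idx, drop = FALSE])
      }
      new_assign <- max.col(-D, ties.method = "first")
      # re-seed empty clusters with the farthest point
      for (c in which(tabulate(new_assign, k) == 0)) {
        far <- which.max(D[cbind(seq_len(n), new_assign)])
        new_assign[far] <- c
      }
      obj <- sum(D[cbind(seq_len(n), new_assign)])
      obj_trace <- c(obj_trace, obj)
      if (identical(new_assign, assign)) break
      assign <- new_assign
    }
    list(assign = assign, obj_trace = obj_trace,
         obj = utils::tail(obj_trace, 1))
  }
  best <- NULL
  for (rs in seq_len(n_start)) {
    run <- one_run(seed + rs - 1L)
    if (is.null(best) || run$obj < best$obj) best <- run
  }
  structure(list(assignments = best$assign, k = k, sigma = sigma,
                 center = ctr, scale = scl, seed = seed,
                 objective = best$obj_trace, K = K, Z = Z),
            class = "kernel_kmeans")
}

#' Label clusters on the small/mean/big grid and pick representatives
#'
#' For k = 9 the cluster centroids (in the original units of the two input
#' features) are placed on a 3 x 3 grid by the tertiles of the centroid
#' coordinates: the first feature (trachea diameter) maps to
#' s/m/b (small/mean/big) and the second (carina angle) likewise, giving the
#' labels ss, sm, sb, ms, mm, mb, bs, bm, bb (diameter letter first).
#' Tertile ties are broken by ascending cluster index. The representative of
#' each cluster is the member closest to the cluster centroid in kernel
#' feature space; clusters whose representative distance exceeds
#' `flag_threshold` (on the normalized kernel-distance scale) are flagged as
#' lacking a clear representative rather than dropped.
#'
#' @param model a [fit_kernel_kmeans()] result with k = 9.
#' @param points the matrix the model was fitted on.
#' @param flag_threshold kernel-space distance above which a representative
#'   is flagged (default 0.75).
#' @return data.frame with cluster, label, centroid coordinates,
#'   representative row index, representative kernel distance, flagged.
#' @export
label_clusters_and_select <- function(model, points, flag_threshold = 0.75) {
  if (model$k != 9) stopf("grid labeling requires k = 9")
  X <- as.matrix(points)
  k <- model$k; K <- model$K; n <- nrow(X)
  cent <- t(vapply(seq_len(k), function(c)
    colMeans(X[model$assignments == c, , drop = FALSE]), numeric(ncol(X))))
  lab_axis <- function(v) {
    o <- order(v, seq_along(v))      # ties by ascending cluster index
    lab <- character(k)
    lab[o] <- rep(c("s", "m", "b"), each = k / 3)
    lab
  }
  labels <- paste0(lab_axis(cent[, 1]), lab_axis(cent[, 2]))
  rep_idx <- integer(k); rep_d <- numeric(k)
  for (c in seq_len(k)) {
    idx <- which(model$assignments == c)
    Kc <- K[idx, idx, drop = FALSE]
    d2 <- diag(K)[idx] - 2 * rowMeans(Kc) + mean(Kc)
    j <- which.min(d2)
    rep_idx[c] <- idx[j]; rep_d[c] <- sqrt(max(d2[j], 0))
  }
  data.frame(cluster = seq_len(k), label = labels,
             centroid_1 = cent[, 1], centroid_2 = cent[, 2],
             representative = rep_idx, rep_distance = rep_d,
             flagged = rep_d > flag_threshold,
             stringsAsFactors = FALSE)
}

#' Kernel k-means objective from an assignment
#'
#' Total within-cluster dispersion in kernel feature space; exposed for
#' convergence checks.
#'
#' @param model a `kernel_kmeans`.
#' @return numeric scalar.
#' @export
kernel_kmeans_objective <- function(model) {
  utils::tail(model$objective, 1)
}
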