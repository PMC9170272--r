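test_that("degenerate cluster counts have closed-form solutions", {
  set.seed(1)
  X <- matrix(rnorm(20), 5, 4)
  # one cluster: center at the column means, distortion = total sum of squares
  one <- kmeans_fit(X, 1)
  expect_equal(drop(one$centers), colMeans(X), tolerance = 1e-12)
  expect_equal(one$distortion, sum(scale(X, scale = FALSE)^2), tolerance = 1e-12)
  # as many clusters as rows: zero distortion
  full <- kmeans_fit(X, nrow(X))
  expect_identical(full$distortion, 0)
  expect_equal(sort(unname(full$assignments)), 1:5)

  expect_error(kmeans_fit(X, 0), class = "lingsync_usage_error")
  expect_error(kmeans_fit(X, 6), class = "lingsync_usage_error")
})

test_that("the partition oracle matches hand geometry", {
  expect_equal(brute_force_kmeans(matrix(1, 2, 2), 1)$distortion, 0)

  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  best <- brute_force_kmeans(square, 2)
  # optimal 2-partition pairs adjacent corners: two segments of length 1,
  # each with within-group SS 2 * (1/2)^2 = 1/2
  expect_equal(best$distortion, 1, tolerance = 1e-12)
  sizes <- table(best$assignments)
  expect_equal(sort(as.integer(sizes)), c(2L, 2L))

  expect_error(brute_force_kmeans(matrix(0, 11, 2), 2), class = "lingsync_usage_error")
  expect_error(brute_force_kmeans(matrix(0, 5, 2), 4), class = "lingsync_usage_error")
})

test_that("restarted Lloyd attains the oracle optimum on a toy set", {
  pts <- matrix(c(0, 0, 0.2, 0, 0.1, 0.3,
                  5, 5, 5.2, 5, 5.1, 5.3), 6, 2, byrow = TRUE)
  fit <- kmeans_fit(pts, 2, n_restarts = 20, seed = 1)
  oracle <- brute_force_kmeans(pts, 2)
  expect_equal(fit$distortion, oracle$distortion, tolerance = 1e-12)
})

test_that("fitted distortion never beats the oracle and agrees with stats::kmeans", {
  for (seed in 1:15) {
    inst <- random_instance(seed)
    fit <- kmeans_fit(inst$X, inst$k, n_restarts = 50, seed = 0)
    oracle <- brute_force_kmeans(inst$X, inst$k)
    expect_gte(fit$distortion + 1e-10, oracle$distortion)
    expect_equal(fit$distortion, oracle$distortion, tolerance = 1e-8)
    # independent route: base R's k-means with many restarts
    ref <- suppressWarnings(stats::kmeans(inst$X, inst$k, nstart = 50, iter.max = 100))
    expect_equal(fit$distortion, ref$tot.withinss, tolerance = 1e-6)
  }
})

test_that("fits are bit-identical given the same seed", {
  X <- zscore_profiles(dyad_profiles("B"))
  f1 <- kmeans_fit(X, 2, seed = 7)
  f2 <- kmeans_fit(X, 2, seed = 7)
  expect_identical(f1, f2)
  # well-separated fixture: the optimum is found from any seed
  f3 <- kmeans_fit(X, 2, seed = 99)
  expect_equal(f1$distortion, f3$distortion, tolerance = 1e-12)
})

test_that("elbow scan finds well-separated blob counts and fixture k", {
  set.seed(5)
  # pairwise-equidistant centers (an elbow at k = 3 needs non-colinear blobs)
  centers <- rbind(c(0, 0, 0, 0), c(12, 0, 0, 0), c(6, 6 * sqrt(3), 0, 0))
  blobs <- centers[rep(1:3, each = 10), ] + matrix(rnorm(120), 30, 4)
  scan <- elbow_scan(blobs, k_max = 8, n_restarts = 20, seed = 0)
  expect_equal(scan$chosen_k, 3L)
  expect_true(all(diff(scan$scan$distortion) <= 1e-9))

  zB <- zscore_profiles(dyad_profiles("B"))
  expect_equal(elbow_scan(zB, seed = 0)$chosen_k, 2L)
})

test_that("a linear distortion decay triggers the low-curvature warning", {
  expect_warning(
    sel <- lingsync:::choose_elbow_k(1:8, seq(80, 10, by = -10)),
    "no pronounced elbow"
  )
  expect_equal(sel$chosen_k, 2L)  # ties break toward the smallest k
  expect_true(sel$low_curvature)

  sharp <- lingsync:::choose_elbow_k(1:5, c(100, 20, 15, 12, 10))
  expect_equal(sharp$chosen_k, 2L)
  expect_false(sharp$low_curvature)
})

test_that("elbow scan validates its k range", {
  X <- matrix(rnorm(24), 6, 4)
  expect_error(elbow_scan(X, k_max = 6), class = "lingsync_usage_error")
  expect_error(elbow_scan(X, k_min = 2, k_max = 3), class = "lingsync_usage_error")
})

test_that("cluster centers are the recomputed per-cluster means", {
  z <- zscore_profiles(dyad_profiles("B"))
  fit <- kmeans_fit(z, 2, seed = 0)
  centers <- cluster_centers_table(fit, z)
  expect_equal(as.matrix(centers[, c("analytic", "clout", "authentic", "tone")]),
               fit$centers, tolerance = 1e-9, ignore_attr = TRUE)
  sep <- attr(centers, "separation")
  expect_equal(dim(sep), c(2L, 2L))
  expect_gt(sep[1, 2], 0)

  # the CBT dyad's two clusters split on clout: therapist side high, client low
  a <- fit$assignments
  t_cl <- as.integer(names(which.max(table(a[grepl("^T", names(a))]))))
  c_cl <- setdiff(unique(unname(a)), t_cl)
  expect_gt(centers$clout[centers$cluster == t_cl], 0)
  expect_lt(centers$clout[centers$cluster == c_cl], 0)

  one <- kmeans_fit(z, 1, seed = 0)
  c1 <- cluster_centers_table(one, z)
  expect_lt(max(abs(as.matrix(c1[, c("analytic", "clout", "authentic", "tone")]))), 1e-9)
})

test_that("PCA projection recovers planar data exactly and beats random projections", {
  set.seed(3)
  basis <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  planar <- matrix(rnorm(40), 20, 2) %*% t(basis)  # rank-2 data in 4-D
  proj <- pca_project(planar)
  expect_equal(sum(attr(proj, "var_explained")), 1, tolerance = 1e-9)

  X <- as.matrix(zscore_profiles(dyad_profiles("A"))[, c("analytic", "clout", "authentic", "tone")])
  p <- pca_project(X)
  pca_var <- sum(p$pc1^2 + p$pc2^2)
  for (i in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
    Xc <- scale(X, scale = FALSE)
    expect_lte(sum((Xc %*% Q)^2), pca_var + 1e-9)
  }

  rank1 <- matrix(1:5, 5, 1) %*% matrix(c(1, 2, 0, 0), 1, 4)
  expect_error(pca_project(rank1), class = "lingsync_degenerate_error")
  expect_error(pca_project(X[1:2, ]), class = "lingsync_usage_error")
})

test_that("the CBT dyad polarizes by role in the 2-D projection", {
  z <- zscore_profiles(dyad_profiles("B"))
  proj <- pca_project(z)
  is_t <- grepl("^T", proj$label)
  # linearly separable along the leading component
  expect_true(max(proj$pc1[!is_t]) < min(proj$pc1[is_t]) ||
              max(proj$pc1[is_t]) < min(proj$pc1[!is_t]))
})

test_that("tidiers expose assignments and fit summaries", {
  z <- zscore_profiles(dyad_profiles("B"))
  fit <- kmeans_fit(z, 2, seed = 0)
  td <- tidy(fit)
  expect_equal(names(td), c("label", "cluster"))
  expect_equal(nrow(td), 28L)
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  expect_equal(gl$distortion, fit$distortion)
})
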