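# ---- internal geometry helpers ---------------------------------------------

# coerce a profile tibble or plain numeric matrix to a labeled matrix
as_cluster_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    return(m)
  }
  if (is.data.frame(x)) {
    if (all(sync_vars %in% names(x))) return(profile_values(x))
    num <- vapply(x, is.numeric, logical(1)) & !names(x) %in% c("session", "token_count")
    m <- as.matrix(x[, num, drop = FALSE])
    rownames(m) <- if ("label" %in% names(x)) x$label else as.character(seq_len(nrow(m)))
    return(m)
  }
  abort_usage("Expected a profile data frame or a numeric matrix.")
}

# squared Euclidean distances from every row of X to every row of C
dist2_to_centers <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
}

# k-means++ seeding: each next center drawn with probability proportional to
# the squared distance from the centers already chosen
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      pick <- if (all(d2 <= 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = pmax(d2, 0))
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  centers
}

# Lloyd iterations to an assignment fixpoint (or iter_max); an emptied
# cluster is reseeded at the point farthest from its current center
lloyd_iterate <- function(X, centers, iter_max = 300L) {
  k <- nrow(centers)
  assign_old <- integer(nrow(X))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- dist2_to_centers(X, centers)
    assignment <- max.col(-D, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assignment == j)) {
        far <- which.max(D[cbind(seq_len(nrow(X)), assignment)])
        assignment[far] <- j
      }
    }
    if (identical(assignment, assign_old) || iter > iter_max) break
    assign_old <- assignment
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[assignment == j, , drop = FALSE])
    }
  }
  resid <- X - centers[assignment, , drop = FALSE]
  list(assignment = assignment, centers = centers,
       distortion = sum(resid^2),
       distortion_unsquared = sum(sqrt(rowSums(resid^2))),
       iter = iter)
}

# ---- user-facing operations -------------------------------------------------

#' Fit k-means with k-means++ restarts
#'
#' Lloyd's algorithm run from `n_restarts` k-means++ seedings; the restart
#' with the lowest distortion (total *squared* Euclidean distance of rows to
#' their assigned center) wins. Deterministic given `seed`. Iterations stop
#' at an assignment fixpoint; an emptied cluster is reseeded at the point
#' farthest from its assigned center.
#'
#' @param x Profile tibble (standardize first with [zscore_profiles()] for
#'   the synchrony workflow) or a numeric matrix with one row per object.
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param n_restarts Number of independent k-means++ restarts.
#' @param seed Integer seed controlling all restarts.
#' @param iter_max Cap on Lloyd iterations per restart.
#' @return A `kmeans_solution`: list with `k`, `assignments` (named integer
#'   vector, cluster ids 1..k), `centers`, `distortion`,
#'   `distortion_unsquared`, `sizes`, `n_restarts`, `seed`.
#' @examples
#' pts <- matrix(c(0, 0, 0, 1, 10, 10, 10, 11), ncol = 2, byrow = TRUE)
#' kmeans_fit(pts, k = 2)$distortion
#' @export
kmeans_fit <- function(x, k, n_restarts = 50, seed = 0, iter_max = 300L) {
  X <- as_cluster_matrix(x)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nrow(X)) {
    abort_usage(sprintf("`k` must be between 1 and the number of rows (%d).", nrow(X)))
  }
  if (n_restarts < 1L) abort_usage("`n_restarts` must be >= 1.")
  best <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_iterate(X, kmeanspp_init(X, k), iter_max)
      if (is.null(best) || fit$distortion < best$distortion) best <- fit
    }
    best
  })
  structure(
    list(
      k = k,
      assignments = setNames(best$assignment, rownames(X)),
      centers = best$centers,
      distortion = best$distortion,
      distortion_unsquared = best$distortion_unsquared,
      sizes = tabulate(best$assignment, nbins = k),
      variables = colnames(X),
      n_restarts = n_restarts,
      seed = seed
    ),
    class = "kmeans_solution"
  )
}

#' @export
print.kmeans_solution <- function(x, ...) {
  cat(sprintf("<kmeans_solution> k = %d, n = %d, distortion = %.4f (sizes: %s)\n",
              x$k, length(x$assignments), x$distortion, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.kmeans_solution <- function(x, ...) {
  tibble(label = names(x$assignments), cluster = unname(x$assignments))
}

#' @export
glance.kmeans_solution <- function(x, ...) {
  tibble(k = x$k, n = length(x$assignments), distortion = x$distortion,
         n_restarts = x$n_restarts, seed = x$seed)
}

#' Exact k-means by exhaustive partition enumeration
#'
#' Test oracle: enumerates every partition of the rows into `k` non-empty
#' groups and returns the global minimum of the within-group sum of squares.
#' Refuses instances beyond 10 rows or k > 3.
#'
#' @inheritParams kmeans_fit
#' @return List with `assignments` (integer vector in canonical first-touch
#'   numbering) and `distortion`.
#' @export
brute_force_kmeans <- function(x, k) {
  X <- as_cluster_matrix(x)
  n <- nrow(X)
  k <- as.integer(k)
  if (n > 10L || k > 3L) abort_usage("brute_force_kmeans is capped at 10 rows and k <= 3.")
  if (k < 1L || k > n) abort_usage("`k` out of range.")

  total_sq <- sum(X^2)
  best <- list(distortion = Inf, assignments = NULL)
  score <- function(a) {
    gs <- rowsum(X, a)                       # per-group coordinate sums
    ns <- tabulate(a, nbins = max(a))
    total_sq - sum(gs^2 / ns)
  }
  # restricted-growth strings = canonical set partitions with exactly k blocks
  recurse <- function(a, i, m) {
    if (i > n) {
      if (m == k) {
        d <- score(a)
        if (d < best$distortion) best <<- list(distortion = d, assignments = a)
      }
      return(invisible())
    }
    top <- min(m + 1L, k)
    for (j in seq_len(top)) {
      if (k - max(m, j) <= n - i) {          # enough rows left to fill k blocks
        a[i] <- j
        recurse(a, i + 1L, max(m, j))
      }
    }
  }
  recurse(integer(n), 1L, 0L)
  best$distortion <- max(best$distortion, 0)
  best
}

# second-difference elbow: largest discrete curvature of the distortion
# curve over interior k; ties broken toward the smallest k
choose_elbow_k <- function(ks, distortions) {
  if (length(ks) < 3L) abort_usage("Elbow selection needs at least three k values.")
  interior <- 2:(length(ks) - 1L)
  curv <- distortions[interior - 1L] - 2 * distortions[interior] + distortions[interior + 1L]
  low <- max(curv) < sqrt(.Machine$double.eps) * max(distortions[1L], 1)
  if (low) {
    warn("Distortion curve shows no pronounced elbow; chosen k is unreliable - inspect the elbow plot.")
  }
  list(chosen_k = ks[interior[which.max(curv)]], curvature = curv, low_curvature = low)
}

#' Scan cluster numbers and pick the elbow
#'
#' Fits [kmeans_fit()] for every `k` in `k_min:k_max` and selects the elbow
#' of the distortion curve as the `k` with the largest discrete second
#' difference `d(k-1) - 2 d(k) + d(k+1)` (maximum curvature), ties going to
#' the smaller `k`. The automatic choice is a numerical stand-in for reading
#' the elbow plot by eye; inspect `autoplot()` of the scan and override `k`
#' in [dyad_synchrony()] when your visual judgment differs.
#'
#' If a distortion comes out above the previous k's value (restart
#' underspend), that k is refit with five times the restarts.
#'
#' @inheritParams kmeans_fit
#' @param k_min,k_max Range of cluster numbers scanned (`k_max` at most
#'   `nrow(x) - 1`).
#' @return An `elbow_scan`: list with `scan` (tibble of `k`, `distortion`,
#'   `distortion_unsquared`), `chosen_k`, `low_curvature`.
#' @export
elbow_scan <- function(x, k_min = 1, k_max = 10, n_restarts = 50, seed = 0) {
  X <- as_cluster_matrix(x)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_max > nrow(X) - 1L) {
    abort_usage(sprintf("`k_max` must be at most nrow - 1 (= %d).", nrow(X) - 1L))
  }
  if (k_max - k_min < 2L) abort_usage("Need at least three k values between `k_min` and `k_max`.")
  ks <- k_min:k_max
  fits <- purrr::map(ks, ~ kmeans_fit(X, .x, n_restarts = n_restarts, seed = seed))
  d <- purrr::map_dbl(fits, "distortion")
  for (i in seq_along(ks)[-1]) {
    if (d[i] > d[i - 1L] + 1e-12) {
      warn(sprintf("Distortion increased at k = %d; refitting with %d restarts.",
                   ks[i], 5L * n_restarts))
      refit <- kmeans_fit(X, ks[i], n_restarts = 5L * n_restarts, seed = seed)
      if (refit$distortion < fits[[i]]$distortion) fits[[i]] <- refit
      d[i] <- min(d[i], fits[[i]]$distortion)
    }
  }
  sel <- choose_elbow_k(ks, d)
  structure(
    list(
      scan = tibble(k = ks, distortion = d,
                    distortion_unsquared = purrr::map_dbl(fits, "distortion_unsquared")),
      chosen_k = sel$chosen_k,
      low_curvature = sel$low_curvature,
      n_restarts = n_restarts,
      seed = seed
    ),
    class = "elbow_scan"
  )
}

#' @export
print.elbow_scan <- function(x, ...) {
  cat(sprintf("<elbow_scan> k = %d..%d, chosen k = %d%s\n",
              min(x$scan$k), max(x$scan$k), x$chosen_k,
              if (x$low_curvature) " (low curvature!)" else ""))
  invisible(x)
}

#' @export
tidy.elbow_scan <- function(x, ...) x$scan

#' Cluster-center table with separation diagnostic
#'
#' Recomputes the per-cluster means of every variable (the "cluster
#' centers") from the assignments, a standard validation that the clusters
#' are distinct in magnitude and/or direction. Pairwise Euclidean distances
#' between centers are attached as attribute `"separation"`.
#'
#' @param solution A [kmeans_fit()] solution.
#' @param x The data the solution was fitted on.
#' @return Tibble of `cluster`, `size` and one column per variable, with
#'   attribute `separation` (a k x k distance matrix).
#' @export
cluster_centers_table <- function(solution, x) {
  X <- as_cluster_matrix(x)
  a <- solution$assignments
  if (nrow(X) != length(a)) abort_usage("`solution` was not fitted on `x` (row mismatch).")
  means <- rowsum(X, a) / as.vector(table(a))
  out <- dplyr::bind_cols(
    tibble(cluster = sort(unique(unname(a))), size = as.integer(table(a))),
    as_tibble(means)
  )
  attr(out, "separation") <- as.matrix(stats::dist(means))
  out
}

#' Project a profile matrix onto its top two principal components
#'
#' Column-centers the data and projects it onto the first two right singular
#' vectors, for a 2-D visualization of cluster structure. Sign convention:
#' each component is flipped so that its largest-magnitude loading is
#' positive.
#'
#' @param x Profile tibble or numeric matrix with at least 3 rows and rank
#'   at least 2.
#' @return A `pca_projection`: tibble of `label`, `pc1`, `pc2` with attribute
#'   `var_explained` (fractions of variance captured by the two components).
#' @export
pca_project <- function(x) {
  X <- as_cluster_matrix(x)
  if (nrow(X) < 3L) abort_usage("PCA projection needs at least 3 rows.")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  s <- svd(Xc)
  if (length(s$d) < 2L || s$d[2] <= max(s$d) * 1e-10) {
    abort_degenerate("Data matrix has rank < 2; cannot project to two dimensions.")
  }
  flip <- vapply(1:2, function(j) {
    v <- s$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(s$u[, 1:2] %*% diag(s$d[1:2]), 2, flip, `*`)
  out <- tibble(label = rownames(X), pc1 = coords[, 1], pc2 = coords[, 2])
  attr(out, "var_explained") <- s$d[1:2]^2 / sum(s$d^2)
  class(out) <- c("pca_projection", class(out))
  out
}
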