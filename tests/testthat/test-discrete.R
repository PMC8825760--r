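# k-means clustering, centroid distances, relabelling, and the k sweep.

make_clusters <- function(labels, centroids) {
  structure(list(labels = as.integer(labels), k = nrow(centroids),
                 centroids = centroids), class = "ps_clusters")
}

test_that("k equal to the number of distinct points gives singleton clusters", {
  X <- cbind(c(0, 2, 5, 9, 14, 20), c(1, 0, 3, 2, 8, 5))
  cl <- kmeans_cluster(X, k = 6, seed = 1)
  expect_identical(sort(tabulate(cl$labels, 6)), rep(1L, 6))
  expect_equal(cl$centroids[cl$labels, ], unname(X))
})

test_that("two well-separated blobs are recovered at k = 2", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
             matrix(rnorm(60, 50, 0.1), ncol = 2))
  truth <- rep(1:2, each = 30)
  cl <- kmeans_cluster(X, k = 2, seed = 9)
  expect_equal(length(unique(cl$labels[truth == 1])), 1L)
  expect_equal(length(unique(cl$labels[truth == 2])), 1L)
  expect_false(cl$labels[1] == cl$labels[31])
})

test_that("clusters on a noiseless spiral are contiguous in t", {
  d <- simulate_trajectory("spiral2d", t_max = 3, noise_sd = 0)
  cl <- kmeans_cluster(d$coords, k = 10, seed = 5)
  ranges <- t(sapply(1:10, function(g) range(d$t[cl$labels == g])))
  o <- order(ranges[, 1])
  expect_true(all(ranges[o[-1], 1] > ranges[o[-10], 2]))  # no t-range overlap
})

test_that("kmeans guards its inputs", {
  X <- matrix(rep(c(0, 1), each = 6), ncol = 2)     # 2 distinct rows
  expect_error(kmeans_cluster(X, k = 3, seed = 1), class = "ps_skip")
  X[1, 1] <- NA
  expect_error(kmeans_cluster(X, k = 2, seed = 1), class = "ps_invalid_input")
})

test_that("centroid distance matrix is Euclidean and handles degenerate centroids", {
  cl <- make_clusters(c(1, 1, 2), rbind(0, 3))
  expect_equal(centroid_distance_matrix(cl)[1, 2], 3)
  cl2 <- make_clusters(c(1, 2), rbind(c(0, 0), c(3, 4)))
  expect_equal(centroid_distance_matrix(cl2)[1, 2], 5)
  cl3 <- make_clusters(c(1, 2), rbind(c(1, 1), c(1, 1)))
  expect_true(all(centroid_distance_matrix(cl3) == 0))
})

test_that("relabelling follows the path positionally", {
  cl <- make_clusters(c(1, 1, 3, 2), matrix(0, 3, 1))
  path <- c(3L, 1L, 2L)
  expect_identical(relabel_to_pseudotime(cl, path), c(1L, 1L, 0L, 2L))
  expect_identical(relabel_to_pseudotime(cl, 1:3), cl$labels - 1L)
  fwd <- relabel_to_pseudotime(cl, path)
  expect_identical(relabel_to_pseudotime(cl, rev(path)), 2L - fwd)
  expect_error(relabel_to_pseudotime(cl, c(1L, 2L)), class = "ps_invalid_input")
})

test_that("sweep columns on a line are monotone and use every label", {
  X <- cbind(seq(0, 10, length.out = 200), 0)
  ps <- sweep_pseudotimes(X, kmin = 2, kmax = 10, seed = 4)
  expect_identical(ps$k_values, 2:10)
  for (j in seq_along(ps$k_values)) {
    col <- ps$matrix[, j]
    expect_setequal(unique(col), 0:(ps$k_values[j] - 1))
    d <- diff(col)                              # monotone along the line
    expect_true(all(d >= 0) || all(d <= 0))
    if (ps$k_values[j] >= 4) expect_gt(abs(cor(col, X[, 1], method = "spearman")), 0.95)
  }
})

test_that("sweep truncates kmax at the distinct-point count", {
  X <- cbind(1:8, 0)
  expect_message(ps <- sweep_pseudotimes(X, kmin = 2, kmax = 100, seed = 1),
                 "truncated")
  expect_identical(ps$k_values, 2:8)
})

test_that("sweep is bit-identical for a fixed seed and order invariant", {
  set.seed(8)
  X <- matrix(rnorm(300), ncol = 3)
  a <- sweep_pseudotimes(X, kmax = 8, seed = 123)
  b <- sweep_pseudotimes(X, kmax = 8, seed = 123)
  expect_identical(a$matrix, b$matrix)
  perm <- sample(nrow(X))
  c <- sweep_pseudotimes(X[perm, ], kmax = 8, seed = 123)
  expect_identical(unname(c$matrix[order(perm), ]), unname(a$matrix))
})

test_that("sub-seeds for one k do not depend on the rest of the range", {
  X <- matrix(rnorm(400, sd = 3), ncol = 2)
  wide <- sweep_pseudotimes(X, kmin = 2, kmax = 12, seed = 77)
  narrow <- sweep_pseudotimes(X, kmin = 7, kmax = 7, seed = 77)
  expect_identical(narrow$matrix[, 1], wide$matrix[, wide$k_values == 7])
})
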