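# Discrete pseudotimes: k-means clustering relabelled along the shortest
# Hamiltonian path through the centroids, swept over a range of k.

new_clusters <- function(labels, k, centroids) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 centroids = centroids),
            class = "ps_clusters")
}

#' Cluster an embedding with k-means
#'
#' Runs `stats::kmeans()` (Hartigan-Wong, random data rows as initial
#' centroids, `iter.max = 100`) `nstart` times and keeps the run with the
#' lowest within-cluster sum of squares. The RNG state is set from `seed`
#' so results are reproducible. Centroids are recomputed as per-cluster
#' means of the assigned cells so they exactly satisfy the centroid
#' invariant. `nstart = 1` is the pipeline default: a deliberately
#' low-robustness clustering makes the ensemble columns more dissimilar,
#' which is what the ensemble feeds on.
#'
#' @param X numeric cells x dims embedding matrix.
#' @param k number of clusters (>= 2).
#' @param nstart number of random initialisations (best of).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return a `ps_clusters`: `labels` (1..k per cell, every cluster
#'   non-empty), `k`, `centroids` (k x dims).
#' @export
kmeans_cluster <- function(X, k, nstart = 1L, seed = NULL) {
  X <- check_matrix(X, min_rows = 2L, what = "embedding")
  if (k < 2L) ps_stop("k must be >= 2", "ps_invalid_input")
  if (nstart < 1L) ps_stop("nstart must be >= 1", "ps_invalid_param")
  n_distinct <- nrow(unique(X))
  if (k > n_distinct) {
    ps_stop(sprintf("k = %d exceeds the %d distinct rows", k, n_distinct), "ps_skip")
  }
  if (!is.null(seed)) set.seed(seed)

  if (k == n_distinct) {
    # Hartigan-Wong needs k < n; with one cluster per distinct row the
    # optimum (zero within-cluster SS) is known directly.
    U <- unique(X)
    tU <- t(U)
    labels <- vapply(seq_len(nrow(X)), function(i) {
      which.max(colSums(abs(tU - X[i, ])) == 0)
    }, integer(1))
    return(new_clusters(labels, k, U))
  }

  fit <- NULL
  for (attempt in 0:3) {             # rare kmeans failures: retry, then skip
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = k, nstart = nstart,
                                     iter.max = 100L)),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$cluster)) == k) break
    fit <- NULL
  }
  if (is.null(fit)) {
    ps_stop(sprintf("k-means failed to produce %d non-empty clusters", k), "ps_skip")
  }
  centroids <- rowsum(X, fit$cluster) / tabulate(fit$cluster, nbins = k)
  rownames(centroids) <- NULL
  new_clusters(fit$cluster, k, centroids)
}

#' Euclidean distance matrix between cluster centroids
#'
#' @param clusters a `ps_clusters` from [kmeans_cluster()].
#' @return k x k symmetric matrix of centroid distances.
#' @export
centroid_distance_matrix <- function(clusters) {
  if (!inherits(clusters, "ps_clusters")) {
    ps_stop("expected a ps_clusters object", "ps_invalid_input")
  }
  if (clusters$k < 2L) ps_stop("need at least 2 clusters", "ps_invalid_input")
  as.matrix(stats::dist(clusters$centroids))
}

#' Relabel a clustering into a discrete pseudotime
#'
#' Renames cluster labels so that label order follows the Hamiltonian path:
#' the cluster at position j of `path$order` becomes label j - 1, giving
#' per-cell integers 0..k-1 in which consecutive values are adjacent
#' clusters on the path.
#'
#' @param clusters a `ps_clusters`.
#' @param path a `ham_path` over the same k clusters.
#' @return integer vector of per-cell discrete pseudotimes in 0..k-1.
#' @export
relabel_to_pseudotime <- function(clusters, path) {
  if (inherits(path, "ham_path")) path <- path$order
  k <- clusters$k
  if (length(path) != k || !setequal(path, seq_len(k))) {
    ps_stop("path order must be a permutation of 1..k", "ps_invalid_input")
  }
  if (any(clusters$labels < 1L | clusters$labels > k)) {
    ps_stop("cluster labels outside 1..k", "ps_invalid_input")
  }
  match(clusters$labels, path) - 1L
}

#' Sweep discrete pseudotimes over a range of k
#'
#' For each k in `kmin:kmax` (truncated to the number of distinct rows):
#' k-means clustering, centroid distance matrix, greedy shortest Hamiltonian
#' path, relabelling. Each k gets a deterministic sub-seed from
#' [mix_seed()], so adding or removing k values never perturbs the other
#' columns. Infeasible k values are skipped and recorded, never fatal.
#'
#' The sweep is cell-order invariant: cells are put into a canonical
#' (lexicographic) order internally before clustering and mapped back, so
#' permuting the input rows permutes the output rows identically and the
#' only source of randomness is `seed`.
#'
#' @param X numeric cells x dims embedding matrix (>= 3 cells).
#' @param kmin,kmax cluster-count range (defaults 2 and 100).
#' @param nstart k-means initialisations per k (default 1).
#' @param seed integer base seed.
#' @return a `ps_pseudotime_set`: `matrix` (cells x m, column `j` holding
#'   values in `0..k_values[j]-1`), `k_values`, `k_skipped`.
#' @export
#' @examples
#' X <- cbind(seq(0, 1, length.out = 50), 0)
#' ps <- sweep_pseudotimes(X, kmin = 2, kmax = 6, seed = 1)
#' ps$k_values
sweep_pseudotimes <- function(X, kmin = 2L, kmax = 100L, nstart = 1L, seed = 1L) {
  X <- check_matrix(X, min_rows = 3L, what = "embedding")
  if (kmin < 2L) ps_stop("kmin must be >= 2", "ps_invalid_param")
  if (kmin > kmax) ps_stop("kmin must not exceed kmax", "ps_invalid_param")

  # canonical cell order: makes the sweep invariant to input row order
  canon <- do.call(order, as.data.frame(X))
  X <- X[canon, , drop = FALSE]

  n_distinct <- nrow(unique(X))
  k_upper <- min(kmax, n_distinct)
  if (k_upper < kmax) {
    message(sprintf("kmax truncated from %d to %d (distinct rows)", kmax, k_upper))
  }
  if (kmin > k_upper) {
    ps_stop(sprintf("fewer distinct rows (%d) than kmin (%d)", n_distinct, kmin),
            "ps_invalid_input")
  }

  ks <- seq.int(kmin, k_upper)
  cols <- vector("list", length(ks))
  ok <- logical(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    res <- tryCatch({
      cl <- kmeans_cluster(X, k, nstart = nstart, seed = mix_seed(seed, k))
      D <- centroid_distance_matrix(cl)
      relabel_to_pseudotime(cl, greedy_hamiltonian_path(D))
    }, ps_skip = function(e) {
      message(sprintf("skipping k = %d: %s", k, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      cols[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) ps_stop("no feasible k value in the requested range", "ps_degenerate")

  mat <- do.call(cbind, cols[ok])
  mat[canon, ] <- mat                       # back to input cell order
  colnames(mat) <- paste0("k=", ks[ok])
  structure(list(matrix = mat, k_values = ks[ok], k_skipped = ks[!ok],
                 kmin = as.integer(kmin), kmax = as.integer(kmax)),
            class = "ps_pseudotime_set")
}

#' @export
print.ps_pseudotime_set <- function(x, ...) {
  cat("Discrete pseudotime set:", nrow(x$matrix), "cells x",
      ncol(x$matrix), "k values (", min(x$k_values), "..", max(x$k_values), ")\n")
  if (length(x$k_skipped)) cat("  skipped k:", paste(x$k_skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Export a discrete pseudotime set as TSV
#'
#' Writes the cells x k matrix with its `k=` column headers for inspection.
#'
#' @param pset a `ps_pseudotime_set`.
#' @param path output file path.
#' @export
write_pseudotime_set <- function(pset, path) {
  utils::write.table(pset$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
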