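# Shortest Hamiltonian path over a cluster-centroid distance matrix.
#
# The greedy solver is Kruskal's minimum-spanning-tree algorithm with the
# extra degree-2 constraint: edges are admitted in non-decreasing weight
# order, skipping any edge that would close a cycle or give a vertex more
# than two incident edges. The admitted edges form a single simple path
# through all k vertices (a degree-constrained MST with degree cap 2).

# Validate a centroid distance matrix: square, symmetric, zero diagonal,
# non-negative, finite, k >= 2.
check_distance_matrix <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    ps_stop("distance matrix must be a square numeric matrix", "ps_invalid_input")
  }
  k <- nrow(D)
  if (k < 2L) ps_stop("distance matrix needs k >= 2 vertices", "ps_invalid_input")
  if (anyNA(D) || any(!is.finite(D))) {
    ps_stop("distance matrix contains non-finite values", "ps_invalid_input")
  }
  if (any(D < 0)) ps_stop("distance matrix has negative entries", "ps_invalid_input")
  if (any(abs(D - t(D)) > 1e-8 * (1 + max(abs(D))))) {
    ps_stop("distance matrix is not symmetric", "ps_invalid_input")
  }
  if (any(diag(D) != 0)) ps_stop("distance matrix diagonal must be zero", "ps_invalid_input")
  D
}

new_ham_path <- function(order, length) {
  structure(list(order = as.integer(order), length = as.numeric(length)),
            class = "ham_path")
}

#' @export
print.ham_path <- function(x, ...) {
  cat("Hamiltonian path over", length(x$order), "vertices, length",
      format(x$length), "\n  order:", paste(x$order, collapse = " - "), "\n")
  invisible(x)
}

#' Greedy shortest Hamiltonian path through cluster centroids
#'
#' Kruskal-style greedy heuristic for the shortest Hamiltonian path
#' (equivalently, a degree-constrained MST with degree cap 2): candidate
#' edges are sorted by `(weight, smaller index, larger index)` and admitted
#' unless they would create a cycle (union-find with path compression) or
#' raise a vertex degree above two. The fixed tie-break makes the result
#' deterministic for a given matrix. A path and its reversal are equivalent;
#' the returned orientation is canonical (smaller endpoint first).
#'
#' @param D square symmetric non-negative distance matrix with zero diagonal
#'   (e.g. Euclidean distances between k-means centroids), k >= 2.
#' @return a `ham_path`: list with `order` (permutation of `1:k`) and
#'   `length` (sum of consecutive-pair distances).
#' @seealso [brute_force_hamiltonian_path()] for the exact small-k solver,
#'   [path_length()].
#' @export
#' @examples
#' D <- as.matrix(dist(c(0, 10, 1, 11, 2)))
#' greedy_hamiltonian_path(D)  # visits 1,3,5 then 2,4: length 11
greedy_hamiltonian_path <- function(D) {
  D <- check_distance_matrix(D)
  k <- nrow(D)
  if (k == 2L) return(new_ham_path(c(1L, 2L), D[1, 2]))

  ut <- which(upper.tri(D), arr.ind = TRUE)   # row < col for every entry
  w <- D[upper.tri(D)]
  o <- order(w, ut[, 1L], ut[, 2L])           # weight, then min, then max index

  parent <- seq_len(k)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  deg <- integer(k)
  adj <- vector("list", k)
  n_edges <- 0L
  total <- 0

  for (e in o) {
    i <- ut[e, 1L]; j <- ut[e, 2L]
    if (deg[i] >= 2L || deg[j] >= 2L) next
    ri <- find_root(i); rj <- find_root(j)
    if (ri == rj) next                        # would close a cycle
    parent[ri] <- rj
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    total <- total + D[i, j]
    n_edges <- n_edges + 1L
    if (n_edges == k - 1L) break
  }
  if (n_edges != k - 1L) {
    ps_stop("greedy path construction admitted fewer than k-1 edges", "ps_internal")
  }

  ends <- which(deg == 1L)
  cur <- min(ends); prev <- 0L
  ord <- integer(k)
  for (s in seq_len(k)) {
    ord[s] <- cur
    nxt <- adj[[cur]][adj[[cur]] != prev]
    prev <- cur
    cur <- if (length(nxt)) nxt[1L] else NA_integer_
  }
  if (ord[1L] > ord[k]) ord <- rev(ord)
  new_ham_path(ord, total)
}

# All permutations of v as a matrix (one per row); factorial growth, callers
# must guard k.
all_permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], all_permutations(v[-i]))
  }))
}

# Memoised undirected orderings of 1:k (first < last), shared across calls.
.perm_cache <- new.env(parent = emptyenv())
undirected_orderings <- function(k) {
  key <- as.character(k)
  if (is.null(.perm_cache[[key]])) {
    p <- all_permutations(seq_len(k))
    .perm_cache[[key]] <- p[p[, 1L] < p[, k], , drop = FALSE]
  }
  .perm_cache[[key]]
}

#' Exact shortest Hamiltonian path by exhaustive enumeration
#'
#' Enumerates all k!/2 undirected vertex orderings and returns a global
#' minimum. Intended as a testing oracle for the greedy heuristic; refuses
#' k > 10. Ties are broken by lexicographically smallest order so the result
#' is deterministic; the orientation is canonical (smaller endpoint first).
#'
#' @inheritParams greedy_hamiltonian_path
#' @return a `ham_path` of globally minimal length.
#' @export
brute_force_hamiltonian_path <- function(D) {
  D <- check_distance_matrix(D)
  k <- nrow(D)
  if (k > 10L) {
    ps_stop("exact enumeration is limited to k <= 10 (k! orderings)", "ps_size")
  }
  if (k == 2L) return(new_ham_path(c(1L, 2L), D[1, 2]))

  perms <- undirected_orderings(k)
  lens <- Reduce(`+`, lapply(seq_len(k - 1L), function(j) {
    D[cbind(perms[, j], perms[, j + 1L])]
  }))
  best <- which(lens <= min(lens) + 0)          # exact ties
  if (length(best) > 1L) {                      # lexicographic tie-break
    cand <- perms[best, , drop = FALSE]
    ordc <- do.call(order, as.data.frame(cand))
    best <- best[ordc[1L]]
  }
  new_ham_path(perms[best, ], lens[best])
}

#' Length of a Hamiltonian path under a distance matrix
#'
#' Sum of distances over consecutive vertex pairs; invariant under reversal
#' of the order.
#'
#' @inheritParams greedy_hamiltonian_path
#' @param order a permutation of `1:nrow(D)`, or a `ham_path`.
#' @return non-negative scalar.
#' @export
path_length <- function(D, order) {
  D <- check_distance_matrix(D)
  if (inherits(order, "ham_path")) order <- order$order
  k <- nrow(D)
  if (length(order) != k || !setequal(order, seq_len(k))) {
    ps_stop("order must be a permutation of 1..k", "ps_invalid_input")
  }
  order <- as.integer(order)
  sum(D[cbind(order[-k], order[-1L])])
}
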