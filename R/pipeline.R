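# End-to-end pipeline: dimensionality reduction -> discrete pseudotime
# sweep -> ensemble aggregation -> LOESS smoothing.

# Shared ensemble + fallback logic: returns the crude pseudotime plus
# provenance. A single-column set short-circuits PCA (min-max scaling is
# the only sensible aggregate); loading-based selection falls back to the
# PC1 pseudotime when it retains fewer than two columns.
ensemble_crude <- function(P, aggregation = c("selection", "pc1")) {
  aggregation <- match.arg(aggregation)
  if (ncol(P$matrix) == 1L) {
    crude <- structure(list(values = rescale01(P$matrix[, 1L]),
                            n_selected = 1L, selected_k = P$k_values),
                       class = "ps_crude")
    return(list(crude = crude, fallback = TRUE, aggregation = aggregation))
  }
  if (aggregation == "pc1") {
    return(list(crude = first_pc_pseudotime(P), fallback = FALSE,
                aggregation = "pc1"))
  }
  L <- pseudotime_loadings(P)
  sel <- select_correlated(L)
  if (length(sel) < 2L) {
    list(crude = first_pc_pseudotime(P), fallback = TRUE, aggregation = "pc1")
  } else {
    list(crude = aggregate_pseudotimes(P, L, sel), fallback = FALSE,
         aggregation = "selection")
  }
}

#' Infer a continuous linear pseudotime from an embedding
#'
#' The full four-step ensemble: (1) for every k in `kmin:kmax`, k-means
#' clustering relabelled along the greedy shortest Hamiltonian path through
#' the centroids gives a discrete pseudotime; (2) the columns are
#' aggregated -- either by PCA-loading selection (columns loading more on
#' PC1 than PC2, min-max scaled, direction-aligned, averaged) or directly
#' by PC1 scores -- into a crude pseudotime; (3) LOESS smoothing of the
#' crude values against their ranking; (4) min-max rescaling to `[0, 1]`.
#' The direction of the result is arbitrary; flip it with
#' [flip_pseudotime()] when marker genes identify the start.
#'
#' For a fixed seed the run is fully deterministic, and the pipeline is
#' cell-order invariant (computation happens in a canonical internal cell
#' order), so permuting the input rows permutes the output identically.
#'
#' @param X numeric cells x dims embedding matrix (>= 3 cells), e.g. the
#'   `coords` of a [simulate_trajectory()] dataset or the output of
#'   [reduce_dimensions()].
#' @param kmin,kmax k-means cluster-count range (defaults 2 and 100;
#'   truncated to the number of distinct rows).
#' @param nstart k-means initialisations per k (default 1; see
#'   [kmeans_cluster()] for why low is good here).
#' @param span,degree LOESS parameters (defaults 0.1 and 2).
#' @param seed integer seed; fans out deterministically to per-k sub-seeds.
#' @param aggregation `"selection"` (default) or `"pc1"`.
#' @return a `ps_run`: `pseudotime` (per-cell values in `[0, 1]`), `crude`,
#'   and a `report` listing k values computed and skipped, `n_selected`,
#'   the selected k values, the aggregation used and whether the PC1
#'   fallback was triggered.
#' @export
#' @examples
#' d <- simulate_trajectory("sine", noise_sd = 0.2, seed = 1)
#' run <- shape_pseudotime(d$coords, kmax = 20, seed = 1)
#' score_pseudotime(run$pseudotime, d$t)
shape_pseudotime <- function(X, kmin = 2L, kmax = 100L, nstart = 1L,
                             span = 0.1, degree = 2L, seed = 1L,
                             aggregation = c("selection", "pc1")) {
  aggregation <- match.arg(aggregation)
  X <- check_matrix(X, min_rows = 3L, what = "embedding")

  # run the whole pipeline in canonical cell order (so rank tie-breaks in
  # the smoother cannot depend on input row order) and map back at the end
  canon <- do.call(order, as.data.frame(X))
  Xc <- X[canon, , drop = FALSE]

  P <- with_stage("sweep", sweep_pseudotimes(Xc, kmin = kmin, kmax = kmax,
                                             nstart = nstart, seed = seed))
  agg <- with_stage("ensemble", ensemble_crude(P, aggregation))
  smoothed <- with_stage("smoothing",
                         smooth_pseudotime(agg$crude, span = span, degree = degree))
  pseudotime <- crude <- numeric(nrow(X))
  pseudotime[canon] <- smoothed
  crude[canon] <- agg$crude$values

  structure(list(
    pseudotime = pseudotime,
    crude = crude,
    report = list(
      n_cells = nrow(X),
      k_values = P$k_values,
      k_skipped = P$k_skipped,
      n_selected = agg$crude$n_selected,
      selected_k = agg$crude$selected_k,
      aggregation = agg$aggregation,
      fallback = agg$fallback,
      params = list(kmin = kmin, kmax = kmax, nstart = nstart, span = span,
                    degree = degree, seed = seed)
    )
  ), class = "ps_run")
}

#' @export
print.ps_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("Pseudotime run: %d cells, %d discrete pseudotimes (k %d..%d%s)\n",
              r$n_cells, length(r$k_values), min(r$k_values), max(r$k_values),
              if (length(r$k_skipped)) sprintf(", %d skipped", length(r$k_skipped)) else ""))
  cat(sprintf("  aggregation: %s (%d columns selected%s)\n", r$aggregation,
              r$n_selected, if (r$fallback) ", fallback to PC1" else ""))
  cat("  pseudotime range:", format(range(x$pseudotime)), "\n")
  invisible(x)
}

#' Reverse the direction of a pseudotime
#'
#' Returns `1 - p` elementwise: an involution that flips the arbitrary
#' direction of an inferred pseudotime (the choice of start is left to the
#' user, e.g. via marker genes).
#'
#' @param p numeric pseudotime vector in `[0, 1]`, or a `ps_run`.
#' @return flipped pseudotime vector.
#' @export
flip_pseudotime <- function(p) {
  if (inherits(p, "ps_run")) p <- p$pseudotime
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    ps_stop("pseudotime must be numeric in [0, 1]", "ps_invalid_input")
  }
  1 - p
}

#' Reduce an expression matrix to a low-dimensional embedding
#'
#' Standard preprocessing ahead of pseudotime inference: `"pca"` keeps the
#' top `n_pcs` principal-component scores of the centered data; `"pca_tsne"`
#' (the default workflow for scRNA-seq) embeds those scores with t-SNE into
#' `tsne_dims` dimensions at the configured perplexity; `"none"` passes the
#' input through. Components beyond the numerical rank of the data are
#' dropped with a warning. t-SNE (via the Rtsne package) is seeded through
#' the same deterministic seed fan-out as the rest of the pipeline.
#'
#' @param E a `ps_expression` from [read_expression()], or a numeric
#'   cells x genes matrix.
#' @param method `"pca_tsne"`, `"pca"` or `"none"`.
#' @param n_pcs number of principal components (default 50).
#' @param tsne_dims t-SNE output dimensionality (default 3).
#' @param perplexity t-SNE perplexity (default 30); must satisfy
#'   `3 * perplexity < cells - 1`.
#' @param seed integer seed.
#' @return numeric cells x d embedding matrix.
#' @export
reduce_dimensions <- function(E, method = c("pca_tsne", "pca", "none"),
                              n_pcs = 50L, tsne_dims = 3L, perplexity = 30,
                              seed = 1L) {
  method <- match.arg(method)
  X <- if (inherits(E, "ps_expression")) E$values else E
  X <- check_matrix(X, min_rows = 1L, what = "expression")
  if (method == "none") return(X)

  n <- nrow(X)
  if (method == "pca_tsne") {
    if (n < 10L) ps_stop("pca_tsne needs at least 10 cells", "ps_invalid_input")
    if (3 * perplexity >= n - 1) {
      ps_stop(sprintf("perplexity %g too large for %d cells (need 3*perplexity < n-1)",
                      perplexity, n), "ps_invalid_param")
    }
    if (!requireNamespace("Rtsne", quietly = TRUE)) {
      ps_stop("the Rtsne package is required for method = 'pca_tsne'", "ps_invalid_param")
    }
  }
  max_pcs <- min(n - 1L, ncol(X))
  if (n_pcs > max_pcs) {
    warning(sprintf("n_pcs truncated from %d to %d (matrix size)", n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nonzero <- sum(pr$sdev > max(pr$sdev) * 1e-8)
  if (n_pcs > nonzero) {
    warning(sprintf("only %d components have non-zero variance; dropping the rest",
                    nonzero))
    n_pcs <- nonzero
  }
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  if (method == "pca") return(scores)

  set.seed(mix_seed(seed, 104729L))
  Rtsne::Rtsne(scores, dims = tsne_dims, perplexity = perplexity,
               pca = FALSE, check_duplicates = FALSE, verbose = FALSE)$Y
}
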