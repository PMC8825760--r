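# Ensemble aggregation of discrete pseudotimes via PCA loadings.
#
# The set of discrete pseudotimes is standardized and decomposed with PCA.
# Columns that load more on PC1 than on PC2 form the largest mutually
# correlating subset; those are min-max scaled, direction-aligned using the
# loading signs, and averaged into a crude continuous pseudotime. Using PC1
# scores directly is kept as the alternative aggregation mode.

# Accept either a ps_pseudotime_set or a bare matrix of columns.
as_pset <- function(P) {
  if (inherits(P, "ps_pseudotime_set")) return(P)
  P <- check_matrix(P, min_rows = 3L, what = "pseudotime set")
  structure(list(matrix = P, k_values = seq_len(ncol(P)), k_skipped = integer(0)),
            class = "ps_pseudotime_set")
}

#' PCA loadings of a discrete pseudotime set
#'
#' Standardizes every column (zero mean, unit variance; zero-variance
#' columns are dropped with a message) and computes the first two principal
#' components with `stats::prcomp`. Loadings are the unit-norm eigenvectors
#' of the column correlation structure. Each eigenvector's sign is fixed so
#' that its largest-magnitude entry is positive, making results
#' deterministic.
#'
#' @param P a `ps_pseudotime_set` from [sweep_pseudotimes()], or a numeric
#'   matrix with one discrete pseudotime per column.
#' @return a `ps_loadings`: `pc1`, `pc2` (per retained column), `pc1_sign`,
#'   `explained_variance` (fractions for PC1/PC2), `columns` (indices of
#'   retained columns in `P`), `k_values` (their k), and the fitted
#'   `prcomp` object in `fit`.
#' @export
pseudotime_loadings <- function(P) {
  P <- as_pset(P)
  M <- P$matrix
  if (ncol(M) < 2L) ps_stop("need at least 2 pseudotime columns for PCA", "ps_invalid_input")
  if (nrow(M) < 3L) ps_stop("need at least 3 cells for PCA", "ps_invalid_input")

  sds <- apply(M, 2L, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) == 0L) ps_stop("all pseudotime columns are constant", "ps_degenerate")
  if (length(keep) < ncol(M)) {
    message(sprintf("dropping %d zero-variance column(s) before PCA",
                    ncol(M) - length(keep)))
  }
  if (length(keep) < 2L) {
    ps_stop("fewer than 2 non-constant pseudotime columns", "ps_degenerate")
  }

  fit <- stats::prcomp(M[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  rot <- fit$rotation
  for (j in 1:2) {                      # deterministic sign convention
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  pc1 <- rot[, 1L]
  structure(list(
    pc1 = unname(pc1),
    pc2 = unname(rot[, 2L]),
    pc1_sign = ifelse(pc1 >= 0, 1L, -1L),
    explained_variance = ev[1:2],
    columns = keep,
    k_values = P$k_values[keep],
    fit = fit
  ), class = "ps_loadings")
}

#' Select the mutually correlating pseudotime columns
#'
#' Returns the columns that contribute more to the first principal component
#' than to the second, judged by absolute loadings (`|pc1| > |pc2|`); signs
#' only encode direction. This picks out the largest subset of mutually
#' correlated pseudotimes and drops columns uncorrelated with it. If fewer
#' than 2 columns qualify, the caller should fall back to
#' [first_pc_pseudotime()].
#'
#' @param loadings a `ps_loadings` from [pseudotime_loadings()].
#' @return integer indices into the retained columns of `loadings`.
#' @export
select_correlated <- function(loadings) {
  if (!inherits(loadings, "ps_loadings")) {
    ps_stop("expected a ps_loadings object", "ps_invalid_input")
  }
  which(abs(loadings$pc1) > abs(loadings$pc2))
}

#' Average selected discrete pseudotimes into a crude pseudotime
#'
#' Each selected column is min-max scaled to `[0, 1]`; columns whose PC1
#' loading is negative are flipped (`x -> 1 - x`) so all run in the same
#' direction; the per-cell mean is taken and min-max rescaled. The global
#' direction of the result is arbitrary.
#'
#' @param P the `ps_pseudotime_set` (or matrix) the loadings were fit on.
#' @param loadings a `ps_loadings` for `P`.
#' @param selected indices into the retained columns (from
#'   [select_correlated()]); must be non-empty.
#' @return a `ps_crude`: `values` in `[0, 1]`, `n_selected`, `selected_k`.
#' @export
aggregate_pseudotimes <- function(P, loadings, selected) {
  P <- as_pset(P)
  if (length(selected) == 0L) ps_stop("empty column selection", "ps_invalid_input")
  cols <- loadings$columns[selected]
  M <- P$matrix[, cols, drop = FALSE]
  M <- apply(M, 2L, rescale01)
  flip <- loadings$pc1[selected] < 0
  M[, flip] <- 1 - M[, flip, drop = FALSE]
  structure(list(
    values = rescale01(rowMeans(M)),
    n_selected = length(selected),
    selected_k = loadings$k_values[selected]
  ), class = "ps_crude")
}

#' First-principal-component pseudotime
#'
#' The alternative aggregation: per-cell scores on PC1 of the standardized
#' pseudotime set, min-max scaled to `[0, 1]`. Used as the fallback when
#' loading-based selection retains fewer than two columns, and by the
#' aggregation-mode comparison.
#'
#' @inheritParams pseudotime_loadings
#' @return a `ps_crude` with `n_selected` equal to the number of retained
#'   columns.
#' @export
first_pc_pseudotime <- function(P) {
  P <- as_pset(P)
  L <- pseudotime_loadings(P)
  structure(list(
    values = rescale01(L$fit$x[, 1L]),
    n_selected = length(L$columns),
    selected_k = L$k_values
  ), class = "ps_crude")
}
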