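# Evaluation against ground truth and the parameter/ablation experiments.

#' Score a pseudotime against a ground-truth progression
#'
#' Both vectors are min-max scaled to `[0, 1]`; the pseudotime is flipped
#' (`1 - p`) if its Pearson correlation with the truth is negative, since
#' trajectory direction is arbitrary. Returns the RMSE on the aligned
#' rescaled vectors plus absolute Pearson and Spearman correlations. The
#' internal rescaling makes the score invariant to increasing affine
#' transforms of either vector.
#'
#' @param p inferred pseudotime (numeric vector or `ps_run`).
#' @param t ground-truth progression, same length, not constant.
#' @return list with `rmse`, `pearson_abs`, `spearman_abs`, `flipped`.
#' @export
score_pseudotime <- function(p, t) {
  if (inherits(p, "ps_run")) p <- p$pseudotime
  if (length(p) != length(t) || length(p) < 3L) {
    ps_stop("p and t must be equal-length vectors of >= 3 cells", "ps_invalid_input")
  }
  if (length(unique(t)) == 1L) ps_stop("ground truth is constant", "ps_invalid_input")
  if (length(unique(p)) == 1L) ps_stop("pseudotime is constant", "ps_invalid_input")
  ps <- rescale01(p)
  ts <- rescale01(t)
  r <- stats::cor(ps, ts)
  flipped <- r < 0
  if (flipped) ps <- 1 - ps
  list(
    rmse = sqrt(mean((ps - ts)^2)),
    pearson_abs = abs(r),
    spearman_abs = abs(stats::cor(p, t, method = "spearman")),
    flipped = flipped
  )
}

#' Compare the two aggregation modes across datasets
#'
#' For each dataset the discrete pseudotime sweep is computed once (so both
#' modes see the identical clusterings and seeds) and aggregated both by
#' loading-based selection and by direct PC1 scores; each crude pseudotime
#' is smoothed and scored against the ground truth.
#'
#' @param datasets list of `ps_trajectory` objects (e.g. from
#'   [simulate_suite()]).
#' @param kmin,kmax,nstart,span,degree pipeline parameters (defaults as in
#'   [shape_pseudotime()]).
#' @param seed integer base seed; dataset i uses sub-seed `mix_seed(seed, i)`.
#' @return list with `results` (data.frame: kind, noise_sd,
#'   pearson_selection, pearson_pc1) and `fraction_selection_wins`.
#' @export
compare_aggregation_modes <- function(datasets, kmin = 2L, kmax = 100L,
                                      nstart = 1L, span = 0.1, degree = 2L,
                                      seed = 1L) {
  if (length(datasets) < 1L) ps_stop("need at least one dataset", "ps_invalid_input")
  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    sub <- mix_seed(seed, i)
    P <- sweep_pseudotimes(d$coords, kmin = kmin, kmax = kmax,
                           nstart = nstart, seed = sub)
    p_sel <- smooth_pseudotime(ensemble_crude(P, "selection")$crude,
                               span = span, degree = degree)
    p_pc1 <- smooth_pseudotime(ensemble_crude(P, "pc1")$crude,
                               span = span, degree = degree)
    data.frame(
      kind = d$kind, noise_sd = d$noise_sd,
      pearson_selection = score_pseudotime(p_sel, d$t)$pearson_abs,
      pearson_pc1 = score_pseudotime(p_pc1, d$t)$pearson_abs
    )
  })
  results <- do.call(rbind, rows)
  list(results = results,
       fraction_selection_wins = mean(results$pearson_selection > results$pearson_pc1))
}

#' Robustness of the ensemble to random initialisation
#'
#' Repeats the full pipeline `n_runs` times with different seeds, shuffling
#' the cell order before each run and un-shuffling the result before
#' scoring it against the ground truth. Because the pipeline is cell-order
#' invariant by construction, the dispersion of the returned absolute
#' Pearson correlations isolates the effect of the random k-means
#' initialisations (the shuffle doubles as an equivariance check).
#'
#' @param dataset a `ps_trajectory`.
#' @param n_runs number of runs (default 50).
#' @param kmin,kmax,nstart,span,degree pipeline parameters.
#' @param seed integer base seed; run r uses sub-seed `mix_seed(seed, r)`.
#' @return numeric vector of per-run absolute Pearson correlations.
#' @export
robustness_experiment <- function(dataset, n_runs = 50L, kmin = 2L,
                                  kmax = 100L, nstart = 1L, span = 0.1,
                                  degree = 2L, seed = 1L) {
  if (n_runs < 2L) ps_stop("n_runs must be >= 2", "ps_invalid_param")
  n <- nrow(dataset$coords)
  vapply(seq_len(n_runs), function(r) {
    sub <- mix_seed(seed, r)
    set.seed(sub)
    perm <- sample.int(n)
    run <- shape_pseudotime(dataset$coords[perm, , drop = FALSE],
                            kmin = kmin, kmax = kmax, nstart = nstart,
                            span = span, degree = degree, seed = sub)
    p <- run$pseudotime[order(perm)]   # undo the shuffle
    score_pseudotime(p, dataset$t)$pearson_abs
  }, numeric(1))
}
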