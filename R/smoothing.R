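# Local polynomial regression (LOESS) smoothing of the crude pseudotime.
#
# The smoother is the classical tri-cube-weighted local polynomial fit:
# for each target point the q = ceil(span * n) nearest neighbours in the
# predictor are weighted by w(u) = (1 - |u|^3)^3 with u = distance divided
# by the largest distance in the window, and a degree-1 or degree-2
# polynomial is fit by weighted least squares. Boundary windows are the
# usual asymmetric nearest-neighbour windows; there are no robustness
# iterations. The fit is exact at every point up to `exact_max_n` cells;
# beyond that it is evaluated on an evenly spaced predictor grid of 5000
# points and interpolated linearly.

# Tri-cube weighted polynomial fit evaluated at a single target x0.
loess_fit_at <- function(x, y, x0, q, degree) {
  d <- abs(x - x0)
  nb <- order(d)[seq_len(q)]           # stable: ties kept in input order
  dmax <- d[nb[q]]
  if (dmax == 0) return(mean(y[nb]))   # all window points at x0
  u <- pmin(d[nb] / dmax, 1)
  w <- (1 - u^3)^3
  if (sum(w > 0) <= degree) return(stats::weighted.mean(y[nb], w + 1e-12))
  B <- outer(x[nb] - x0, 0:degree, "^")
  fit <- stats::lm.wfit(B, y[nb], w)
  b0 <- fit$coefficients[1L]
  if (is.na(b0)) stats::weighted.mean(y[nb], w) else b0
}

#' Local polynomial regression with tri-cube weights
#'
#' Fits y on x locally at every point: each window holds the
#' `q = ceiling(span * n)` nearest neighbours in x, weighted by the
#' tri-cube kernel on distances scaled by the window radius, and a
#' polynomial of the given degree is fit by weighted least squares. A
#' degree >= 1 fit reproduces exactly linear data exactly.
#'
#' @param x predictor vector (finite).
#' @param y response vector, same length as `x`.
#' @param span fraction of points per window, in `(0, 1]` (default 0.1).
#' @param degree local polynomial degree, 1 or 2 (default 2).
#' @param exact_max_n above this many points the fit is evaluated on a
#'   5000-point evenly spaced predictor grid and linearly interpolated
#'   (default 50000).
#' @return fitted values at each `x`, in input order.
#' @export
#' @examples
#' x <- 1:100
#' y <- 0.5 + 2 * x
#' max(abs(loess_fit(x, y) - y)) < 1e-10  # exact on linear data
loess_fit <- function(x, y, span = 0.1, degree = 2L, exact_max_n = 50000L) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    ps_stop("x and y must be numeric vectors of equal length", "ps_invalid_input")
  }
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) {
    ps_stop("non-finite values in x or y", "ps_invalid_input")
  }
  if (!degree %in% c(1L, 2L)) ps_stop("degree must be 1 or 2", "ps_invalid_param")
  if (span <= 0 || span > 1) ps_stop("span must be in (0, 1]", "ps_invalid_param")
  n <- length(x)
  if (n < degree + 1L) ps_stop("too few points to determine the local polynomial",
                               "ps_invalid_input")
  q <- as.integer(ceiling(span * n))
  # q >= degree + 2 keeps local fits overdetermined; a whole-data window is
  # allowed down to degree + 1 points (exact polynomial interpolation).
  if (q < degree + 2L && q < n) {
    ps_stop(sprintf("window of %d points too small for degree %d (need >= %d); increase span",
                    q, degree, degree + 2L), "ps_invalid_param")
  }

  if (n <= exact_max_n) {
    vapply(x, function(x0) loess_fit_at(x, y, x0, q, degree), numeric(1))
  } else {
    grid <- seq(min(x), max(x), length.out = 5000L)
    fg <- vapply(grid, function(x0) loess_fit_at(x, y, x0, q, degree), numeric(1))
    stats::approx(grid, fg, xout = x, rule = 2)$y
  }
}

#' Smooth a crude pseudotime with LOESS
#'
#' The crude pseudotime is regressed on its own ranking (response = crude
#' values, predictor = ranks), which irons out the discreteness left by the
#' averaged cluster labels while preserving the ordering; the fitted values
#' are min-max rescaled to `[0, 1]`. Rank ties are resolved ordinally in
#' stable input order so the predictor has no duplicates (average ranks
#' would make degree-2 local fits singular).
#'
#' @param crude a `ps_crude` from [aggregate_pseudotimes()] /
#'   [first_pc_pseudotime()], or a bare numeric vector.
#' @param span,degree LOESS parameters (defaults 0.1 and 2).
#' @return numeric vector of continuous pseudotimes in `[0, 1]` (min 0,
#'   max 1).
#' @export
smooth_pseudotime <- function(crude, span = 0.1, degree = 2L) {
  values <- if (inherits(crude, "ps_crude")) crude$values else crude
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    ps_stop("crude pseudotime must be finite numeric", "ps_invalid_input")
  }
  if (length(unique(values)) == 1L) {
    ps_stop("crude pseudotime is constant; no ordering exists", "ps_degenerate")
  }
  n <- length(values)
  if (n < 2L) ps_stop("need at least 2 cells", "ps_invalid_input")
  degree <- if (n < degree + 2L) 1L else as.integer(degree)  # tiny-n fallback
  span <- max(span, min(1, (degree + 2L) / n))               # window >= degree + 2
  r <- rank(values, ties.method = "first")
  rescale01(loess_fit(r, values, span = span, degree = degree))
}
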