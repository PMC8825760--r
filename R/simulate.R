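# Trigonometric trajectory simulator with ground-truth progression.
#
# Points are sampled along a parametric curve at t increments of 0.01 and
# perturbed with i.i.d. per-coordinate Gaussian noise. The t parameter is
# kept as the (approximate, once noise is added) ground-truth pseudotime.

# Parametric curve families. Scale factors keep the curve extent large
# relative to the 0.05-0.95 noise range so the noise sweep spans easy to
# hard recovery; default t ranges keep 1157 <= n <= 1785.
trajectory_kinds <- function() c("spiral2d", "spiral2d_quadratic", "spiral3d",
                                 "spiral3d_quadratic", "sine")

trajectory_curve <- function(kind) {
  switch(kind,
    spiral2d = list(f = function(t) cbind(x = t * cos(t), y = t * sin(t)),
                    t_max = 12.57),
    spiral2d_quadratic = list(
      f = function(t) cbind(x = (t^2 / 8) * cos(t), y = (t^2 / 8) * sin(t)),
      t_max = 12.57),
    spiral3d = list(
      f = function(t) cbind(x = 4 * cos(t), y = 4 * sin(t), z = 0.4 * t),
      t_max = 17.85),
    spiral3d_quadratic = list(
      f = function(t) cbind(x = (t^2 / 8) * cos(t), y = (t^2 / 8) * sin(t),
                            z = 0.4 * t),
      t_max = 12.57),
    sine = list(f = function(t) cbind(x = t, y = 2 * sin(t)), t_max = 12.57),
    ps_stop(sprintf("unknown trajectory kind '%s'", kind), "ps_invalid_param")
  )
}

#' Simulate a noisy trigonometric trajectory
#'
#' Samples `t = 0, 0.01, ..., < t_max` (`n = ceiling(t_max / 0.01)` points)
#' along one of five parametric curves and adds independent Gaussian noise
#' of standard deviation `noise_sd` to every coordinate. At `noise_sd = 0`
#' the points lie exactly on the curve and `t` is the exact progression;
#' with noise, `t` remains a close approximation of the ground truth.
#'
#' Curve families (2-D unless noted): `spiral2d` \eqn{(t\cos t, t\sin t)};
#' `spiral2d_quadratic` \eqn{((t^2/8)\cos t, (t^2/8)\sin t)}; `spiral3d`
#' \eqn{(4\cos t, 4\sin t, 0.4t)} (3-D helix); `spiral3d_quadratic` the
#' quadratic spiral with the same linear z; `sine` \eqn{(t, 2\sin t)}.
#'
#' @param kind one of `"spiral2d"`, `"spiral2d_quadratic"`, `"spiral3d"`,
#'   `"spiral3d_quadratic"`, `"sine"`.
#' @param t_max end of the t range (exclusive); defaults to the per-kind
#'   range (12.57, or 17.85 for `spiral3d`).
#' @param noise_sd Gaussian noise standard deviation, >= 0.
#' @param seed integer seed for the noise draws.
#' @return a `ps_trajectory`: `coords` (n x d), `t` (length n), `kind`,
#'   `noise_sd`.
#' @export
#' @examples
#' d <- simulate_trajectory("spiral2d", noise_sd = 0)
#' nrow(d$coords)  # 1257
simulate_trajectory <- function(kind = trajectory_kinds(), t_max = NULL,
                                noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (noise_sd < 0) ps_stop("noise_sd must be >= 0", "ps_invalid_param")
  curve <- trajectory_curve(kind)
  if (is.null(t_max)) t_max <- curve$t_max
  if (t_max <= 0) ps_stop("t_max must be positive", "ps_invalid_param")

  n <- as.integer(ceiling(t_max / 0.01))
  t <- seq(0, by = 0.01, length.out = n)
  coords <- curve$f(t)
  if (noise_sd > 0) {
    set.seed(seed)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, noise_sd),
                              nrow = n, ncol = ncol(coords))
  }
  structure(list(coords = coords, t = t, kind = kind, noise_sd = noise_sd),
            class = "ps_trajectory")
}

#' @export
print.ps_trajectory <- function(x, ...) {
  cat(sprintf("Simulated %s trajectory: %d points, %d dims, noise sd %.2f\n",
              x$kind, nrow(x$coords), ncol(x$coords), x$noise_sd))
  invisible(x)
}

#' Simulate the full 50-dataset trajectory suite
#'
#' Five curve kinds crossed with ten noise levels
#' (sd = 0.05, 0.15, ..., 0.95), 50 datasets in total; each dataset draws
#' its noise from a deterministic sub-seed of `seed`.
#'
#' @param seed integer base seed.
#' @param noise_levels noise standard deviations (default
#'   `seq(0.05, 0.95, by = 0.1)`).
#' @return a list of 50 `ps_trajectory` objects, grouped by kind.
#' @export
simulate_suite <- function(seed = 1L, noise_levels = seq(0.05, 0.95, by = 0.1)) {
  kinds <- trajectory_kinds()
  out <- vector("list", length(kinds) * length(noise_levels))
  i <- 0L
  for (kind in kinds) {
    for (sd in noise_levels) {
      i <- i + 1L
      out[[i]] <- simulate_trajectory(kind, noise_sd = sd,
                                      seed = mix_seed(seed, i))
    }
  }
  out
}

#' Write a simulated trajectory as CSV
#'
#' Columns `t, x, y[, z]`, one row per point.
#'
#' @param dataset a `ps_trajectory`.
#' @param path output file path.
#' @export
write_trajectory <- function(dataset, path) {
  df <- data.frame(t = dataset$t, dataset$coords, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
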