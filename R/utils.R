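# Shared low-level helpers: structured conditions, seed mixing, [0,1] rescaling.

#' Signal a classed pseudoshaper condition
#'
#' All user-facing errors in the package carry a subclass so callers (and the
#' CLI) can map them to exit codes: `ps_invalid_input`, `ps_invalid_param`,
#' `ps_degenerate`, `ps_size`, `ps_skip` (a per-k skip signal caught by
#' [sweep_pseudotimes()]) and `ps_internal`.
#'
#' @param message error message.
#' @param class condition subclass, one of the classes above.
#' @keywords internal
ps_stop <- function(message, class = "ps_invalid_input") {
  stop(structure(
    class = c(class, "pseudoshaper_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Derive a deterministic sub-seed from a base seed and a salt
#'
#' A fixed integer mixing function (two rounds of multiplicative congruential
#' scrambling modulo the Mersenne prime 2^31 - 1) so that per-k and per-run
#' sub-seeds do not shift when other k values or runs are added or removed.
#' All arithmetic stays below 2^53, exact in doubles; the result is a
#' non-negative 32-bit integer.
#'
#' @param seed base integer seed.
#' @param salt integer salt (e.g. the k value or the run index).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' mix_seed(1L, 10L)
#' mix_seed(1L, 10L) == mix_seed(1L, 10L)
mix_seed <- function(seed, salt) {
  m <- 2147483647
  x <- ((abs(as.numeric(seed)) %% m) * 48271 + (abs(as.numeric(salt)) %% m) * 16807 + 12345) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

#' Min-max rescale a vector to [0, 1]
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return `(x - min(x)) / (max(x) - min(x))`.
#' @export
rescale01 <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    ps_stop("rescale01: input must be finite numeric", "ps_invalid_input")
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    ps_stop("rescale01: input is constant, no ordering exists", "ps_degenerate")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Re-raise errors from a pipeline stage with the stage name prefixed,
# preserving the condition class.
with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "pseudoshaper_error") && !grepl("^\\[", conditionMessage(e))) {
      stop(structure(
        class = class(e),
        list(message = sprintf("[%s] %s", stage, conditionMessage(e)), call = conditionCall(e))
      ))
    }
  })
}

# Validate a numeric matrix input (finite, at least min_rows rows).
check_matrix <- function(X, min_rows = 1L, what = "matrix") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    ps_stop(sprintf("%s must be a numeric matrix", what), "ps_invalid_input")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    ps_stop(sprintf("%s contains non-finite values", what), "ps_invalid_input")
  }
  if (nrow(X) < min_rows) {
    ps_stop(sprintf("%s must have at least %d rows", what, min_rows), "ps_invalid_input")
  }
  X
}
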