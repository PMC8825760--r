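# Independent oracles and fixture builders shared across test files.

# Distance matrix from 1-D point positions.
dist1d <- function(pos) as.matrix(dist(pos))

# Random Euclidean instance: k points uniform in a d-cube.
random_instance <- function(k, d = 3) {
  as.matrix(dist(matrix(runif(k * d), nrow = k, ncol = d)))
}

# Per-point tri-cube weighted least squares via explicit normal equations
# (solve of t(B) W B), an independent route from the package's lm.wfit fit.
loess_oracle <- function(x, y, span, degree) {
  n <- length(x)
  q <- as.integer(ceiling(span * n))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    nb <- order(d)[seq_len(q)]
    dmax <- d[nb[q]]
    if (dmax == 0) return(mean(y[nb]))
    u <- pmin(d[nb] / dmax, 1)
    w <- (1 - u^3)^3
    B <- outer(x[nb] - x[i], 0:degree, "^")
    beta <- solve(crossprod(B, w * B), crossprod(B, w * y[nb]))
    beta[1]
  }, numeric(1))
}

# Eigendecomposition of the explicit column correlation matrix: independent
# PCA oracle (loadings = eigenvectors, scores = standardized data projected).
pca_oracle <- function(M) {
  R <- cor(M)
  e <- eigen(R, symmetric = TRUE)
  Z <- scale(M)
  list(vectors = e$vectors, values = e$values, scores = Z %*% e$vectors)
}

# Columns generated from one shared latent ordering plus discretisation
# noise, mimicking a pseudotime set.
latent_column_set <- function(t, m, levels = 20, jitter = 0.3) {
  sapply(seq_len(m), function(j) {
    noisy <- t + rnorm(length(t), 0, jitter * diff(range(t)))
    as.integer(cut(noisy, levels)) - 1L
  })
}

expect_valid_path <- function(path, k) {
  expect_s3_class(path, "ham_path")
  expect_true(setequal(path$order, seq_len(k)))
  expect_length(path$order, k)
  expect_lt(path$order[1], path$order[k])  # canonical orientation
}
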