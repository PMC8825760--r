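# PCA-loading aggregation of discrete pseudotime sets.

make_loadings <- function(pc1, pc2, columns = seq_along(pc1)) {
  structure(list(pc1 = pc1, pc2 = pc2, pc1_sign = ifelse(pc1 >= 0, 1L, -1L),
                 columns = columns, k_values = columns),
            class = "ps_loadings")
}

test_that("perfectly correlated columns put all variance on PC1", {
  P <- cbind(a = 0:10, b = 0:10)
  L <- pseudotime_loadings(P)
  expect_equal(L$explained_variance[1], 1)
  expect_equal(abs(L$pc1), rep(1 / sqrt(2), 2))
})

test_that("anti-correlated columns load PC1 with opposite signs", {
  t <- seq(0, 1, length.out = 50)
  L <- pseudotime_loadings(cbind(t, -t))
  expect_equal(abs(L$pc1[1]), abs(L$pc1[2]))
  expect_equal(sign(L$pc1[1]) * sign(L$pc1[2]), -1)
})

test_that("loadings match an explicit eigendecomposition of the correlation matrix", {
  set.seed(21)
  t <- runif(120)
  M <- sapply(1:5, function(j) t + rnorm(120, 0, 0.3))
  L <- pseudotime_loadings(M)
  o <- pca_oracle(M)
  for (j in 1:2) {
    ours <- if (j == 1) L$pc1 else L$pc2
    ref <- o$vectors[, j]
    if (sum(ours * ref) < 0) ref <- -ref        # sign convention differs
    expect_equal(ours, ref, tolerance = 1e-8)
  }
  expect_equal(L$explained_variance, o$values[1:2] / sum(o$values), tolerance = 1e-8)
})

test_that("selection keeps columns loading more on PC1 than PC2", {
  L <- make_loadings(c(0.9, -0.85, 0.10), c(0.10, 0.20, 0.95))
  expect_identical(select_correlated(L), c(1L, 2L))
  tie <- make_loadings(c(0.5, -0.5), c(0.5, 0.5))   # strict inequality fails
  expect_length(select_correlated(tie), 0)
})

test_that("selection excludes an independent noise column", {
  set.seed(33)
  t <- seq(0, 1, length.out = 150)
  hits <- 0L
  for (rep in 1:200) {
    M <- cbind(latent_column_set(t, 9), sample(0L:19L, 150, replace = TRUE))
    sel <- select_correlated(pseudotime_loadings(M))
    if (!(10L %in% sel) && length(sel) >= 5) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("selection keeps a mutually correlated majority on a correlated set", {
  # With exchangeable correlated columns PC2's unit-norm loadings must exceed
  # PC1's on some columns, so a complete selection is not attainable; the
  # guarantee is a non-trivial subset whose members are mutually correlated.
  set.seed(5)
  t <- seq(0, 1, length.out = 200)
  M <- latent_column_set(t, 8, jitter = 0.02)
  expect_true(all(abs(cor(M)) > 0.9))
  sel <- select_correlated(pseudotime_loadings(M))
  expect_gte(length(sel), 4)
  expect_true(all(abs(cor(M[, sel])) > 0.9))
})

test_that("aggregation scales, aligns and averages the selected columns", {
  P <- cbind(c(0, 1, 2), c(2, 1, 0))
  L <- make_loadings(c(0.7, -0.7), c(0.1, 0.1))
  agg <- aggregate_pseudotimes(P, L, 1:2)
  expect_equal(agg$values, c(0, 0.5, 1))
  expect_equal(agg$n_selected, 2L)

  single <- aggregate_pseudotimes(cbind(c(0, 1, 2, 3)),
                                  make_loadings(0.9, 0.1), 1L)
  expect_equal(single$values, c(0, 1/3, 2/3, 1))
  expect_error(aggregate_pseudotimes(P, L, integer(0)), class = "ps_invalid_input")
})

test_that("aggregated crude tracks the latent ordering at least as well as the columns", {
  set.seed(9)
  t <- seq(0, 1, length.out = 300)
  M <- latent_column_set(t, 10)
  L <- pseudotime_loadings(M)
  sel <- select_correlated(L)
  agg <- aggregate_pseudotimes(M, L, sel)
  best_single <- max(abs(cor(M, t)))
  expect_gte(abs(cor(agg$values, t)), best_single - 0.02)
  expect_equal(range(agg$values), c(0, 1))
})

test_that("aggregation is invariant to column order and column flips up to direction", {
  set.seed(14)
  t <- seq(0, 1, length.out = 100)
  M <- latent_column_set(t, 6)
  agg_of <- function(M) {
    L <- pseudotime_loadings(M)
    aggregate_pseudotimes(M, L, select_correlated(L))$values
  }
  base <- agg_of(M)

  perm <- sample(ncol(M))
  pv <- agg_of(M[, perm])
  expect_true(isTRUE(all.equal(pv, base)) || isTRUE(all.equal(1 - pv, base)))

  Mf <- M
  Mf[, 2] <- max(Mf[, 2]) - Mf[, 2]             # flip one column beforehand
  fv <- agg_of(Mf)
  expect_true(isTRUE(all.equal(fv, base)) || isTRUE(all.equal(1 - fv, base)))
})

test_that("PC1 pseudotime matches the eigendecomposition oracle", {
  set.seed(40)
  t <- runif(80)
  M <- sapply(1:5, function(j) t + rnorm(80, 0, 0.2))
  pc1 <- first_pc_pseudotime(M)
  ref <- pca_oracle(M)$scores[, 1]
  ref <- (ref - min(ref)) / diff(range(ref))
  ok <- isTRUE(all.equal(pc1$values, ref, tolerance = 1e-8)) ||
        isTRUE(all.equal(pc1$values, 1 - ref, tolerance = 1e-8))
  expect_true(ok)

  ident <- first_pc_pseudotime(cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_true(isTRUE(all.equal(ident$values, c(0, 0.5, 1))) ||
              isTRUE(all.equal(ident$values, c(1, 0.5, 0))))
})

test_that("degenerate pseudotime sets are rejected", {
  expect_error(pseudotime_loadings(cbind(rep(1, 5), rep(2, 5))),
               class = "ps_degenerate")
  expect_message(
    expect_error(pseudotime_loadings(cbind(0:4, rep(2, 5))), class = "ps_degenerate"),
    "zero-variance")
})
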