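# Greedy and exact shortest Hamiltonian path solvers.

test_that("collinear points are ordered along the line", {
  D <- dist1d(c(0, 1, 2, 3))
  g <- greedy_hamiltonian_path(D)
  expect_identical(g$order, 1:4)
  expect_equal(g$length, 3)
  b <- brute_force_hamiltonian_path(D)
  expect_identical(b$order, 1:4)
})

test_that("k = 2 has the single possible path", {
  D <- matrix(c(0, 7, 7, 0), 2, 2)
  g <- greedy_hamiltonian_path(D)
  expect_identical(g$order, 1:2)
  expect_equal(g$length, 7)
})

test_that("middle vertex is forced in a 3-point instance", {
  D <- matrix(c(0, 1, 5, 1, 0, 1, 5, 1, 0), 3, 3)
  b <- brute_force_hamiltonian_path(D)
  expect_identical(b$order, c(1L, 2L, 3L))
  expect_equal(b$length, 2)
})

test_that("interleaved 1-D instance is solved optimally by the greedy heuristic", {
  # points at 0, 10, 1, 11, 2: optimal path visits 0,1,2 then 10,11 (length 11)
  D <- dist1d(c(0, 10, 1, 11, 2))
  g <- greedy_hamiltonian_path(D)
  expect_identical(g$order, c(1L, 3L, 5L, 2L, 4L))
  expect_equal(g$length, 11)
  expect_equal(path_length(D, g$order), 11)
  b <- brute_force_hamiltonian_path(D)
  expect_equal(b$length, 11)
  expect_identical(b$order, g$order)
})

test_that("greedy output is always a valid Hamiltonian path", {
  set.seed(42)
  for (rep in 1:100) {
    k <- sample(3:30, 1)
    D <- random_instance(k)
    g <- greedy_hamiltonian_path(D)
    expect_valid_path(g, k)
    expect_equal(path_length(D, g$order), g$length)
  }
})

test_that("greedy is never shorter than the exact oracle, equal on collinear data", {
  set.seed(7)
  for (rep in 1:60) {
    k <- sample(3:8, 1)
    D <- random_instance(k, d = 2)
    g <- greedy_hamiltonian_path(D)
    b <- brute_force_hamiltonian_path(D)
    expect_gte(g$length + 1e-12, b$length)
  }
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    D <- dist1d(runif(k, 0, 100))
    expect_equal(greedy_hamiltonian_path(D)$length,
                 brute_force_hamiltonian_path(D)$length)
  }
})

test_that("solver is deterministic and path length is reversal invariant", {
  set.seed(11)
  D <- random_instance(12)
  g1 <- greedy_hamiltonian_path(D)
  g2 <- greedy_hamiltonian_path(D)
  expect_identical(g1$order, g2$order)
  expect_equal(path_length(D, g1$order), path_length(D, rev(g1$order)))
})

test_that("tied edge weights are admitted in deterministic index order", {
  # unit square: four sides tied at weight 1, two diagonals at sqrt(2)
  D <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  g1 <- greedy_hamiltonian_path(D)
  expect_identical(g1$order, greedy_hamiltonian_path(D)$order)
  expect_equal(g1$length, 3)
})

test_that("invalid distance matrices are rejected", {
  expect_error(greedy_hamiltonian_path(matrix(1:6, 2, 3)), class = "ps_invalid_input")
  expect_error(greedy_hamiltonian_path(matrix(0, 1, 1)), class = "ps_invalid_input")
  M <- dist1d(c(0, 1, 2)); M[1, 2] <- 99                       # asymmetric
  expect_error(greedy_hamiltonian_path(M), class = "ps_invalid_input")
  N <- dist1d(c(0, 1, 2)); N[1, 2] <- N[2, 1] <- -1            # negative
  expect_error(greedy_hamiltonian_path(N), class = "ps_invalid_input")
  expect_error(brute_force_hamiltonian_path(random_instance(11)), class = "ps_size")
  expect_error(path_length(dist1d(c(0, 1, 2)), c(1, 1, 2)), class = "ps_invalid_input")
})
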