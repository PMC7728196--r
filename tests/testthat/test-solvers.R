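test_that("per-sample QP returns the constrained least-squares optimum", {
  # interior optimum: unconstrained solution is feasible
  expect_equal(solve_proportions_column(c(0.3, 0.5), diag(2)),
               c(0.3, 0.5), tolerance = 1e-10, ignore_attr = TRUE)
  # boundary optimum: unconstrained (0.8, 0.6) violates the sum constraint;
  # frozen expectation verified against the dense grid oracle below
  expect_equal(solve_proportions_column(c(0.8, 0.6), diag(2)),
               c(0.6, 0.4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(solve_proportions_column(c(0, 0), diag(2)),
               c(0, 0), ignore_attr = TRUE)
})

test_that("QP solutions agree with a dense grid oracle and satisfy KKT", {
  for (seed in 1:6) {
    set.seed(seed)
    K <- sample(2:3, 1)
    n <- 12
    W <- matrix(runif(n * K, 0.5, 2), n, K)
    # half the cases push against the sum constraint
    h_true <- runif(K); if (seed %% 2) h_true <- h_true / sum(h_true) * 1.4
    y <- drop(W %*% h_true) + runif(n, 0, 0.05)
    h <- solve_proportions_column(y, W)
    h_grid <- qp_grid_oracle(y, W, step = 0.01)
    expect_lt(sum((y - W %*% h)^2), sum((y - W %*% h_grid)^2) + 1e-8)
    expect_lt(max(abs(h - h_grid)), 0.015)
    expect_lt(qp_kkt_residual(y, W, h), 1e-8)
    expect_true(all(h >= 0) && sum(h) <= 1 + 1e-8)
  }
})

test_that("QP rejects degenerate and non-finite inputs", {
  expect_error(solve_proportions_column(c(1, 1), cbind(c(1, 1), c(0, 0))),
               "all-zero")
  expect_error(solve_proportions_column(c(1, NA), diag(2)), "non-finite")
})

test_that("per-gene NNLS matches its closed form and an independent solver", {
  expect_equal(solve_basis_row(c(1, 1), matrix(c(0.5, 0.5), 1)), 2,
               tolerance = 1e-12)
  # unconstrained optimum -2 is clipped at zero: closed form max(0, r.h/h.h)
  expect_equal(solve_basis_row(c(-1, -1), matrix(c(0.5, 0.5), 1)), 0)
  expect_warning(w <- solve_basis_row(c(3, 3), matrix(0, 1, 2)),
                 "all-zero")
  expect_equal(w, 0)

  skip_if_not_installed("pracma")
  for (seed in 1:8) {
    set.seed(seed)
    K2 <- sample(1:4, 1); m <- 10
    H2 <- matrix(runif(K2 * m), K2, m)
    r <- rnorm(m, 0, 2)
    mine <- solve_basis_row(r, H2)
    ref <- pracma::lsqnonneg(t(H2), r)$x
    expect_equal(mine, ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("W2 initialization is seeded, shaped and non-negative", {
  Y <- expression_matrix(matrix(runif(50, 1, 10), 10, 5))
  a <- initialize_W2(Y, 3, seed = 42)
  b <- initialize_W2(Y, 3, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, initialize_W2(Y, 3, seed = 43)))
  expect_equal(dim(a), c(10L, 3L))
  expect_true(all(a >= 0))
  # jittered sampled columns stay within 10% of some column of Y
  expect_true(all(a >= 0.9 * apply(Y, 1, min) - 1e-12))

  expect_equal(ncol(initialize_W2(Y, 0)), 0L)
  expect_warning(u <- initialize_W2(Y, 7, seed = 1), "falling back")
  expect_equal(dim(u), c(10L, 7L))
})
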