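test_that("noiseless full-reference mixtures are recovered exactly", {
  set.seed(5)
  W <- synth_basis(120, 3, seed = 9)
  H <- t(prede:::rdirichlet_mat(8, rep(1, 3)))
  Y <- expression_matrix(W %*% H)
  fit <- fit_prede(Y, reference_panel(W), K = 3)
  expect_lt(max(abs(fit$H_hat - H)), 1e-6)
  expect_equal(fit$n_iterations, 1L)          # convex mode: single pass
  expect_true(fit$converged)
  expect_equal(fit$ssr, fit$objective_trace[length(fit$objective_trace)])
})

test_that("objective trace is non-increasing and constraints hold", {
  for (seed in 1:25) {
    inst <- random_instance(seed, n = 30, m = 8,
                            K = 2 + seed %% 3, K1 = seed %% 3)
    fit <- fit_prede(inst$Y, inst$W1, inst$K,
                     prede_control(n_restarts = 1, max_iter = 40, seed = seed))
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_true(all(fit$H_hat >= -1e-10))
    expect_true(all(colSums(fit$H_hat) <= 1 + 1e-8))
    expect_true(all(fit$W2_hat >= 0))
    expect_equal(fit$ssr, fit$objective_trace[fit$n_iterations])
  }
})

test_that("degenerate modes reduce to the classical methods", {
  inst <- random_instance(3, n = 25, m = 6, K = 3, K1 = 3)
  # full reference: result is exactly the per-column constrained regression
  fit <- fit_prede(inst$Y, inst$W1, K = 3)
  ref <- vapply(seq_len(ncol(inst$Y)),
                function(j) solve_proportions_column(inst$Y[, j], inst$W1),
                numeric(3))
  ref[ref < 0] <- 0
  expect_equal(unname(fit$H_hat), unname(ref), tolerance = 1e-10)
  expect_equal(ncol(fit$W2_hat), 0L)
  expect_equal(fit$n_restarts_used, 1L)

  # reference-free: W1 is never consulted
  fit0 <- fit_prede(inst$Y, NULL, K = 2,
                    prede_control(n_restarts = 2, max_iter = 30, seed = 2))
  expect_equal(fit0$K1, 0L)
  expect_equal(ncol(fit0$W2_hat), 2L)
  expect_true(all(diff(fit0$objective_trace) <= 1e-9))
})

test_that("fits are deterministic given the seed", {
  inst <- random_instance(11, n = 30, m = 8, K = 3, K1 = 2)
  ctl <- prede_control(n_restarts = 2, max_iter = 25, seed = 7)
  f1 <- fit_prede(inst$Y, inst$W1, 3, ctl)
  f2 <- fit_prede(inst$Y, inst$W1, 3, ctl)
  expect_identical(f1$H_hat, f2$H_hat)
  expect_identical(f1$W2_hat, f2$W2_hat)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("invalid fitting inputs are rejected", {
  inst <- random_instance(1, n = 20, m = 5, K = 2, K1 = 2)
  expect_error(fit_prede(inst$Y, inst$W1, K = 1), "at least the number")
  expect_error(fit_prede(expression_matrix(matrix(0, 4, 2)), NULL, 1),
               "identically zero")
  Wbad <- reference_panel(matrix(1, 3, 1), gene_ids = c("x", "y", "z"))
  Ysm <- expression_matrix(matrix(1, 3, 2), gene_ids = c("a", "b", "c"))
  expect_error(fit_prede(Ysm, Wbad, 2), "align_genes")
})

test_that("a held-out profile is recovered from a noiseless partial mixture", {
  d <- mixture_design(300, 30, K = 4, known_indices = 1:3, seed = 21)
  tr <- generate_mixture(d)
  fit <- fit_prede(expression_matrix(tr$Y_noisy),
                   reference_panel(truth_reference(tr)), K = 4,
                   prede_control(n_restarts = 2, seed = 3, max_iter = 200))
  ev <- evaluate_deconvolution(tr, fit)
  expect_lt(ev$proportion_mae$overall, 0.05)
  expect_gt(ev$profile_pcc[["celltype_4"]], 0.9)
})
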