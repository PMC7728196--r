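test_that("component matching equals exhaustive permutation search", {
  set.seed(9)
  A <- matrix(rlnorm(60), 20, 3)
  expect_identical(match_components(A, A), 1:3)
  sw <- c(3L, 1L, 2L)
  expect_identical(match_components(A, A[, sw]), sw)

  for (seed in 1:10) {
    set.seed(seed)
    K2 <- sample(2:5, 1)
    At <- matrix(rnorm(15 * K2), 15, K2)
    Bt <- matrix(rnorm(15 * K2), 15, K2)
    perm <- match_components(At, Bt)
    score <- sum(vapply(seq_len(K2),
                        function(j) cor(At[, perm[j]], Bt[, j]), numeric(1)))
    expect_equal(score, match_oracle(At, Bt)$score, tolerance = 1e-12)
  }

  expect_warning(match_components(cbind(rep(1, 5), 1:5),
                                  matrix(rnorm(10), 5, 2)),
                 "constant")
})

test_that("proportion MAE averages per type and overall", {
  H1 <- matrix(0.5, 2, 3); H2 <- matrix(0.4, 2, 3)
  m <- mae_proportions(H1, H1)
  expect_equal(m$overall, 0)
  expect_equal(mae_proportions(H1, H2)$overall, 0.1)
  H3 <- matrix(c(0.2, 0.5, 0.5, 0.5), 2, 2)
  H4 <- matrix(c(0.4, 0.5, 0.5, 0.5), 2, 2)
  expect_equal(mae_proportions(H3, H4)$overall, 0.05)
  expect_equal(unname(mae_proportions(H3, H4)$per_type), c(0.1, 0))
  expect_error(mae_proportions(H1, H3), "identical dimensions")
})

test_that("pcc follows the product-moment definition with guards", {
  x <- c(1, 2, 3)
  expect_equal(pcc(x, 2 * x + 3), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(x, c(1, 3, 2)), 0.5)       # hand computation
  expect_warning(v <- pcc(x, c(2, 2, 2)), "zero variance")
  expect_true(is.nan(v))
  expect_error(pcc(1:2, 1:2), "at least 3")
})

test_that("Shannon index is the entropy of the renormalized composition", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  # renormalization: scale invariance
  expect_equal(shannon_index(c(2, 1, 1)), shannon_index(c(0.5, 0.25, 0.25)))
  expect_error(shannon_index(c(0, 0)), "all-zero")
  # maximized by the uniform composition
  set.seed(2)
  for (i in 1:10) {
    p <- prede:::rdirichlet_mat(1, rep(1, 5))
    expect_lte(shannon_index(drop(p)), log(5) + 1e-12)
  }
})

test_that("Bray-Curtis matches its formula, vegan, and its properties", {
  expect_equal(bray_curtis(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.6, 0.4), c(0.4, 0.6)), 0.2)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all zero")

  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:6) {
    a <- runif(5); b <- runif(5)
    ref <- as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
    expect_equal(bray_curtis(a, b), ref, tolerance = 1e-12)
    expect_equal(bray_curtis(a, b), bray_curtis(b, a))
    expect_gte(bray_curtis(a, b), 0)
    expect_lte(bray_curtis(a, b), 1)
  }
})

test_that("relative proportions renormalize within a subset", {
  H <- rbind(t1 = c(0.3, 0.4), t2 = c(0.1, 0.2), t3 = c(0.2, 0.1))
  colnames(H) <- c("s1", "s2")
  # full-subset renormalization of columns already summing to 1 is identity
  H1 <- matrix(c(0.6, 0.4, 0.2, 0.8), 2, 2,
               dimnames = list(c("a", "b"), NULL))
  expect_equal(relative_proportions(H1, c("a", "b")), H1)
  r <- relative_proportions(H, c("t1", "t2"))
  expect_equal(unname(r[, 1]), c(0.75, 0.25))
  expect_error(relative_proportions(H, "nope"), "unknown cell-type")
  Hz <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  expect_warning(rz <- relative_proportions(Hz, "a"), "zero total")
  expect_true(is.nan(rz[1, 1]))
  expect_equal(unname(rz[1, 2]), 1)
})
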