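test_that("mixture designs validate their specification", {
  expect_error(mixture_design(20, 5, K = 6), "10 \\* K")
  expect_error(mixture_design(100, 5, K = 3, known_indices = c(1, 1)),
               "distinct")
  expect_error(mixture_design(100, 5, K = 3,
                              rare = list(component = 1, f = 0.1),
                              groups = list(list(indices = 1:3, prop = 1))),
               "mutually exclusive")
  expect_error(mixture_design(100, 5, K = 3,
                              groups = list(list(indices = 1:2, prop = 1))),
               "partition")
  expect_error(mixture_design(100, 5, K = 3,
                              groups = list(list(indices = 1:2, prop = 0.7),
                                            list(indices = 3, prop = 0.7))),
               "sum to 1")
})

test_that("similarity-controlled bases hit their target correlation", {
  W <- synth_basis(1500, 4, similarity = list(list(pair = c(1, 2), pcc = 0.95)),
                   seed = 13)
  expect_gt(cor(W[, 1], W[, 2]), 0.94)
  expect_lt(cor(W[, 1], W[, 2]), 0.96)
  expect_true(all(W >= 0))
})

test_that("independent baseline profiles are weakly correlated", {
  for (seed in 1:8) {
    W <- synth_basis(2000, 6, seed = seed)
    pc <- cor(W)
    expect_lt(max(abs(pc[upper.tri(pc)])), 0.8)
  }
})

test_that("proportion draws honor the design modes", {
  # plain: columns sum to 1
  d <- mixture_design(200, 50, K = 4, seed = 2)
  H <- sample_proportions(d)
  expect_equal(colSums(H), rep(1, 50), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(H >= 0))

  # rare: pinned row, remainder renormalized
  dr <- mixture_design(200, 40, K = 6, rare = list(component = 6, f = 0.1),
                       seed = 3)
  Hr <- sample_proportions(dr)
  expect_equal(unname(Hr[6, ]), rep(0.1, 40))
  expect_equal(colSums(Hr), rep(1, 40), tolerance = 1e-12, ignore_attr = TRUE)

  # groups: realized group totals near the targets
  dg <- mixture_design(200, 100, K = 8,
                       groups = list(list(indices = 1:3, prop = 0.6),
                                     list(indices = 4:6, prop = 0.2),
                                     list(indices = 7:8, prop = 0.2)),
                       seed = 4)
  Hg <- sample_proportions(dg)
  expect_equal(colSums(Hg), rep(1, 100), tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(abs(mean(colSums(Hg[1:3, ])) - 0.6), 0.03)
  expect_lt(abs(mean(colSums(Hg[4:6, ])) - 0.2), 0.03)
  expect_lt(abs(mean(colSums(Hg[7:8, ])) - 0.2), 0.03)
})

test_that("noise is mean-proportional, truncated and seeded", {
  Y <- matrix(10, 2, 10000)
  expect_identical(add_noise(Y, 0), Y)
  Yn <- add_noise(Y, 0.3, seed = 6)
  expect_true(all(Yn >= 0))
  # stated sd: 0.3 * 10 = 3, checked empirically over 1e4 entries
  expect_lt(abs(sd(Yn[1, ] - 10) - 3) / 3, 0.1)
  expect_identical(add_noise(Y, 0.3, seed = 6), Yn)
})

test_that("generated ground truth is internally consistent and seeded", {
  d <- mixture_design(150, 12, K = 3, known_indices = 1:2, noise_c = 0.2,
                      seed = 17)
  tr <- generate_mixture(d)
  expect_equal(tr$Y_clean, tr$W_true %*% tr$H_true)
  expect_true(all(tr$Y_noisy >= 0))
  expect_identical(generate_mixture(d), tr)
  expect_identical(colnames(truth_reference(tr)), c("celltype_1", "celltype_2"))
})
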