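# Independent oracles and small fixture builders used across the suite.

# Dense grid search over the simplex {h >= 0, sum(h) <= 1} at the given step:
# a brute-force oracle for the constrained per-sample QP.
qp_grid_oracle <- function(y, W, step = 0.01) {
  K <- ncol(W)
  s <- seq(0, 1, by = step)
  G <- switch(as.character(K),
    "1" = matrix(s, nrow = 1),
    "2" = {
      g <- expand.grid(s, s)
      t(as.matrix(g[rowSums(g) <= 1 + 1e-12, ]))
    },
    "3" = {
      g <- expand.grid(s, s, s)
      t(as.matrix(g[rowSums(g) <= 1 + 1e-12, ]))
    },
    stop("grid oracle supports K <= 3"))
  obj <- colSums((matrix(y, nrow(W), ncol(G)) - W %*% G)^2)
  G[, which.min(obj)]
}

# Exhaustive assignment oracle: best sum of column-wise Pearson correlations
# over all K2! pairings, for K2 <= 5.
match_oracle <- function(A, B) {
  K2 <- ncol(A)
  perms <- all_permutations(K2)
  best <- -Inf; best_perm <- NULL
  for (p in perms) {
    s <- sum(vapply(seq_len(K2),
                    function(j) suppressWarnings(cor(A[, p[j]], B[, j])),
                    numeric(1)))
    if (s > best) { best <- s; best_perm <- p }
  }
  list(perm = best_perm, score = best)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  # insert k into every slot of each (k-1)-permutation
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# Small random mixture instance with valid constraints for property loops.
random_instance <- function(seed, n = 30, m = 8, K = 3, K1 = 1) {
  K1 <- min(K1, K)
  set.seed(seed)
  W <- matrix(runif(n * K, 0.5, 3), n, K)
  H <- t(prede:::rdirichlet_mat(m, rep(1, K)))
  Y <- expression_matrix(W %*% H + matrix(abs(rnorm(n * m, 0, 0.1)), n, m))
  W1 <- if (K1 > 0) {
    reference_panel(W[, seq_len(K1), drop = FALSE],
                    gene_ids = rownames(Y))
  } else NULL
  list(Y = Y, W1 = W1, W = W, H = H, K = K, K1 = K1)
}

# Kuhn-Tucker residual of the sum-constrained QP solution: all of
# stationarity, feasibility and complementary slackness must vanish.
qp_kkt_residual <- function(y, W, h) {
  g <- drop(2 * crossprod(W, W %*% h - y))     # gradient
  s <- 1 - sum(h)
  # multiplier for the sum constraint: if active, it equals the common
  # negative gradient over the strictly positive coordinates
  pos <- h > 1e-10
  mu <- if (s < 1e-8 && any(pos)) max(0, -max(g[pos])) else 0
  stat <- g + mu                                # + lambda_i, lambda_i >= 0
  max(c(-(h), -s, abs(ifelse(pos, stat, pmin(stat, 0))), mu * s))
}
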