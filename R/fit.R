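#' Solver options for the alternating fit
#'
#' @param max_iter maximum number of outer iterations per restart.
#' @param rel_tol convergence threshold on the relative objective decrease
#'   `(prev - cur) / max(prev, eps)` between consecutive outer iterations.
#'   Scale-free, the standard stopping rule for alternating minimization.
#' @param n_restarts number of independent random initializations; the fit
#'   with the lowest final objective is kept (the problem is non-convex for
#'   `K1 < K`).
#' @param seed base integer seed; restart `r` uses `seed + r - 1`.
#' @param init_method initialization of the unknown basis, see
#'   [initialize_W2()].
#' @return an object of class `prede_control`.
#' @export
prede_control <- function(max_iter = 1000L, rel_tol = 1e-6, n_restarts = 5L,
                          seed = 1L,
                          init_method = c("sampled_columns", "uniform")) {
  init_method <- match.arg(init_method)
  max_iter <- as.integer(max_iter)
  n_restarts <- as.integer(n_restarts)
  seed <- as.integer(seed)
  stopifnot(max_iter >= 1L, rel_tol >= 0, n_restarts >= 1L, !is.na(seed))
  structure(list(max_iter = max_iter, rel_tol = rel_tol,
                 n_restarts = n_restarts, seed = seed,
                 init_method = init_method),
            class = "prede_control")
}

#' Partial-reference deconvolution by alternating constrained optimization
#'
#' Fits the partial-reference NMF model `Y = W1 H1 + W2 H2 + e` for a fixed
#' total number of cell types `K`: the profiles `W1` of `K1` cell types are
#' known and held fixed, while the unknown profiles `W2` (genes x (K - K1))
#' and the full proportion matrix `H = rbind(H1, H2)` are estimated by
#' minimizing the squared Frobenius residual subject to `W2 >= 0`, `H >= 0`
#' and column sums of `H` at most 1.
#'
#' Each outer iteration alternates two exact convex steps: the proportion
#' step solves one constrained quadratic program per sample
#' ([solve_proportions_column()]) with the current basis fixed, and the basis
#' step solves one non-negative least-squares problem per gene
#' ([solve_basis_row()]) with the proportions fixed. Both steps are exact
#' minimizers of the joint objective, so the objective trace is
#' non-increasing. The algorithm stops when the relative objective decrease
#' falls below `control$rel_tol` or after `control$max_iter` iterations, and
#' the best of `control$n_restarts` random restarts is returned.
#'
#' Two boundary settings recover the classical methods: `K1 = K` skips the
#' basis step entirely and reduces to per-sample constrained regression
#' (reference-based deconvolution; deterministic, so a single restart is
#' used), and `K1 = 0` (`W1 = NULL`) is reference-free NMF under the same
#' constraints.
#'
#' @param Y genes x samples non-negative mixture matrix, see
#'   [expression_matrix()].
#' @param W1 genes x K1 reference panel with rownames identical to
#'   `rownames(Y)` (use [align_genes()] first), or `NULL` for reference-free
#'   mode.
#' @param K total number of cell types, `K >= max(K1, 1)`.
#' @param control a [prede_control()] object.
#' @return an object of class `prede_fit` with elements `W2_hat`, `H_hat`,
#'   `objective_trace`, `ssr`, `n_iterations`, `converged`, `seed`,
#'   `n_restarts_used`, `K`, `K1`.
#' @export
fit_prede <- function(Y, W1 = NULL, K, control = prede_control()) {
  validate_expression_matrix(Y)
  if (all(Y == 0)) stop("Y is identically zero", call. = FALSE)
  if (is.null(W1))
    W1 <- matrix(numeric(0), nrow = nrow(Y), ncol = 0L,
                 dimnames = list(rownames(Y), NULL))
  validate_reference_panel(W1)
  K1 <- ncol(W1)
  K <- as.integer(K)
  if (K < K1)
    stop("K (", K, ") must be at least the number of reference profiles K1 (",
         K1, ")", call. = FALSE)
  if (K < 1L) stop("K must be at least 1", call. = FALSE)
  if (K1 > 0L && !identical(rownames(Y), rownames(W1)))
    stop("Y and W1 are not gene-aligned; run align_genes() first",
         call. = FALSE)
  stopifnot(inherits(control, "prede_control"))

  K2 <- K - K1
  n_restarts <- if (K2 == 0L) 1L else control$n_restarts

  best <- NULL
  for (r in seq_len(n_restarts)) {
    seed_r <- control$seed + r - 1L
    run <- prede_single_run(Y, W1, K2, control, seed_r)
    if (is.null(best) || run$ssr < best$ssr) best <- run
  }

  labels <- c(colnames(W1), if (K2 > 0L) paste0("unknown_", seq_len(K2)))
  dimnames(best$H) <- list(labels, colnames(Y))
  dimnames(best$W2) <- list(rownames(Y),
                            if (K2 > 0L) paste0("unknown_", seq_len(K2)))

  structure(list(W2_hat = best$W2,
                 H_hat = best$H,
                 objective_trace = best$trace,
                 ssr = best$ssr,
                 n_iterations = length(best$trace),
                 converged = best$converged,
                 seed = control$seed,
                 n_restarts_used = n_restarts,
                 K = K, K1 = K1),
            class = "prede_fit")
}

# One restart of the alternating scheme. Exactness of both convex steps makes
# the recorded objective non-increasing; if floating-point round-off ever
# produces a non-decrease, the previous iterate is restored and the run is
# declared converged.
prede_single_run <- function(Y, W1, K2, control, seed_r) {
  K1 <- ncol(W1)
  W2 <- initialize_W2(Y, K2, control$init_method, seed_r)
  H <- NULL
  trace <- numeric(0)
  converged <- FALSE
  eps <- .Machine$double.eps

  for (iter in seq_len(control$max_iter)) {
    W <- cbind(W1, W2)
    H_new <- cpp_solve_h(W, Y, H)
    if (K2 > 0L) {
      R <- if (K1 > 0L)
        Y - W1 %*% H_new[seq_len(K1), , drop = FALSE] else Y
      H2 <- H_new[K1 + seq_len(K2), , drop = FALSE]
      W2_new <- t(cpp_nnls(t(H2), t(R), t(W2)))
    } else {
      W2_new <- W2
    }
    obj <- sum((Y - cbind(W1, W2_new) %*% H_new)^2)

    if (iter > 1L) {
      prev <- trace[length(trace)]
      dec <- prev - obj
      if (dec < 0) {            # numerical stall: keep the previous iterate
        converged <- TRUE
        break
      }
      trace <- c(trace, obj)
      H <- H_new; W2 <- W2_new
      if (dec / max(prev, eps) < control$rel_tol) {
        converged <- TRUE
        break
      }
    } else {
      trace <- obj
      H <- H_new; W2 <- W2_new
      if (K2 == 0L) {           # convex single-step mode: nothing to iterate
        converged <- TRUE
        break
      }
    }
  }
  # clip negative numerical dust in H
  H[H < 0] <- 0
  list(W2 = W2, H = H, trace = trace, ssr = trace[length(trace)],
       converged = converged)
}

#' @export
print.prede_fit <- function(x, ...) {
  cat("Partial-reference deconvolution fit\n")
  cat("  cell types: K =", x$K, "(known K1 =", x$K1,
      ", unknown K2 =", x$K - x$K1, ")\n")
  cat("  samples:", ncol(x$H_hat), " genes:", nrow(x$W2_hat), "\n")
  cat("  SSR:", format(x$ssr), " after", x$n_iterations, "iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n")
  invisible(x)
}
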