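#' Constrained proportion estimate for a single sample
#'
#' Solves the per-sample quadratic program of the deconvolution model:
#' \deqn{\min_h \|y - W h\|^2 \quad s.t. \quad h \ge 0,\ \textstyle\sum_k h_k \le 1,}
#' the exact convex subproblem used for the proportion step of [fit_prede()].
#' Together with non-negativity, the sum constraint implies every entry lies
#' in \[0, 1\]; the residual mass `1 - sum(h)` is interpretable as signal not
#' captured by the modeled cell types.
#'
#' The non-negative relaxation is solved first (Lawson-Hanson active set);
#' when its optimum violates the sum constraint, the problem is re-solved
#' exactly through the least-distance-programming reduction, so the returned
#' solution satisfies the KKT conditions to machine precision.
#'
#' @param y non-negative numeric vector of length n (one mixture column).
#' @param W non-negative n x K matrix of cell-type profiles; no column may be
#'   all zero.
#' @return numeric vector of length K of estimated proportions.
#' @export
solve_proportions_column <- function(y, W) {
  W <- as.matrix(W)
  y <- as.numeric(y)
  if (length(y) != nrow(W))
    stop("length(y) must equal nrow(W)", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y)) || anyNA(W) || any(!is.finite(W)))
    stop("non-finite values in solver input", call. = FALSE)
  zero <- colSums(abs(W)) == 0
  if (any(zero)) {
    lab <- if (is.null(colnames(W))) which(zero) else colnames(W)[zero]
    stop("all-zero profile column(s) in W make the corresponding ",
         "proportion unidentifiable: ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  h <- drop(cpp_solve_h(W, matrix(y, ncol = 1L)))
  names(h) <- colnames(W)
  h
}

#' Non-negative basis estimate for a single gene
#'
#' Solves the per-gene subproblem of the basis step of [fit_prede()]:
#' \deqn{\min_{w \ge 0} \|r - w H_2\|^2,}
#' where `r` is the gene's residual row after the known-reference
#' contribution has been subtracted, and `H_2` holds the proportions of the
#' unknown cell types. Components whose `H_2` row is all zero are absent from
#' every sample; their weight is set to 0 with a warning rather than failing.
#'
#' @param r numeric vector of length m (may be negative: it is a residual).
#' @param H2 non-negative K2 x m matrix of unknown-component proportions.
#' @return non-negative numeric vector of length K2.
#' @export
solve_basis_row <- function(r, H2) {
  H2 <- as.matrix(H2)
  r <- as.numeric(r)
  if (length(r) != ncol(H2))
    stop("length(r) must equal ncol(H2)", call. = FALSE)
  if (anyNA(r) || any(!is.finite(r)) || anyNA(H2) || any(!is.finite(H2)))
    stop("non-finite values in solver input", call. = FALSE)
  zero <- rowSums(abs(H2)) == 0
  if (any(zero))
    warning("component(s) with all-zero proportions across samples; ",
            "their basis weights are set to 0: ",
            paste(which(zero), collapse = ", "), call. = FALSE)
  drop(cpp_nnls(t(H2), matrix(r, ncol = 1L)))
}

#' Random initialization of the unknown basis
#'
#' Produces the starting value of the unknown basis matrix for one restart of
#' the alternating fit. The default draws K2 distinct mixture columns and
#' perturbs each entrywise by independent Uniform(0.9, 1.1) jitter, giving a
#' start on the scale of the data; `"uniform"` draws iid Uniform(0, max(Y))
#' entries. Both are deterministic given `seed`.
#'
#' @param Y genes x samples mixture matrix.
#' @param K2 number of unknown components (`K2 = 0` yields a 0-column matrix).
#' @param method `"sampled_columns"` (default) or `"uniform"`. When `K2`
#'   exceeds the number of samples, `"sampled_columns"` falls back to
#'   `"uniform"` with a warning.
#' @param seed integer seed.
#' @return non-negative matrix with `nrow(Y)` rows and `K2` columns.
#' @export
initialize_W2 <- function(Y, K2, method = c("sampled_columns", "uniform"),
                          seed = 1L) {
  method <- match.arg(method)
  n <- nrow(Y)
  if (K2 == 0L)
    return(matrix(numeric(0), nrow = n, ncol = 0L,
                  dimnames = list(rownames(Y), NULL)))
  if (K2 < 0L) stop("K2 must be non-negative", call. = FALSE)
  if (method == "sampled_columns" && K2 > ncol(Y)) {
    warning("K2 exceeds the number of samples; ",
            "falling back to uniform initialization", call. = FALSE)
    method <- "uniform"
  }
  set.seed(as.integer(seed))
  W2 <- if (method == "sampled_columns") {
    cols <- sample.int(ncol(Y), K2)
    Y[, cols, drop = FALSE] *
      matrix(runif(n * K2, 0.9, 1.1), nrow = n)
  } else {
    matrix(runif(n * K2, 0, max(Y)), nrow = n)
  }
  dimnames(W2) <- list(rownames(Y), paste0("unknown_", seq_len(K2)))
  W2
}
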