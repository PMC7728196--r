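#' Match estimated components to true components by optimal assignment
#'
#' Estimated unknown components come back in arbitrary order, so accuracy
#' metrics require a pairing with the truth. The pairing is the bijection
#' maximizing the sum of column-wise Pearson correlations, found by
#' maximum-weight bipartite matching on the K2 x K2 correlation matrix.
#' Constant (zero-variance) columns get correlation 0 against everything,
#' with a warning.
#'
#' @param W_true_unknown genes x K2 matrix of true profiles (or true
#'   proportion rows, transposed, when matching on proportions).
#' @param W2_hat genes x K2 matrix of estimated profiles, same K2.
#' @return integer permutation `p` of `1:K2`: estimated column `j` is paired
#'   with true column `p[j]`.
#' @export
match_components <- function(W_true_unknown, W2_hat) {
  A <- as.matrix(W_true_unknown); B <- as.matrix(W2_hat)
  K2 <- ncol(A)
  if (ncol(B) != K2)
    stop("both sides must have the same number of components", call. = FALSE)
  if (K2 == 0L) return(integer(0))
  if (nrow(A) != nrow(B))
    stop("component matrices must have the same number of rows",
         call. = FALSE)
  const_a <- apply(A, 2, sd) == 0
  const_b <- apply(B, 2, sd) == 0
  if (any(const_a) || any(const_b))
    warning("constant column(s) in component matching; ",
            "their correlations are set to 0", call. = FALSE)
  C <- matrix(0, K2, K2)   # rows: true, cols: estimated
  for (i in seq_len(K2)) {
    for (j in seq_len(K2)) {
      if (!const_a[i] && !const_b[j]) C[i, j] <- cor(A[, i], B[, j])
    }
  }
  if (K2 == 1L) return(1L)
  g <- igraph::make_full_bipartite_graph(K2, K2)
  # edges are emitted row-major: (true 1, est 1), (true 1, est 2), ...
  igraph::E(g)$weight <- as.vector(t(C)) + 2  # shift > 0 so matching is perfect
  mm <- igraph::max_bipartite_match(g)$matching
  est_for_true <- mm[seq_len(K2)] - K2        # true i -> estimated column
  perm <- integer(K2)
  perm[est_for_true] <- seq_len(K2)           # estimated j -> true perm[j]
  perm
}

#' Mean absolute error between true and estimated proportions
#'
#' @param H_true,H_hat K x m proportion matrices with components already in
#'   matched order.
#' @return list with `per_type` (mean over samples of the absolute error,
#'   one value per cell type) and `overall` (mean over all K x m entries).
#' @export
mae_proportions <- function(H_true, H_hat) {
  H_true <- as.matrix(H_true); H_hat <- as.matrix(H_hat)
  if (!all(dim(H_true) == dim(H_hat)))
    stop("proportion matrices must have identical dimensions", call. = FALSE)
  err <- abs(H_true - H_hat)
  per_type <- rowMeans(err)
  names(per_type) <- rownames(H_true)
  list(per_type = per_type, overall = mean(err))
}

#' Pearson correlation with degenerate-input guard
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return the Pearson product-moment correlation; `NaN` with a warning when
#'   either input has zero variance.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NaN)
  }
  cor(x, y)
}

#' Shannon heterogeneity index of a proportion vector
#'
#' Entropy `-sum(p * log(p))` (natural log; the base only rescales) of the
#' vector renormalized to sum 1, with `0 * log(0) := 0`. Used as a per-sample
#' heterogeneity score of the cell-type composition.
#'
#' @param h non-negative vector, not all zero.
#' @return non-negative real; 0 for a single-type sample, `log(K)` for the
#'   uniform composition over K types.
#' @export
shannon_index <- function(h) {
  h <- as.numeric(h)
  if (any(h < 0)) stop("proportions must be non-negative", call. = FALSE)
  s <- sum(h)
  if (s == 0) stop("all-zero proportion vector", call. = FALSE)
  p <- h / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two proportion vectors
#'
#' `sum(|h1 - h2|) / sum(h1 + h2)`: 0 for identical compositions, 1 for
#' compositions with disjoint support.
#'
#' @param h1,h2 non-negative vectors of equal length, not both all zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(h1, h2) {
  h1 <- as.numeric(h1); h2 <- as.numeric(h2)
  if (length(h1) != length(h2)) stop("unequal lengths", call. = FALSE)
  if (any(h1 < 0) || any(h2 < 0))
    stop("proportions must be non-negative", call. = FALSE)
  tot <- sum(h1) + sum(h2)
  if (tot == 0) stop("both vectors are all zero", call. = FALSE)
  sum(abs(h1 - h2)) / tot
}

#' Relative proportions within a subset of cell types
#'
#' Restricts a proportion matrix to the given cell types and renormalizes
#' every column to sum 1 (e.g. relative abundances among immune cell types
#' only). Columns whose subset total is 0 become all-`NaN` with a warning.
#'
#' @param H K x m proportion matrix with cell-type rownames.
#' @param subset non-empty character vector of row labels.
#' @return the restricted, renormalized matrix.
#' @export
relative_proportions <- function(H, subset) {
  H <- as.matrix(H)
  if (!length(subset)) stop("subset must be non-empty", call. = FALSE)
  missing <- setdiff(subset, rownames(H))
  if (length(missing))
    stop("unknown cell-type label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  Hs <- H[subset, , drop = FALSE]
  tot <- colSums(Hs)
  if (any(tot == 0))
    warning(sum(tot == 0), " column(s) have zero total over the subset; ",
            "returned as NaN", call. = FALSE)
  sweep(Hs, 2, tot, "/")
}

#' Score a deconvolution fit against simulated ground truth
#'
#' Pairs the estimated unknown components with the true ones via
#' [match_components()] (on profiles by default; on proportion rows when
#' profiles are poorly identified, e.g. reference-free mode), reorders the
#' estimate accordingly and reports proportion MAE, per-type proportion
#' correlations and per-unknown-type profile correlations.
#'
#' @param truth a [generate_mixture()] result.
#' @param fit a [fit_prede()] result on that truth's data, fit with
#'   `truth_reference(truth)` as the panel (`K` may differ from the design's
#'   true `K` only if the unknown counts coincide).
#' @param match_by `"profile"` (default) or `"proportion"`.
#' @return an object of class `prede_eval`: list with `matching`,
#'   `proportion_mae` (list per_type/overall), `proportion_pcc` (per type)
#'   and `profile_pcc` (per unknown type).
#' @export
evaluate_deconvolution <- function(truth, fit,
                                   match_by = c("profile", "proportion")) {
  stopifnot(inherits(truth, "prede_truth"), inherits(fit, "prede_fit"))
  match_by <- match.arg(match_by)
  known <- truth$design$known_indices
  unknown <- setdiff(seq_len(truth$design$K), known)
  K2 <- fit$K - fit$K1
  if (length(unknown) != K2)
    stop("fit has ", K2, " unknown components but the design has ",
         length(unknown), call. = FALSE)

  if (K2 > 0L) {
    perm <- if (match_by == "profile") {
      match_components(truth$W_true[, unknown, drop = FALSE], fit$W2_hat)
    } else {
      match_components(t(truth$H_true[unknown, , drop = FALSE]),
                       t(fit$H_hat[fit$K1 + seq_len(K2), , drop = FALSE]))
    }
  } else {
    perm <- integer(0)
  }

  # reorder estimate into the truth's component order
  true_order <- c(known, unknown)
  est_rows <- seq_len(fit$K)
  if (K2 > 0L) {
    est_unknown <- (fit$K1 + seq_len(K2))[order(perm)]
    est_rows <- c(seq_len(fit$K1), est_unknown)
  }
  H_true_ord <- truth$H_true[true_order, , drop = FALSE]
  H_hat_ord <- fit$H_hat[est_rows, , drop = FALSE]

  mae <- mae_proportions(H_true_ord, H_hat_ord)
  prop_pcc <- vapply(seq_len(nrow(H_true_ord)), function(k) {
    suppressWarnings(pcc(H_true_ord[k, ], H_hat_ord[k, ]))
  }, numeric(1))
  names(prop_pcc) <- rownames(H_true_ord)

  profile_pcc <- if (K2 > 0L) {
    W_true_unk <- truth$W_true[, unknown, drop = FALSE]
    W2_ord <- fit$W2_hat[, order(perm), drop = FALSE]
    out <- vapply(seq_len(K2), function(k) {
      suppressWarnings(pcc(W_true_unk[, k], W2_ord[, k]))
    }, numeric(1))
    names(out) <- colnames(W_true_unk)
    out
  } else numeric(0)

  structure(list(matching = perm, proportion_mae = mae,
                 proportion_pcc = prop_pcc, profile_pcc = profile_pcc,
                 match_by = match_by),
            class = "prede_eval")
}

#' @export
print.prede_eval <- function(x, ...) {
  cat("Deconvolution accuracy report\n")
  cat("  overall proportion MAE:", format(x$proportion_mae$overall), "\n")
  if (length(x$profile_pcc))
    cat("  unknown-profile PCC:",
        paste(format(x$profile_pcc, digits = 3), collapse = ", "), "\n")
  invisible(x)
}
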