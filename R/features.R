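#' Select high-variability genes by coefficient of variation
#'
#' Ranks genes by the coefficient of variation (sample standard deviation
#' divided by mean) computed on the bulk mixture matrix alone, and keeps the
#' top `k`. Genes whose mean is below `1e-8` are excluded before ranking
#' (the CV is undefined at mean zero). Ties are broken by input gene order.
#' The reference panel is subset to the selected genes afterwards, not used
#' in the ranking.
#'
#' @param Y genes x samples mixture matrix.
#' @param k number of genes to keep (default 1000). If fewer genes survive
#'   the mean filter, all of them are returned with a warning.
#' @return an object of class `prede_features`: a list with
#'   `selected_gene_ids` (ordered by decreasing CV), `cv_values` (named, same
#'   order) and `k_requested`.
#' @export
select_features <- function(Y, k = 1000L) {
  validate_expression_matrix(Y)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  means <- rowMeans(Y)
  keep <- means >= 1e-8
  if (!any(keep))
    stop("all genes excluded by the mean filter; cannot rank by CV",
         call. = FALSE)
  Yk <- Y[keep, , drop = FALSE]
  mk <- means[keep]
  sds <- sqrt(rowSums((Yk - mk)^2) / max(ncol(Yk) - 1L, 1L))
  cv <- sds / mk
  ord <- order(-cv, seq_along(cv))          # ties keep input order
  if (sum(keep) < k)
    warning("only ", sum(keep), " genes survive the mean filter; ",
            "returning all of them (k = ", k, " requested)", call. = FALSE)
  top <- head(ord, k)
  structure(list(selected_gene_ids = rownames(Yk)[top],
                 cv_values = stats::setNames(cv[top], rownames(Yk)[top]),
                 k_requested = k),
            class = "prede_features")
}

#' @export
print.prede_features <- function(x, ...) {
  cat("CV feature selection:", length(x$selected_gene_ids), "genes kept (",
      x$k_requested, "requested )\n")
  invisible(x)
}

#' Joint quantile normalization of gene-aligned expression matrices
#'
#' Classic quantile normalization across all columns of all supplied
#' matrices jointly: each column's sorted values are replaced by the
#' across-column mean of sorted values (ties resolved by averaging), after
#' which every column shares the same value multiset. Used to put basis
#' profiles from heterogeneous sources on a common distribution before
#' mixing.
#'
#' @param matrices a single matrix or a list of gene-aligned matrices (at
#'   least two columns in total).
#' @return the input, quantile normalized: a matrix if a matrix was given, a
#'   list of matrices otherwise.
#' @export
quantile_normalize <- function(matrices) {
  single <- is.matrix(matrices)
  if (single) matrices <- list(matrices)
  if (!length(matrices) || !all(vapply(matrices, is.matrix, logical(1))))
    stop("matrices must be a matrix or a list of matrices", call. = FALSE)
  genes <- rownames(matrices[[1L]])
  for (M in matrices)
    if (!identical(rownames(M), genes))
      stop("matrices are not gene-aligned; identical rownames required",
           call. = FALSE)
  combined <- do.call(cbind, matrices)
  if (ncol(combined) < 2L)
    stop("need at least two columns in total to quantile normalize",
         call. = FALSE)
  normed <- limma::normalizeQuantiles(combined, ties = TRUE)
  dimnames(normed) <- dimnames(combined)
  if (single) return(normed)
  ends <- cumsum(vapply(matrices, ncol, integer(1)))
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- Map(function(s, e) normed[, s:e, drop = FALSE], starts, ends)
  names(out) <- names(matrices)
  out
}
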