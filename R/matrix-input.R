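#' Construct a validated expression matrix
#'
#' Bulk mixture data are represented as a plain numeric matrix with genes as
#' rows and samples as columns, carrying gene identifiers as `rownames` and
#' sample identifiers as `colnames`. Expression values must be on a linear
#' (non-log) scale, since the mixing model is linear in expression.
#'
#' @param values numeric matrix, genes x samples, all entries finite and
#'   non-negative.
#' @param gene_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`; both must be duplicate-free.
#' @return the validated numeric matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
  values
}

#' Construct a validated reference panel of known cell-type profiles
#'
#' A reference panel holds the expression profiles of the known cell types
#' (the known part of the basis matrix), gene-aligned to the mixture matrix
#' it will be fit against. An empty panel (zero columns) encodes the
#' reference-free setting.
#'
#' @param values numeric matrix, genes x K1, non-negative; a matrix with zero
#'   columns is permitted.
#' @param gene_ids,cell_type_labels optional dimnames overrides.
#' @return the validated numeric matrix.
#' @export
reference_panel <- function(values, gene_ids = rownames(values),
                            cell_type_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(cell_type_labels) && ncol(values) > 0)
    cell_type_labels <- paste0("celltype_", seq_len(ncol(values)))
  rownames(values) <- as.character(gene_ids)
  if (ncol(values) > 0) colnames(values) <- as.character(cell_type_labels)
  validate_reference_panel(values)
  values
}

validate_expression_matrix <- function(Y, what = "expression matrix") {
  if (!is.matrix(Y) || !is.numeric(Y))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(Y) < 1L || ncol(Y) < 1L)
    stop(what, " must have at least one gene and one sample", call. = FALSE)
  if (anyNA(Y) || any(!is.finite(Y)))
    stop(what, " contains missing or non-finite values", call. = FALSE)
  if (any(Y < 0))
    stop(what, " contains negative values; expression must be on a linear, ",
         "non-negative scale (see the delog2 option of read_expression_matrix)",
         call. = FALSE)
  check_unique_ids(rownames(Y), "gene")
  check_unique_ids(colnames(Y), "sample/column")
  invisible(Y)
}

validate_reference_panel <- function(W1) {
  if (!is.matrix(W1) || !is.numeric(W1))
    stop("reference panel must be a numeric matrix", call. = FALSE)
  if (ncol(W1) == 0L) return(invisible(W1))
  if (anyNA(W1) || any(!is.finite(W1)))
    stop("reference panel contains missing or non-finite values", call. = FALSE)
  if (any(W1 < 0))
    stop("reference panel contains negative values", call. = FALSE)
  check_unique_ids(rownames(W1), "gene")
  check_unique_ids(colnames(W1), "cell-type")
  zero <- colSums(W1) == 0
  if (any(zero))
    stop("reference panel has all-zero profile(s): ",
         paste(colnames(W1)[zero], collapse = ", "), call. = FALSE)
  invisible(W1)
}

check_unique_ids <- function(ids, what) {
  if (is.null(ids))
    stop("missing ", what, " identifiers", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated ", what, " identifiers: ",
         paste(head(dup, 5L), collapse = ", "), call. = FALSE)
  invisible(ids)
}

#' Align a mixture matrix and a reference panel on shared genes
#'
#' Restricts both matrices to the intersection of their gene identifiers, in
#' the gene order of `Y`. Fitting requires identical gene sets in identical
#' order; this is the canonical way to establish that.
#'
#' @param Y genes x samples mixture matrix (see [expression_matrix()]).
#' @param W1 genes x K1 reference panel (see [reference_panel()]).
#' @return list with elements `Y` and `W1`, both restricted to the shared
#'   genes. A warning is emitted when fewer than half of the genes of `Y`
#'   survive the intersection.
#' @export
align_genes <- function(Y, W1) {
  validate_expression_matrix(Y)
  validate_reference_panel(W1)
  if (ncol(W1) == 0L) return(list(Y = Y, W1 = W1[rownames(Y), , drop = FALSE]))
  shared <- intersect(rownames(Y), rownames(W1))
  if (length(shared) == 0L)
    stop("no genes shared between the mixture matrix (", nrow(Y),
         " genes) and the reference panel (", nrow(W1), " genes)",
         call. = FALSE)
  shared <- rownames(Y)[rownames(Y) %in% shared]
  if (length(shared) < 0.5 * nrow(Y))
    warning("gene alignment retains only ", length(shared), " of ", nrow(Y),
            " mixture genes", call. = FALSE)
  list(Y = Y[shared, , drop = FALSE], W1 = W1[shared, , drop = FALSE])
}
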