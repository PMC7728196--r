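#' Read a delimited expression matrix
#'
#' Reads a genes-as-rows delimited text file: first column gene identifiers,
#' header row of column identifiers. The delimiter is auto-detected (tab or
#' comma). Rows containing missing values are dropped with a message;
#' duplicate gene identifiers and (after optional unlogging) negative values
#' are errors.
#'
#' @param path file path.
#' @param delog2 if `TRUE`, applies `2^x - 1` entrywise before validation,
#'   for matrices stored as `log2(x + 1)`. Values are never transformed
#'   silently.
#' @param transpose if `TRUE`, the file is samples-as-rows and is transposed
#'   after reading.
#' @return validated numeric matrix (genes x columns).
#' @export
read_expression_matrix <- function(path, delog2 = FALSE, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("no data rows/columns in ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated gene identifiers in ", path, ": ",
         paste(head(dup, 5L), collapse = ", "), call. = FALSE)
  rownames(M) <- ids
  drop_rows <- apply(M, 1L, anyNA)
  if (any(drop_rows)) {
    message("dropping ", sum(drop_rows), " row(s) with missing values")
    M <- M[!drop_rows, , drop = FALSE]
    if (nrow(M) == 0L) stop("all rows contain missing values", call. = FALSE)
  }
  if (transpose) M <- t(M)
  if (delog2) M <- 2^M - 1
  if (any(M < 0))
    stop("negative values in ", path,
         if (!delog2) " (log-scale input? see delog2)" else "",
         call. = FALSE)
  expression_matrix(M)
}

write_matrix_tsv <- function(M, path, row_label = "gene") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- row_label
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

manifest_json <- function(outdir, ...) {
  manifest <- list(..., package_version = as.character(packageVersion("prede")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a result object to a directory of plain-text files
#'
#' Every result is written as TSV matrices plus a JSON manifest recording
#' the seed and options, so a run is fully reproducible from its output
#' directory. Matrices round-trip through [read_expression_matrix()] at
#' better than 10 significant digits.
#'
#' @param x a `prede_fit`, `prede_select`, `prede_eval` or `prede_truth`
#'   object.
#' @param outdir output directory (created if needed).
#' @param ... unused.
#' @return invisibly, the vector of files written.
#' @export
write_result <- function(x, outdir, ...) UseMethod("write_result")

#' @export
write_result.prede_fit <- function(x, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(x$H_hat, file.path(outdir, "H.tsv"), "cell_type")
  if (ncol(x$W2_hat) > 0L)
    write_matrix_tsv(x$W2_hat, file.path(outdir, "W2.tsv"))
  write.table(data.frame(iteration = seq_along(x$objective_trace),
                         objective = format(x$objective_trace, digits = 15)),
              file.path(outdir, "objective_trace.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_json(outdir, result = "fit", seed = x$seed, K = x$K, K1 = x$K1,
                n_restarts_used = x$n_restarts_used, ssr = x$ssr,
                n_iterations = x$n_iterations, converged = x$converged)
  invisible(file.path(outdir, c("H.tsv", "W2.tsv", "objective_trace.tsv",
                                "manifest.json")))
}

#' @export
write_result.prede_select <- function(x, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(x$fits, file.path(outdir, "aicc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest_json(outdir, result = "select_k", seed = x$seed, K1 = x$K1,
                selected_K = x$selected_K)
  invisible(file.path(outdir, c("aicc.tsv", "manifest.json")))
}

#' @export
write_result.prede_eval <- function(x, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  per_type <- data.frame(cell_type = names(x$proportion_mae$per_type),
                         mae = x$proportion_mae$per_type,
                         proportion_pcc = x$proportion_pcc)
  write.table(per_type, file.path(outdir, "per_type.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary <- list(result = "evaluate",
                  overall_mae = x$proportion_mae$overall,
                  profile_pcc = as.list(x$profile_pcc),
                  matching = x$matching, match_by = x$match_by)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(outdir, c("per_type.tsv", "summary.json")))
}

#' @export
write_result.prede_truth <- function(x, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(x$Y_noisy, file.path(outdir, "Y.tsv"))
  write_matrix_tsv(x$W_true, file.path(outdir, "W_true.tsv"))
  write_matrix_tsv(x$H_true, file.path(outdir, "H_true.tsv"), "cell_type")
  W1 <- truth_reference(x)
  if (ncol(W1) > 0L) write_matrix_tsv(W1, file.path(outdir, "W1.tsv"))
  d <- x$design
  manifest_json(outdir, result = "simulate", seed = d$seed,
                n_genes = d$n_genes, n_samples = d$n_samples, K = d$K,
                known_indices = d$known_indices, noise_c = d$noise_c,
                dirichlet_alpha = d$dirichlet_alpha)
  invisible(file.path(outdir, c("Y.tsv", "W_true.tsv", "H_true.tsv",
                                "manifest.json")))
}

#' Serialize or load a mixture design as YAML
#'
#' @param design a [mixture_design()].
#' @param path file path.
#' @return `write_design` returns `path` invisibly; `read_design` returns
#'   the reconstructed [mixture_design()].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "mixture_design"))
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- yaml::read_yaml(path)
  groups <- if (!is.null(d$groups))
    lapply(d$groups, function(g) list(indices = unlist(g$indices),
                                      prop = g$prop))
  similarity <- if (!is.null(d$similarity))
    lapply(d$similarity, function(s) list(pair = unlist(s$pair),
                                          pcc = s$pcc))
  mixture_design(n_genes = d$n_genes, n_samples = d$n_samples, K = d$K,
                 known_indices = unlist(d$known_indices),
                 dirichlet_alpha = d$dirichlet_alpha %||% 1,
                 noise_c = d$noise_c %||% 0,
                 rare = d$rare, groups = groups,
                 similarity = similarity, seed = d$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
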