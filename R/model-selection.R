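#' Number of free parameters of the partial-reference model
#'
#' For `K` total cell types of which `K1` have known profiles, the free
#' parameters are the entries of the unknown basis (`n x (K - K1)`) and of
#' the full proportion matrix (`K x m`), i.e. `K * (n + m) - n * K1`. When
#' `K1 = K` only the proportions are free and the count reduces to `K * m`.
#'
#' @param n number of genes (features).
#' @param m number of samples.
#' @param K total number of cell types.
#' @param K1 number of known cell types, `0 <= K1 <= K`.
#' @return integer parameter count.
#' @export
count_parameters <- function(n, m, K, K1) {
  stopifnot(n >= 1, m >= 1, K >= 1, K1 >= 0)
  if (K1 > K)
    stop("K1 (", K1, ") cannot exceed K (", K, ")", call. = FALSE)
  as.integer(K * (n + m) - n * K1)
}

#' Small-sample-corrected Akaike information criterion
#'
#' Evaluates
#' \deqn{AICc = N \ln(SSR/N) + 2p + \frac{2p(p+1)}{N - p - 1}}
#' for a least-squares model with `p` free parameters fit to `N`
#' observations with residual sum of squares `SSR`. The correction term
#' penalizes heavily when `p` approaches `N`; when `N - p - 1 <= 0` the
#' criterion is `+Inf` (the model is not admissible at this sample size). A
#' perfect fit (`ssr = 0`) returns `-Inf` with a warning, since it dominates
#' any finite criterion value.
#'
#' @param ssr non-negative residual sum of squares.
#' @param N number of observations (for deconvolution, genes x samples).
#' @param p number of free parameters, see [count_parameters()].
#' @return the criterion value (possibly infinite).
#' @export
aicc <- function(ssr, N, p) {
  stopifnot(N >= 1, p >= 0)
  if (ssr < 0) stop("ssr must be non-negative", call. = FALSE)
  if (N - p - 1 <= 0) return(Inf)
  if (ssr == 0) {
    warning("ssr is exactly 0; AICc is -Inf (perfect fit)", call. = FALSE)
    return(-Inf)
  }
  N * log(ssr / N) + 2 * p + 2 * p * (p + 1) / (N - p - 1)
}

#' Select the number of cell types by AICc minimization
#'
#' Fits the deconvolution model for every candidate `K` in
#' `K_min:K_max` and scores each fit by [aicc()] with `N = n * m`
#' observations (residuals are counted at the level of individual
#' gene-by-sample entries) and `p = count_parameters(n, m, K, K1)`. The
#' selected `K` is the smallest candidate attaining the minimum finite
#' criterion value (parsimony on ties). Candidates are fit independently,
#' each with the full restart budget of `control`.
#'
#' @param Y genes x samples mixture matrix.
#' @param W1 reference panel (or `NULL` for reference-free selection).
#' @param K_min,K_max candidate range; `K_min` must be at least
#'   `max(K1, 1)`.
#' @param control a [prede_control()] object.
#' @return an object of class `prede_select` with elements `candidate_Ks`,
#'   `aicc_values`, `selected_K` and `fits` (a data frame with one row per
#'   candidate: K, ssr, converged, n_iterations, aicc).
#' @export
select_K <- function(Y, W1 = NULL, K_min, K_max, control = prede_control()) {
  validate_expression_matrix(Y)
  K1 <- if (is.null(W1)) 0L else ncol(W1)
  K_min <- as.integer(K_min); K_max <- as.integer(K_max)
  if (K_min < K1)
    stop("K_min (", K_min, ") is below the number of reference profiles K1 (",
         K1, "); reference cell types cannot exceed the total", call. = FALSE)
  if (K_min < 1L || K_max < K_min)
    stop("need 1 <= K_min <= K_max", call. = FALSE)

  n <- nrow(Y); m <- ncol(Y); N <- n * m
  Ks <- K_min:K_max
  fits <- vector("list", length(Ks))
  vals <- numeric(length(Ks))
  for (i in seq_along(Ks)) {
    fit <- fit_prede(Y, W1, Ks[i], control)
    fits[[i]] <- fit
    vals[i] <- aicc(fit$ssr, N, count_parameters(n, m, Ks[i], K1))
  }
  if (all(!is.finite(vals) & vals > 0))
    stop("AICc is infinite for every candidate K; ",
         "the model is over-parameterized at this data size", call. = FALSE)
  selected <- Ks[which.min(vals)]   # which.min takes the first (smallest K)

  structure(list(candidate_Ks = Ks,
                 aicc_values = vals,
                 selected_K = selected,
                 fits = data.frame(
                   K = Ks,
                   ssr = vapply(fits, `[[`, numeric(1), "ssr"),
                   converged = vapply(fits, `[[`, logical(1), "converged"),
                   n_iterations = vapply(fits, `[[`, integer(1),
                                         "n_iterations"),
                   aicc = vals),
                 K1 = K1,
                 seed = control$seed),
            class = "prede_select")
}

#' @export
print.prede_select <- function(x, ...) {
  cat("AICc selection of the number of cell types\n")
  cat("  candidates:", min(x$candidate_Ks), "..", max(x$candidate_Ks),
      " (K1 =", x$K1, ")\n")
  cat("  selected K =", x$selected_K, "\n")
  print(x$fits, row.names = FALSE)
  invisible(x)
}
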