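#' Specify a simulated mixture benchmark
#'
#' A mixture design fixes everything needed to generate one synthetic bulk
#' deconvolution benchmark: basis profiles for `K` cell types (of which the
#' ones in `known_indices` are handed to the estimator as the reference),
#' per-sample proportions, and mean-proportional Gaussian noise.
#'
#' Proportion modes (mutually exclusive beyond the plain default):
#' * plain — each sample's proportions are Dirichlet(`dirichlet_alpha`)
#'   draws over the `K` simplex (columns sum to 1);
#' * `rare` — one component is pinned at a fixed proportion `f` in every
#'   sample and the remaining `K - 1` proportions are Dirichlet draws scaled
#'   by `1 - f`;
#' * `groups` — components are partitioned into groups (e.g. cancer /
#'   immune / normal); per-sample group totals are Dirichlet draws
#'   concentrated around the target group proportions (concentration 100, so
#'   realized totals are "roughly" the targets), then split within each
#'   group by a nested Dirichlet.
#'
#' @param n_genes,n_samples dimensions of the simulated mixture matrix.
#' @param K total number of cell types; `n_genes` must be at least `10 * K`.
#' @param known_indices integer indices (possibly empty) of the cell types
#'   whose true profiles form the reference panel.
#' @param dirichlet_alpha Dirichlet concentration for proportion draws
#'   (default 1: uniform over the simplex).
#' @param noise_c noise level in \[0, 1\]: per gene, Gaussian noise with
#'   standard deviation `noise_c` times the gene's mean clean expression.
#' @param rare optional `list(component =, f =)` with `0 < f < 1`.
#' @param groups optional list of `list(indices =, prop =)` entries whose
#'   `indices` partition `1:K` and whose `prop` values sum to 1.
#' @param similarity optional list of `list(pair = c(i, j), pcc =)` entries;
#'   the basis column `j` is rebuilt as a blend of column `i` and a fresh
#'   profile, calibrated so their Pearson correlation hits `pcc` (see
#'   [synth_basis()]).
#' @param seed integer seed; generation is fully deterministic given the
#'   design.
#' @return an object of class `mixture_design`.
#' @export
mixture_design <- function(n_genes, n_samples, K, known_indices = integer(0),
                           dirichlet_alpha = 1, noise_c = 0, rare = NULL,
                           groups = NULL, similarity = NULL, seed = 1L) {
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  K <- as.integer(K); known_indices <- as.integer(known_indices)
  stopifnot(n_genes >= 1L, n_samples >= 1L, K >= 1L,
            dirichlet_alpha > 0, noise_c >= 0, noise_c <= 1)
  if (n_genes < 10L * K)
    stop("n_genes must be at least 10 * K", call. = FALSE)
  if (length(known_indices) &&
      (anyDuplicated(known_indices) || any(known_indices < 1L) ||
       any(known_indices > K)))
    stop("known_indices must be distinct indices in 1..K", call. = FALSE)
  if (!is.null(rare)) {
    if (!is.list(rare) || is.null(rare$component) || is.null(rare$f))
      stop("rare must be list(component =, f =)", call. = FALSE)
    if (!is.null(groups))
      stop("rare and groups modes are mutually exclusive", call. = FALSE)
    stopifnot(rare$f > 0, rare$f < 1,
              rare$component >= 1, rare$component <= K)
  }
  if (!is.null(groups)) {
    idx <- unlist(lapply(groups, `[[`, "indices"))
    props <- vapply(groups, `[[`, numeric(1), "prop")
    if (!setequal(idx, seq_len(K)) || anyDuplicated(idx))
      stop("group indices must partition 1..K", call. = FALSE)
    if (abs(sum(props) - 1) > 1e-8)
      stop("group proportions must sum to 1", call. = FALSE)
  }
  if (!is.null(similarity)) {
    for (s in similarity) {
      stopifnot(length(s$pair) == 2L, all(s$pair %in% seq_len(K)),
                s$pair[1] != s$pair[2], s$pcc > -1, s$pcc < 1)
    }
  }
  structure(list(n_genes = n_genes, n_samples = n_samples, K = K,
                 known_indices = known_indices,
                 dirichlet_alpha = dirichlet_alpha, noise_c = noise_c,
                 rare = rare, groups = groups, similarity = similarity,
                 seed = as.integer(seed)),
            class = "mixture_design")
}

# Dirichlet draws, one per row, via the normalized-gamma construction.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Synthetic basis profiles with controllable pairwise similarity
#'
#' Draws `K` baseline cell-type profiles with iid log-normal entries
#' (log-mean 3, log-sd 1.2), mimicking the dispersion of linear-scale
#' expression across genes; independent draws give weakly correlated,
#' well-separated profiles. For every `(pair = c(i, j), pcc = rho)` entry of
#' `similarity`, column `j` is rebuilt as the convex blend
#' `lambda * column_i + (1 - lambda) * fresh profile`, with `lambda`
#' calibrated by bisection until the sample Pearson correlation of columns
#' `i` and `j` is within 0.01 of `rho`.
#'
#' @param n_genes number of genes, at least `10 * K`.
#' @param K number of profiles.
#' @param similarity optional list of `list(pair = c(i, j), pcc =)` entries.
#' @param seed integer seed.
#' @return non-negative `n_genes` x `K` matrix.
#' @export
synth_basis <- function(n_genes, K, similarity = NULL, seed = 1L) {
  n_genes <- as.integer(n_genes); K <- as.integer(K)
  if (n_genes < 10L * K)
    stop("n_genes must be at least 10 * K", call. = FALSE)
  set.seed(as.integer(seed))
  W <- matrix(rlnorm(n_genes * K, meanlog = 3, sdlog = 1.2), nrow = n_genes)
  if (!is.null(similarity)) {
    for (s in similarity) {
      i <- s$pair[1]; j <- s$pair[2]; rho <- s$pcc
      fresh <- rlnorm(n_genes, meanlog = 3, sdlog = 1.2)
      lo <- 0; hi <- 1
      best <- Inf; done <- FALSE
      for (step in seq_len(60L)) {
        lam <- (lo + hi) / 2
        cand <- lam * W[, i] + (1 - lam) * fresh
        p <- cor(W[, i], cand)
        if (abs(p - rho) < best) best <- abs(p - rho)
        if (abs(p - rho) <= 0.01) {
          W[, j] <- cand
          done <- TRUE
          break
        }
        if (p < rho) lo <- lam else hi <- lam
      }
      if (!done)
        stop("similarity calibration for pair (", i, ",", j,
             ") failed to reach target PCC ", rho,
             " (best |PCC - target| = ", format(best), ")", call. = FALSE)
    }
  }
  dimnames(W) <- list(sprintf("gene_%05d", seq_len(n_genes)),
                      paste0("celltype_", seq_len(K)))
  W
}

#' Draw the true proportion matrix of a mixture design
#'
#' Columns are samples and always sum to exactly 1 (the estimator's
#' column-sum-at-most-one constraint contains the simulation truth). See
#' [mixture_design()] for the plain, rare and group modes.
#'
#' @param design a [mixture_design()].
#' @return `K` x `n_samples` proportion matrix.
#' @export
sample_proportions <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  set.seed(design$seed + 1L)
  K <- design$K; m <- design$n_samples; alpha <- design$dirichlet_alpha
  if (!is.null(design$rare)) {
    f <- design$rare$f; rc <- design$rare$component
    rest <- t(rdirichlet_mat(m, rep(alpha, K - 1L))) * (1 - f)
    H <- matrix(0, nrow = K, ncol = m)
    H[rc, ] <- f
    H[setdiff(seq_len(K), rc), ] <- rest
  } else if (!is.null(design$groups)) {
    targets <- vapply(design$groups, `[[`, numeric(1), "prop")
    totals <- rdirichlet_mat(m, 100 * targets)     # m x n_groups
    H <- matrix(0, nrow = K, ncol = m)
    for (g in seq_along(design$groups)) {
      idx <- design$groups[[g]]$indices
      within <- rdirichlet_mat(m, rep(alpha, length(idx)))
      H[idx, ] <- t(within * totals[, g])
    }
  } else {
    H <- t(rdirichlet_mat(m, rep(alpha, K)))
  }
  dimnames(H) <- list(paste0("celltype_", seq_len(K)),
                      sprintf("sample_%03d", seq_len(m)))
  H
}

#' Add mean-proportional Gaussian noise to a clean mixture
#'
#' For every gene, iid Gaussian noise with mean 0 and standard deviation
#' `c` times the gene's mean clean expression is added to each entry of its
#' row; resulting negative values are truncated at 0 (expression is
#' non-negative, as the estimator assumes).
#'
#' @param Y_clean non-negative genes x samples matrix.
#' @param c noise level, `c >= 0`; `c = 0` returns `Y_clean` unchanged.
#' @param seed integer seed.
#' @return matrix of the same shape, entries >= 0.
#' @export
add_noise <- function(Y_clean, c = 0, seed = 1L) {
  stopifnot(c >= 0)
  if (c == 0) return(Y_clean)
  set.seed(as.integer(seed))
  n <- nrow(Y_clean); m <- ncol(Y_clean)
  sds <- c * rowMeans(Y_clean)
  E <- matrix(rnorm(n * m, mean = 0, sd = sds), nrow = n)  # sd recycles by row
  pmax(Y_clean + E, 0)
}

#' Generate a full synthetic benchmark with ground truth
#'
#' Composes [synth_basis()], [sample_proportions()], the matrix product and
#' [add_noise()], recording every intermediate. Fully deterministic given
#' the design (the basis, proportion and noise draws use `seed`, `seed + 1`
#' and `seed + 2` respectively).
#'
#' @param design a [mixture_design()].
#' @return an object of class `prede_truth`: list with `W_true`, `H_true`,
#'   `Y_clean` (`= W_true %*% H_true` exactly), `Y_noisy` and `design`.
#' @export
generate_mixture <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  W <- synth_basis(design$n_genes, design$K, design$similarity, design$seed)
  H <- sample_proportions(design)
  Y_clean <- W %*% H
  Y_noisy <- add_noise(Y_clean, design$noise_c, design$seed + 2L)
  structure(list(W_true = W, H_true = H, Y_clean = Y_clean,
                 Y_noisy = Y_noisy, design = design),
            class = "prede_truth")
}

#' Extract the known reference panel of a simulated truth
#'
#' @param truth a [generate_mixture()] result.
#' @return the true profiles of the design's `known_indices`, as a
#'   reference panel (genes x K1 matrix).
#' @export
truth_reference <- function(truth) {
  stopifnot(inherits(truth, "prede_truth"))
  truth$W_true[, truth$design$known_indices, drop = FALSE]
}

#' @export
print.prede_truth <- function(x, ...) {
  d <- x$design
  cat("Simulated mixture:", d$n_genes, "genes x", d$n_samples, "samples,",
      d$K, "cell types (", length(d$known_indices), "known ), noise c =",
      d$noise_c, "\n")
  invisible(x)
}
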