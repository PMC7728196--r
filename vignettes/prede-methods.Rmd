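---
title: "Partial-reference deconvolution: model, algorithm and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-reference deconvolution: model, algorithm and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prede)
```

## The deconvolution model

A bulk expression profile is modeled as a linear mixture of cell-type
profiles: for `n` genes and `m` samples,

$$ Y = W H + \varepsilon, \qquad Y \in \mathbb{R}^{n \times m}_{\ge 0}, $$

where the basis matrix `W` (genes × `K` cell types) holds the pure
expression profiles and `H` (`K` × samples) the mixing proportions. The two
classical regimes are reference-based deconvolution (`W` known, solve `H`
per sample by constrained regression) and reference-free factorization
(`W` and `H` both unknown, a constrained NMF). This package addresses the
intermediate and practically common regime: profiles are available for only
`K1 < K` of the cell types. Writing `W = (W1, W2)` and
`H = (H1; H2)`, the estimator solves

$$ \min_{W_2, H}\ \lVert Y - W_1 H_1 - W_2 H_2 \rVert_F^2
\quad \text{s.t.}\quad W_2 \ge 0,\ H \ge 0,\ \textstyle\sum_k H_{kj} \le 1
\ \forall j. $$

The column-sum constraint is implemented as `<= 1` rather than the strict
inequality: a closed feasible set is required for the quadratic programs to
attain their minima, and the residual mass `1 - sum(h)` has a natural
reading as signal from unmodeled sources. Together with non-negativity it
confines every proportion to `[0, 1]`.

Linear-scale expression is assumed throughout, because mixing is linear in
linear units. Nothing is ever unlogged silently; `read_expression_matrix()`
exposes `delog2` for matrices stored as `log2(x + 1)`.

## The alternating algorithm

Both constraint sets are convex and the objective is biconvex, so the fit
alternates two exact convex solves:

1. **Proportion step.** With `W = (W1, W2)` fixed, the objective separates
   over samples into `m` independent `K`-variable quadratic programs
   (`solve_proportions_column()`). Each is solved exactly: the non-negative
   least-squares relaxation first (Lawson–Hanson active set), and, for the
   samples whose relaxed optimum violates the sum constraint, the full
   inequality-constrained problem via the classical reduction of
   least-squares-with-inequalities to least distance programming, which
   costs one additional small NNLS solve. Solutions satisfy the KKT
   conditions to machine precision.
2. **Basis step.** With `H` fixed, the objective separates over genes into
   `n` independent `K - K1`-variable NNLS problems on the residual
   `Y - W1 H1` (`solve_basis_row()`).

Because each step is an exact minimizer of the joint objective, the
objective trace is non-increasing by construction; the implementation
additionally restores the previous iterate and stops if floating-point
round-off ever produces a non-decrease. Components whose proportions vanish
in every sample are kept at zero weight rather than aborting the iteration.

Key solver parameters (`prede_control()`):

* `rel_tol` (default `1e-6`) — convergence is declared when the relative
  objective decrease `(prev - cur) / max(prev, eps)` falls below this.
  A relative criterion is scale-free, the standard choice for alternating
  minimization; an iteration cap (`max_iter`, default 1000) bounds runtime.
* `n_restarts` (default 5) — the problem is non-convex for `K1 < K`, so the
  fit is repeated from independent random initializations (seeds `seed`,
  `seed + 1`, …) and the lowest final objective is kept. With `K1 = K` the
  problem is convex and a single pass is used.
* `init_method` (default `sampled_columns`) — the unknown basis starts from
  `K - K1` distinct mixture columns jittered entrywise by Uniform(0.9, 1.1),
  which is on the scale of the data and converges fast; an iid
  Uniform(0, max(Y)) alternative is provided. Both are seeded, and a fit is
  bit-reproducible given its seed.

Degenerate inputs: an all-zero reference profile is a hard error (its
proportion is unidentifiable); an all-zero proportion row during the basis
step yields zero weights with a warning; negative numerical dust in `H`
(at the `-1e-12` scale left by the QP) is clipped to zero on output.

## Choosing the number of cell types

`K` is selected by scanning a candidate grid and minimizing the
small-sample-corrected Akaike criterion

$$ AICc = N \ln(SSR/N) + 2p + \frac{2p(p+1)}{N - p - 1}, $$

with observations counted at the level of matrix entries, `N = n m`, and
`p = K(n + m) - n K1` free parameters (the entries of `W2` and `H`). When
`N - p - 1 <= 0` the candidate is inadmissible and scores `+Inf`; ties are
broken toward the smallest `K` (parsimony). Candidates are fit
independently — no warm starts across `K` — so each point of the curve is an
unbiased, restartable fit; feature selection is performed once on the
mixture matrix before scanning, not per candidate.

## Feature selection and normalization

Deconvolution inputs are reduced to the top `k` (default 1000) genes by
coefficient of variation, computed on the bulk mixture only (the reference
panel is subset to the selected genes afterwards). The sample
(`n - 1`) denominator is used for the standard deviation; the ranking is
insensitive to this for realistic sample counts. Genes with mean below
`1e-8` are excluded first, since CV is undefined at zero mean.
`quantile_normalize()` (classic rank-wise means, ties averaged) is provided
to put basis profiles from heterogeneous sources on one distribution before
mixing, as is common when constructing benchmark mixtures.

## The simulation benchmark

`mixture_design()` + `generate_mixture()` reproduce the benchmark designs
used to validate the method, with everything seeded and recorded:

* **Basis profiles** — iid log-normal entries (log-mean 3, log-sd 1.2),
  mimicking the dispersion of linear-scale expression; independent columns
  are weakly correlated (typically pairwise PCC < 0.8 at 2000 genes).
  A similarity specification rebuilds chosen columns as convex blends of
  another column and a fresh profile, bisection-calibrated until the pair
  hits a target correlation (e.g. 0.95) within 0.01 — the "highly similar
  unknown cell type" scenario.
* **Proportions** — per-sample Dirichlet draws with concentration
  `alpha = 1` (uniform over the simplex; the benchmark literature states
  the distribution but not its parameters, and the uniform choice adds no
  structure). Columns sum to exactly 1, which the estimator's `<= 1`
  constraint contains. The rare-population mode pins one component at a
  fixed proportion `f` and scales a `K - 1` Dirichlet draw by `1 - f`; the
  grouped mode (e.g. cancer/immune/normal at 60/20/20) draws per-sample
  group totals from a Dirichlet with concentration 100 around the targets —
  so realized totals are "roughly" the targets, with a standard error of a
  few percent — and splits within groups by a nested Dirichlet.
* **Noise** — per gene, iid Gaussian noise with standard deviation
  `c × (mean clean expression of the gene)`, negatives truncated at zero
  (expression is non-negative, and the estimator assumes `Y >= 0`).

Problem sizes: the test suite exercises the estimator on instances from
25×6 up to 600×80 and the bundled benchmark script on 1000×100 mixtures
(five generation seeds per design, scans with a single restart at
`rel_tol = 1e-5`, `max_iter = 150`); the package defaults are heavier and
intended for real analyses.

### What the generator does and does not emulate

The generator reproduces the *structure* of the published benchmarks —
partial references, Dirichlet mixing, mean-proportional noise, rare and
grouped populations, similarity-controlled bases — but not the empirical
covariance of real cell-line profiles, nor count noise, batch effects or
dropout. One consequence is worth stating plainly, because it changes a
headline behavior. With heavy-tailed linear-scale basis entries, the
per-gene noise scale `c × mean_g` is itself heavy-tailed, and the noise
matrix has a few very large singular values: each additional free component
can absorb one leading noise direction. AICc adds `2(n + m)` per component,
which only rejects an added component once its SSR gain falls below
roughly `1 - e^{-2(n+m)/N}` (about 2% at 1000×100); the leading noise
directions of this generator yield more than that, so on these synthetic
mixtures the AICc curve keeps decreasing past the true `K` and model
selection overshoots. On light-tailed data (for example
array-scale values, whose per-gene noise scales vary far less), the top
noise singular values sit below the penalty and the criterion turns up at
the true `K`. Passing
tests on this generator therefore certify the estimator (recovery of
proportions and held-out profiles, constraint satisfaction, monotone
convergence) and the *mechanics* of selection (the criterion, its guards,
argmin extraction), not the end-to-end accuracy of AICc-based `K` recovery
under heavy-tailed mean-proportional noise; the benchmark script reports
the selected `K` values as computed.

The accuracy metrics are deliberately standard: proportion MAE and Pearson
correlations after pairing estimated unknown components with the truth by
maximum-weight bipartite assignment on profile correlations (pairing on
proportion rows is available for the reference-free mode, where profiles
are identified only up to scale); Shannon entropy (natural log — the base
only rescales) of a sample's composition as a heterogeneity score; and
Bray–Curtis dissimilarity between composition vectors.

## Known limitations

* Expression profiles are assumed stable across samples within a cell
  type; continuously varying (e.g. differentiating) populations violate
  the fixed-basis model.
* The iid Gaussian error assumption is inappropriate for raw counts;
  transform or use count-aware models upstream.
* AICc-based selection is reliable only when every population is
  moderately abundant (rare types below roughly 5–7% tend to be absorbed
  into other components) and, as discussed above, degrades when the noise
  scale is heavy-tailed across genes.
* `K1 = K` is exact and fast; `K1 = 0` inherits the usual NMF
  non-identifiability (components recovered up to permutation and, in
  proportion terms, attenuation), so restarts matter most there.
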