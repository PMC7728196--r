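# prede

Deconvolution of bulk gene expression mixtures with **partial references**:
the practically common setting where pure expression profiles are available
for only some of the cell types in a tissue (say, sorted immune cells), while
the rest (say, the tumor subclones) are unknown. `prede` estimates the
proportions of *all* cell types together with the expression profiles of the
unknown ones, and chooses how many cell types the mixture contains.

## The model

For `n` genes and `m` samples, bulk expression is a linear mixture

```
Y = W H + e,     W = (W1, W2),   H = (H1; H2)
```

with `W1` (genes × K1) the known profiles and `W2`, `H` estimated by

```
min ||Y − W1·H1 − W2·H2||²_F    s.t.  W2 ≥ 0,  H ≥ 0,  colSums(H) ≤ 1
```

solved by alternating two exact convex steps: one constrained quadratic
program per sample for proportions, one non-negative least-squares problem
per gene for the unknown basis (compiled Lawson–Hanson active-set solvers;
the sum-constrained QP is solved exactly via the least-distance-programming
reduction). `K1 = K` reduces to classical reference-based regression,
`K1 = 0` to reference-free NMF. The total number of cell types is selected
by minimizing the small-sample-corrected Akaike criterion

```
AICc = N·ln(SSR/N) + 2p + 2p(p+1)/(N−p−1),   N = n·m,  p = K(n+m) − n·K1
```

over a candidate grid. The package also ships the simulation benchmark the
method is validated with (Dirichlet proportions, mean-proportional Gaussian
noise, rare populations, similarity-controlled and grouped
cancer/immune/normal designs), accuracy metrics (component matching by
optimal assignment, MAE, Pearson correlation, Shannon heterogeneity,
Bray–Curtis dissimilarity), delimited-matrix IO and a command-line
interface. See `vignettes/prede-methods.Rmd` for the full methods account.

## Worked example

```r
library(prede)

# simulate a benchmark: 500 genes, 60 samples, 5 cell types, 4 known
design <- mixture_design(n_genes = 500, n_samples = 60, K = 5,
                         known_indices = 1:4, noise_c = 0.1, seed = 42)
truth <- generate_mixture(design)

Y  <- expression_matrix(truth$Y_noisy)
W1 <- reference_panel(truth_reference(truth))

# fit with the held-out fifth profile unknown
fit <- fit_prede(Y, W1, K = 5, prede_control(seed = 1))
fit
#> Partial-reference deconvolution fit
#>   cell types: K = 5 (known K1 = 4 , unknown K2 = 1 )
#>   samples: 60  genes: 500
#>   SSR: 789793.8  after 443 iterations ( converged )

# score against the ground truth
report <- evaluate_deconvolution(truth, fit)
report
#> Deconvolution accuracy report
#>   overall proportion MAE: 0.009490009
#>   unknown-profile PCC: 0.998
round(report$proportion_pcc, 3)
#> celltype_1 celltype_2 celltype_3 celltype_4 celltype_5
#>      0.999      0.998      0.999      0.997      0.999
```

The proportions of all five cell types are recovered to an MAE below 0.01,
and the profile of the withheld cell type is reconstructed with correlation
0.998 to the truth. `select_K(Y, W1, K_min, K_max)` scans candidate
component counts and reports the AICc curve and its argmin.

## Command line

```sh
prede simulate --design design.yaml --out sim/
prede select-k --expr sim/Y.tsv --ref sim/W1.tsv --kmin 2 --kmax 15 --seed 1 --out sel/
prede fit      --expr sim/Y.tsv --ref sim/W1.tsv --k 6 --seed 1 --out fit/
prede evaluate --truth sim/ --fit fit/ --out report/
```

(omit `--ref` for reference-free mode; `--features` controls top-CV gene
selection, default 1000; every run writes a JSON manifest with its seed and
options.)

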