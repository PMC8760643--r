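# dyndlt

Model-free pseudotime estimation and marker-gene detection for dynamic
transcriptomic count data, by thin positive dictionary learning (dynDLT).

## The problem

Cells sampled along a developmental or perturbation time course are
snapshots of a continuous process. *Pseudotime* estimation orders samples
by their progression through that process using expression similarity
alone. Most pseudotime pipelines start with a dimension-reduction step —
typically PCA, ICA, or t-SNE — whose structural assumptions (orthogonal or
statistically independent components, local-neighbourhood preservation)
can hide exactly the dynamics of interest.

dynDLT replaces that step with dictionary learning, which imposes no
dependence structure on the derived dimensions. Given a gene-by-sample
matrix `X` (p genes x n samples), it factorises

```
x_i = D r_i + e,    D ∈ R^{p×m},  r_i ∈ R^m,  i = 1..n
```

with unit-norm, entry-wise non-negative atoms (columns of `D`) and a
*thin* dictionary, `m < n << p`, learned under an l1 sparsity penalty.
The final coefficients are computed by orthogonal matching pursuit with
sparsity `s = m` — i.e. exact least-squares projection — so every sample
has a usable coefficient for every atom. Two readings follow:

* **Pseudotime**: the ranks of one coefficient row `R[j, ]` order the
  samples in time.
* **Gene modules / markers**: the largest entries of atom `d_j` are the
  marker genes of the process that atom encodes.

The package also ships the accompanying simulation benchmark (dynamic
patterns injected into negative-binomial count baselines, with graded
noise and zero-count perturbations), uniform adapters for ICA / NMF / PCA /
t-SNE / UMAP comparisons, a Spearman-correlation + marker-overlap
evaluation harness, and an MST "polygonal reconstruction" pseudotime mode
that uses the whole low-dimensional representation instead of a single
atom.

## Worked example

```r
library(dyndlt)

# Simulate one benchmark-style dataset (reduced size to keep it quick):
# 2000 x 200 NB baseline, 100 genes with an increasing pattern, noise.
cfg <- sim_config(g_sim_size = 100, pattern = "increasing", noise_scale = 1,
                  p_total = 2000, n = 200, seed = 0)
ds  <- simulate_dataset(cfg)

# Fit dynDLT with 3 atoms.
fit <- fit_dyndlt(ds, m = 3, seed = 0)
glance(fit)

# Score against the simulated ground truth.
rec <- score_dataset(fit, ds, dataset_id = "demo")
rec[, c("subpattern", "best_correlation", "best_component", "marker_overlap_pct")]

# Pseudotime from the best atom, and from the MST mode.
pt  <- pseudotime_from_atom(fit, rec$best_component)
mst <- trajectory_pseudotime(fit)
abs(spearman_cor(pt$pseudotime_rank, 1:200))    # atom-based
abs(spearman_cor(mst$pseudotime_rank, 1:200))   # whole-representation MST

# Marker genes of the dynamic atom.
head(marker_genes(fit, rec$best_component, k = 100), 3)
```

Output:

```
# glance(fit)
  m sparsity_s reconstruction_error relative_error iterations converged n_degenerate_atoms seed
1 3          3                  566          0.557         25      TRUE                  0    0

# rec
  subpattern best_correlation best_component marker_overlap_pct
1 increasing            0.958              2                 32

# pseudotime vs true simulated order
[1] 0.958   # atom-based
[1] 0.883   # MST polygonal reconstruction

# head(marker_genes(...), 3)
   rank gene_index gene_id  weight
1     1        924 gene_924 0.0580
2     2        760 gene_760 0.0570
3     3        531 gene_531 0.0552
```

`best_correlation` is the absolute Spearman correlation between the best
atom's coefficients and the true simulated ordering — 0.95 means the
pseudotime recovers the time course almost perfectly. `marker_overlap_pct`
is the share of the truly dynamic genes among the top-`|g_sim|` entries of
the best atom; on the uncorrelated synthetic baseline this metric has an
information ceiling well below 100% (see the methods vignette), and it
rises both with `|g_sim|` and with `m`.

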