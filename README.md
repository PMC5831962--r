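# sllesc2

Feature-gene selection for two-class gene-expression studies (bulk
microarray or pseudobulked single-cell) where thousands of genes are
measured on a few dozen samples. In that regime classifiers overfit
("curse of dimensionality") and strongly coexpressed genes carry the same
information many times over. `sllesc2` selects a small panel of
discriminative, mutually non-redundant genes by combining a supervised
manifold embedding with a rank-correlation redundancy filter, and ships
the evaluation harness (imbalanced-classification metrics, nested
cross-validation, threshold sweep) and a synthetic-data generator used to
validate it.

## Method

Given an expression matrix `X` (N samples x D genes) with binary labels:

1. **Supervised locally linear embedding (SLLE).** Pairwise Euclidean
   distances are inflated between classes,
   `Δ'(i,j) = Δ(i,j) + λ·max(Δ)·1[label_i ≠ label_j]`, `λ ∈ [0,1]`
   (λ = 0 is plain unsupervised LLE, λ = 1 fully supervised). Each sample
   is reconstructed from its k nearest neighbors under `Δ'` by weights `W`
   minimizing `ε_i = ||x_i − Σ_j W_ij x_j||²` with `Σ_j W_ij = 1` (solved
   from the regularized local Gram matrix
   `G_jl = (x_i − x_j)·(x_i − x_l)`). The embedding `Y` (N x d) consists of
   the bottom non-constant eigenvectors of `M = (I−W)ᵀ(I−W)`, centered and
   scaled so `(1/N)YᵀY = I`.
2. **Gene relevance.** PCA explained-variance fractions `c_1..c_d` of the
   embedding weight each component; a gene's relevance is
   `rel(g) = Σ_c c_c · |ρ_s(x_g, Y_c)|`, where `ρ_s` is Spearman's rank
   correlation with tie-averaged ranks (Pearson correlation of the rank
   vectors).
3. **Redundancy filter (SC²).** Genes are walked in decreasing relevance;
   the current best survivor is kept and every lower-ranked gene with
   `|ρ_s| ≥ threshold` against it is removed as coexpressed. The top
   `n_select` survivors form the panel.

Defaults follow the method's published configuration: `k = 5`, `λ = 1`,
`threshold = 0.3`, `n_select = 5`. Evaluation reports Acc, TPR, TNR,
precision, F-measure, `G-mean = √(TPR·TNR)` and AUC (Mann–Whitney rank
statistic), from stratified k-fold cross-validation with selection re-fit
inside every training fold.

## Worked example

```r
library(sllesc2)

# 40 samples, 3 informative coexpression blocks of 4 genes, 100 noise genes
sim <- generate_expression(
  synthetic_spec(n_samples_per_class = 20, n_informative = 3,
                 copies_per_block = 3, n_noise = 100), seed = 7)

res <- slle_sc2_select(sim$data, k = 5, lambda_s = 1, d = 2,
                       threshold = 0.3, n_select = 3)
print(res)
#> selection_result (mode=full): 3 gene(s)
#>         gene relevance
#> 1 inf1_copy3 0.4975077
#> 2    noise57 0.3866267
#> 3    noise88 0.3521329
#> 81 gene(s) removed as redundant at threshold 0.3

cv <- cross_validate(sim$data, selector = list(n_select = 3),
                     classifier = "lda", folds = 5, repeats = 2,
                     seed = 7, positive = "pos")
print(cv)
#> cv_report: 5-fold x 2 repeat(s), classifier=lda
#>         acc    tpr    tnr precision f_measure g_mean    auc
#> mean 0.8125 0.7250 0.9000     0.820    0.7540 0.7516 0.9438
#> sd   0.1473 0.2993 0.1748     0.319    0.2835 0.2841 0.0748
```

The top gene is a member of an informative block (relevance = mean
|Spearman| association with the two embedding coordinates, which separate
the classes); its coexpressed block mates — and every other gene carrying
the same class signal — were removed by the 0.3 filter, which is why the
rest of the panel comes from weakly correlated genes. The CV table shows
held-out metrics with selection re-fit per fold; `auc` is the
rank-statistic area under the ROC curve.

The five-sample rank-correlation example used throughout the tests:

```r
x <- worked_example()
rank_with_ties(x$values[, "a1"])   # 4 2 3 1 5
rank_with_ties(x$values[, "a2"])   # 5 2 3 1 4
spearman_rho(x$values[, "a1"], x$values[, "a2"])   # 0.9
```

## Command line

```sh
exec/slle-sc2 simulate --preset small --seed 1 --out data/
exec/slle-sc2 select --expr data/expr.tsv --labels data/labels.tsv \
    --k 5 --lambda 1.0 --threshold 0.3 --n-select 5 --out run/
exec/slle-sc2 evaluate --expr data/expr.tsv --labels data/labels.tsv --classifier lda --out run/
exec/slle-sc2 sweep --expr data/expr.tsv --labels data/labels.tsv --out run/
```

Outputs are delimited text plus a `manifest.json` recording parameters,
seed and input digests; identical runs produce byte-identical files.

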