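---
title: "Supervised embedding and correlation filtering for feature-gene selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised embedding and correlation filtering for feature-gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sllesc2)
```

## The problem and the model

Two-class expression studies typically measure thousands of genes on tens
of samples. Two pathologies follow: classifiers overfit, and coexpressed
genes (members of the same regulatory program, or probe-level duplicates)
enter any relevance ranking as a block, so a "top 50 genes" list can carry
far fewer than 50 independent signals. `sllesc2` addresses both with a
three-stage pipeline.

**Stage 1 — supervised locally linear embedding.** LLE assumes the
samples lie near a low-dimensional manifold in gene space: each sample
$x_i$ is reconstructed from its $k$ nearest neighbors with weights $W$
minimizing $\varepsilon_i = \lVert x_i - \sum_j W_{ij} x_j \rVert^2$
subject to $\sum_j W_{ij} = 1$, and the embedding $Y$ minimizes the same
reconstruction cost in $d$ dimensions, i.e. the bottom non-constant
eigenvectors of $M = (I - W)^\top (I - W)$ under the constraints
$\sum_i Y_i = 0$ and $\frac1N Y^\top Y = I$. The supervised variant
inflates between-class distances before the neighbor search,
$$\Delta'(i,j) = \Delta(i,j) + \lambda \cdot \max(\Delta) \cdot
\mathbf{1}[\ell_i \neq \ell_j], \qquad \lambda \in [0,1],$$
so neighborhoods become class-pure as $\lambda \to 1$ and the leading
embedding coordinate aligns with the class structure. $\lambda = 0$
recovers plain LLE exactly (the package tests assert bit-for-bit
equality).

**Stage 2 — gene relevance.** The embedding lives in sample space, but
selections must be reported as original genes. Each embedding component
$Y_c$ is weighted by its PCA explained-variance fraction $c_c$, and a
gene's relevance is
$$\mathrm{rel}(g) = \sum_{c=1}^{d} c_c \,\bigl|\rho_s(x_g, Y_c)\bigr|,$$
with $\rho_s$ the Spearman rank correlation (Pearson correlation of
tie-averaged ranks; the smallest value gets rank 1 and ties share the
average of the ranks they span). Spearman is used, rather than Pearson on
raw values, because expression scales are arbitrary and monotone: the
coefficient is invariant under any strictly increasing transform of
either argument.

**Stage 3 — redundancy filter.** Genes are walked in decreasing
relevance. The best survivor is kept; every lower-ranked survivor with
$|\rho_s| \geq$ `threshold` against it is removed as coexpressed; the walk
continues with the next survivor. The top `n_select` survivors form the
panel. By construction no kept pair reaches the threshold (re-verified
exhaustively in the tests).

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 5 | samples | neighborhood size of the embedding; the method's published configuration, adequate for 30–100-sample studies |
| `lambda_s` | 1 | – | full supervision; 0 = unsupervised LLE, intermediate = semi-supervised |
| `d` | 2 | dimensions | the embedding dimension is not pinned by the method's description; twice the number of classes is the package default, exposed and worth sweeping in applications |
| `threshold` | 0.3 | |rho| | redundancy cut; chosen in the original development by a 0–1 sweep of cross-validated accuracy |
| `n_select` | 5 | genes | matches the scale of published selected panels (3–5 genes) |
| `reg_tol` | 1e-3 | – | Gram regularization (below) |

## Numerical choices

- **Gram regularization.** The local Gram matrix
  $G_{jl} = (x_i - x_j)\cdot(x_i - x_l)$ is singular whenever $k$ exceeds
  the local intrinsic rank, which is the norm in expression data.
  `reg_tol * trace(G)` is added to the diagonal before solving (the
  standard LLE conditioning fix); `reg_tol = 0` is allowed and raises a
  named error on a singular sample, so exact small cases remain exact.
- **Which distances define what.** Supervised distances are used *only*
  to pick neighbors; reconstruction weights and the cost matrix are
  computed from the original coordinates, because the reconstruction
  objective is defined on the points themselves. An option
  (`supervised_weights = TRUE`) appends a class-indicator coordinate for
  users who want supervision inside the weight solve too.
- **Null space of the cost matrix.** $M$ always annihilates the constant
  vector. With $\lambda = 1$ the supervised kNN graph usually splits into
  one connected component per class, so the near-null space of $M$ has
  dimension $>1$ and an eigen-solver returns an *arbitrary* orthonormal
  basis of it — "drop the first eigenvector" is then ill-defined and can
  leave un-centered coordinates. The package instead projects the constant
  direction out of the whole near-null block (eigenvalues $< 10^{-8}$) and
  re-orthonormalizes the remainder by SVD. Retained coordinates are
  exactly centered; with class-pure neighborhoods the first retained
  coordinate is the between-class contrast, which is precisely the signal
  the relevance stage should see.
- **Determinism.** Neighbor ties break by ascending sample index;
  ranking ties by ascending gene index; each eigenvector's sign is fixed
  by making its largest-magnitude entry positive. Same input and seed give
  byte-identical outputs (manifest timestamps are opt-in for this reason).
- **Degenerate inputs.** Constant genes have undefined rank correlation:
  they get relevance 0 and are dropped before filtering, with warnings.
  Metrics: precision is defined as 0 when there are no positive
  predictions (and F-measure is then 0); AUC uses the tie-corrected
  rank-statistic form, so all-equal scores give 0.5.
- **PCA on a sphered embedding.** Because $\frac1N Y^\top Y = I$, the PCA
  of an LLE embedding has (near-)equal eigenvalues and a degenerate
  rotation. Relevance therefore correlates genes against the embedding
  columns *as given* (ordered by cost eigenvalue) and uses the PCA
  fractions only as weights — for an LLE embedding they are near-uniform,
  and in the `"sc2"` ablation mode (PCA on raw data, no embedding) they
  are the genuine explained-variance shares.
- **Signed vs absolute correlation.** Negatively coexpressed genes are as
  redundant as positively coexpressed ones, so the filter compares
  $|\rho_s|$ by default; `absolute = FALSE` restores the signed
  comparison.

## The synthetic generator

`generate_expression()` emulates the structure the method assumes: for
each of `n_informative` blocks a seed gene
$g_b \sim \mathcal N(\pm\,\mathrm{effect}/2,\ \sigma)$ by class, each of
`copies_per_block` coexpressed copies
$\rho\, g_b + \sqrt{1-\rho^2}\,\epsilon$, plus `n_noise` pure-noise genes
$\mathcal N(0, \sigma)$. Defaults (30 samples per class, 5 blocks of 4,
200 noise genes, effect 2, $\rho = 0.9$, $\sigma = 1$) mirror a small
microarray study. It does **not** emulate platform artifacts, probe
effects, heavy tails, or normalization pipelines — a green test on this
generator establishes correctness of the algorithmic pipeline, not
biological recall on real arrays.

One property of this stated world deserves emphasis because it is a
property of the *method*, visible on real data too: every informative
gene carries the class-mean shift, so two informative genes from
*different* blocks have population correlation
$\frac{\mathrm{effect}^2/4}{\mathrm{effect}^2/4 + \sigma^2}$ — $0.5$ at
the default effect 2 — which exceeds the default 0.3 threshold. The
greedy filter therefore keeps a single strongly class-associated gene and
removes the rest of the class signal as "redundant", filling the panel
from weakly correlated genes. Consequently block *purity* of a selection
is 1.0 (never two genes of one block), while block *coverage* in the top
5 is low (~0.2 over 20 seeds) unless the effect is small
($\lesssim 1.3\sigma$) or the threshold is raised above the class-driven
correlation. This is the documented behavior of correlation-threshold
filters on class-correlated features, not an implementation defect; the
corresponding recovery test is left asserting the optimistic coverage and
fails honestly.

## Evaluation harness

`cross_validate()` stratifies folds by class (fold sizes and per-fold
class counts within $\pm1$), re-fits the gene selection inside each
training fold (no selection leakage — a test recomputes a fold's panel
from its training samples alone and asserts identity), and reports Acc,
TPR, TNR, precision, F-measure, G-mean $=\sqrt{\mathrm{TPR}\cdot
\mathrm{TNR}}$ and AUC per fold with means and standard deviations over
`repeats` $\times$ `folds` outcomes (default $2 \times 10 = 20$).
Classifiers are pluggable; this build provides `"lda"` (MASS),
`"logistic"` (stats::glm) and a minimal internal `"knn"` — margin-based
and tree backends are not available in the supported dependency set.
`threshold_sweep()` evaluates the 0–1 threshold grid (step 0.1),
computing the embedding and ranking once per fold and redoing only the
filter and classifier per threshold; `n_selected` (survivor count on the
full data) is non-decreasing in the threshold by construction.

## Known limitations

- No out-of-sample extension of the embedding: a new sample cannot be
  projected without recomputing the eigenproblem.
- Dense eigendecomposition of the $N \times N$ cost matrix: fine for
  microarray-scale $N$ (tens to hundreds), not for $N \gg 10^4$.
- The aggressive-filter behavior above: with strongly class-correlated
  features and a low threshold, the selected panel deliberately carries
  few strongly discriminative genes. Sweep the threshold on your own data
  (`threshold_sweep()`) rather than trusting the 0.3 default.
- Binary classes only, by design of the supervised distance.
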