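---
title: "Deep regularized NMF for drug-disease association prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep regularized NMF for drug-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmfdr)
```

## The problem and the model

Known drug-disease associations form a sparse binary matrix
$A \in \{0,1\}^{m \times n}$ in which a zero means *unknown*, not
*negative* — the matrix-completion convention used throughout this
package. Side information arrives as drug-drug and disease-disease
similarity matrices in $[0,1]$ with unit diagonal. The model assumes that
(i) the association structure is approximately low-rank, (ii) similar
drugs treat similar diseases (manifold assumption), and (iii) the
similarity matrices are informative about the same latent factors that
generate associations. When these assumptions fail — e.g. similarities
derived from a property unrelated to indications — the Laplacian term
actively hurts, which is why its weight $\alpha$ is small by default.

Each entity view concatenates its fused similarity with the association
block: $X_R = [R, A_1]$ ($m \times (m+n)$) and $X_D = [D, A_2^\top]$
($n \times (m+n)$). Fusion is the element-wise mean of the available
similarity matrices, symmetrized as $(M + M^\top)/2$ to absorb
floating-point asymmetry. Each view is factorized $\ell$ layers deep,
$X \approx W_\ell H_\ell \cdots H_1$ with all factors nonnegative, by
minimizing

$$
\|X - W_\ell H_\ell \cdots H_1\|_F^2
+ \alpha \sum_i \operatorname{Tr}(W_i^\top L W_i)
+ \beta \sum_{i<\ell} \|W_i - W_{i+1} H_{i+1}\|_F^2
+ \lambda \sum_i \|W_i\|_F^2
+ \mu \sum_i \|H_i\|_F^2 ,
$$

where $L = U - S$ is the graph Laplacian of the view's fused similarity
and $U$ is diagonal with $U_{jj} = \sum_i S_{ji}$. The degree sums
deliberately include the diagonal self-similarity; a drug similar only to
itself then contributes an all-zero Laplacian row and is simply
unregularized, rather than pushed toward zero. The $\beta$ terms relax
the deep factorization: instead of demanding $W_i = W_{i+1} H_{i+1}$
exactly, adjacent layers are tied quadratically, which stabilizes the
multiplicative updates.

Optimization is multiplicative: each factor is updated as
$W_i \leftarrow W_i \odot \sqrt{\text{num}/\text{den}}$ where numerator
and denominator collect the positive and negative parts
($[M]^\pm = (|M| \pm M)/2$) of the gradient terms, so nonnegativity is
preserved by construction. The ridge coefficient on $W_i$ is
$\beta + \lambda$ for layers with a deeper neighbour and $\lambda$ for
the deepest layer; in a single-layer model every $\beta$ neighbour term
is absent. Factors are initialized by layer-wise NMF pretraining
($X \approx W_1 H_1$, then $W_1 \approx W_2 H_2$, ...) with classical
Frobenius multiplicative updates.

The final score matrix averages the two views' reconstructed association
blocks, $A^* = (A^*_1 + A^*_2)/2$ — the arithmetic mean, the only
combiner we considered, keeping each view an equal, independently fitted
witness. Scores are left unclamped and training positives are not
overwritten; ranking consumers exclude known pairs themselves.

## Tunable parameters

All parameters are dimensionless. Defaults follow the values found
optimal on the published benchmark datasets:

| parameter | default | role |
|---|---|---|
| `alpha` | 0.01 | Laplacian (manifold) weight; small because the raw data term dominates on informative similarities |
| `beta` | 1 | relaxation weight tying adjacent layers |
| `lam`, `mu` | 1 | ridge on bases / coefficients; kept equal by default to shrink the tuning space, independently settable |
| `taus` | (0.8, 0.6) | layer dimensions $l_i = \mathrm{round}(\tau_i \min(m,n))$, clamped to $\ge 1$; both views share the dimensions |
| `k` | 10 | KNN neighbours for cold-start filling |
| `decay` | 0.9 | rank decay of KNN weights; 1 recovers plain similarity weighting |
| `xi1`, `xi2` | 5e-4, 5e-7 | stopping tolerances (see below) |
| `max_iter` | 500 | sweep cap after pretraining |
| `pretrain_iters` | 200 | multiplicative iterations per pretraining layer |

## The KNN fill

An all-zero association row is invisible to the data term, so cold-start
entities would be reconstructed from regularization alone. For every such
row $p$, the $k$ most similar *other* rows $j_1, \dots, j_k$ (descending
similarity, ties broken by identifier order, self excluded) are combined
as

$$
\tilde A(p, \cdot) = \frac{\sum_i \eta^{\,i-1} S(p, j_i) A(j_i, \cdot)}
                          {\sum_i \eta^{\,i-1} S(p, j_i)},
$$

a rank-decayed, similarity-weighted, normalized average in $[0,1]$. The
descending arrangement of neighbours matters precisely because the decay
$\eta$ is applied by rank. When all neighbour similarities are zero the
row stays zero rather than dividing by zero. Rows that already contain a
positive are never touched, so the fill is idempotent. The drug-side and
disease-side fills are computed independently from the same raw $A$,
producing the two blocks $A_1$ and $A_2$. The exact weighting scheme is a
design choice of this package (decay default 0.9, both the decayed and
plain variants exposed) rather than a canonical formula.

## Numerical choices

* **Denominator guard.** Update denominators are floored at
  $\varepsilon = 10^{-10}$ (`pmax(den, eps)`), not incremented by it. The
  floor guards division by zero identically but leaves exact fixed points
  exact: at a strictly positive exact factorization with all
  regularizers off, `num == den` and the update is the identity to
  machine precision, a property the test suite asserts at $10^{-12}$. An
  additive guard would perturb every update by $O(\varepsilon/\text{den})$.
* **Stopping rule.** After each full sweep (layers $1..\ell$, $W_i$ then
  $H_i$) we compute $h$, the relative Frobenius change of the
  reconstructed *association block* — not the whole $X$, since the
  similarity block is not what the model is asked to predict. Iteration
  stops when $h \le \xi_1$ and the trend
  $|h_k - h_{k-1}| / \max(1, |h_{k-1}|) \le \xi_2$, or at `max_iter`.
  A zero-norm previous block defines $h = 0$ (degenerate, converged).
  With fewer than two recorded values the rule never fires.
* **Sweep order.** Within a sweep we update layer by layer, $W_i$ then
  $H_i$, for $i = 1..\ell$, the order in which the per-layer rules
  interleave most naturally. The update rules themselves do not
  prescribe an order, so the alternative all-$W$-then-all-$H$ schedule
  is exposed as `dnmf_params(sweep = "w_first")`.
* **Determinism.** Every stochastic step (synthetic data, factor
  initialization, fold assignment) flows from explicit integer seeds;
  per-layer and per-view seeds are derived deterministically from the
  master seed, and the library restores the caller's RNG state. All
  pipeline entry points are bit-reproducible, which the tests assert with
  `identical()`.
* **Ordering canonicalization.** `predict_ddas()` internally sorts
  entities by identifier before fitting and restores the input order on
  return, so predictions are bit-invariant under consistent permutations
  of the input files — otherwise the positional random initialization
  would break this.
* **Degenerate inputs.** Matrices with zero rows round-trip through the
  TSV dialect; duplicate identifiers are rejected rather than merged
  (silent merging would corrupt similarity alignment); `k` is clamped to
  $m - 1$ with a warning; a fold or mask that empties a row is handled by
  the same cold-start path as a novel drug.

## Evaluation protocols

**10-fold CV.** The *positive cells* are partitioned into ten random
folds (sizes differing by at most one). Each fold is zeroed in the
training matrix, the full pipeline (including preprocessing) is re-run,
and the fold is scored with label 1 on its cells and 0 on every cell
that is zero in the original matrix; training positives of other folds
are never scored. We read the protocol as the universal 9-train/1-test
convention. Negatives are never masked: a zero is "unknown", not a
held-out negative. Aggregate metrics are the plain mean over folds.

**Cold start.** Every drug with exactly one known association is in turn
treated as novel: its positive is removed, leaving an all-zero row that
exercises the KNN fill, the pipeline is re-run, and the drug's score row
is recorded (label 1 on the held-out disease, 0 on its original-zero
cells). Rows are pooled before computing metrics, because a per-drug AUC
is undefined with a single positive. Drug similarities whose names
indicate interaction- or side-effect-derived sources (`ddi`, `se`) are
excluded by default in this mode — such data cannot exist for a truly
novel drug.

**Metrics.** AUC in its Mann-Whitney form (ties count half); AUPR as the
area under the precision-recall step curve with tied scores processed as
a block; and R-precision — precision among the top-$P$ items, $P$ the
number of positives — chosen as the least arbitrary threshold-free
operating point since no single threshold is canonical for this task.
All three are verified against brute-force enumeration oracles at
$10^{-12}$.

## The synthetic generator

`generate_dataset()` plants nonnegative factors $U$ ($m \times r$), $V$
($n \times r$) drawn as $|N(0,1)|$, takes $UV^\top$ as ground truth, and
sets $A = 1$ at the $\lceil \text{density} \cdot mn \rceil$ largest
ground-truth entries. Thresholding (rather than Bernoulli sampling) makes
the true ranking of unknown pairs unambiguous, giving recovery tests a
clean oracle. Similarities are min-max-rescaled Gram matrices $UU^\top$,
$VV^\top$ with symmetric Gaussian noise added, then re-symmetrized,
clipped to $[0,1]$ and unit-diagonal-forced — mirroring the structural
properties (symmetry, range, diagonal) of real similarity matrices.
Cold-start targets are created by thinning the densest rows to their
single highest-scoring positive, so the target actually loses
information.

The generator's default density is 0.01, matching the ~1% sparsity of
the published association datasets; default noise scale 0.1 keeps the
similarities informative but not clean. What the generator does *not*
emulate: the heavy-tailed, multi-modal marginals of chemical-fingerprint
similarities, block structure from drug classes, and correlated noise
across similarity sources. Passing recovery tests therefore demonstrates
that the implementation optimizes its objective and exploits planted
structure — not that the model will reach any particular performance on
real pharmacological data.

## Study problem sizes

The recovery studies run on a 60-drug x 40-disease, rank-5 dataset: CV
at density 0.03 and similarity noise 0.1 (72 positives, ~7 per fold),
the cold-start study at the generator defaults with 5 forced singleton
rows. These sizes give stable metrics from a desk-scale run while
exercising every code path (two layers, both views, fills, both
protocols); unit tests use smaller instances still.

## Known limitations

* Monotone descent of the *full* regularized objective is not guaranteed
  by theory and not asserted; monotonicity tests cover the unregularized
  single-layer case, where the classical result applies, plus a
  regularized-sweep spot check.
* On small, clean synthetic data the KNN fill's cold-start benefit is
  real but thin: the factorization already interpolates empty rows
  through the similarity block and the Laplacian, so the fill's
  advantage over the no-fill ablation is fragile at desk scale and
  should be judged on realistic data.
* AUPR under heavy imbalance is sensitive to the very top of the
  ranking; per-fold AUPR on ~7 positives is noisy by nature, which is
  why the CV aggregate averages folds rather than pooling.
* Dense algebra throughout: fine for the intended scales (hundreds to
  ~1500 entities), wasteful far beyond that.
* Only the labeled-TSV dialect is supported for I/O; container formats
  from other ecosystems must be converted first.
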