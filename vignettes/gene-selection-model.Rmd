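---
title: "Correlation-guided unsupervised gene selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-guided unsupervised gene selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g3cs)
```

## The selection problem

Microarray and other bulk expression studies routinely measure thousands of
genes on a few dozen samples. Most genes are irrelevant to the biological
contrast of interest, and many of the relevant ones are mutually redundant —
co-expressed probes, members of one regulon, or technical near-duplicates.
Selecting a small, non-redundant, informative gene subset improves downstream
classification and interpretation. This package implements an *unsupervised*
selector: it never sees sample labels; labels enter only the optional
evaluation harness.

## Model

Let $X \in \mathbb{R}^{m \times n}$ hold $m$ genes on $n$ samples. The model
couples four ingredients through the objective

$$
\min_{P, F, Z}\;
\|P^\top X - F Z^\top\|_F^2
+ \alpha \|P\|_{2,1}
+ \beta\, \mathrm{Tr}(P^\top \bar{M} P)
+ \gamma\, \mathrm{Tr}(Z^\top L Z)
\quad \text{s.t. } F^\top F = I,\; Z^\top Z = I,\; Z \ge 0 .
$$

* **Regression onto pseudo-labels.** $P \in \mathbb{R}^{m \times c}$ projects
  genes onto a $c$-dimensional pseudo-label space; $Z \in \mathbb{R}^{n
  \times c}$ is a relaxed nonnegative cluster-indicator matrix and $F \in
  \mathbb{R}^{c \times c}$ an orthogonal factor, so $F Z^\top$ plays the role
  of an (unknown) label matrix discovered by orthogonal clustering.
* **Row sparsity.** $\|P\|_{2,1} = \sum_i \|P^i\|_2$ sums row norms; genes
  whose rows survive the penalty carry the projection and are the selected
  genes. Gene importance is scored as $\|P^i\|_2$ (`gene_scores()`).
* **Redundancy penalty.** $\bar M$ is an adjusted gene-pair covariance
  matrix. `covariance_matrix()` computes the across-sample covariance
  $M_{ij} = \sum_s (X_{is}-\mu_i)(X_{js}-\mu_j)/(n-1)$;
  `adjust_correlation()` aggregates each gene's covariance with all other
  genes so that $\mathrm{Tr}(P^\top \bar M P)$ discourages spending
  projection weight on mutually correlated genes.
* **Sample manifold.** $L = D - S$ is the unnormalized Laplacian of a
  $k$-nearest-neighbour graph over samples with heat-kernel weights
  $S_{ij} = \exp(-\|x_i - x_j\|^2 / 2t^2)$ (OR-symmetrized, zero diagonal);
  $\mathrm{Tr}(Z^\top L Z)$ keeps cluster assignments smooth across
  neighbouring samples.

### The adjusted covariance and its two readings

Two natural adjustments of $M$ are implemented behind
`adjust_correlation(mode = )`:

* `"printed"` (default): keep the diagonal $M_{ii}$ and replace every
  off-diagonal entry of row $i$ with $\sum_{k \ne i} M_{ik}$;
* `"diag-rowsum"`: keep the off-diagonal covariances and put the aggregate
  $\sum_{k \ne i} M_{ik}$ on the diagonal, replacing the self-covariance
  (which carries no redundancy information).

Both readings are exact in `adjust_correlation()` and both are asymmetric in
general, so the result is symmetrized by default — the quadratic form only
senses the symmetric part, and symmetrizing makes its gradient $2\bar M P$
exact.

### Keeping the penalty convex

Either adjusted matrix is indefinite in general. In the printed form the
off-diagonal structure is a rank-two outer-product pattern whose negative
eigenvalue grows with $m$, so the raw penalty would make the objective
unbounded below and the $P$ subproblem a saddle rather than a minimum; we
observed exactly this as diverging, sign-flipping objective traces. The
solver therefore applies the penalty through the positive-semidefinite part
of the symmetrized $\bar M$ (eigenvalues clipped at zero), in both the $P$
update and the objective it monitors. This keeps every objective term
nonnegative and the $P$ step the exact minimizer of a strictly convex
quadratic, while still charging projection weight placed on directions of
large aggregate covariance. The clipping is a solver-level choice exposed as
`g3cs_config(psd_penalty = )`; setting it to `FALSE` reproduces the raw
indefinite penalty for study.

## Optimization

`g3cs_fit()` alternates three block updates until the relative objective
change falls below `tol` (default `1e-5`, `max_iter = 200`):

1. **P — closed form with iterative reweighting.** For fixed $(F, Z)$ the
   row-sparse subproblem is majorized by a weighted ridge problem with
   diagonal weights $G_{ii} = 1/(2 \max(\|P^i\|_2, \varepsilon))$
   (`compute_G()`, floor $\varepsilon = 10^{-8}$), giving the normal
   equations $(XX^\top + \alpha G + \beta \bar M)P = XZF^\top$. A few inner
   $P/G$ refreshes per sweep (default 3) bring the block close to its
   subproblem minimum; this reweighting scheme is monotone for the block.
2. **F — orthogonal Procrustes.** With $Z$ near column-orthonormal the
   subproblem reduces to $\min_{F^\top F = I}\|W - F\|_F$ with
   $W = P^\top X Z$, solved exactly by the polar factor of $W$ (SVD). A
   penalized elementwise alternative (`f_method = "multiplicative"`, penalty
   constant `rho`) is retained for comparison; its fixed points coincide
   with the penalized stationarity condition, but it is approximate and
   zero-locked entries cannot move, so Procrustes is the default.
3. **Z — damped multiplicative KKT step.** The nonnegative indicator is
   updated elementwise as
   $Z \leftarrow Z \odot \big(\text{num}/\text{den}\big)^{1/2}$ with
   numerator $2(X^\top P F)^+ + 2\gamma S Z + \kappa Z$ and denominator
   $2(X^\top P F)^- + 2 Z F^\top F + 2\gamma D Z + \kappa Z Z^\top Z$,
   where $A^\pm$ are the elementwise positive/negative parts and the
   Laplacian gradient is split as $L = D - S$ so every factor stays
   nonnegative. The $\kappa$ term enforces $Z^\top Z \approx I$ softly.
   The elementwise square root is essential: the undamped ratio is
   scale-unstable around the orthogonality constraint (the quartic
   $ZZ^\top Z$ term doubles the log-scale error each step, producing a
   persistent period-2 oscillation of the objective), while the damped rule
   has the same fixed points and contracts toward them. Within a sweep the
   step is iterated (up to `z_inner`, default 150, with early exit once $Z$
   is stationary) so each sweep approximates an exact block minimization.

**Initialization.** $Z$ starts from $k$-means on the spectral embedding of
the sample graph ($c$ eigenvectors of $L$ with smallest eigenvalues),
converted to a column-normalized indicator and lifted by $+0.01$ so no entry
is zero-locked; when the graph has no edges — a kernel width far below the
data's distance scale underflows every similarity — $k$-means runs on the
top-$c$ principal components of the samples instead. $F$ starts at the
identity and $P$ at its first closed-form update with unit-row-norm weights.
All randomness (the $k$-means restarts) is governed by `seed`; two runs with
the same configuration are bitwise identical.

**Degenerate inputs.** Non-finite expression values, duplicate identifiers
and sub-2×2 matrices are rejected at construction. A singular $P$ system
(possible at $\alpha = \beta = 0$ since $XX^\top$ has rank at most $n < m$)
is ridge-stabilized with a warning. A non-finite objective aborts with the
offending term named.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 | weight of the row-sparsity term (objective units) |
| `beta` | 1 | weight of the covariance penalty; scale-dependent, since covariance is in squared expression units |
| `gamma` | 1 | weight of the manifold term |
| `n_clusters` | — | pseudo-label dimension $c$; set to the expected number of sample groups (the number of distinct labels when labels exist) |
| `k_neighbors` | 5 | sample-graph neighbour count |
| `t_width` | 0.5 | heat-kernel width, in the units of sample Euclidean distance |
| `rho`, `kappa` | $10^3$ | orthogonality penalty constants for the multiplicative F rule and the Z step |
| `tol`, `max_iter` | $10^{-5}$, 200 | relative objective-change stop rule |
| `epsilon` | $10^{-8}$ | row-norm floor in the reweighting matrix |

For hyperparameter search the package ships `default_grid()`, all
combinations of $\alpha, \beta, \gamma \in \{10^{-3}, \dots, 10^{3}\}$, and
`selection_curve()` reports the best cross-validated accuracy over a grid at
each candidate subset size (default $\{10, 20, 30, 40, 50\}$ genes) — a
best-over-grid protocol, deliberately optimistic.

Note that `t_width = 0.5` is small relative to Euclidean distances between
raw high-dimensional expression profiles; on data whose pairwise squared
distances are in the hundreds the kernel underflows and the graph is empty,
which silently disables the manifold term (and triggers the PCA
initialization fallback). Set `t_width` near the median pairwise distance
when the manifold term is wanted.

## The synthetic generator

`generate_dataset(synthetic_spec())` emulates the structure the model
assumes: `n_samples = 60` samples in `n_clusters = 3` near-equal blocks;
`n_informative = 10` genes whose per-cluster means are `effect_size = 2`
noise standard deviations times a random ±1 sign pattern over clusters
(patterns are never constant, so every informative gene separates at least
one cluster pair); `n_redundant = 20` genes that are round-robin noisy
copies of informative parents (perturbation sd `redundancy_sd = 0.1`); and
`n_noise = 170` pure $N(0, 1)$ genes. Everything is Gaussian — a reasonable
model for log-scale microarray intensities — and fully determined by `seed`.

What the generator does **not** emulate: heavy-tailed or count noise, batch
effects, missing values, probe-level artifacts, and correlation *between*
families other than what the shared cluster structure induces. Passing tests
on this generator therefore demonstrates the solver's mechanics — descent,
constraint handling, redundancy demotion — not performance on real
microarray data.

A structural property of the generator worth stating explicitly: with
`redundancy_sd = 0.1` on top of unit-sd profiles, a redundant copy is
statistically almost interchangeable with its parent — the copy carries the
parent's realized noise plus a perturbation an order of magnitude smaller,
so their correlation exceeds 0.95 and any per-gene relevance statistic
takes nearly identical values on both. No ranking method can reliably place
the parents above their copies on such data; what the covariance penalty
*can* do — and what the rank-shift diagnostic `redundancy_rank_shift()`
measures — is demote redundant families as a whole relative to the
penalty-free ranking.

## Test and evaluation problem sizes

The reference conditions used throughout the test suite are the generator
defaults above (200 × 60, three clusters). Solver-behaviour checks run 20
seeded fits at those conditions; oracle-equivalence checks use random
matrices up to 12 × 10 against brute-force double-loop implementations; the
grid-recovery check runs the $\{0.1, 1, 10\}^3$ grid on 10 seeds. The
cross-validation harness is calibrated on perfectly separable data (expects
100% accuracy) and on permuted labels (expects chance within three binomial
standard errors).

## Known limitations

* The covariance penalty is scale-dependent by design (covariance, not
  correlation); genes on inflated scales attract disproportionate penalty.
  Use `standardize_genes()` first if that is unwanted — but note this
  changes $\bar M$.
* The evaluation protocol selects genes on the full data set before
  splitting into folds, which optimistically biases accuracy; nest
  `g3cs_fit()` inside your own fold loop for an unbiased estimate.
* Objective descent is an empirical property with slack, not a theorem: the
  damped multiplicative Z step descends its penalized subproblem, which
  differs from the reported objective by the $\kappa$ penalty term.
* $c$ must be supplied; the model offers no guidance for choosing it beyond
  external knowledge of the sample structure.
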