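---
title: "Methods: geometric self-expressive models for side-effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric self-expressive models for side-effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsem)
```

## The model and its assumptions

The data are a binary incidence matrix $X \in \{0,1\}^{n \times m}$ over
$n$ drugs and $m$ side effects. A zero is *unlabelled*, not a verified
negative: the modelling task is to rank the zeros of $X$ by how likely they
are to be missing ones. The geometric self-expressive model (GSEM)
represents each drug as a non-negative combination of the other drugs and
each side effect as a non-negative combination of the other side effects:

$$X \approx HX, \qquad X \approx XW, \qquad \hat X = HX + XW,$$

with $H \ge 0$ ($n \times n$) and $W \ge 0$ ($m \times m$). Each factor is
the solution of its own convex program; for $W$,

$$\min_{W \ge 0}\; \tfrac12\lVert X - XW\rVert_F^2
  + \tfrac{a}{2}\lVert W\rVert_F^2 + b\lVert W\rVert_1
  + \sum_g \tfrac{\mu_g}{2}\,\mathrm{Tr}(W L_g W^\top)
  + \gamma\,\mathrm{Tr}(W),$$

and the analogous program for $H$ with reconstruction $X - HX$, smoothness
$\mathrm{Tr}(H^\top L_g H)$, and constants $(c, d, \alpha_g)$. The implicit
assumption is a *union-of-subspaces* structure: drugs (and effects) fall
into groups whose association patterns are mutually predictive, so each row
of $X$ is nearly a combination of a few other rows. Unlike low-rank
factorization the self-expressive form does not cap the rank of $\hat X$;
it generalizes low-rank matrix completion while staying convex.

Two modelling choices deserve emphasis:

* **Non-negativity** buys interpretability: a predicted score is a pure sum
  of learned similarities, enumerated exactly by `explain_score()`. Every
  entry of $\hat X$ equals the sum of $H_{iu}$ over drugs $u$ with
  $x_{uj}=1$ plus $W_{vj}$ over effects $v$ with $x_{iv}=1$, to machine
  precision — this identity is property-tested over entire fitted matrices.
* **Convexity plus KKT-convergent updates** buy reproducibility: fits from
  different random initializations reach the same objective value, so the
  learned similarities are a property of the data and the penalties, not of
  a seed.

### Graph assignment

The smoothness penalties attach side information to the two fits. On
dimensional grounds graphs over *drugs* ($n \times n$ Laplacians) can only
regularize $H$, and graphs over *side effects* only $W$; the package
enforces exactly that. With the standard five-graph setup this means the
chemical, indication, target and drug-taxonomy graphs smooth $H$ (weights
$\mu_{\text{chem}}=0.1$, $\mu_{\text{ind}}=0.5$, $\mu_{\text{target}}=0.01$,
$\mu_{\text{atc}}=5$ are sensible starting points) and the side-effect
terminology graph smooths $W$ ($\alpha_{\text{meddra}}=0.5$). The rows of
$H$ are the drug self-representations, so $H$'s penalty smooths rows
($\mathrm{Tr}(H^\top L H)$); the columns of $W$ are the side-effect
self-representations, so $W$'s penalty smooths columns
($\mathrm{Tr}(W L W^\top)$). We define the penalty as the trace form
itself; it equals half the adjacency-weighted sum of squared coefficient
differences, and the absorbable factor of 2 is left inside the weights.

## The optimizer

`fit_selfrep()` iterates a multiplicative update (for $W$):

$$w_{ij} \leftarrow w_{ij}\,
  \frac{\bigl(X^\top X + \sum_g \mu_g W A_g\bigr)_{ij}}
       {\bigl(X^\top X W + \sum_g \mu_g W D_g + aW + b + \gamma I
        + \varepsilon\bigr)_{ij}},$$

the diagonally-rescaled gradient scheme familiar from non-negative matrix
factorization: denominator minus numerator is exactly the gradient, so
fixed points with positive entries are stationary and entries at zero stay
at zero (zeros are absorbing — documented behaviour, which is why
initialization is strictly positive). For $H$ the update is the transposed
analogue whose denominator carries $H X X^\top$, the form consistent with
the analytic gradient of $\tfrac12\lVert X-HX\rVert_F^2$ — the property
tests (monotone descent, finite-difference gradient agreement, KKT
residual) all hinge on this consistency and would fail for the
transposed-product variant.

Numerical choices, all covered by tests:

* **Initialization**: i.i.d. Uniform$(0, 0.01)$ under a caller-provided
  seed; one RNG stream per fit, and the global RNG state is restored
  afterwards.
* **Stopping**: $\max_{ij} |\Delta S_{ij}| / (|S_{ij}| + 10^{-12}) <
  \text{tol}$, default tol $= 10^{-2}$ (typically a few tens of iterations);
  the convergence studies in the tests use $10^{-6}$. Hitting `max_iter`
  (default 500) warns and returns the best iterate rather than erroring.
* **Stabilizer**: $\varepsilon = 10^{-12}$ on every denominator entry
  guards against $0/0$ for entities with empty rows/columns, whose
  coefficients legitimately decay to zero (reported with a warning).
* **Diagonal handling**: during optimization the diagonal is only
  *penalized* ($\gamma = 10^4$ by default, large against the data term);
  after convergence it is below $10^{-3}$ and `gsem()` hard-zeroes it so no
  residual self-loop can leak a drug's own training labels into its scores.
* **Optimality**: `kkt_residual()` returns
  $\max_{ij}\,|\min(S_{ij}, \nabla_{ij})|$, zero exactly at a KKT point.
  At tol $10^{-6}$ the residual is below $10^{-4}$ and the objective agrees
  with a long-run projected-gradient solve of the same program to within
  $10^{-4}$ relative, across seeds.

## Tuning parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `l2` (`a`/`c`) | ridge weight | 0 | strong values (tens) stabilize dense instances |
| `l1` (`b`/`d`) | lasso weight | 0 | adds a constant to the update denominator |
| `graph_weights` | $\mu_g$ / $\alpha_g$ | none | per-graph smoothness strength |
| `diag_penalty` ($\gamma$) | trace penalty | $10^4$ | must dominate the data term |
| `tol` | relative-change stop | $10^{-2}$ | $10^{-6}$ for optimality studies |
| `max_iter` | iteration cap | 500 | warns, never throws |
| `init_upper` | init scale | 0.01 | strictly positive start |

All parameters are unitless weights on Frobenius/absolute/trace terms of
the objective.

## The evaluation protocol

`split_associations()` holds out $\lfloor 0.1 P\rfloor$ of the $P$
positives for testing and $\lfloor 0.1 (P-|\text{test}|)\rfloor$ of the
remainder for validation (floor rounding: at $P = 27{,}610$ this yields
exactly 2,761 / 2,484 / 22,365), then samples two negatives per positive
uniformly from the zero entries, excluding every labelled positive and
keeping validation and test negatives disjoint. AUROC uses mid-rank tie
handling (all-tied scores give exactly 0.5); AUPR integrates precision over
recall step-wise with ties grouped at one threshold. Both are verified
against exhaustive pairwise/step-wise oracles on every input up to length
12.

The ratio of reporting frequency, $\mathrm{RRF}(j) = \sum_i x_{ij} / Z$
with $Z$ the largest column count, measures how broadly an effect is
reported; group-wise shifts are tested with one-tailed Wilcoxon rank-sum
tests (both tails evaluated, the more significant reported with its
direction) under Benjamini-Hochberg adjustment. For reproducible p-values
at toy scale the implementation enumerates the exact rank-sum distribution
(mid-ranks doubled to integers, a subset-sum dynamic program) whenever
either side has fewer than 10 observations, and otherwise uses the
tie-corrected normal approximation of `stats::wilcox.test` without
continuity correction. Note that with a strongly shifted group present,
*other* groups correctly become significant in the opposite direction —
each group is compared against the pooled complement.

`integration_eval()` reproduces the single-drug data-integration design:
the target drug keeps only its clinical-trial associations; the other drugs
train either on clinical associations (strategy 1) or clinical plus
postmarketing (strategy 2); drugs chemically similar to the target at
Tanimoto $\ge 0.6$ are removed first so analogs cannot leak the answer; the
AUROC is computed over the target's training zeros with its postmarketing
associations as positives.

## The synthetic world

`synthetic_spec()` defaults describe the study conditions used throughout
the tests: 60 drugs and 50 side effects in $4 \times 4$ clusters, each drug
cluster expressing one side-effect cluster, association probability 0.6
inside compatible blocks and 0.02 outside, cluster graphs with edge
probabilities 0.8 (within) and 0.05 (across), and a balanced
branching-3, depth-4 hierarchy mirroring the 4-level structure of drug
classification codes (sibling leaves at distance 2, opposite branches at
8). Every drug is guaranteed at least five positives by row resampling,
mirroring the common inclusion rule for trial-annotated drugs; with 4
side-effect clusters this floor needs roughly 40 or more side effects to be
attainable, so smaller test instances use 2 clusters. The block sizes used
in the test suite (up to $60 \times 50$ for descent checks, $8 \times 6$
for optimality studies, 20 repetitions of $40 \times 40$ for the
integration experiment) keep the full suite and the acceptance script in
the low minutes on one core.

The generator emulates the union-of-subspaces structure and the sparsity
regime the model assumes, and that is all it emulates. Real
pharmacovigilance data additionally have a long-tailed reporting
distribution over side effects, correlated (not block-random) similarity
graphs, selection bias in which trial associations get recorded, and far
larger scale. Passing the recovery experiment (held-out AUROC $\ge 0.9$,
comfortably above a degree-product popularity baseline) therefore shows
that the implementation recovers planted self-expressive structure — it is
a correctness check on the machinery, not a claim about clinical
performance on real data.

## Design decisions taken where the design was open

* **Set-to-set taxonomy distance**: minimum over cross-pairs of annotation
  codes. The minimum is the conservative choice that reproduces the known
  bounds (2 and 8) for singly-annotated entities. It is *not* a full metric
  over multi-code sets — a two-code hub can shortcut the triangle
  inequality — so the metric property is only asserted for single-code
  annotations, where the set distance coincides with the (true) graph
  metric.
* **Taxonomy normalizer**: the empirical maximum set distance over the
  annotated entities, not the theoretical bound, so the most distant
  observed pair always has similarity exactly 0.
* **Multi-axial terminologies**: a node may have several parents; shortest
  paths may cross axes.
* **Negative pools**: negatives are sampled from entries that are zero in
  the *full* labelled matrix, so a sampled negative is never contradicted
  by any labelled set.
* **Edge-list symmetrization**: when both directions of a pair are given to
  the constructor the larger weight wins; a *file* carrying inconsistent
  duplicate directions is rejected as corrupt instead.
* **Empty feature sets** get similarity 0 to everything, with a warning.

## Limitations

* The fits are dense $O(k^2)$ in memory and $O(nmk)$ per iteration; the
  implementation targets the hundreds-of-entities scale, not
  millions.
* Zeros of the training matrix are treated as unlabelled; the model cannot
  use verified negatives.
* Adding a new compound requires refitting (no incremental update path).
* Multiplicative updates converge slowly near the boundary at tight
  tolerances; the projected-gradient comparison is the accuracy backstop in
  the tests, not a production solver.
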