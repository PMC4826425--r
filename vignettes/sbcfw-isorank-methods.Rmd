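---
title: "Aligning interaction networks with stochastic block-coordinate Frank-Wolfe"
author: "netAlignFW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning interaction networks with stochastic block-coordinate Frank-Wolfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netAlignFW)
```

## The model

Given two undirected networks $G_a$ (the query, $N_a$ nodes) and $G_b$ (the
target, $N_b$ nodes), global network alignment in the IsoRank tradition
scores every node pair $(u, v)$ by how well the neighborhoods of $u$ and $v$
match recursively. Let $B = A_a \otimes A_b$ be the Kronecker product of the
two adjacency matrices: the adjacency of the product graph on the
$N = N_a N_b$ pairs, in which pair $(u, v)$ neighbors $(u', v')$ exactly when
$u \sim u'$ and $v \sim v'$. Dividing each column by its degree sum gives the
column-stochastic transition matrix

$$\bar B = B\,\mathrm{Diag}(B\mathbf 1)^{-1},$$

the random walk on node pairs. If both inputs are connected and
non-bipartite the walk is irreducible and ergodic, and the pair-score vector
sought is its unique stationary distribution — the maximal right eigenvector
$\bar B x = x$ with $\mathbf 1^\top x = 1$, $x \ge 0$. External evidence
(sequence similarity such as BLAST bit-scores) enters through the mixture

$$\hat B = \alpha \bar B + (1 - \alpha)\,\bar S \mathbf 1^\top,
  \qquad \bar S = S / \lVert S\rVert_1,\ \alpha \in [0, 1],$$

whose rank-one part re-injects mass proportional to the normalized
similarity vector at every step (the same device as the teleportation term
in PageRank; it also makes the chain irreducible regardless of topology when
$\alpha < 1$).

For the degree normalization we use $\lVert S \rVert_1$, which keeps
$\hat B$ column-stochastic on the simplex. Pairs whose product degree is
zero get an all-zero column (`0/0 := 0`); such inputs are accepted with a
warning since the stationary interpretation is then no longer guaranteed.

Rather than run the power method — which needs a full $O(N^2)$-cost pass per
step at the scale of whole interactomes — the eigenvector problem is recast
as a convex quadratic program on the unit simplex
$\mathfrak H = \{x : \mathbf 1^\top x = 1,\ x \ge 0\}$:

$$\min_{x \in \mathfrak H}\ f(x) = \tfrac12 \lVert \hat B x - x \rVert^2
  = \tfrac12\, x^\top M x, \qquad M = E^\top E,\ E = \hat B - I.$$

$M$ is positive semi-definite by construction, $f$ is convex, and $f = 0$ at
the eigenvector.

## The solver

The program is solved by a stochastic block-coordinate variant of the
Frank-Wolfe (conditional-gradient) method. The $N$ pair coordinates are
split into $n$ near-equal blocks; each iteration

1. samples one block $i$ uniformly;
2. computes the partial gradient $\nabla_i f(x) = [E^\top]_i\, p$ from the
   tracked residual $p = E x$;
3. solves the linearized subproblem over the slice of the simplex where all
   coordinates outside the block are pinned at their current values. This
   has a closed form: the slice is a scaled simplex carrying the block mass
   $L = \sum_{l \in i} x_l$, and the minimizing vertex puts all of $L$ on
   the block coordinate $j$ with the smallest partial-gradient entry (ties:
   smallest index), $s = x - U_i x + L e_j$;
4. takes the exact line-search step. Along the segment the residual is
   $(1-\gamma)p + \gamma q$ with $q = E s$, so
   $\hat\gamma = (p^\top p - p^\top q)/\lVert p - q\rVert^2$, clipped to
   $[0, 1]$ (or $\gamma = 0$ if $\hat\gamma \le 0$ or the direction is
   degenerate).

Because $s - x$ is nonzero only on one block, both
$q = p + E(s - x)$ and the residual update
$p \leftarrow p + \gamma E(s - x)$ touch only the block and its product
neighborhood — never all of $N$ — which is what makes the per-iteration
cost a fraction $1/n$ of a full pass. The same recurrences give the
objective $f = \tfrac12 p^\top p$ and the stopping rule
$\lVert p \rVert \le \xi \lVert x \rVert$ for free. Exact line search makes
the objective trace non-increasing deterministically, not just in
expectation, and the solver treats any observed increase beyond $10^{-9}$
as an internal defect and aborts.

Initialization places mass $1/b$ on one randomly drawn block of size $b$
(block sizes are $\lfloor N/n \rfloor$ or $\lceil N/n \rceil$ when $n$ does
not divide $N$; the initial mass is $1/b$ for the drawn block's actual size
so the simplex constraint is exact). A block-sparse start keeps even the
first residual computation cheap.

### Block sampling modes

With a partition fixed once, the subproblem constraints force every block's
mass to be invariant across the whole run — the oracle vertex conserves
block sums — so an iterate initialized with all mass in one block could
never move mass between blocks. The default mode therefore re-randomizes
the partition every iteration (equivalently: draws a uniform random subset
of size $\lceil N/n \rceil$), which removes the pathology while preserving
the expected-descent argument. `fixed_partition` is retained as an option
for studying the literal fixed-partition behavior.

### Two engines, one algorithm

`sbcfwIsoRank()` exposes two implementations of the identical iteration.
The `"reference"` engine is the modular R loop (`sbcfwRun()` plus the
callback operations `partialGradient()`, `simplexBlockLMO()`,
`optimalStep()`, `computeQ()`, `updateResidual()`, `residualStop()`), with
an optional `debug` mode that re-derives $p$ and $q$ from scratch at every
iteration and certifies the recurrences to $10^{-10}$. The `"compiled"`
engine (default) runs the same loop in C++ with sparse accumulators and
incrementally tracked scalars $p^\top p$, $x^\top x$ and $\bar S^\top p$
(refreshed by full dot products every 16384 iterations to cancel
floating-point drift). Both engines consume the same block-sampling RNG
stream — a partial Fisher-Yates shuffle, one uniform draw per selected
index — so for a given seed they visit identical blocks, and their traces
agree to floating-point accuracy. The compiled engine exists because
conditional-gradient methods spend very many very cheap iterations: single
moves transfer one block's mass onto one coordinate, so tight tolerances
routinely take $10^5$–$10^6$ iterations.

### Convergence behavior and realistic tolerances

Frank-Wolfe methods on a simplex converge at rate $O(1/k)$ in general and
only enter a linear-rate regime once the iterate is near an optimum lying
in the relative interior. For this objective the interior margin is the
smallest stationary probability, which shrinks with $N$; in practice the
relative-residual tolerance $\xi = 0.1$ (the default, sufficient for
correct alignment extraction on all benchmark instances here) is reached in
hundreds of iterations, while tolerances like $10^{-6}$ are realistic at
pair dimensions up to a few hundred and become expensive beyond that. The
verification suite therefore checks tight-tolerance behavior on instances
with $N \le 2500$ and alignment-level behavior at the loose, practical
tolerance.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.5 with similarity, 1.0 without | weight of topology vs. similarity in $\hat B$; dimensionless |
| `nBlocks` | 30 | number of coordinate blocks $n$; per-iteration cost scales as $1/n$, iteration count grows with $n$ |
| `xi` | 0.1 | relative residual stopping tolerance $\lVert \hat Bx - x\rVert \le \xi\lVert x\rVert$ |
| `seed` | 42 | drives block sampling and initialization; runs are bit-reproducible per seed |
| `mode` | `repartition` | block sampling mode (see above) |
| `maxIter` | $50\,n\lceil\log N\rceil$ | iteration cap; hitting it returns `converged = FALSE` rather than an error |

The `nBlocks` default of 30 reflects the empirically favorable
middle of the range on query-scale problems: larger $n$ makes iterations
cheaper but more numerous, and the product of the two costs is minimized at
moderate $n$ (the benchmark helper `cmdSweep()` reproduces the iteration
side of this trade-off).

## Alignment extraction

The converged score vector reshapes (query-major) to an $N_a \times N_b$
score matrix. A greedy maximum-score matching — repeatedly take the largest
remaining entry, delete its row and column, ties toward the smallest query
then target index — yields a deterministic one-to-one alignment, following
the established practice for IsoRank-family scores; a Hungarian-style
optimal assignment is deliberately out of scope. An `argmax` per-row mode
(possibly many-to-one) is available for diagnostics. Accuracy against a
known correspondence is the fraction of all query nodes aligned to their
true partner, so unmatched query nodes count as errors.

## Synthetic benchmark instances

`plantedInstance()` emulates the cross-database query setting: a connected
induced subgraph of the target is extracted as the query (the inducing node
map is the ground truth), and the target is then decorrelated by
degree-preserving double-edge swaps on a fraction of its edges — modelling
two databases archiving partly different interactions for the same
organism without altering the degree sequence that shapes the stationary
structure. Similarity scores put weight `signal` on every true pair plus
uniform noise scores on random decoy pairs. Generated targets are connected
and non-bipartite by construction (random bridging of components, plus a
planted triangle if a draw comes out bipartite).

What these fixtures do *not* emulate: the degree distributions of real
interactomes are heavier-tailed than Erdős–Rényi draws, similarity scores
of real protein families are structured rather than uniform noise, and real
cross-species queries have no exact planted correspondence. Passing the
suite therefore demonstrates the correctness of the optimization machinery
and the recovery behavior under controlled conditions, not biological
performance on any particular interactome pair.

Dense brute-force oracles ship in the package itself
(`denseTransition()`, `denseOracleStationary()`, `denseM()`) so an
installation can be verified end-to-end: the power method on the explicitly
materialized transition matrix is the classical solver for this problem and
serves as the independent reference at small $N$.

## Numerical choices

* Argmin ties in the block oracle resolve to the smallest coordinate index;
  greedy-matching ties to the smallest query then target index. All outputs
  are therefore seed-independent given the score vector.
* The step size returns $\gamma = 0$ when $\lVert p - q\rVert^2 < 10^{-15}$
  (degenerate direction).
* A sampled block carrying zero mass produces `s = x`; the iteration counts
  as a stall (recorded in the solver state) and no resampling happens
  inside an iteration. In repartition mode stalls are transient.
* The stopping rule is implemented as the norm inequality
  $\lVert p\rVert_2 \le \xi \lVert x\rVert_2$, with $p^\top p$ the tracked
  quantity.
* Partial gradients in the reference engine are computed by a full
  transpose-apply followed by masking — simpler to verify, never worse than
  the $O(N^2/n)$ contract; the compiled engine gathers block entries
  directly.
* Verification tolerances: dense-oracle identities at $10^{-12}$, adjoint
  and recurrence identities at $10^{-10}$, trace monotonicity at
  $10^{-12}$.

## Problem sizes used in the verification suite

The acceptance checks run, per invocation: 20 pure-topology instances
(targets 12–28 nodes, queries 4–8) solved to $\xi = 10^{-6}$ and compared
with the closed-form degree-proportional optimum; 10 similarity-mixed
instances ($N = 960$) matched against the dense power-method oracle; 20
Hessian eigenvalue checks ($N \le 800$); 500-iteration debug runs for the
recurrences; planted-query recovery at $N = 600$ for $n \in \{1, 10, 30\}$;
a 10-seed iteration-trend sweep over $n \in \{1, 10, 50\}$; and the two
study-scale dimension computations ($6 \times 1622 = 9732$ and
$14 \times 6392 = 89488$). These sizes were chosen so each property is
exercised in the regime where its guarantee is informative.

## Known limitations

* No convergence-rate certificate is attached to the generalized block
  scheme; only monotone descent to the global optimum of the convex
  program is guaranteed.
* Tight tolerances at large $N$ are expensive (the $O(1/k)$ regime above);
  for production queries the loose default is the intended operating point.
* One-to-one greedy extraction can be suboptimal as an assignment; no
  many-to-many post-processing is offered.
* Directed or weighted networks, and products of more than two networks,
  are out of scope.

## A worked example

```{r example}
inst <- plantedInstance(targetSize = 100, querySize = 6, meanDegree = 6,
                        rewireFraction = 0.05, noisePairs = 6, seed = 1)
st <- sbcfwIsoRank(inst$query, inst$target, sim = inst$sim, alpha = 0.5,
                   nBlocks = 30, xi = 0.1, seed = 2)
st
res <- extractAlignment(st, inst$query, inst$target, truth = inst$truth)
res
```
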