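---
title: "Methods: circular orderings, split weights, and planar split networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular orderings, split weights, and planar split networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circularnet)
```

## The model

A *split* `A|B` is a bipartition of the taxon set; a weighted split system
assigns each split a non-negative weight `lambda(S)`.  The split distance
between taxa `x` and `y` is the total weight of splits separating them.
Phylogenetic trees are the special case of pairwise compatible splits; a
*circular* split system is one whose splits are all intervals of a single
cyclic arrangement `theta` of the taxa.  Circular systems strictly contain
tree-like systems and are exactly the systems drawable as outer-labeled
planar networks, which makes them a natural house for conflicting
phylogenetic signal.

Given an observed dissimilarity matrix `d`, the package computes a circular
split system whose metric approximates `d`, in three stages:

1. **Circular ordering.** Agglomeration over components: starting from `n`
   singletons, the pair of components minimizing the neighbor-joining
   adjusted distance (the Q-criterion applied to components, with the
   average distance between the active chain ends as the component
   distance) is joined, chain ends being selected by the same criterion
   with the four candidate ends treated as temporary singleton components.
   After each of the `n - 1` joins the working distance matrix is reduced
   in place; the concatenation formulas use fixed 1/2, 1/3, 1/6
   coefficients so the reduction is symmetric in the two chains, removing
   any dependence on which chain is called first.  The final chain closes
   into a Hamiltonian cycle.

   On circular input this selection is *consistent*: the selected pair is
   always adjacent in some circular ordering compatible with `d`, so the
   computed cycle supports an exact representation.  We verify this
   property empirically in the test suite (it holds on hundreds of random
   circular metrics, and the first selected pair on additive input is
   always a cherry of the generating tree).  Two printed variants of the
   selection criterion -- excluding both chosen components from the row
   sums, and halving the cross terms of the two-chain end selection --
   break this consistency on roughly 10-20% of random circular instances;
   the package therefore uses the uniform Q-criterion formulation
   throughout, which shows no failures.

2. **Split weights.** For the computed ordering all `n(n-1)/2` interval
   splits are candidates, and their weights minimize
   `||A lambda - d||^2` subject to `lambda >= 0`, where `A` is the 0/1
   circular design matrix (pair `ij` vs. interval split `kl`).  `A` is
   never formed: products with `A`, `A^T` and `A^{-1}` are evaluated by
   O(n^2) inclusion-exclusion recurrences (C++ kernels).  `A^{-1}` is one
   cyclic "Crofton" stencil,
   `y[k,l] = (x[k-1,l-1] + x[k,l] - x[k,l-1] - x[k-1,l]) / 2`,
   which on a circular metric returns each interval's isolation weight.

   All solvers start from `max(A^{-1} d, 0)`; when `A^{-1} d` is already
   non-negative -- always the case for circular `d` -- this is the global
   optimum and no iterations run, so exact inputs are solved in O(n^2).
   Otherwise one of three solvers runs (all matrix-free):

   * *Active set* (default): truncated CGNR (conjugate gradients on the
     normal equations, masked to the free coordinates) solves each
     equality-constrained subproblem; many variables may enter the active
     set per iteration (the fraction `rho = 0.6` of infeasible
     coordinates with the smallest `lambda * (lambda - lambda*)`), and the
     CGNR iteration count is capped at `max(50, n)` -- running it to
     convergence between active-set updates is wasteful.
   * *Gradient projection*: exact first-local-minimum search of the
     piecewise-quadratic objective along the projected steepest-descent
     path (breakpoints where coordinates hit zero, coincident breakpoints
     merged, one-sided derivatives at the segment ends), followed by CGNR
     refinement on the identified face, accepted through a projected
     backtracking search with a sufficient-decrease test.  The secondary
     search is our interpretation of the refinement step, which the
     original description delegates to the general convergence conditions
     of projected-search methods.
   * *Accelerated projected gradient*: Nesterov momentum with fixed step
     `1/||A^T A||` (power iteration estimate inflated 5%, since an
     over-estimate merely shortens steps) and adaptive restart when
     `g^T (lambda_{k+1} - lambda_k) > 0`.

   Convergence uses one certificate everywhere: the squared norm of the
   projected gradient below `delta = delta_scale * ||A^T d||^2`
   (`delta_scale = 1e-8` by default).  Because `delta` scales with the
   *data* norm rather than the residual, near-noise-free problems can
   satisfy it while still ~1e-3 relative above the true optimum; analyses
   that compare solvers against each other or against a dense reference
   should set `delta_scale` to `1e-12`--`1e-14` (the tests do).  Splits
   with weight at or below `1e-8 * max(d)` are pruned from the reported
   system -- reported split counts presuppose some pruning, and this
   threshold is at the numerical noise floor of the solvers.

3. **Network construction.** Taxon `i` of the ordering receives angle
   `(i-1)/n * 360` degrees, each split the mean angle of its interval; a
   split is drawn as parallel edges of length equal to its weight at its
   angle.  The *outline* is the boundary polygon: walking the taxa in
   cyclic order, each split is crossed twice, opening (`+`) and closing
   (`-`), closings before openings within a step and nested intervals
   innermost-out, so the polygon closes exactly and stays simple.  The
   *full network* inserts split bands one at a time (interval start
   ascending, length descending): the boundary path spanning the interval
   is duplicated, ladder edges labeled with the new split connect original
   to duplicate, interval-side attachments move to the duplicates, and
   coordinates are resolved at the end by accumulating oriented edge
   displacements over a spanning tree.  The construction is specified by
   its properties rather than by any particular insertion recipe: each
   edge carries exactly one split and each split at least one edge;
   deleting a split's edges leaves exactly the two sides of its
   bipartition; no geodesic repeats a split; all edges of a split are
   parallel with length equal to its weight.  The property suite (plus a
   segment-intersection planarity check) is enforced in the tests on
   random systems.

The *fit* statistic `100 * (1 - sum (d_ij - p_ij)^2 / sum d_ij^2)` compares
the input to the network's geodesic distances; it is exactly 100 on
circular input and degrades with noise.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `method` | `active_set` | solver; the active-set method gives the sparsest systems and best fits in our experience |
| `delta_scale` | `1e-8` | convergence threshold scale (unitless; multiplies `||A^T d||^2`) |
| `rho` | `0.6` | fraction of infeasible coordinates entering the active set per iteration |
| `cgnr_cap` | `max(50, n)` | inner CGNR iteration bound |
| `max_outer_iterations` | `1000` | outer-iteration bound; on exhaustion the best iterate is returned flagged non-converged rather than raising |
| `weight_prune_threshold` | `1e-8 * max(d)` | splits at or below are dropped |
| `theta0` | `1.0` | initial momentum parameter (performance is insensitive over 0.1--1.0) |

Numerical details fixed by the implementation: CGNR stops at relative
normal-equation residual `1e-10` or its cap; coordinates within `1e-12` of
zero after a feasibility step are treated as active; breakpoints merged
within relative `1e-12`; selection ties in the ordering resolved first by
the smaller component distance (label-independent; with exactly four
components the criterion ties every pair with its complement, so this
matters structurally), then by taxon-index order.  Degenerate inputs: `n
<= 3` orderings are returned directly; an all-zero `d` yields an empty
split system; the fit is undefined (error) for identically zero `d`.

## The synthetic generator

`random_circular_instance()` emulates the statistical situation the
least-squares step assumes: a circular metric plus additive Gaussian noise.
Defaults -- 25 taxa, all trivial splits plus 20% of the internal circular
splits, exponential weights with mean 1, no noise -- generate a sparse but
clearly non-tree-like system in which every pair of taxa is separated
(coincident taxa would make the ordering partially arbitrary).  Noise, when
requested, is specified in absolute distance units and truncated at zero;
2% of the mean distance is a reasonable stand-in for distance-estimation
error.  `random_tree_instance()` draws random unrooted topologies with
exponential branch lengths for the additive special case.

What passing tests on these instances do *not* show: real distance data are
not exact circular metrics plus independent Gaussian noise -- estimation
errors are correlated, signals can be strongly non-circular, and the
least-squares model is at best a working assumption.  Recovery and fit
results on synthetic data certify the algorithms, not the biological
adequacy of a network computed from any particular data set.

## Problem sizes

The test suite exercises exact-recovery and property checks at `n` up to
50 taxa (densities 0.2 and 1.0), solver agreement on noisy instances at
`n` in {20, 50, 100} over ten replicates, and network axioms on systems of
up to 10 taxa where exhaustive graph checks are affordable; operator
correctness is verified against densely constructed design matrices for
`n` in 3..12 and the inverse round-trip at `n = 200`.  These sizes give
complete coverage of the combinatorics while keeping a full run in the
minutes range; the algorithms themselves scale as O(n^3) (ordering),
O(n^2) per operator application, and the outline stays linear in the
number of splits, so hundreds of taxa are routine for the pipeline.

## Known limitations

* With four components the selection criterion structurally ties
  complementary pairs; the secondary closer-pair rule makes the choice
  deterministic and label-independent, but a different (equally valid)
  cycle can result than under other tie rules.
* The convergence certificate inherits the data-norm scaling discussed
  above; reported non-convergence of the accelerated solver on hard noisy
  instances at default iteration caps reflects the ill-conditioning of the
  design matrix, whose condition number grows rapidly with `n`.
* The full network of a dense system on many taxa has Theta(n^4) nodes
  (every crossing pair of splits contributes); the outline should be
  preferred for visualization at scale.
* Only circular split systems are drawn; general split systems (convex
  hull constructions) are out of scope.

## A worked run

```{r example}
inst <- random_circular_instance(n = 12, split_density = 0.3, seed = 42)
nn <- neighbor_net(inst$d)
nn
```

With noise the fit drops below 100 and the estimated system picks up small
spurious splits; the solver diagnostics record iterations and the
projected-gradient certificate:

```{r noisy}
dn <- perturb(inst$d, noise_sd = 0.05, seed = 1)
nn2 <- neighbor_net(dn, method = "active_set")
nn2$fit
attr(nn2$splits, "nnls")
```
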