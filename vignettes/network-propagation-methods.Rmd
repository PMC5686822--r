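---
title: "Disease miRNA prioritization on mutual miRNA-target networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease miRNA prioritization on mutual miRNA-target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrmtn)
```

## The model

miRNAs regulate genes by binding their transcripts, and targets in turn
modulate miRNA levels, so the miRNA-target relationship can be modelled
as a *mutual* interaction. This package builds, from a plain
(miRNA, gene) interaction table, a bipartite network whose nodes are
miRNAs and genes and whose undirected unit-weight edges are the
interactions, and prioritizes candidate disease miRNAs by a random walk
with restart (RWR) on that network:

$$p_{t+1} = (1-\gamma)\,W' p_t + \gamma\, p_0,$$

where $W'$ normalizes every node's outgoing weight to 1 and $\gamma$ is
the restart probability. Iteration stops when
$\lVert p_{t+1}-p_t\rVert_1 < 10^{-6}$. The walker's steady state
scores each node by its proximity to the restart distribution, which
encodes the disease: mass $\alpha$ is shared uniformly by the known
disease miRNAs $S_m$ and mass $1-\alpha$ by their target genes $S_g$.
Seeding the targets as well as the miRNAs is the point of the method:
it injects the disease signal into the gene layer, where disease genes
cluster, and lets it flow back to nearby candidate miRNAs.

The method assumes the "disease module" principle -- miRNAs and genes
involved in the same phenotype lie close together in the interaction
network. When that fails (associations scattered uniformly over the
network), propagation has nothing to exploit and AUCs fall toward 0.5;
the label-permutation baselines in the test suite show exactly this.

Directed networks (edges miRNA → gene only) are representable but
unusable for this seeding scheme: gene nodes have no outgoing links, so
the walker's mass vanishes at them and non-seed nodes score (near)
zero. The engine therefore refuses the directed mode in the
cross-validation harness and tags direct runs "mass-deficient".

### Comparators

*RWRMDA* runs the same walk on a homogeneous miRNA similarity network:
two miRNAs are joined iff they share a target, weighted by
$|T_i \cap T_j| / \min(|T_i|,|T_j|)$, and only miRNAs seed the walk.
Isolated miRNAs (no shared target with anyone) cannot appear in this
network, which slightly shrinks its ranking universe relative to the
heterogeneous one.

*RLSMDA* is a semi-supervised regularized least-squares blend

$$F^* = w\,F_M^{*T} + (1-w)\,F_D^*, \qquad
  F_M^* = S_M (S_M + \eta_M I)^{-1} A^T,$$

and the analogous disease-space term with the phenotype similarity
matrix $S_D$. The inverse in $F_M^*$ is the solution of the
regularized least-squares functional
$\lVert A^T - S\alpha\rVert^2 + \eta\,\mathrm{tr}(\alpha^T S \alpha)$;
the package solves the linear system rather than forming an inverse. An
inverse-free variant $S(S+\eta I)A^T$ is kept behind
`smoother = "product"` for comparison, since it circulates in the
literature, but it is not a least-squares solution and is not the
default.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $\gamma$ | restart probability; high values keep mass near the seeds | 0.7 | sweep grid $\{0.1,\dots,0.9\}$ |
| $\alpha$ | seed mass on miRNAs vs their targets | 0.9 | sweep grid $\{0.1,0.3,0.5,0.7,0.9\}$; $\alpha = 1$ degenerates to miRNA-only seeding |
| tol | L1 convergence threshold | $10^{-6}$ | |
| max_iter | iteration cap | 1000 | non-convergence is an error, never a silent return |
| $\eta_M, \eta_D$ | RLSMDA regularization | 1 | $\eta \to 0$ recovers $A$; $\eta \to \infty$ shrinks to 0 |
| $w$ | RLSMDA space blend | 0.9 | $w = 1$/$w = 0$ isolate one space |

The defaults $\alpha = 0.9,\ \gamma = 0.7$ are the best-performing
setting of the original study's sweep and are reproduced as the
package's defaults; `parameter_sweep()` recomputes the grid on any
data set.

## Evaluation design

Leave-one-out cross-validation holds out each known (disease, miRNA)
association in turn; the remaining known miRNAs (plus, for RWRMTN,
their targets -- recomputed per round so nothing about the held-out
miRNA leaks into the seeds) drive the ranking, and the held-out miRNA
competes against every network miRNA not known to be associated with
that disease. Diseases with fewer than two usable associations are
skipped with a logged reason rather than erroring, since real curated
sets always contain singletons.

The per-disease AUC uses the exact nonparametric estimator: with
thresholds at every achieved rank and ties interpolated through their
group, the trapezoidal area per record reduces to
$(\text{candidates} - \text{midrank})/(\text{candidates} - 1)$, the
Mann-Whitney probability that the held-out miRNA outranks a random
non-associated candidate; a disease's AUC is the mean over its rounds
(all rounds share one candidate count) and the grand mean weights every
disease equally regardless of how many associations it has. Displayed
ranks use a deterministic tie-break (descending score, then ascending
id) so outputs are platform-stable, while AUCs use midranks so ties do
not bias them.

k-fold CV shuffles each eligible disease's associations with a seeded
RNG and deals them round-robin into folds; with k equal to the
association count this reproduces LOOCV exactly (a tested identity).
The original folds of any published k-fold experiment are
unrecoverable, so published k-fold figures can only be checked within a
seed-to-seed tolerance.

Enrichment follows the top-k procedure: rank, take the first
k (default 100) candidates, count hits in a reference association set,
and compute the upper-tail hypergeometric probability. The population
convention -- the one consistent with the published leiomyoma example
(p = 0.012 at k = 2, K = 3, n = 100, N = 1547) -- takes the universe to
be the network's miRNAs minus the disease's seeds, and counts reference
miRNAs inside that universe. Reference naming drift across databases
("-5p"/"-3p" arms) is handled by an optional stem-matching mode,
off by default.

## Synthetic data: what it does and does not emulate

`fixture_spec()` describes a desk-scale study: `n_mirnas = 30`,
`n_genes = 120`, background edge density 0.08, three diseases, module
size 8, cohesion 0.9. Background interactions are i.i.d. Bernoulli;
each disease plants a module of miRNAs wired (at the cohesion rate) to
a shared gene core of the same size, and a random half of the module is
labeled "known" while the other half is hidden ground truth. This
reproduces the one structural feature the methods rely on -- cohesive
disease neighborhoods embedded in a sparse bipartite background -- at
roughly the real networks' edge sparsity, scaled down ~25x so the whole
pipeline runs in seconds.

What it deliberately does not mimic: scale-free degree distributions,
correlated target sets between related miRNA families, literature
ascertainment bias in curated associations, and naming noise. Green
tests on these fixtures therefore demonstrate algorithmic correctness
and the expected qualitative behaviour (planted modules recovered,
permuted labels not), not performance on any real database; the
full-size published numbers are checked by separate acceptance tests
that require the original exports.

All generators draw from sub-seeds derived from the spec's master seed
(one fixed sub-seed per operation), so adding a generator call never
perturbs earlier outputs and every artifact is byte-reproducible.

## Numerical choices and edge cases

- **Convergence norm.** The L1 norm, scale-matched to probability
  vectors and standard in RWR prioritization.
- **Operator orientation.** Outgoing-edge normalization defines row
  stochasticity; the operator applied to the column vector $p_t$ is its
  transpose. On non-regular graphs the two differ, so the convention is
  fixed here once.
- **Seeds missing from the network.** Dropped with a warning and the
  remaining seed mass renormalized (a hard error would make LOOCV on
  real curated data impossible, since curated miRNAs are often absent
  from a given interaction export). Empty effective seed sets are an
  error. An empty derived $S_g$ with $\alpha < 1$ falls back to
  miRNA-only seeding with a warning.
- **Ties.** Midrank for AUC (unbiased under ties), lexicographic id for
  displayed ranks (deterministic).
- **Hypergeometric tail.** Exact summation of the point masses over the
  tail; verified against full enumeration for universes up to 12.
- **Bipartite periodicity.** miRNA-gene graphs are bipartite, so the
  un-restarted walk oscillates; any $\gamma > 0$ damps the oscillation
  at rate $(1-\gamma)^t$. At the default $\gamma = 0.7$ convergence
  takes tens of iterations; very small $\gamma$ converges slowly and
  may hit `max_iter`, which is reported as an error rather than a
  stale vector.

## Problem sizes used in the checks

Unit and property tests run on graphs of 4-40 miRNAs; the acceptance
script uses the default 30-miRNA study for LOOCV/sweep/enrichment and a
60-miRNA, module-size-24 study for 10-fold CV (diseases need at least
10 known associations to be eligible there, and a 12-member known half
clears that). These sizes were chosen so the planted signal is strong
enough to measure while every property is cheap to verify; all reported
quantities are recomputed from the seed at run time.

## Known limitations

- The phenotype similarity matrix for RLSMDA is consumed as an input
  (or generated synthetically); deriving one from clinical text is out
  of scope.
- Heterogeneous edges are unweighted; target-site scores can filter the
  ingest (`score_min`) but never weight the walk.
- Enrichment p-values are reported raw, per disease, without
  multiple-testing correction across diseases, matching the standard
  reporting of the top-k validation procedure.
- The homogeneous network drops isolated miRNAs, so RWRMDA and RWRMTN
  rank slightly different universes on the same interaction set; AUC
  comparisons between them inherit that asymmetry from the methods
  themselves.
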