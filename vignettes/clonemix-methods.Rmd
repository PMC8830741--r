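---
title: "Subclone inference from single-cell SNV matrices: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subclone inference from single-cell SNV matrices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemix)
```

## The problem

Single-cell DNA sequencing yields, after variant calling, an $N \times M$
matrix $D$ of mutation presence/absence calls for $N$ tumor cells at $M$
SNV loci. The calls are badly corrupted: allele dropout turns true 1s into
observed 0s (false negatives, rate $\beta$, reported anywhere between 0.1
and 0.8), amplification artifacts turn 0s into 1s (false positives, rate
$\alpha$, typically around 1%), a large fraction $\eta$ of entries is
simply unobserved, and a fraction $\rho$ of "cells" are doublets — two
cells captured together whose genotypes merge. `clonemix` clusters the
cells into subclones, reconstructs each subclone's genotype, and estimates
$\alpha$ and $\beta$ from the data alone.

## The mixture model

Each cell is assumed to come from one of $K$ subclones with genotype
vectors $C_k \in \{0,1\}^M$ and mixing weights $\pi_k$. Conditional on the
subclone, observed entries are independent with

$$p(d \mid c) = \begin{cases}
1-\alpha & d=0, c=0 \\
\alpha & d=1, c=0 \\
\beta & d=0, c=1 \\
1-\beta & d=1, c=1,
\end{cases}$$

and missing entries contribute a factor of 1 (they are excluded from all
sums; missingness is treated as non-informative, which keeps every M-step
closed-form). The observed-data log-likelihood is
$\ell = \sum_i \log \sum_k \pi_k \, p(D_i \mid C_k)$.

### EM estimation

The E-step computes responsibilities $\gamma_{ik}$ by Bayes' rule in the
log domain (log-sum-exp; responsibilities cannot underflow to an all-zero
row). The M-step maximizes the expected complete-data objective
coordinate-wise in the order $C$, $\beta$, $\alpha$, $\pi$ — each
sub-update is an exact maximizer given the others, so the likelihood is
non-decreasing across iterations, which the test suite asserts at
tolerance $10^{-8}$:

* $C_{kj}$: argmax over $s \in \{0,1\}$ of the
  responsibility-weighted log-probability of column $j$ restricted to
  observed entries; an exact tie resolves to 0, the conservative call
  under an infinite-sites-like prior.
* $\beta$: weighted fraction of observed 0-calls among entries whose
  cluster genotype is 1 (and symmetrically for $\alpha$). Both rates are
  clamped to $[10^{-6}, 1-10^{-6}]$ so no logarithm degenerates. A zero
  denominator (no mutated genotype anywhere) leaves the previous value in
  place with a warning.

Initialization follows the scheme the model was designed with: uniform
$\pi^{(0)}$, $\alpha^{(0)} = 0.01$, a grid search over
$\beta^{(0)} \in \{0.1, \dots, 0.5\}$ (the grid is configurable; the
original values are not published), and $C^{(0)}$ drawn as $K$ distinct
cell rows of $D$ with missing entries zeroed. Each $(K, \beta^{(0)})$
pair is restarted `n_restarts = 10` times from fresh draws and the run
with the best final likelihood wins, ties to the earliest run.
Convergence is declared when the absolute log-likelihood change drops
below `tol = 1e-6` (cap `max_iter = 300`). If a component's weight falls
below $1/(10N)$, its genotype row is re-seeded from a random cell and the
monotonicity guarantee is suspended for that iteration (the fit records
these iterations). User-supplied $\alpha$ and/or $\beta$ are honored by
skipping their updates.

EM is a local optimizer: on about 1% of tiny unstructured instances
(e.g. $6 \times 3$ matrices), every data-row initialization converges to
the same sub-optimal basin and no restart budget reaches the enumerated
global optimum. The acceptance suite documents this by comparing against
exhaustive enumeration over all $2^{KM}$ genotype matrices.

## Choosing the number of subclones

Models with $K = 1, 2, 3, \dots$ are each fitted with the full
restart/grid protocol, and fits are compared by an inter-cluster-variance
score built from two quantities per cluster pair:

* the **expected** distance $d(i,k)$: the number of loci at which two
  random cells of clusters $i$ and $k$ are expected to show different
  observed states, computed from the inferred genotypes and the empirical
  per-locus mismatch probabilities
  $p_{00} = 2\alpha^*(1-\alpha^*)(1-\eta)^2 + 2\eta(1-\eta)$,
  $p_{01} = p_{10} = [(1-\alpha^*)(1-\beta^*) + \alpha^*\beta^*](1-\eta)^2 + 2\eta(1-\eta)$,
  $p_{11} = 2\beta^*(1-\beta^*)(1-\eta)^2 + 2\eta(1-\eta)$
  (missing is a third observed state; two missing entries count as equal,
  hence the $2\eta(1-\eta)$ term and no $\eta^2$ term);
* the **observed** mean distance $\hat d(i,k)$ over all cross pairs of
  cells, with the matching ternary-state convention.

`model_score()` turns each pair into $s(i,k) = \exp(-(d-\hat d)^2)$ and
averages over the $K(K-1)/2$ unordered pairs ($s_1 = 0$ by convention, so
any separable structure beats homogeneity). The search keeps increasing
$K$ until the best score has not strictly improved for $\kappa = 10$
consecutive values (or $K$ reaches `k_max`, default $\min(N, 50)$).

### Why the selector hardens the plain score

Implementing the plain score exposed two structural failure modes, both
reproducible with oracle parameters, so `select_k()` decides between
candidate models with a hardened variant of the same ingredients (the
plain $s_K$ is still computed and reported in the per-$K$ trace):

1. **Self-calibration of under-split models.** A fit with too few
   clusters absorbs subclonal structure into inflated $\hat\alpha$,
   $\hat\beta$; those same inflated rates enter $p_{st}$, so the expected
   distances re-agree with the observed ones and the merged model scores
   near 1. The selector therefore re-scores every candidate with the
   error-rate estimates of the highest-likelihood (most refined) fit,
   whose rate estimates are stable across over-parameterized $K$.
2. **Scale- and size-dependence of the Gaussian.** $(d - \hat d)$ is a
   sum over $M$ loci; its sampling noise grows as $\sqrt{M}$ and shrinks
   with cluster size, so with raw gaps the score of a correct model is
   dominated by the noise of its smallest clusters, while signed
   per-locus errors of a merged model largely cancel in the cross-cluster
   sum. The selector standardizes every gap by the sampling error of
   $\hat d$ (a Hájek-projection estimate with a 0.02-locus floor that
   absorbs the sub-locus residuals left by the rate clamps on clean
   data), and adds each cluster's within-cluster self-consistency gap —
   expected versus observed mean distance *inside* the cluster — where
   merging inflates the observed distance with no possibility of
   cancellation. A pair's score is then
   $\exp(-(z_{ik}^2 + z_i^2 + z_k^2)/3)$, still in $(0,1]$ and averaged
   over unordered pairs.

Across $K$ the hardened score is near 0 while clusters are still merged,
rises steeply, and then fluctuates on a plateau of adequately complex
models. The argmax would pick plateau noise, so the selector returns the
smallest $K$ reaching 75% of the plateau maximum — an automated knee
rule. Components that end with no assigned cells are dropped from the
returned fit, so the reported $K$ counts populated subclones (duplicate
components arise naturally when $K$ exceeds the number of separable
populations).

## The simulator

`simulate_dataset()` generates ground-truthed data from a random clonal
tree: the root gets one child, each further subclone attaches uniformly
to an existing non-root node, and each of the $M$ mutations lands on one
uniformly chosen edge (each exactly once — the infinite sites model, so
noise-free matrices always pass the three-gamete test). Cells join
subclones by preferential attachment (every subclone starts with
pseudo-size 1, later cells join proportionally to current size), which
makes subclone sizes jointly flat-Dirichlet — deliberately unequal; any
subclone left empty receives one reassigned cell so truth labels are
always populated. A cell's true genotype is the union of mutations on its
root path. Doublets (`round(rho*N)` cells, uniformly chosen) OR their row
with that of another uniformly chosen cell before noise; finally each
entry is independently made missing with probability $\eta$, else flipped
$0\to1$ with probability $\alpha$ or $1\to0$ with probability $\beta$.
Defaults are the benchmark's standard factors
$(\alpha, \beta, \eta, \rho) = (0.01, 0.2, 0.2, 0.1)$, and
`sim_preset("D1")` … `"D7"` reproduce the seven benchmark designs.

What the generator does *not* emulate: locus- or cell-specific error
rates (amplification bias), copy-number loss, read-count uncertainty, and
spatially correlated missingness. Passing the simulation benchmarks
therefore shows correct inference under the model's own noise
assumptions, not robustness to every artifact of real libraries.

The flat-Dirichlet subclone sizes matter for interpretation: at $N=500$,
$K=10$ a replicate routinely contains subclones of 3–10 cells. With
$\beta = 0.5$ such subclones are statistically unrecoverable (a true-K
oracle fit reaches only $V \approx 0.89$–0.93 on such seeds), which caps
the achievable mean V-measure in the high-dropout benchmark below what a
more balanced size distribution would give.

## Evaluation metrics

Clustering is scored by the V-measure (harmonic mean of homogeneity and
completeness from the truth/prediction contingency table; the
implementation was cross-checked against an independent reference),
genotyping by entry-wise accuracy, sensitivity and specificity of the
predicted matrix $Z$ (row $i$ = genotype of cell $i$'s cluster) against
the true matrix. All metrics exclude doublet cells, which the simulator
records. A rate whose reference class is empty is reported `NA`.

## Lineage reconstruction

The inferred subclone genotypes (plus a zero-genotype diploid root) form
a complete graph weighted by Hamming distance; `build_mst()` extracts the
minimum spanning tree with Prim's algorithm and deterministic
lexicographic tie-breaking, and `lineage_newick()` exports it with branch
lengths and subclone sizes. This is a display-level proxy for the clonal
lineage, not a phylogeny estimate.

## Problem sizes used in the checks

The packaged checks run the full pipeline at the benchmark designs
scaled to a desk footprint: ten replicates of the $200 \times 50$, $K=5$
design at default noise with the full default protocol; five replicates
of $500 \times 200$, $K=10$ at $\beta=0.5$ and four at $\eta=0.5$ with
3 restarts and two-point $\beta^{(0)}$ grids; one $1000 \times 500$
replicate at $\beta=0.8$; and fifty $100 \times 100$ rate-sweep matrices
whose error rates are re-estimated at the design $K$ with the full
restart protocol — that experiment measures rate recovery, so it does not
confound it with model selection. Tiny-instance EM optimality is checked
against exhaustive enumeration ($N \le 8$, $M \le 5$, $K \le 2$).

## Known limitations

* Doublets are not modeled; they mildly inflate $\hat\alpha$ (the rate
  sweep shows the estimated false-positive rate sitting slightly above
  truth) and can seed spurious small clusters.
* Error rates are global; per-locus or per-cell rates are out of scope.
* The selector's knee fraction (75%) and the 0.02-locus standard-error
  floor are fixed design constants; they were chosen for the plateau
  shape of the hardened score and are not exposed as tuning knobs.
* With very weak signal (high $\beta$ and small subclones) the selector
  merges unrecoverable subclones rather than inventing structure; the
  reported $K$ is then a lower bound on the true clone count.
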