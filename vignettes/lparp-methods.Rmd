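---
title: "Label propagation and similarity projection for lncRNA-disease inference: methods and design notes"
author: "lparp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label propagation and similarity projection for lncRNA-disease inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lparp)
```

## The problem and the model

Curated catalogues of experimentally supported lncRNA-disease associations
are sparse: a 2014-era snapshot holds a few hundred associations over
roughly 150 lncRNAs and 190 diseases (about 1% of all pairs). The
inference task is bipartite link prediction under the guilt-by-association
premise: lncRNAs with similar functions tend to be involved in
phenotypically similar diseases. `lparp` scores every unobserved
(lncRNA, disease) pair in two stages.

**Inputs.** A binary incidence matrix $LD \in \{0,1\}^{n_l \times n_d}$
($n_l$ lncRNAs, $n_d$ diseases), optionally a disease semantic similarity
$DD$ and an lncRNA functional similarity $LL$.

**Similarity layer.** Semantic and functional similarities have many exact
zeros (diseases in unrelated ontology branches, unannotated lncRNAs), so
each is integrated with a Gaussian interaction-profile (GIP) kernel
computed from $LD$ itself:
$$GL(i,j) = \exp\left(-\gamma_l \lVert lp(l_i) - lp(l_j)\rVert^2\right),
\qquad \gamma_l = \gamma' \Big/ \tfrac{1}{n_l}\sum_i \lVert lp(l_i)\rVert^2,$$
with $lp(l_i)$ row $i$ of $LD$ (columns of $LD$ for the disease-side
kernel $GD$). The integrated similarity keeps the primary value where it
is nonzero and falls back to the kernel elsewhere:
$LL^f(i,j) = LL(i,j)$ if $LL(i,j) \neq 0$, else $GL(i,j)$ (likewise
$DD^f$). The zero test is exact because these entries are constructed
values, not noisy measurements.

**Stage one: label propagation.** Each integrated network is normalized
and the known labels diffused to a fixed point:
$$F_L(t+1) = \alpha\, LL^* F_L(t) + (1-\alpha)\, LD, \qquad
  F_D(t+1) = \beta\, DD^* F_D(t) + (1-\beta)\, LD^T,$$
starting from $F_L(0) = LD$ and $F_D(0) = LD^T$ and stopping when the
largest elementwise update falls below $10^{-6}$. The estimated score is
the average $F_e = (F_L^\infty + (F_D^\infty)^T)/2$.

**Stage two: similarity projection.** The integrated similarities are
projected onto the column-normalized estimated scores,
$$LD^{pl}(i,j) = \frac{LL^f(i,\cdot) \cdot F_e(\cdot,j)}{\lVert F_e(\cdot,j)\rVert_2},
\qquad
  LD^{pd}(d,l) = \frac{DD^f(d,\cdot) \cdot F_e(l,\cdot)}{\lVert F_e(l,\cdot)\rVert_2},$$
and averaged into the final prediction $LD^* = (LD^{pl} + (LD^{pd})^T)/2$.
This step is sometimes called a "random projection" in the literature
around the method; it is fully deterministic — no randomness is
introduced and no seed is consumed.

```{r pipeline, eval = FALSE}
sim <- simulateAssociations(SyntheticConfig(seed = 1))
scores <- lparpPredict(sim$LD, sim$DD, sim$LL)
cv <- lparpLOOCV(sim$LD, sim$DD, sim$LL)
cvAUC(cv)
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha`, `beta` | 0.9 | retention rates (unitless, $[0,1]$): fraction of each node's score received from neighbours per step; $1-\alpha$ is re-injected from the initial labels. 0.9 is the value selected by LOOCV sweeps on all three published catalogue snapshots; [parameterSweep()] reproduces the selection on any dataset. They are tied during selection but kept as separate arguments. |
| `tol` | $10^{-6}$ | convergence threshold on the max-abs update; part of the method definition. |
| `maxIter` | 1000 | iteration cap. Under the default normalization the iteration contracts at rate $\le \alpha/2$, reaching $10^{-6}$ in well under 150 iterations; the cap only triggers on degenerate configurations. |
| `normalization` | `"sum"` | see below. |
| `gammaPrime` | 1 | GIP bandwidth numerator; 1 reproduces the original GIP convention (bandwidth = reciprocal mean squared profile norm). |
| `delta` | 0.5 | per-edge decay of ancestor contributions in the DAG semantic similarity; the standard choice in the disease-ontology literature. |

## Numerical and design choices

**Normalization reading.** The degree normalization is stated in the
source literature with ambiguous index bindings. We read it as
$N(i,j) = S(i,j)/(\mathrm{rowsum}_i + \mathrm{colsum}_j)$ — the only
reading in which the two sums differ — which for symmetric $S$ is the
Laplacian-style $S(i,j)/(\deg i + \deg j)$. Entrywise
$N \le \tfrac12 D^{-1/2} S D^{-1/2}$, so $\rho(N) \le 1/2$ and the
propagation always converges for $\alpha < 2$. The familiar
$D^{-1/2} S D^{-1/2}$ is exposed as `normalization = "symmetric"` for
sensitivity checks. As a belt-and-braces guard, `propagateLabels()`
verifies $\rho(\text{retention} \cdot N) < 1$ before iterating and fails
fast otherwise, which also makes the closed-form solve
$(1-\alpha)(I-\alpha N)^{-1}Y$ a valid oracle for the iteration.

**Convergence norm.** The stopping rule uses the max-abs elementwise
difference, the strictest of the common choices, since the source
statement names no norm.

**Initialisation.** $F_D(0) = LD^T$ is stated explicitly in the source
method; $F_L(0)$ is left implicit and fixed to $LD$ by the symmetry of
the two recursions.

**Deferred similarity constructions.** The source method cites the
standard constructions for both similarity inputs without restating them.
We implement Wang's DAG recursion for disease semantic similarity
($D_i(i)=1$, $D_i(t) = \delta \max_{t'} D_i(t')$ over children $t'$ of
$t$ on a path to $i$; pairwise score from shared-ancestor contributions)
and the max-average construction for lncRNA functional similarity, with
two conventions: pairs involving an unannotated lncRNA score 0, and the
diagonal is forced to 1 so no lncRNA has an all-zero similarity row.

**Zero-norm convention.** In stage two, a zero-norm column (or row) of
$F_e$ — which arises for isolated diseases and new lncRNAs when the
similarity side carries no mass either — contributes a zero output
column rather than NaN. All pipeline outputs are finite for any input
meeting the documented preconditions.

**Tie handling.** ROC curves sweep the union of observed scores with
ties grouped; the trapezoidal area then equals the Mann-Whitney
statistic with ties counted half. Candidate lists use competition
ranking ("1,1,3"), deterministic under ties.

**Cross-validation leakage.** The published protocol does not say
whether GIP kernels were computed once on the full matrix or refreshed
per fold. The default here is per-fold (`gipRefresh = "fold"`): the
held-out cell is zeroed before any training-fold similarity is computed,
so the label being predicted can never inform the model that predicts
it. Likewise, when the functional similarity is derived rather than
supplied, it is derived from each fold's training matrix.
`gipRefresh = "full"` is available for reproduction attempts against
protocols that may have computed kernels once.

**LOOCV negative set.** Positives are pooled over folds and compared
against the unknown pairs of the full matrix, scored in the fold in
which the positive was held out (global pooling; `pooling =
"per_disease"` restricts negatives to the held-out pair's disease
column for per-query ranking).

## The synthetic benchmark

`simulateAssociations()` plants a co-block structure: lncRNAs and
diseases are partitioned into `nBlocks` groups (disease families and the
lncRNA modules acting in them); associations are Bernoulli draws at
`densityIn = 0.25` within a co-block and `densityOut = 0.01` outside,
and similarities are `simIn = 0.8` within / `simOut = 0.1` between
blocks plus clipped Gaussian noise (`noiseSd = 0.05`), symmetrized, unit
diagonal. The default 60 x 40 size with 4 blocks yields roughly 200
associations — large enough that leave-one-out folds retain block
support, small enough that a full LOOCV (one refit per known pair, about
200 refits) runs in seconds. These sizes are also what the shipped
regression tests and the acceptance script use.

The generator emulates the two properties the method actually exploits —
sparse associations concentrated in similarity blocks, and similarity
matrices consistent with those blocks. It does *not* emulate the heavy-
tailed degree distribution of curated catalogues, disease-name
heterogeneity, or ascertainment bias toward well-studied lncRNAs, so
passing benchmarks here demonstrate correctness of the machinery and
recoverability of planted structure, not performance on any real
catalogue.

`separableInstance()` is the deterministic extreme: fully associated
co-blocks with exact 0/1 similarities, on which LOOCV attains AUC
exactly 1. Blocks must have at least two lncRNAs and two diseases:
removing one association then leaves the held-out pair's row and column
with same-block support, keeping its score in the within-block regime
while every negative receives only the weak between-block GIP leakage.
With singleton blocks that support vanishes — the held-out pair's row
and column go entirely empty, its score collapses into the background,
and perfect recovery provably fails — hence the minimum size of 4 per
side.

## Reproducibility

The pipeline is deterministic end to end; the only stochastic components
are the generator and the permutation nulls, each driven by a single
integer seed through a private RNG stream (the caller's `.Random.seed`
is never touched). The CLI logs every effective parameter with its
provenance (default, config file or flag) and stamps output files with
the tool version and effective configuration, so any reported AUC can be
audited.

## Known limitations

- Predictions for an entity with no associations *and* no informative
  similarities are uninformative (scores near zero by the zero-norm
  convention) — there is simply no signal to propagate.
- Scores are reported raw; no final normalization is applied. Ranking —
  the quantity all evaluation uses — is invariant to monotone rescaling,
  but raw scores are not comparable across datasets.
- Dense matrix algebra throughout: appropriate for catalogue-scale
  problems (up to a few thousand nodes), not for genome-scale networks.
- Identifier matching is exact and case-sensitive; reconciling disease
  nomenclature across database versions is deliberately left to the
  user.
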