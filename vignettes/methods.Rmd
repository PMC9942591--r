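---
title: "Methods: empirical Bayes site rates and conservation grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical Bayes site rates and conservation grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery:
the model and its assumptions, the tunable parameters and their defaults,
what the simulator does and does not emulate, the numerical choices, and
the known limitations.

## The estimation model

A site's data is one alignment column; the generative model is a
reversible continuous-time Markov chain running along a fixed phylogenetic
tree. The rate matrix is built from a symmetric exchangeability matrix
$S$ and stationary frequencies $\pi$ as $Q_{ij} = S_{ij}\pi_j$, row sums
zero, normalized so that $-\sum_i \pi_i Q_{ii} = 1$: one unit of branch
length then equals one expected substitution per site at the average rate.
Proteins use the JTT replacement model; nucleotides use Jukes–Cantor.
Model choice is deliberately fixed (no model selection): the JTT default
mirrors long-standing practice in conservation servers, and alternative
matrices would slot into `build_model()` without touching the rest of the
machinery.

Rate variation across sites is modeled by a gamma prior with mean one and
shape $\alpha$; small $\alpha$ means strong heterogeneity. The prior is
discretized into $K$ equal-probability categories, each represented by the
exact mean of the gamma density over its inter-quantile bin (computed from
the incomplete gamma function, so the category means always average to
one). The likelihood of column $i$ at category rate $r_k$,
$L_i(r_k)$, is computed by Felsenstein pruning with the transition
matrices $P(r_k b)$ on each branch of length $b$.

Two quantities follow:

* **Shape fitting.** $\hat\alpha$ maximizes
  $\sum_i \log \frac1K \sum_k L_i(r_k)$ by golden-section search on
  $\log\alpha \in [\log 0.05, \log 20]$ with absolute tolerance $10^{-3}$.
  The bounds cover everything from near-invariant ($\alpha\to$ large is a
  single-rate model) to extremely heterogeneous alignments; when the
  optimum lands on a bound (e.g. an invariant alignment, which carries no
  heterogeneity signal) a warning is emitted and the boundary value used.
* **Per-site rates.** The empirical Bayes posterior over categories is
  $w_{ik} \propto \frac1K L_i(r_k)$; the point estimate is the posterior
  mean $\hat r_i = \sum_k w_{ik} r_k$ and the credible interval is the
  central 95% interval on the discrete category grid (largest index with
  cumulative mass under 0.025, smallest index reaching 0.975).

Assumptions worth stating plainly: the tree is treated as known and fixed
(no branch-length re-optimization under the full model); sites are
independent given the tree; the same stationary process runs on every
branch (no covarion or branch-heterogeneous effects); gaps, `X`/`N`, and
ambiguity codes are missing data, contributing all-ones partial
likelihoods. A column with fewer than two informative characters has a
flat likelihood in $r$, so it is assigned the prior and flagged.

## Parameters and defaults

| parameter | default | units / range | rationale |
|---|---|---|---|
| `K` (gamma categories) | 16 | count | fine enough that the discrete CI grid is informative; doubling K changes posterior means negligibly while doubling cost |
| CI level | 0.95 | probability | conventional central interval; reported on the category grid |
| reliability rule | span ≤ 3 grades and ≥ 6 informative | — | a 9-grade scale where the interval covers more than a third of the scale is not a usable assignment; 6 sequences is the point below which single-sequence noise dominates a column |
| distance cap | 5 | substitutions/site | keeps saturated pairs finite for NJ; beyond ~3 the correction is uninformative anyway |
| identity bounds | 0.35–0.95 | fraction | below ~35% alignment quality dominates error; above 95% a hit is redundant with the query |
| coverage bound | 0.60 | fraction | fragments shorter than this grade only part of the query |
| redundancy threshold | 0.95 | fraction | standard de-redundancy level for conservation pipelines |
| representatives | 150 | count | the pipeline's default working-set size; 5 minimum (hard error), warnings outside 50–300 |
| aligner gap costs | open 10, extend 0.5 (BLOSUM62) | score units | standard protein global-alignment defaults for same-molecule mapping |

All are arguments, none are hard-coded.

## Grading

Rates over the query's ungapped positions are standardized with the
population standard deviation (mean 0, SD 1; positive = fast-evolving),
then binned into nine equal-width bins symmetric around zero with
half-range $h = \max(|\min s|, |\max s|)$ and width $2h/9$:
grade $= \mathrm{clamp}(9 - \lfloor (s+h)/w \rfloor, 1, 9)$. This is the
simplest scheme satisfying the three semantic anchors — score 0 is grade
5 (average), $-h$ is grade 9 (most conserved), $+h$ is grade 1 (most
variable) — and it is invariant to rescaling the score vector. A
consequence of anchoring the bins symmetrically at zero is that only the
extreme that attains the half-range is guaranteed its extreme bin; a
strongly skewed score vector may leave the opposite extreme bin empty.
Credible bounds are pushed through the same standardization and binning
(a low rate bound maps to a high grade), giving each site a contiguous
grade interval.

## What the simulator emulates — and what it does not

`random_tree()` grows a topology by uniform leaf splitting (a Yule
process) and draws i.i.d. exponential branch lengths;
`simulate_alignment()` evolves each site independently under exactly the
substitution model and per-site rate multiplier the estimator assumes,
drawing continuous gamma rates rather than the discretized categories so
that the estimator is tested against its intended prior, not its own
approximation. Everything is deterministic given the seed.

This is a best-case data generator: no indels (gaps appear in real
alignments and enter here only as missing data), no alignment error, no
among-branch rate variation, no compositional heterogeneity, no
correlated sites. Passing recovery tests on simulated data therefore
demonstrates the correctness of the estimator under its own model — it
does not bound the error on real alignments, where tree error and
misalignment typically dominate.

Problem sizes used in the test-suite recovery checks were chosen as the
package's standard validation conditions: 60 taxa × 300 sites (shape 0.8)
for rank-correlation recovery and 80 taxa × 500 sites (shape 0.5) for
shape recovery, with exhaustive-enumeration likelihood checks on all tree
shapes of up to four leaves.

## Numerical choices

* **Transition matrices** come from the $\pi$-symmetrized
  eigendecomposition of $Q$ (real spectrum, stable exponentials); tiny
  negative entries from round-off are clamped to zero.
* **Pruning** runs on all sites at once per node, with per-node column
  rescaling; the log scale factors are accumulated per site, so
  300-taxon trees do not underflow.
* **Degenerate inputs**: all-missing columns return probability one;
  zero-length branches give exact identity transitions; a constant rate
  vector standardizes to all-zero scores and grade 5 everywhere; pairs of
  sequences with no shared columns receive the capped distance.
* **Determinism**: hits are sorted by E-value with lexicographic id
  tie-breaks before clustering, so the selection (and everything
  downstream) is a pure function of the input multiset plus the seed.
  Greedy clustering scans in that canonical order, with a composition
  upper bound and an equal-length fast path used only to skip alignments
  that provably cannot (or trivially do) reach the threshold — the
  decisions are identical to aligning every pair.
* **NJ ties** are resolved by ape's deterministic implementation;
  negative branch-length estimates are clamped to zero after joining.

## Design decisions that were genuinely open

* **Tree construction.** Nothing in the rate model dictates how the tree
  is built; this package uses model-corrected distances (Poisson for
  proteins, Jukes–Cantor for nucleotides) and classic neighbor joining,
  and accepts user trees as an override. Likelihoods are invariant to
  root placement under the reversible models used (asserted by test), so
  the NJ tree's arbitrary rooting is harmless.
* **Representative thinning.** Given more clusters than the target, the
  package samples representatives at evenly spaced ranks of the
  E-value-ordered list rather than taking the top ranks: the set should
  cover the similarity gradient, not just the query's nearest neighbors.
* **Clustering identity.** Pairwise identity is matches over the shorter
  ungapped length, on a global alignment with match +1 / mismatch 0 /
  gap −1 — the short-sequence normalization familiar from greedy
  clustering tools, stated here explicitly for reproducibility.
* **B-factor payload.** The structure writer stores the integer grade
  (not the continuous score) in the temperature-factor column: grades are
  what the coloring scripts select on, and integers survive the `%6.2f`
  PDB field exactly, which makes the round-trip testable.
* **Sessions vs scripts.** Viewer output is plain-text PyMOL/ChimeraX
  command scripts rather than binary session files: scripts are
  version-stable, diffable, and carry the same coloring.

## Limitations

* One substitution model per alphabet (JTT / JC); no +F frequencies, no
  model selection, no covarion or mixture models.
* The tree is fixed after construction; branch lengths are not
  re-optimized under the gamma model, so rates are conditional on the
  distance-based tree when no tree is supplied.
* Homology search itself is out of scope: the pipeline ingests result
  files (BLAST tabular or generic TSV plus sequences) and never fetches
  from databases.
* Identical-chain propagation requires byte-identical sequences after
  modified-residue normalization; near-identical chains (point mutants)
  are deliberately not propagated.
* The grade scale is relative to the query's own rate distribution; grades
  are not comparable across unrelated runs.
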