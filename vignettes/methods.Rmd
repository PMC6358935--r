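---
title: "Predicting kinase–substrate interactions by heterogeneous-network matrix completion"
author: "ksmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting kinase–substrate interactions by heterogeneous-network matrix completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksmc)
```

# The model

`ksmc` treats kinase–substrate prediction as a matrix-completion problem on
a heterogeneous network. Three matrices are combined: the kinase–kinase
sequence similarity matrix $M_{KK}$ ($m \times m$), the substrate–substrate
similarity matrix $M_{SS}$ ($n \times n$), and the binary interaction
matrix $M_{KS}$ ($m \times n$), stacked as the symmetric block matrix

$$
M = \begin{pmatrix} M_{KK} & M_{KS} \\ M_{KS}^\top & M_{SS} \end{pmatrix}.
$$

The biological assumption is that phosphorylation is organized by families:
similar kinases phosphorylate similar substrates, so the "true" completed
$M$ should be approximately low-rank, with the similarity blocks and the
interaction blocks explained by the same small set of latent factors.
Missing interactions are scored by recovering the matrix of minimum
complexity consistent with what is observed. Rank minimization itself is
NP-hard, so the convex surrogate used throughout is the nuclear norm
$\lVert X \rVert_* = \sum_i \sigma_i(X)$, via

$$
\min_X \; \tau \lVert X \rVert_* + \tfrac12 \lVert X \rVert_F^2
\quad \text{s.t.} \quad P_\Omega(X) = P_\Omega(M),
$$

where $\Omega$ is the set of observed entries and $P_\Omega$ zeroes
everything outside it. The solver is singular value thresholding (SVT):
with $D_\tau$ the operator that shrinks every singular value by $\tau$
(the proximal map of $\tau\lVert\cdot\rVert_*$, verified in the test suite
by brute-force grid minimization on $2 \times 2$ instances),

$$
X^k = D_\tau(Y^{k-1}), \qquad
Y^k = Y^{k-1} + \delta\, P_\Omega(M - X^k),
$$

kick-started at $Y^0 = \lceil \tau / (\delta \lVert P_\Omega(M) \rVert_2)
\rceil\, \delta\, P_\Omega(M)$. Because $M$ and $\Omega$ are symmetric,
every iterate is symmetric; the implementation asserts this rather than
assuming it. The prediction score for pair $(i, j)$ is the average of the
two off-diagonal block entries of the final $X^k$ — identical for an
exactly symmetric iterate, and invariant under transposition by
construction.

# The pipeline stage by stage

## Sequence similarity

Similarities are optimal Smith–Waterman local alignment scores under
BLOSUM62 with affine gap penalties (open 10, extend 0.5; a gap of length
$L$ costs $10 + 0.5(L-1)$, the EMBOSS `water` convention). The alignment
kernel is implemented in compiled code in this package and is validated in
the tests against two independent references: a brute-force dynamic
program coded separately in R, and `Biostrings::pairwiseAlignment`.

Raw alignment scores grow with sequence length, so they are normalized by
the geometric mean of the self-scores,

$$
\mathrm{sim}(a, b) = \frac{SW(a,b)}{\sqrt{SW(a,a)\, SW(b,b)}},
$$

which guarantees values in $[0,1]$, unit diagonal, and symmetry — the
properties the adjustment threshold and the block matrix presuppose. This
normalization is the package's choice (it is the standard one for
kernel-style protein similarity); alignment-tool "percent similarity"
output would be an alternative convention, and precomputed similarity
matrices can be supplied in its place through the TSV import path.

## Network adjustment

Known interactions are propagated to highly similar partners: for every
known edge $(k, s_1)$ and substrate $s_2 \neq s_1$ with
$\mathrm{sim}(s_1, s_2) > t$, the edge $(k, s_2)$ is added. Defaults:

* `t = 0.9` — the operating threshold of the method; at the similarity
  levels produced by the normalization above this adds edges only between
  near-duplicate sequences.
* strict inequality — similarity exactly $t$ propagates nothing.
* substrate-side only (`adjust_mode = "substrate"`) — the mirrored
  kinase-side rule and a two-sided mode exist behind the same flag, since
  kinase similarity is computed anyway; the two-sided mode applies both
  rules to the *original* matrix in one pass. Single-pass semantics are
  deliberate: cascading through newly added edges could densify the
  network catastrophically at moderate thresholds.

The implementation is a boolean matrix product; the tests compare it
against a literal triple-loop enumeration.

## Observation set

Which entries count as "observed" is the one genuinely open design choice
in the formulation, and it matters. The default, `positives_only`, places
in $\Omega$ all similarity entries and the 1-entries of the interaction
blocks; interaction zeros are *unknowns*. The rationale: under the
constraint $P_\Omega(X) = P_\Omega(M)$, an observed zero is pinned to zero
at convergence, so if zeros were observed nothing could be predicted
except through early stopping — an ill-defined predictor. With
`positives_only` the zeros are exactly the quantities the completion
fills in. The alternative `all_bipartite` policy (every entry observed) is
retained as a flag for ablation.

## Solver parameters

* $\tau$ (`tau = "auto"` $\to 5(m+n)$, the SVT literature's
  recommendation scaled to the side length of the square system). Larger
  $\tau$ pushes the solution toward the minimum-nuclear-norm completion
  but slows the ramp-up of the iteration.
* $\delta$ (`delta = "auto"` $\to (m+n)/|\Omega|$, with $|\Omega|$
  counting matrix cells, symmetric duplicates included). This step size is
  implemented exactly as specified even though the SVT literature
  recommends the larger $1.2 (m+n)^2 / |\Omega|$; the latter is available
  as `delta = "auto-literature"`. The default is conservative: with
  similarity blocks fully observed, $|\Omega| \approx m^2 + n^2$ and
  $\delta$ is small, so convergence of the feasibility residual is slow.
* Stopping: relative residual $\lVert P_\Omega(M - X^k)\rVert_F /
  \lVert P_\Omega(M)\rVert_F < 10^{-4}$ or 500 iterations. Both are
  configurable; neither is prescribed by the formulation itself, so the
  `completion_result` reports the full residual trace and a `converged`
  flag instead of hiding the state. In practice the *ranking* of candidate
  pairs stabilizes long before the residual reaches tolerance, which is
  why the evaluation protocols work at the 500-iteration default; users
  who need converged score *values* should raise `max_iter`.
* $\lVert P_\Omega(M) \rVert$ in the kick-start is read as the spectral
  norm (`y0_norm = "spectral"`); a Frobenius variant is one flag away.
* Divergence (residual exceeding $10\times$ its initial value, which
  happens when a manual $\delta$ is too large) aborts with a diagnostic
  rather than returning garbage.
* SVD backend: LAPACK full SVD. At the intended scale (hundreds to ~1000
  nodes) a full dense SVD per iteration is unproblematic; randomized or
  truncated backends are out of scope.

## Evaluation protocols

*Ten-fold cross-validation.* Known positives are split uniformly into ten
folds (sizes differ by at most one). For each fold, the held-out positives
are removed **before** the adjustment step, and adjustment, assembly and
completion are all recomputed on the training network — the alternative
(adjusting once on the full data) would leak test labels through the added
edges. Held-out positives are then ranked against all pairs never observed
as positive (the standard unlabeled-as-negative convention); training
positives are excluded from the pool. The headline number is the pooled
(micro-averaged) ROC AUC over folds; per-fold AUCs are reported with mean
and standard deviation. A leakage assertion runs inside every fold, and
the test suite additionally checks that handing the trainer a
still-present "held-out" pair trips the assertion.

*De-novo test.* For a queried kinase, *all* of its interactions are
deleted, the pipeline reruns, and the ROC is computed over that kinase's
row only (its true substrates vs. its other substrates). This simulates a
kinase with no annotation at all, where the only usable signal flows
through the similarity blocks.

*ROC/AUC.* Thresholds sweep the distinct score values with ties grouped;
the AUC is the trapezoidal integral, which the tests verify is identical
(to $10^{-12}$) to the tie-corrected Mann–Whitney $U/(n_+ n_-)$ computed
by explicit pairwise comparison.

# The synthetic benchmark

Real kinase–substrate data at the scale that motivated this method (a few
hundred kinases, several hundred substrates, ~1–2 thousand interactions,
many degree-1 nodes) lives in curated databases that cannot be bundled.
The `generate_planted_instance()` module emulates its *statistical shape*
with known ground truth:

* **Sequences**: one random ancestor per cluster over the uniform
  20-letter alphabet; members are ancestors with i.i.d. substitutions (5%
  by default, always to a different residue). Length 200 by default.
* **Interactions**: a stochastic block model aligned with the sequence
  clusters — edge probability 0.8 within a cluster, 0.02 across — whose
  expected adjacency has rank equal to the number of clusters, i.e.
  exactly the low-rank structure the completion assumes.
* **Geometry**: 3 clusters, 8 kinases and 20 substrates per cluster.
  These sizes keep a full cross-validation (10 folds × adjustment +
  assembly + SVT on a 84×84 system) in the seconds range while leaving
  enough positives (~400) for stable AUC estimates.

What the generator does **not** emulate: real amino-acid composition,
indels and domain architecture, the heavy-tailed degree distribution of
curated interaction data, and annotation bias. Passing the planted-signal
tests therefore demonstrates that the machinery recovers the structure it
assumes when that structure is present — it is not evidence about
performance on any real proteome. The substrate-label-shuffled null
control (AUC expected near 0.5) guards against the opposite failure:
protocols that manufacture signal out of degree structure or leakage.

# Numerical and degenerate-case choices

* Ranked outputs sort by descending score with lexicographic
  (kinase id, substrate id) tie-breaks in the C locale, so reruns are
  byte-identical.
* All randomized steps (sequence generation, block-model edges, fold
  assignment, label shuffling) are pure functions of an explicit integer
  seed; nothing reads the global RNG state without restoring it.
* An interaction list with no pairs yields an all-zero matrix plus a
  warning (completion on it is meaningless but well-defined); a kinase
  with no known substrate is an error for a single de-novo query and a
  logged skip in all-kinase mode.
* Sequences are validated against the substitution alphabet; `*` and `-`
  are rejected by name, and the ambiguity codes B, Z, X score via their
  extended BLOSUM62 rows.
* Self-alignment scores are strictly positive for any valid sequence
  under BLOSUM62, so the similarity normalization cannot divide by zero;
  the code still guards the division and errors with the offending record
  named.

## A note on planted-recovery tests at small sizes

The recovery test completes a symmetric rank-2 $10 \times 10$ matrix from
a random symmetric 70% observation mask. At this size the premise that
nuclear-norm minimization identifies the planted matrix does **not** hold
for every random mask: for a substantial fraction of instances there
exists a completion of strictly smaller nuclear norm than the planted
truth, and *any* correct solver returns that other matrix. The fixture
therefore fixes an instance whose identifiability was certified with an
independently implemented Douglas–Rachford nuclear-norm minimizer; on that
instance the SVT solver must (and does, in the tests) reproduce the
unobserved entries to well under 1% relative error, and recovery failure
would indict the solver rather than the instance.

# Known limitations

* Sequence similarity is the only feature; structural, localization or
  phosphosite-motif information is out of scope, as are site-level
  predictions — the unit of prediction is the protein pair.
* The unlabeled-as-negative evaluation convention understates true
  performance if many "negatives" are undiscovered positives, as is
  likely in phosphorylation data.
* With the default conservative step size the feasibility residual
  converges slowly; treat `converged = FALSE` with the residual trace as
  information, not as failure, when only rankings are needed.
* All-vs-all exact alignment is quadratic in the number of sequences; at
  a few thousand sequences a heuristic prefilter (not provided) would be
  the practical route.

# Session info

```{r}
sessionInfo()
```
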