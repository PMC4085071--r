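---
title: "Distance-based functional diversity: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based functional diversity: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funhill)
```

## The measures

Ordinary Hill numbers summarise an assemblage of $S$ species with relative
abundances $p_1, \dots, p_S$ as an *effective number of species*,

$$^qD = \Big(\sum_{i: p_i > 0} p_i^q\Big)^{1/(1-q)}, \qquad
  ^1D = \exp\Big(-\sum_i p_i \log p_i\Big),$$

with the order $q \ge 0$ controlling how strongly abundant species dominate
($q = 0$ richness, $q = 1$ exp-Shannon, $q = 2$ inverse Simpson). Hill
numbers obey the replication principle: pooling $N$ equally large, equally
diverse, completely distinct assemblages multiplies diversity by $N$. That
property is what makes ratios of these quantities interpretable as
differentiation, and it is the reason this package works on the effective
number scale rather than on entropies.

`funhill` extends this machinery to species pairwise functional distances
$d_{ij}$ (from traits, or any symmetric nonnegative matrix). The quadratic
entropy $Q = \sum_{i,j} d_{ij} p_i p_j$ is the abundance-weighted mean
distance between two random individuals. Treating the $S^2$ *pairs* of
species as the units, with joint abundances $p_i p_j$ and weights $d_{ij}$,
and equating the $q$-th power sum of the actual assemblage with that of an
idealized assemblage whose every pair sits at the constant distance $Q$,
gives the functional Hill number

$$^qD(Q) = \Big[\sum_{i,j:\,p_i p_j > 0} \frac{d_{ij}}{Q}\,(p_i p_j)^q
  \Big]^{1/(2(1-q))},$$

the effective number of equally abundant, equally distinct species. Two
derived quantities put it back on the distance scale: the mean functional
diversity $^qMD(Q) = Q \cdot {}^qD(Q)$ (effective distance sum from one
species to the rest) and the total functional diversity
$^qFD(Q) = Q \cdot [{}^qD(Q)]^2$ (effective total distance between
species). Useful anchors, all of which the test suite checks:

* constant $d_{ij}$ for every pair (diagonal included) collapses $^qD(Q)$
  onto the ordinary Hill number;
* $^0FD(Q) = FAD$, the raw sum of pairwise distances among present species,
  and $^0D(Q) = \sqrt{FAD/Q}$;
* equal abundances give $^qD(Q) = S$ and $^qFD(Q) = FAD$ at every order;
* $^2FD(Q) = Q^2 / (Q - GS_D)$ links order 2 to the distance-weighted
  Gini--Simpson index.

$^qD(Q)$ and $^qMD(Q)$ satisfy the replication principle; $^qFD(Q)$,
being their product, is multiplied by $N^2$ when $N$ completely distinct
equally large assemblages with equal within/cross mean distances are
pooled. The package's `replicated_disjoint()` builds exactly that block
construction, and the suite verifies the $N$, $N$, $N^2$ scalings for
$N \in \{2, 3, 4\}$.

## Decomposition and similarity

For $N$ assemblages with abundances $z_{ik}$, gamma diversities are
computed from the pooled relative abundances $z_{i+}/z_{++}$. The alpha
component follows the "effective number per assemblage (pair)" definition:
for the total functional diversity,

$$^qFD_\alpha = \frac{Q}{N^2}\Big[\sum_{i,j}\frac{d_{ij}}{Q}
  \sum_{k,m}\Big(\frac{z_{ik} z_{jm}}{z_{++}^2}\Big)^q\Big]^{1/(1-q)},$$

where $Q$ is always the *pooled* assemblage's quadratic entropy. This
definition keeps gamma $\ge$ alpha for every order and either pooling
scheme, and makes beta $= \gamma/\alpha$ range-independent of alpha:
$^qFD_\beta \in [1, N^2]$ (effective number of completely distinct
assemblage pairs) while the betas of $^qD(Q)$, $^qMD(Q)$ and the ordinary
Hill numbers lie in $[1, N]$.

Two pooling schemes are supported. `scheme = "relative"` (the default, and
the one used by every worked example in the package) rescales each
assemblage to relative abundances first, weighting assemblages equally;
`scheme = "absolute"` pools raw abundances, weighting assemblages by size.
When columns already sum to one the two coincide, which the suite checks.

Because the beta components have known ranges depending only on $N$, they
transform onto $[0, 1]$. From $FD_\beta$: the local distance-overlap
$C^*_{qN}$ (functional Sørensen / Horn / Morisita–Horn at $q = 0, 1, 2$),
the regional distance-overlap $U^*_{qN}$ (functional Jaccard at $q = 0$),
the homogeneity $S^*_{qN}$ and the turnover complement $V^*_{qN}$. From the
Hill-number beta: the abundance-only $C_{qN}$ and $U_{qN}$. Differentiation
is reported as one minus similarity throughout. As functions of the beta
value, $S^*$ coincides with $U^*$'s $q = 0$ form and $C^*$'s $q = 2$ form,
and $V^*$ with $C^*$'s $q = 0$ form and $U^*$'s $q = 2$ form; the suite
asserts these coincidences numerically.

## Parameters that matter

* **`q`** (unitless, default grid `c(0, 1, 2)`; profiles use 0–5 in steps
  of 0.05): sensitivity to abundance. Profiles change little beyond
  $q \approx 4$, so the default plotting range covers the informative part.
* **`scheme`** (`"relative"`/`"absolute"`): choose by the question —
  relative compares composition with equal assemblage weight, absolute
  compares absolute abundances.
* **`d_max_scope`** in `legacy_differentiation()`: the legacy species
  equivalents $1/(1 - Q/d_{max})$ need a maximum distance; the default
  takes it from the pooled matrix (equivalent to prescaling all distances
  by the global maximum), with a per-assemblage alternative exposed. The
  pooled default reproduces the published comparison table for the
  four-species example; the verification test is kept precisely because the
  convention matters.
* **Symmetry tolerance** (`tol = 1e-10`, relative): asymmetric input is an
  error, never silently symmetrized; `symmetrize = "mean"` is an explicit
  opt-in.

## Numerical choices

* $q = 1$ dispatches to its closed-form limit exactly at `q == 1`; there is
  no epsilon window. Continuity is tested by evaluating at $1 \pm 10^{-6}$.
* Pairs with $p_i p_j = 0$ are excluded from every sum, which both guards
  $\log 0$ and makes $q = 0$ count only species actually present.
* The betas of $D$ and $MD$ are reported as $\sqrt{FD_\beta}$ rather than
  recomputed, so the identities $D_\beta = MD_\beta$ and
  $FD_\beta = D_\beta^2$ hold to machine precision.
* A single species with zero intraspecific distance has $Q = 0$; the
  functional measures are then returned as $D = 1$, $MD = FD = 0$ with a
  warning. $Q = 0$ with several species is an error (the measures are
  undefined and no convention is published).
* Beta values are clamped into their admissible range only within
  $10^{-9}$ (float noise); larger violations raise an error because they
  signal an upstream bug, not a rounding issue.
* The alpha sum is evaluated as a quadratic form in the per-species row
  aggregates $r_i = \sum_k a_{ik}^q$, giving $O(S^2 + SN)$ work instead of
  the naive $O(S^2 N^2)$; the test suite checks it against the literal
  quadruple-loop sum on instances with $S \le 6$, $N \le 3$.

## What the generators emulate

`example2_fixture()` is deterministic: two completely distinct two-species
assemblages, within-assemblage distance 0.1 (reconstructed as the unique
value giving alpha quadratic entropy 0.05 under equal abundances), and
cross distances 0.2 — raised to 0.9/0.8 for two pairs in the
non-ultrametric case. `example1_communities()` is the 28-species,
two-assemblage layout with 12 shared species; its heterogeneous variant
draws within-assemblage abundances from a lognormal (meanlog 0, sdlog 1)
species-abundance model, a standard choice since the published
heterogeneous tables are not machine-readable. `example1_matrix()`
regenerates the two contrasting distance recipes — beta(4, 4) everywhere,
versus uniform(0.8, 1) between non-shared species and uniform(0, 0.2)
elsewhere. The published draws of these matrices had no seed, so only
distributional statements (near-equal versus strongly separated alpha and
gamma quadratic entropies, non-ultrametricity) are reproducible from the
recipe, and those are what the tests assert. None of these generators
emulate sampling error, detection bias or undetected species: passing
tests say the mathematics is right, not that plug-in estimates are
unbiased on real survey data.

Property tests run on seeded `random_instance()` draws (uniform distances
bounded away from zero, uniform abundances with up to 40% structural
zeros). Sizes are kept small — $S \le 6$, $N \le 4$, a few hundred
instances — because the oracle is a quadruple loop and the properties are
scale-free; the whole suite runs in a few seconds.

## Design choices where the design was open

* The alpha formula for the functional Hill number is taken as
  $\frac{1}{N}[\,\cdot\,]^{1/(2(1-q))}$, the unique form consistent with
  $FD_\alpha = Q \cdot D_\alpha^2$ and with the identical beta components
  for $D$ and $MD$.
* The cross-assemblage identity at order 0 is implemented as FAD
  additivity: for completely distinct assemblages the pooled FAD is the sum
  of the four within/cross blocks, which the suite verifies.
* Gower distances use pairwise deletion with renormalization over jointly
  observed traits; quantitative ranges are taken over the whole table, a
  zero-range trait is dropped with a warning, and a species pair with no
  jointly observed trait is an error naming the pair. Ordinal traits are
  treated as categorical with a warning rather than interpolated.
* The command-line wrapper (`inst/cli/funhill`) stays a thin shell over the
  exported functions; all logic lives in the package so the R interface,
  the CLI and the tests exercise the same code.

## Limitations

* All estimates are plug-in: no rarefaction/extrapolation or bias
  correction for unseen species, and negative orders are not supported.
* The legacy maximum-distance species equivalents are provided for
  comparison only; they are known to misbehave on non-ultrametric matrices
  (use `is_ultrametric()` to check, and prefer the distance-overlap
  measures).
* Dendrogram-based functional diversity, phylogenetic Hill numbers and
  similarity-sensitive diversity in the sense of species-similarity
  matrices are out of scope.
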