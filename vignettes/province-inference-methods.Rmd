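---
title: "Methods: constrained regression trees for biogeographic provinces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained regression trees for biogeographic provinces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventbiogeo)
```

This vignette is the package's own account of the statistical machinery:
the models, the tunable parameters and their defaults, the numerical
conventions, and what the synthetic-data tests do and do not establish.

## The model

Sites are rows of a presence/absence matrix $Y$ (sites × species). Working
on raw 0/1 data makes Euclidean geometry misleading (double-zero problem),
so rows are Hellinger-transformed, $y'_{ij} = \sqrt{y_{ij} / y_{i\cdot}}$;
each non-empty row then has unit squared norm, and squared Euclidean
distances between rows are bounded and composition-driven.

A multivariate regression tree (MRT) partitions sites by axis-parallel
thresholds on explanatory variables — here latitude and encoded longitude —
minimizing the within-node sum of squares
$SS(t) = \sum_{i \in t} \lVert y'_i - \bar{y}'_t \rVert^2$ of the
transformed composition. Each leaf of the tree is a candidate biogeographic
province: a geographically contiguous (in the encoded coordinate plane)
group of sites with homogeneous fauna. Because the coordinates are used as
plain Cartesian variables, the analysis is *not* rotation- or
wrap-invariant; this is a documented property of the method, not a bug, and
the package makes it a first-class object of study (below).

### Growing

`grow_mrt()` searches, at every node, all thresholds placed at midpoints
between adjacent distinct sorted values of each constraint column and takes
the split maximizing $SS(t) - SS(t_L) - SS(t_R)$. Ties are resolved by
constraint-column order (latitude before longitude in
`build_constraints()` output), then by the smaller threshold. Growth is
best-first (largest achievable gain next), so a `max_leaves` cap yields the
same tree as growing fully and pruning back. Defaults: `min_node_size = 2`
(interpreted as the smallest node still eligible for splitting, like
rpart's `minsplit`, so the grown tree matches an unconstrained exhaustive
split search), `max_leaves =` number of sites. A split must improve fit by
more than `1e-12 × root SS` to be accepted; nodes whose constraint columns
are constant become leaves (with a warning at the root).

### Pruning and cross-validation

`prune_mrt()` performs standard weakest-link cost-complexity pruning:
internal nodes are collapsed in order of
$g(t) = (SS(t) - \sum_{\ell \in T_t} SS(\ell)) / (|T_t| - 1)$, giving a
nested subtree sequence with strictly increasing complexity $\alpha$ and
strictly decreasing leaf counts. Nodes with (numerically) tied $g$ collapse
together, so some sizes can be skipped — `assign_provinces()` reports the
nearest achievable sizes when asked for one that is not in the sequence.

`cross_validate()` shuffles sites into $v$ near-equal folds (uniformly, no
stratification), grows and prunes a tree per training set, and drops each
held-out site down the fold tree by its coordinates. Fold subtrees are
matched to the full-data sequence via geometric means of consecutive
$\alpha$ values (the standard CART convention). The cross-validated
relative error is pooled held-out squared error divided by the full-data
root SS; its standard error is taken across per-site held-out
contributions ($se = sd(e_i)\sqrt{n} / SS_{root}$) — the source material
shows ±1 SE bars without defining them, so this definition is the
package's own choice.

`multi_cv()` repeats this with re-randomized folds (derived deterministic
seeds, so results are bit-reproducible) and tabulates the per-replicate
optimal size, defined as the *smallest* size attaining the minimal xerror —
the conservative reading consistent with the 1-SE recommendation.
`select_size()` offers `most_frequent_min` (modal optimal size, ties to the
smaller) and `one_se` (smallest size within one SE of the minimum mean
xerror, using the across-replicate mean xerror and mean SE). Default
`v = 10`; the original analysis states only "1,000 multiple
cross-validations", so the fold count is exposed in the configuration.

### Longitude encoding

Longitude is a circle; a Cartesian treatment must cut it somewhere. The
three supported encodings (`greenwich_pm180`, `east_of_60W`,
`east_of_greenwich`) are bijections of the same circle differing only in
the cut. Pairwise order of encoded longitudes changes exactly for pairs
straddling the cut (a tested invariant), which is why provinces spanning a
cut can be split by the tree under one encoding and recovered under
another. The `east_of_60W` cut is placed exactly at −60° (sites at −60°
encode to 0). Latitude is never re-encoded. No great-circle alternative is
offered: the method under study treats coordinates as Cartesian, and
providing a spherical variant would change the method rather than
reproduce it.

## Raup-Crick clustering

`raup_crick()` computes, per site pair, the exact hypergeometric tail
probability $p = P(|A \cap B| \ge s_{obs})$ under a null in which both
richness-$a$ and richness-$b$ species sets are drawn equiprobably from the
$S$-species pool; similarity is $1 - p$ (the convention is recorded on the
object, since the literature uses both orientations). The tail is summed in
log space from explicit binomial coefficients — deliberately not
`phyper()` — so the test-suite's full-enumeration oracle is a genuinely
independent route. An occurrence-frequency-weighted null (Monte Carlo, +1
smoothing so unobserved species remain drawable) is available behind
`null = "frequency"`; the classic equiprobable null is the default because
the source analysis names only "the Raup-Crick similarity coefficient".
A pool of only two sites makes the tail degenerate (the observed overlap
can be forced by $a + b > S$), so meaningful similarities need the sites
embedded in a larger species pool. `agglomerate()` is backed by
`stats::hclust` (UPGMA by default; linkage configurable and recorded), with
newick export via ape.

## Molecular arithmetic

`tamura_nei()` implements the TN93 distance from observed purine-transition,
pyrimidine-transition and transversion proportions with base frequencies
pooled over both sequences, after pairwise deletion of columns containing
gaps or ambiguity codes in either sequence (the deletion rule is unstated
in the source; pairwise deletion is the common default for pairwise
distances). Saturated pairs (any logarithm argument ≤ 0) raise a per-pair
error; `run_divergence()` reports them per pair rather than failing the
run. Gap characters produced by `gap_code()` (simple indel coding: one
binary character per distinct maximal gap extent, exact-span scoring) are
*excluded* from distances — they exist for downstream phylogenetics, which
is out of scope here.

A numerical note: TN93 collapses exactly to Jukes-Cantor
($-(3/4)\ln(1-4p/3)$) when base frequencies are equal **and** each of the
six unordered base pairs is equally represented among differences, i.e.
$P_1 = P_2 = p/6$, $Q = 2p/3$. The often-quoted "balanced classes"
shorthand $P_1 = P_2 = Q/2$ does *not* collapse to JC (the two differ in
the third decimal at $p = 0.1$); the tests assert the exact identity.

`date_divergence()` is the rate-based clock: time (My) = percent distance /
(percent per My). With the anomuran 16S calibration of 0.53 %/My a 6.45 %
divergence dates to 12.2 My (one-decimal reporting alongside full
precision); alternative published crustacean rates (0.65, 0.9, 0.67 %/My)
are presets. These dates inherit every caveat of single-calibration clocks
and are reported as arithmetic, not inference.

## The synthetic generator: what a green test establishes

`generate_metacommunity()` draws Bernoulli occupancy: own-province endemics
at `endemicity × detection_prob`, foreign endemics at
`(1 − endemicity) × detection_prob`, cosmopolitans at `detection_prob`.
Defaults mirror the scales used in the acceptance criteria — K = 3
provinces, 10 sites/province, 15 endemics/province, endemicity 0.9,
detection 0.9 — with 5 cosmopolitan species (the criteria leave the
cosmopolitan pool unstated; 5 ≈ 10% of the pool was chosen once as a
realistic shared fraction and not tuned). Province centroids are
longitudinally separable by default (evenly spaced in [−120, 120], jitter
±2°); `centroid_longitudes`/`centroid_latitudes` allow antimeridian-
straddling configurations for the encoding-sensitivity tests.

The generator emulates province-structured occupancy with detection noise.
It does **not** emulate: distance-decay within provinces, species-richness
gradients, correlated detection across species at a site, or dispersal
along ridge topology. A green province-recovery test therefore establishes
that the estimator recovers clean block structure under coordinate
constraints — not that any real dataset's province count is correct, and
in particular not the published 5/7/11-province counts, which depend on an
external global species matrix this package does not ship.
`generate_pair_alignment()` evolves one lineage under the exact TN93
transition kernel (`Matrix::expm` of the scaled rate matrix), so the
distance estimator is tested against its own generating model — an
estimator-consistency check, not a model-adequacy check.

## Determinism

Every stochastic step takes an explicit integer seed; replicate seeds are
derived by a fixed affine map modulo $2^{31}-1$. Identical configuration
and seeds reproduce `run_biogeography()` bundles byte-identically (the
manifest, which carries the only timestamp, is excluded from the
comparison and exists so a run can be re-executed exactly).

## Known limitations

- Constraint variables are continuous only; no categorical constraints,
  surrogate splits, or missing-coordinate handling.
- The Cartesian coordinate treatment inherits the cut-line and
  high-latitude distortions discussed above; the package exposes rather
  than fixes them.
- Raup-Crick p-values are exact only under the equiprobable null; the
  frequency-weighted variant is Monte Carlo with smoothing.
- Divergence dating assumes a strict clock and a single calibration.
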