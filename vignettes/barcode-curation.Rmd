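---
title: "Methods: iterative barcode-library curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative barcode-library curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(barcurate)
```

This vignette is the package's account of its own models and the design
decisions behind them. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## Distances and the barcode gap

All distances are Kimura two-parameter (K2P) with pairwise site deletion:
for each sequence pair, sites where either character is not a plain
A/C/G/T are dropped, transitions and transversions are counted as
proportions P and Q of the remaining sites, and

d = −½·log((1 − 2P − Q)·sqrt(1 − 2Q)).

Pairs with a non-positive logarithm argument (mutational saturation) are
reported as `Inf`, excluded from medians, and capped at twice the largest
finite distance before any tree is built. Distances are substitutions/site
throughout (never percentages internally; 0.022 means 2.2%).

`gap_table()` reports, per OTU, the maximum intraspecific distance (0 for
singletons) and the nearest-neighbour (NN) distance — the smallest
distance from any member to any member of any other OTU, ties broken
toward the lexicographically smallest OTU id. An OTU *has a barcode gap*
when its NN distance strictly exceeds its maximum intraspecific distance.
Global summaries are the medians of both columns over OTUs and their fold
ratio. Whether such medians should run over OTUs or over nominal labels is
ambiguous in practice; this package computes them over the OTUs of the
supplied partition.

## Surrogate trees

The tree-based delimiters consume desk-scale surrogates: a Saitou–Nei
neighbour-joining tree (negative branches zeroed with the deficit moved to
the sister branch, preserving paths through the parent) midpoint-rooted
for PTP, and a UPGMA chronogram for GMYC. The chronogram uses a strict
clock in which **pairwise** divergence accumulates at `clock_rate` = 0.012
per My (1.2%/My pairwise, i.e. 0.6%/My per lineage — the convention is
stated here because the percentage alone is ambiguous): a pair at distance
d coalesces at age d/0.012 My. Both delimiters also accept user-supplied
newick trees (e.g. ML or Bayesian chronograms) for full-scale analyses;
the surrogates will not reproduce results that depend on heavyweight tree
inference. Identical haplotypes are collapsed before delimitation (first
record of each class is the representative) and labels are re-expanded
afterwards.

## The four delimiters

**RSL.** Single-linkage clusters at `seed_threshold` = 0.022, then
refinement: for each cluster, the two-way split at its deepest
single-linkage merge is accepted whenever it strictly increases the
partition-wide mean silhouette on the distance matrix (singletons score 0;
a one-cluster partition scores 0), repeated to a fixed point. This is a
documented approximation of refined single linkage; BIN compatibility is
explicitly disclaimed.

**ABGD.** For each prior intraspecific limit p on a geometric grid
(`p_min` = 0.001 to `p_max` = 0.1 in 10 steps, the defaults of the
original method), the ranked pairwise distances are scanned for the first
significant gap whose upper side exceeds p; the library is cut into
connected components at the gap and the procedure recurses within groups
until stable. *Gap significance*: a spacing qualifies when it exceeds
`gap_width_x` = 1.5 times the largest spacing observed among all smaller
distances — a conservative envelope of the local slope of the
ranked-distance function. A mean-spacing slope estimate was rejected
during development: spacings of a dense distance ladder exceed 1.5× their
local mean far too often (for exponential spacings, ~22% of the time), so
the first-gap rule would fire on noise. The selected partition is the one
at the largest prior whose recursive group count equals the modal count
across the grid, with two refinements: priors smaller than every observed
distance are a vacuous intraspecific hypothesis and do not vote, and tied
modal counts are resolved in favour of the candidate partition with the
higher mean silhouette.

**PTP.** Edges are classed speciation vs coalescent by a *frontier* of
subtree roots; branch lengths in each class are exponential, with one rate
per within-species subtree plus a speciation rate in multi mode (the
default, after the multi-rate variant of the method) or one shared
coalescent rate in single mode. Branches shorter than `min_br` = 1e-7 are
uninformative and excluded from the likelihood; as a consequence a
frontier stem must be at least `min_br` long — otherwise collapsing a
zero-length edge into a species boundary would split for free. The search
alternates an exact two-state dynamic programme over the tree (optimal
frontier at fixed rates) with closed-form rate re-estimation, from the
one-species start plus `restarts` = 10 seeded random frontiers. On
trees of ≤ 12 tips the test suite verifies the result against exhaustive
frontier enumeration. A tree in which fewer than 10% of branches are
informative returns one OTU with a warning.

**GMYC.** On an ultrametric chronogram, branching events are ordered from
the root and every inter-event interval contributes
`b·exp(−b·x)` with `b` the *total* rate: λ_div·n_div^p_div for the
diversification lineages (branches at or above the frontier, entity stems
included) plus λ_coal·Σ_k C(n_k,2)^p_coal over the coalescent entities.
Lineage counts are post-split (the backward-coalescent convention, which
also keeps every observed event's rate positive), the root event is
conditioned on, and zero-length (tied) intervals carry no exposure. Both
rates and both scaling exponents are optimised (L-BFGS-B; exponents
restricted to [0, 1]). Two formulation choices matter and were made after
explicit comparison on model-true chronograms:

- *Total-rate event factors*, not per-process ones: with typed factors the
  single-coalescent null systematically out-fits the true mixed model,
  because the null's event terms grow with the global lineage count while
  the mixed model's are bounded by entity sizes.
- *Exponents bounded to [0, 1]*: p = 1 recovers the canonical
  Yule/coalescent rates; p < 1 damps the count dependence; super-linear
  scaling is excluded because n^p with large p lets a *single* process
  reproduce the before/after rate jump that defines the mixed model,
  making the threshold unidentifiable.

Single mode scans every branching-time threshold and keeps the maximum;
the result stands only if a likelihood-ratio test against the
single-coalescent null is significant (χ², `df` = 2 by default — the df
of this test is debated, so it is a config knob; `alpha` = 0.05).
Multi mode then refines the frontier per lineage, greedily accepting
splits/merges while AIC improves, with 4 + (number of entities) counted
as parameters. Trees with fewer than 4 tips return one OTU with the test
flagged inapplicable.

## Consensus

The delimitation consensus places two records together when at least
`min_agree` = 2 of the methods do, and takes connected components of that
co-membership graph — deterministic, order-independent, and transitive by
construction (mirroring the 2-of-3 rule used on the assignment side). All
methods are weighted equally.

## Assignment

`build_assignment_reference()` draws one representative per OTU uniformly
at random (seeded) and computes per-OTU parameters **from the full
library**: θ1 = the OTU's maximum intraspecific K2P distance (singletons
fall back to the global median over multi-member OTUs, or 0.005 when none
exists — assignment must not fail on singletons) and θ2 = the OTU's NN
distance.

**FZ** selects the OTU with the nearest representative (1-NN on K2P) and
attaches a Z-shaped fuzzy membership value with a = θ1 and b = θ2 of the
selected OTU: 1 for x ≤ a, 1 − 2((x−a)/(b−a))² up to the midpoint,
2((x−b)/(b−a))² beyond it, 0 for x ≥ b; degenerate b ≤ a collapses to a
step at a. The functional form and the (θ1, θ2) sourcing are this
package's documented choice; the contract the tests pin is bounds [0, 1],
monotone non-increase, and value ½ at the midpoint. Because FZ always
selects the nearest OTU its ratio diagnostic never exceeds 1.

**FZKMER** first picks the k-mer length (1..`k_max` = 5) that maximises
leave-one-out self-assignment accuracy over the library in normalised
k-mer frequency space (Euclidean distance; smallest k on ties), then
assigns by the nearest representative in that space. Its fuzzy bounds are
quantile estimates from the library's k-mer distances: a = 95th percentile
of intra-OTU, b = 5th percentile of inter-OTU distances. The reported
distance/ratio diagnostics are K2P-based for comparability across
methods; the k-mer-space distance is reported alongside.

**BP** is a one-hidden-layer back-propagation network (logistic hidden
units, softmax output) trained by full-batch gradient descent with
momentum 0.9 on z-scored `k_feat` = 3-mer frequencies of all library
members, labelled by OTU; the winning softmax output is the probability.
Defaults: 10 hidden units, 1000 epochs, learning rate 0.01, all seeded
(training is bit-deterministic under a fixed seed). The architecture and
encoding are this package's stand-in for a neural-network assigner; the
z-scoring is required because raw k-mer frequencies (~1/64) starve the
gradients.

The consensus verdict takes the OTU selected by ≥ 2 of the 3 methods
(levels 3/3 and 2/3), else "ambiguous"; the mean probability is always
the arithmetic mean of the three. The ratio diagnostic divides the
query's distance to the selected OTU by its distance to the nearest
*other* OTU; the alternative reading (the selected OTU's own θ1/θ2) is
available via `ratio_diagnostic(mode = "otu")`.

## The two-round workflow

Round 1 delimits the reference, builds the assignment reference from the
consensus, and assigns every query. Round 2 delimits the pooled
reference + query set, diffs the pooled consensus against round 1
(maximum-overlap OTU matching, ties to the smallest OTU id; new / merged /
split bookkeeping; adjusted Rand index via mclust, verified against a
brute-force pair-count oracle), promotes one seeded-random query from
every query-only consensus OTU into the reference — singleton new OTUs
included, no size floor — rebuilds the assignment reference from the
updated partition (which automatically honours merges and splits), and
reassigns the non-promoted queries.

Classification: a query's truth is its pooled-consensus OTU mapped onto
the reference partition by maximum overlap; queries whose pooled OTU
contains no reference member can never be true positives and are counted
as false positives; ambiguous verdicts are excluded from the numerator of
`pct_correct` but kept in its denominator. Percentages are rounded to one
decimal place and `pct_consensus_total` is the **sum of the rounded**
3/3 and 2/3 components — the arithmetic a reader would do from a printed
table — so it can differ from the directly rounded total by one unit in
the last place (the stored invariant tolerates this).

Promoted representatives never appear in round-2 query tallies. The whole
run is a deterministic function of the master seed: every stochastic stage
derives its own seed from it.

## The synthetic generator

`simulate_library()` generates what the analysis assumes: a Yule species
tree rescaled so the *smallest* between-species divergence equals
`gap_factor × intra_depth`, with node ages compressed above
`max_divergence`/2 (default 0.35 pairwise — deep COI divergences are
bounded in real data by mutational saturation, and without the ceiling the
rescaling can push the deepest splits past the point where K2P distances
are even finite). Sequences evolve by the K2P substitution process itself
(κ = 2), deliberately matching the distance estimator rather than a
richer model. Within species, individuals radiate from the species
ancestor as a star (a Kingman-coalescent option exists); the true pairwise
intraspecific divergence is calibrated to 0.5 × `intra_depth` so that,
after estimator noise at 538 sites, the typical maximum *estimated* intra
distance sits near `intra_depth` and ~99% of intra pairs fall below
1.5 × `intra_depth`. Scenario knobs add cryptic pairs (two true OTUs, one
nominal label), query-only unsampled OTUs, and mislabeled records (wrong
nominal label, truth unchanged). Queries carry empty nominal labels.

What the generator does **not** emulate: rate heterogeneity across sites
and lineages (GTR+Γ-style), indels and alignment error, sequencing error,
population structure and migration, and uneven sampling per species.
Passing tests therefore demonstrate correct behaviour on gap-structured,
alignment-clean data — the regime the method's assumptions describe — not
robustness to violations of those assumptions.

## Problem sizes and numerical conventions

The default test and acceptance scale is 15 species × 5 sequences of
538 bp (plus 2 queries per species and, in workflow scenarios, 3
unsampled query OTUs), with 20 simulated libraries for delimitation
sweeps and 10 for workflow sweeps. Coordinates are 0-based half-open;
sequences are uppercased on load; ambiguity codes are retained and
handled by pairwise deletion at distance time; the stop-codon screen
translates all three forward frames under the vertebrate mitochondrial
code and passes a record whose minimum stop count is zero. Ultrametricity
is checked at 1e−9 relative tolerance (1e−6 on input chronograms, which
have been through floating-point cophenetic arithmetic). Nearest-neighbour
and OTU-matching ties always break toward the lexicographically smallest
id, making every report deterministic.
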