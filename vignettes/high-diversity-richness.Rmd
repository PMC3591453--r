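---
title: "Richness estimation in high-diversity amplicon surveys: models and methods"
author: "hidiv package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Richness estimation in high-diversity amplicon surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hidiv)
```

## The problem

Amplicon surveys of highly diverse environments (agricultural soils,
sediments, gut communities) routinely return tens of thousands of 16S rRNA
reads spread over thousands of OTUs, many observed exactly once. Richness
estimators such as Chao1 and ACE assign most of their predictive weight to
those singletons, so three questions become entangled: how many singletons
are genuine rare lineages, how many are sequencing artifacts, and what does
either answer do to the estimate? `hidiv` approaches this with planted-truth
simulation — communities whose richness and abundance structure are known
exactly — plus a filtering workflow that uses taxonomic assignment to decide
which unclassifiable reads deserve to stay in the analysis.

## The community model

A planted community is parameterized by `community_design()`:

* `n_otus` seed sequences of length `seed_length` (default 250 nt, a typical
  pyrosequencing amplicon length), generated at random and rejection-sampled
  so that all pairwise distances exceed `seed_min_separation`. The default
  separation is 0.03 — the clustering threshold itself — but fixtures that
  assert *exact* recovery use 0.06, because OTUs separated by barely more
  than `d` can legitimately merge once their members wander
  `member_distance` away from the seeds. Recovery at threshold `d` is
  guaranteed only when the separation exceeds `d + 2 * member_distance`.
* per-OTU member counts drawn as `max(1, round(exp(z)))`, `z ~ N(mu, sigma)`.
  The rounding and the floor at 1 are a deliberate, documented
  discretization: every planted OTU must exist, and rounding is unbiased to
  first order. The consequences for fitting are discussed below.
* each member beyond the first (the unmutated seed itself) is produced by
  `mutate_to_distance()`: single point-mutation events — transitions,
  transversions, insertions, deletions with default mix
  (0.35, 0.35, 0.15, 0.15) — applied one at a time, re-measuring the
  alignment distance after each, until the distance enters
  `[target - tol, target + tol]` with `tol = 0.003`. At 250 nt and a 1.25%
  target this lands members at about 3 edits from their seed, which bounds
  any intra-OTU pair by about 6 edits (2.4%) — safely inside a 3% threshold.
* `replication = 2` or `3` duplicates/triplicates every read with fresh ids
  (`.dup1`, `.dup2`), modelling communities where every genetic lineage has
  at least two or three individuals. This forces the singleton count of any
  clustering to zero, which in turn forces `Chao1 = S_obs`.

What the simulator deliberately does **not** model: position-dependent
mutation rates and base-pairing coevolution in rRNA, phylum composition,
primer/region effects, chimeras, and sequencing-error profiles. Passing
tests on these communities therefore demonstrate the behaviour of the
*analysis machinery* under known truth, not the full noise structure of
real experiments; erroneous-read behaviour is represented abstractly, by
planting well-separated singleton reads in the unclassified group.

## Distance and clustering

Dissimilarity is computed from a global end-to-end Needleman–Wunsch
alignment under unit costs (match 0, mismatch 1, indel 1) as
`(mismatches + indel columns) / alignment columns`. Two numerical choices
deserve note:

* among minimum-edit alignments the indel/column split can differ between
  tracebacks, so the traceback preference is fixed (diagonal, then
  deletion, then insertion) and the sequence pair is put into a canonical
  order before aligning — this makes the reported distance deterministic
  and exactly symmetric;
* the greedy clusterer uses a banded alignment with band
  `ceiling(2 d max_len) + 8`. A band can only over-estimate the distance,
  and any distance beyond the band exceeds `d` anyway, so accept/reject
  decisions at `d` are unaffected. The brute-force oracle always runs the
  full dynamic program.

`greedy_cluster()` dereplicates identical reads, processes unique sequences
by decreasing duplicate count (ties: decreasing length, then id), and
assigns each to the *first* centroid within `d` (first-fit; best-fit is
available behind a flag), else founds a new cluster. An 8-mer prefilter
(candidates must share at least half the query's distinct 8-mers) screens
centroids before any alignment is paid for; on planted fixtures the true
seed always survives the screen. `brute_force_cluster()` computes all
pairwise distances and takes single-linkage components of the graph with
edges at distance at most `d` (via `hclust`/`cutree`). Single linkage is
the most permissive grouping; on well-separated planted communities the
greedy and brute-force partitions coincide, and the test suite asserts
this equivalence rather than assuming it.

## Estimators, rarefaction, diagnostics

`chao1_corrected()` implements the bias-corrected form
`S_obs + F1(F1-1)/(2(F2+1))`, finite even without doubletons.
`ace()` uses the classic rare/abundant split at size 10 with its two
degenerate branches pinned down: no rare clusters returns `S_obs`, and zero
sample coverage (all rare reads singletons — exactly what an all-singleton
synthetic community produces) falls back to the corrected Chao1. Both
implementations agree with `vegan::estimateR` to machine precision in the
cross-check tests, but are computed independently of it.

`rarefaction_curve()` subsamples cluster *labels* of the one full
clustering without replacement (no re-clustering per depth, matching
standard pipeline practice) on the grid `step, 2 step, ..., N`, appending
`N` itself so the endpoint reproduces the full-data estimates exactly.
Averages use `iters` independent subsamples (default 10). The expected
observed-richness curve has a hypergeometric closed form,
`sum_j [1 - C(N - N_j, n) / C(N, n)]`, exposed as
`expected_rarefied_richness()` and used to verify unbiasedness.

`last_k_average()` and `curve_slope()` summarize the curve tail. The slope
is defined as the mean successive difference over the last `k` grid steps,
in estimator units *per step* — per-step and per-read conventions differ by
a factor of `step`, and published slope figures rarely state which is
meant, so the unit is made explicit here rather than matched to any
particular reported value.

## Fitting the abundance distribution

`fit_lognormal()` fits `Normal(mu, sigma)` to log cluster sizes. The
obvious estimator — mean and ML standard deviation of `log(size)` — is
biased on discretized abundances: for sizes generated as
`max(1, round(exp(z)))` with `mu = 1, sigma = 1.2`, the expectation of
`log(size)` is about 1.12 and its standard deviation about 1.02, errors of
many standard errors at realistic richness. The bias comes entirely from
the rounding grid and the floor at 1, so the default method models them:
size `k >= 2` is treated as the censoring interval
`[log(k - 0.5), log(k + 0.5)]` and size 1 as `(-inf, log 1.5]`, and the
interval-censored ML fit (`fitdistrplus::fitdistcens`) recovers the
generating parameters within their standard errors. The naive estimator
remains available as `method = "moments"`; it is also the cleanest way to
see the location property that duplicating a dataset shifts `mu_hat` by
exactly `log 2` while leaving `sigma_hat` untouched. All-equal sizes make
`sigma` unidentifiable and are returned flagged degenerate rather than
fitted.

## The filtering workflow

`run_pipeline()` chains: quality filter (inclusive length bounds; at most
`max_n` ambiguous bases, default 0) → exclusion-list removal (chimera
detection is consumed as an id list, not implemented) → taxonomy partition
into target / contaminant / unclassified (the table is authoritative; reads
absent from it are unclassified; the U/N ratio is reported) → clustering of
*only* the unclassified subset with removal of its singletons → pooling of
the survivors with the target group → final clustering and estimation.

The rationale for the singleton rule: at a 3% threshold a read must carry
more than `floor(length * d)` errors (6 for 200 nt, 9 for 300 nt) to escape
its cluster of origin, and identical error patterns in two reads are
vanishingly unlikely, so error-laden reads appear as singletons among the
unclassified; conversely an unclassified read that clusters with at least
one other is credible and is kept. Dropped ids are reported, never silently
discarded — they remain candidate evidence of rare novel lineages. Removing
reads that are singleton clusters lowers both `S_obs` and `F1` by one each,
so the filtered Chao1 can only move down on fixtures where the removed
reads are all singletons; the acceptance suite checks this monotonicity on
a constructed scenario.

Design choices left open by the workflow's description and decided here:
the unclassified-singleton clustering uses the same threshold `d` as the
final clustering (configurable); groups are exactly
`{target, contaminant, unclassified}` with the taxon-to-group mapping
configurable; per-dataset quality rules are configuration, not code.
`naive_classifier()` (best shared-k-mer-fraction label assignment) is a
testing stand-in for a real homology-search-plus-binning classifier and is
documented as such.

## Scenario fixtures and problem sizes

`make_scenario()` produces end-to-end fixtures whose truth reports are
*exact* by construction: unlabeled community reads are removed from the
taxonomy table only as whole OTUs with at least two members (they must
survive the singleton filter), and planted unclassified singletons are
rejection-sampled to lie farther than `d` from every other unclassified
read (they must be dropped). `estimator_behavior_suite()` sweeps
(`mu`, `sigma`, replication) grids and records full-depth estimates next
to the planted truth.

The shipped tests and the acceptance script run at deliberately moderate
scale — communities of 25–200 OTUs (up to a few hundred reads), 5000-draw
abundance samples, 400-draw Monte-Carlo rarefaction checks — chosen so the
whole suite completes in about a minute on a single core. The estimator
phenomena exercised (singleton-driven overestimation, exact estimation of
duplicated communities, location shifts under duplication) are scale-free
in these regimes, which is what makes reduced-scale verification
meaningful.

## Known limitations

* The simulator's idealizations listed above; in particular, no
  sequencing-error or chimera simulation — erroneous reads enter only as
  abstract planted singletons.
* Greedy clustering is order-dependent by nature; determinism is obtained
  by fixing the order, not by removing the dependence. Regimes where OTUs
  are separated by less than `d + 2 * member_distance` can split or merge
  legitimately, and the oracle-equivalence guarantees do not extend there.
* The averaged observed-richness rarefaction curve is non-decreasing in
  expectation, but near a plateau the Monte-Carlo noise of adjacent depths
  can exceed the expected increment; monotonicity assertions in the tests
  therefore use curves that are still rising (or exactly deterministic).
* ACE's `gamma^2` term uses the standard rare-class formula with the cutoff
  fixed at 10 by default; other conventions exist and give slightly
  different values on the same data.
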