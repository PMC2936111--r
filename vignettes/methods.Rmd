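---
title: "Methods: V6 tag community analysis with spongetag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: V6 tag community analysis with spongetag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongetag)
```

## The problem

Deep amplicon sequencing of a short hypervariable region of the 16S rRNA
gene (the ~50-60 nt V6 "tag") makes it possible to census host-associated
bacterial communities to depths where the *rare biosphere* — taxa at
relative abundances of 1e-4 and below — becomes observable. In the
host-symbiont setting this supports two questions this package is built
around:

1. **How diverse is the symbiont community?** (OTU richness via
   clustering, rarefaction, Chao1/ACE.)
2. **Where do symbionts come from?** Lineages previously reported only
   from hosts ("sponge-specific clusters") may be detected in adults and
   larvae but never in surrounding seawater — consistent with vertical
   transmission — or additionally at trace abundance in seawater,
   consistent with environmental (re)acquisition from the rare biosphere.

The pipeline stages are deliberately simple, classical procedures; the
value is in implementing them *exactly* as specified, with tests, so the
chain from raw tags to a transmission call is reproducible.

## Taxonomic assignment

Each tag is compared against every reference in an annotated 16S database
(an exhaustive in-process scan stands in for a blast search; an optional
shared-8-mer prefilter keeps the top 500 references before exact scoring,
which is a no-op for desk-scale databases and exact-tested against the
exhaustive scan). Comparison is a **semi-global alignment**: the tag must
be aligned end to end, the reference's overhangs are free (match +1,
mismatch -1, gap open -2, gap extend -1). Similarity is `1 - p` with `p`
the gap-aware mismatch fraction described below. The aligner is
score-equivalent to `Biostrings::pairwiseAlignment(type = "global-local")`
and that equivalence is asserted in the test suite.

Why semi-global and not ends-free both sides: with both ends free, a
50-60 nt tag can align a tiny exact-matching core to an *unrelated*
reference; since terminal gaps are ignored by the distance, that pair
would score as 100% similar. Requiring the tag to be fully aligned removes
the artefact while keeping reference overhangs free, which is the correct
model for a fragment-of-gene comparison.

Assignment then follows a nearest-set majority rule:

* the **nearest set** is every hit within 0.1% sequence divergence of the
  best hit;
* proceeding coarse to fine (phylum, class, order, family, genus), a label
  is adopted only if the best similarity reaches the rank threshold
  (75 / 80 / 85 / 90 / 95%), at least 60% of *all* nearest-set members
  carry the label (members unannotated at the rank count against the
  majority), and the label is consistent with the already-assigned coarser
  ranks. Assignment stops at the first failure, so label paths are always
  prefix-complete.
* sponge-specific (`SC`) and sponge-coral-specific (`SCC`) cluster labels
  use the same majority rule at a 75% similarity threshold; members
  without a cluster label count against the majority.

Design choices made where the procedure was genuinely open: thresholds are
inclusive (`>=`) although "above 95%" could be read strictly — inclusive
endpoints are conventional and the choice only affects exact-boundary
values (it is configurable); similarity for thresholding is raw identity
(the Jukes-Cantor correction is reserved for OTU distances); the 0.1%
window is applied on the raw divergence scale; ties everywhere break on
lexicographic reference id for platform independence. Tags whose best
similarity clears 75% but which fail the majority at phylum get a distinct
status (`unassigned_no_majority`) rather than being conflated with
low-similarity tags.

## Distances and OTU clustering

Tags are dereplicated (exact string identity) and the non-redundant set is
aligned — either with an externally supplied MSA or with the built-in
centre-star alignment (every unique sequence aligned semi-globally to the
highest-abundance sequence, insertions projected onto centre coordinates).
The centre-star route exists so the pipeline runs with no external binary;
for 50-60 nt fragments of a common gene region it is close to what a
general MSA tool produces, but it is a heuristic and an externally
computed alignment can always be substituted.

The pairwise distance is Jukes-Cantor,
`d = -(3/4) ln(1 - (4/3) p)`, on a gap-aware `p`:

* terminal gaps are ignored (comparison restricted to the span where both
  rows are inside their non-terminal region);
* every maximal internal gap run in one row is a single evolutionary
  event: one difference, one compared position;
* base-base columns each count one compared position; ambiguous bases are
  not compared; columns where both rows have gaps are skipped without
  interrupting a gap run (they are artefacts of the multiple alignment).

Numerical policies: `p >= 0.75` saturates the model and is capped at
`d = 5` with a warning (distant pairs never co-cluster at the cutoffs of
interest, so the cap only keeps clustering total); distances are written
at 6 decimals so files round-trip exactly.

OTUs are formed by **furthest-neighbour (complete-linkage)**
agglomeration: two clusters merge at height `h` only if *every* cross-pair
distance is at most `h`; the partition at similarity level `s` is the
state after all merges at height `<= 1 - s`. Because p-distances are small
rationals, tied merge heights are common; ties are processed in
lexicographic order of cluster labels (a cluster is labelled by its
lexicographically smallest member), making partitions platform- and
run-independent. The implementation is O(n^2) with nearest-neighbour
caching and is exact-tested against both a brute-force merge loop and
`stats::hclust(method = "complete")` on tie-free random matrices.

OTU abundances are recovered by mapping each unique sequence's per-sample
counts back onto its cluster; representatives are the highest-abundance
member (ties lexicographic). Conservation (table total = kept tags) is a
tested invariant at every level.

## Richness and diversity

* **Rarefaction** is exact:
  `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`, evaluated in log-gamma
  space so deep samples do not overflow; tested against 10,000-replicate
  Monte-Carlo subsampling and against `vegan::rarefy`.
* **Chao1** uses the classic form `S_obs + F1^2 / (2 F2)` with the
  bias-corrected form `S_obs + F1(F1-1) / (2(F2+1))` on request and as the
  automatic fallback when `F2 = 0` (the convention of the DOTUR era; the
  underlying study does not state the variant).
* **ACE** uses the standard rare/abundant split at 10 reads; if every rare
  OTU is a singleton the coverage estimate is zero and the function falls
  back to bias-corrected Chao1 with a warning. Both estimators are tested
  against `vegan::estimateR`.

## Community comparison and transmission

Per-sample taxon profiles at any rank are percentages either of all
QC-kept tags (default; labels plus the separately-reported unassigned
fraction sum to 100%) or of assigned tags only. Bray-Curtis similarity,
`S = 100 (1 - sum|x_i - y_i| / sum(x_i + y_i))`, is computed on the
percent profiles without transformation (a square-root transform is
available as a flag; the study's software default is unknown).

A cluster is *detected* in a sample group if at least `min_count` (default
1) of its tags occur in at least one sample of the group — a single tag in
a single seawater replicate therefore counts, mirroring how trace
detections in the rare biosphere are treated. Clusters detected in sponges
but never in seawater are called `sponge_exclusive` (vertical
transmission); the rest `also_in_seawater`. The summary reports the number
detected, the number also in seawater, and the percent exclusive.

## The synthetic world

`scenario_spec()` states the simulated study design once; tests and the
acceptance report use these defaults unchanged:

* 3 sponge species x 3 adult replicates, 3 larval samples (species 1),
  4 seawater replicates; 5000 tags per sample (a desk-scale stand-in for
  the tens of thousands per sample of a real pyrosequencing run — deep
  enough that a taxon at 1e-4 is detected stochastically across
  replicates, small enough that the whole pipeline runs in a few minutes
  on one CPU).
* A reference database evolved down a balanced rank tree (8 phyla, 256
  references, 128 genera). Hypervariable (V6 window) positions evolve
  faster than the backbone — per-branch substitution rates 0.16 / 0.13 /
  0.10 / 0.085 / 0.075 / 0.03 from phylum to reference, backbone at 0.3x —
  so short tags are informative at fine ranks while cross-phylum
  similarity falls below the 75% assignment floor, reproducing the
  existence of unassignable tags.
* Lognormal rank abundance (`meanlog 0, sdlog 1.5`): a few dominant taxa
  and a long rare tail, the shape deep tag surveys report. 24 genera carry
  cluster labels, 8 per sponge species; cluster-labelled genera are
  enforced to at least 0.2% relative abundance in their host (symbionts
  are enriched in hosts — this is the study's premise, and without it a
  cluster could be invisible even in its own host at desk-scale depth).
* Seawater holds 38 genera of its own plus, for a random half of each
  sponge's cluster genera, the cluster's references seeded at 1e-4 each —
  so detection across the 4 seawater replicates is stochastic and often
  confined to a single replicate. The *designed* percent-exclusive is
  therefore 50%.
* Larvae are `0.8 x adult + 0.2 x seawater`, modelling the seawater
  carried along when larvae are collected.
* Sequencing error is a flat 0.2% substitution + 0.1% indel per base
  (454-style magnitude; homopolymer-aware error is out of scope). Error
  counts per read are exact binomial draws, so the realized substitution
  fraction matches the stated rate — a tested invariant.

What a green test does **not** establish: the simulator has no chimeras,
no PCR bias, no homopolymer errors, fixed-window amplicons rather than
primer-defined ones, and a balanced reference tree far smaller than a real
curated database. Green means the *procedures* behave as specified on a
community with the stated statistical shape, not that biological findings
at full scale are reproduced.

## What the tests assert

`tests/testthat/test-acceptance.R` carries the binding checks: hand-derived
closed forms (`jukes_cantor(0.1) = 0.107326`, Chao1 14/12, ACE 6.7867,
`E[S_2] = 5/3`); equality of the clusterer with independent oracles on 200
random matrices; exact rarefaction within 3 SE of Monte-Carlo; prefilter =
exhaustive scan; the three rule-forced assignment fixtures; >= 95% genus
recovery for tags at <= 2% divergence; Chao1/ACE within [0.5, 1.5] x true
richness in >= 90% of 100 lognormal communities; end-to-end
transmission-status recovery >= 90% with percent-exclusive within 10
points of the designed 50%; and the structural invariants (monotone OTU
counts, estimators >= S_obs, Bray-Curtis symmetry, count conservation,
within-species replicate similarity above sponge-seawater similarity).

`scripts/acceptance.R` re-runs a seed-controlled subset of these from the
installed package and reports what it computed; the study's own headline
numbers rest on ~394,000 real tags and a curated reference database that
are not redistributable, so no external-data targets are defined.

## Known limitations

* The centre-star MSA degrades for sequence sets spanning very large
  divergence; distances between near-saturated pairs are capped anyway.
* Assignment cost is O(tags x references); the k-mer prefilter bounds the
  exact-scoring set at 500, but a real SILVA-scale database would need an
  indexed search front end.
* The semi-global aligner charges a tag overhang that extends past a
  reference end (it cannot open a free gap before the reference start);
  irrelevant when references contain the amplified region, as here.
* `classify_transmission` is a presence/absence rule; it inherits the
  sensitivity limits of the sequencing depth and of `min_count`.
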