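---
title: "MOTU clustering and large-scale integrative taxonomy with litmotu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MOTU clustering and large-scale integrative taxonomy with litmotu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmotu)
```

## The problem

Hyperdiverse, hyperabundant and mostly undescribed arthropod clades — "dark
taxa" — cannot be revised by sorting thousands of specimens to morphospecies
first. The reverse workflow clusters cheap COI minibarcodes into molecular
operational taxonomic units (MOTUs) first and validates cluster boundaries
afterwards by examining a small, targeted subsample of specimens. litmotu
implements the computational stages of that workflow: distance computation,
objective clustering, the stability classification and specimen-selection
rules of large-scale integrative taxonomy (LIT), morphology/barcode
congruence with conflict resolution, and a two-batch completeness
assessment. A seeded community simulator with known species truth makes
every stage testable end to end.

## Distances

All comparisons use the uncorrected p-distance: the fraction of differing
sites among the positions where both sequences carry an unambiguous base.
Gaps, `N` and IUPAC ambiguity codes are excluded pair by pair ("pairwise
deletion") rather than column-wide, which maximizes usable signal on short
(313 bp) fragments with sporadic missing data. A pair sharing fewer than
`min_overlap` comparable sites (default 100, about a third of a
minibarcode) carries no usable information: its distance is flagged invalid
and such pairs never link clusters. No model correction (K2P etc.) is
applied — threshold-based species delimitation in this literature is
calibrated on raw distances.

Distances are compared to thresholds with `<=` plus a `1e-12` tolerance, so
a pair at exactly 3.0% belongs in a "3% cluster" regardless of binary
floating-point representation.

## Objective clustering

`objective_cluster()` forms MOTUs as the connected components of the graph
linking every specimen pair at distance ≤ threshold, i.e. single-linkage
with full transitive closure: clusters may chain through intermediate
haplotypes. Single linkage was fixed deliberately: it is the behaviour of
classical threshold clustering of barcodes, and it guarantees that
partitions at increasing thresholds are *nested*, the property the
stability stage depends on. MOTU labels are canonical (each MOTU is named
after its lexicographically smallest member), so the partition is invariant
to input order. The test suite checks clustering against an independent
brute-force transitive-closure oracle on randomized small instances.

## LIT stability and the examination plan

Working at a base threshold (default 3%), each MOTU is classified:

* **singleton** — one specimen;
* **instable** — its specimen set does not appear as one whole cluster at
  every threshold of a grid (default 1–3% in 0.5% steps), or its maximum
  intra-MOTU pairwise distance exceeds 1.5%;
* **stable** — otherwise.

The grid endpoints (1% and 3%) follow the published protocol; the 0.5% step
is this package's choice and is configurable — a finer step only makes the
composition test stricter. Alongside the binary class, a stability index
(the fraction of grid thresholds at which the composition is unchanged) is
reported as a diagnostic.

The examination plan then selects specimens for morphological study:
singletons contribute their only specimen; a stable MOTU is tested with the
pair of specimens representing its two most distant haplotypes (one
specimen if it is monomorphic); an instable MOTU contributes its most
distant specimen pair plus one representative of every "main" haplotype not
already covered. "Main haplotype" is not defined quantitatively in the LIT
literature; the default here is any haplotype with at least 2 members, with
the largest haplotype always included (`main_min_count` configures this).
Haplotypes are equivalence classes of sequences identical on all mutually
compared sites; with missing data that relation is not transitive, so
groups are the connected components of the zero-distance graph, which keeps
the grouping deterministic. All ties (most-distant pairs, representatives)
break lexicographically on specimen id, so plans are byte-reproducible.

## Congruence and conflict resolution

Agreement between a MOTU partition and a morphospecies partition is
summarized by the match ratio,

$$\mathrm{match\ ratio} = \frac{2\,N_{congruent}}{N_{MOTU} + N_{morph}},$$

where $N_{congruent}$ counts clusters forming identical specimen sets in
both partitions after restriction to the shared (examined) specimens. The
statistic is symmetric and equals 1 exactly for identical partitions.

Species-level statuses follow the two LIT rules, evaluated on examined
specimens only: a morphospecies is congruent iff (i) its examined specimens
form exactly one MOTU and (ii) that MOTU contains no other morphospecies.
Violations are resolved across the threshold grid, nearest thresholds
first (minimal perturbation of the base partition): a MOTU holding several
morphospecies is split if some finer threshold separates the labels
cleanly; a morphospecies spanning several MOTUs is fused if some coarser
threshold unites its specimens without admitting another label. Resolution
is local — specimens outside the affected clusters never move. If no grid
threshold restores congruence, the case is recorded as a genuine conflict
and its specimens are left without a species assignment; unexamined
specimens inherit the species of their final cluster.

## Completeness and the randomization null

Given batch labels, `coverage_stats()` asks how completely a first specimen
batch anticipated the fauna in a second: among MOTUs of the *combined*
partition occupied by batch-2 specimens, how many also contain a batch-1
specimen (MOTU coverage), and what fraction of batch-2 specimens those
shared MOTUs hold (specimen coverage). Coverage is deliberately computed on
the combined clustering rather than per-batch clusterings, so "new" MOTUs
are exactly those absent from batch 1 under a common partition.

`randomization_test()` builds the null distribution for haphazard batch
assignment: each replicate redraws batch 1 as a uniform random subset of
the observed size and recomputes both coverages on the fixed combined
partition (batch labels do not affect distances, so re-clustering per
replicate would only waste cycles). Defaults are 100 replicates at the 5%
threshold; the summary reports means with the sample standard deviation
(n − 1). The generator state is seeded explicitly and restored afterwards,
so per-replicate vectors are exactly reproducible.

## The synthetic community generator

`simulate_community()` produces data with the structure this tooling is
meant for, with known truth:

* **Species ancestors** are independent random protein-coding sequences
  (default 313 bp) sampled codon-wise from the sense codons of the
  invertebrate mitochondrial code, so frame 0 is stop-free by construction
  and the stop-codon filter passes by design; a flag injects
  pseudogene-like stop-bearing copies to exercise the filter. Ancestors are
  redrawn until all pairs respect the minimum interspecific divergence
  (default 5%); an unreachable bound errors after bounded retries.
* **Haplotype clouds**: each haplotype differs from its species ancestor at
  no more than `floor(max_intra * L / 2)` sites, so the maximum
  intraspecific distance respects the 1% default bound. Mutations are
  substitutions only (codon-aware, never creating stops), keeping sequences
  aligned by construction.
* **Abundances** follow a ranked geometric model by default, realized by a
  deterministic largest-remainder allocation with one specimen guaranteed
  per species. The default parameter (p = 0.18 at 30 species / 300
  specimens) leaves about 20% of species as singletons, matching the rare-
  species-heavy profile of Malaise-trap communities.
* **Anomalies**: cryptic pairs are injected at an exact divergence (default
  1.5%, single haplotype per species so the realized value is exact) — they
  merge at 3% and must be recovered by splitting at a finer threshold;
  divergent conspecific lineages (default 4%) split at 3% and must be
  recovered by fusing at a coarser one.
* **Batches** are assigned by a uniform random split (default 50:50), and
  the emitted morphospecies table equals the truth, optionally with a
  configurable label-error rate.

What the simulator does *not* emulate — and hence what passing tests do not
establish about field data: realistic coalescent genealogies within
species, indels and alignment error, contamination and chimeras, uneven
geographic or habitat structure between batches, and interspecific
divergences that crowd the clustering thresholds (real barcode gaps can be
far narrower than random-sequence divergences). The package's behaviour on
such data is constrained by the rule definitions, not demonstrated by the
simulations.

## Numerical and design choices

* Threshold comparisons: `<=` with `1e-12` tolerance (see above).
* Invalid (low-overlap) pairs are treated as "no information", never as
  links and never as errors unless `strict = TRUE`.
* Stop-codon QC defaults to the invertebrate mitochondrial code with the
  "any frame" policy, because the reading frame after primer trimming is
  not guaranteed; fixed-frame policies are available and are strictly more
  stringent.
* Determinism everywhere: canonical MOTU ids, lexicographic tie-breaks,
  explicit seeds, and pipeline outputs written in sorted order, so
  re-running a configuration reproduces byte-identical files (checksummed
  in `manifest.json`).
* Metadata travels in a separate TSV keyed by specimen id rather than in
  FASTA headers, whose format is not guaranteed in deposited data.

Problem sizes: the bundled tests and the acceptance script run communities
of roughly 30–300 specimens and oracle instances of up to 12 sequences;
the distance stage itself (indicator-matrix cross-products) handles a few
thousand minibarcodes in seconds, which is the scale of a typical dark-taxon
revision (two batches of ~1500 specimens).

## A worked run

```{r example, eval = FALSE}
sim <- simulate_community(community_spec(n_species = 12, total = 100,
                                         n_cryptic_pairs = 1, seed = 42))
pd <- distance_matrix(sim$records, min_overlap = 100)
p3 <- objective_cluster(pd, 0.03)

grid <- cluster_grid(pd, c(0.01, 0.015, 0.02, 0.025, 0.03, 0.04, 0.05))
res <- resolve_conflicts(grid, sim$morph, p3)
res$log          # which MOTUs were split/fused, and at which threshold

batches <- setNames(sim$records$batch, sim$records$specimen_id)
coverage_stats(objective_cluster(pd, 0.05), batches)
```

## Known limitations

* ABGD, PTP and tree-based delimitation are not re-implemented; their
  partitions enter through `import_partition()` only.
* Alignment is out of scope: inputs must be equal-length (aligned or
  amplicon-trimmed) sequences.
* The congruence stage trusts the morphospecies table; label error is
  modelled in the simulator but not corrected for in the statistics.
* The conflict-resolution search is restricted to the supplied threshold
  grid; a congruent configuration at an intermediate, untried threshold
  would be missed.
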