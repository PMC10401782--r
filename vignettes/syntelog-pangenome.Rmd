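---
title: "Syntelog pan-genomes, haplotype divergence and introgression scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syntelog pan-genomes, haplotype divergence and introgression scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntelogr)
```

## The model

`syntelogr` builds a pan-genome whose unit is the **syntelog group (SG)**:
a cross-genome cluster of genes that occupy corresponding positions inside
collinear (syntenic) blocks. The positional constraint is what separates
orthologs from recently diverged paralogs, which pure sequence-similarity
clustering (e.g. Markov clustering of all-vs-all hits) tends to conflate;
it is also what gives every SG a coordinate on a framework genome, so that
downstream statistics become genomic *tracks*.

The pipeline is: best-hit filtering and tandem collapsing → anchor
chaining → pairwise syntelog calling → iterative merge → occupancy
classification → per-SG haplotypes → inter-population divergence →
introgression blocks. Each stage is an exported function; `run_pipeline()`
wires them together and a thin CLI (`inst/scripts/syntelogr`) exposes the
workflow as subcommands.

## Coordinates and gene order

All coordinates are internally 0-based half-open; GFF3 input (1-based,
closed) is converted on ingest and BED taken verbatim, so BED-style output
needs no shifting. Gene order ("rank") is recomputed from sorted start
coordinates per chromosome and never trusted from file order — the synteny
logic depends only on ranks, while the distance cap of the chainer operates
on base-pair midpoints. Strand is stored but not used by the chainer:
inversions are handled by searching descending chains.

## Anchor scores and the chaining DP

The chainer consumes anchors — retained best hits annotated with ranks and
midpoints — and finds highest-scoring collinear paths. Its parameters, all
exposed through `chain_params()`:

* `Z = 12` — cap on the per-anchor match score. Anchor scores are
  bitscore-derived, `score = Z * bitscore / (2 * align_len)`, so that a
  (near-)self hit saturates at `Z` (a full-length identical protein
  alignment has a bitscore of about twice its length). The cap keeps a few
  very strong anchors from overwhelming collinearity evidence. The precise
  scoring inside the original chaining tools is not published in detail;
  this scheme reproduces their documented semantics (score cap, distance
  cap, gap penalty, minimum pairs) and is fully specified here.
* `D = 200000` bp — maximum distance between consecutive chained anchors,
  measured between gene midpoints and enforced on *both* genomes.
* `g = 1` — penalty per skipped gene on either genome between consecutive
  anchors.
* `A = 5` — minimum anchors per accepted chain.

The DP is O(n²) over the anchors of one chromosome pair (compiled code);
both orientations are searched. Chains are extracted greedily by
descending score into anchor-disjoint sets; extraction stops when the best
remaining chain falls below `A` anchors. In principle a shorter
higher-scoring chain could mask a longer qualifying one at that point; in
practice accepted chains are extracted intact first, and the stopping rule
bounds the number of DP passes. Ties in the DP terminal choice resolve to
the leftmost anchor on genome A, making results deterministic.

`call_syntelogs()` enforces one-to-one pairing per genome pair: a gene
claimed by two chains follows the higher-scoring chain. One-to-one pairing
is what lets the merge treat SG membership as a partition.

## Tandem collapsing

Best-hit asymmetries between two genomes are dominated by
individual-specific tandem duplicates. `collapse_tandem()` collapses runs
of same-chromosome genes within one rank of each other that share a
best-hit subject in a partner genome, keeping the member with the highest
bitscore (ties to the smaller rank). Collapsing happens before chaining.

In the full pipeline each genome is collapsed against **every** partner
genome in turn, not just the framework: a duplicate in an SG that the
framework lacks can only be recognised against some other genome that has
the single-copy state. Iterating over partners makes the collapsed
universe consistent across all pairwise comparisons; a duplication shared
by literally every genome is left alone (it is then a family-level event,
not an individual-specific artefact).

## The iterative merge

Merging starts from the framework genome (every framework gene seeds an
SG, in coordinate order) and adds genomes one at a time. Each new gene
joins the SG it links to through pairwise syntelog pairs with
already-merged genomes. Two policies close the gaps the construction
leaves open:

* **Conflict policy.** A gene linking to several SGs joins the one with
  the most links (majority evidence); ties go to the earliest-created SG.
  SGs are never retroactively fused — the merge is strictly incremental,
  and fusing would break the one-gene-one-SG partition.
* **Per-genome uniqueness.** An SG takes at most one member per genome; a
  second candidate from the same genome falls through to its next-best SG
  or founds a new one.

On conflict-free input (every gene links to at most one SG) the resulting
partition is provably independent of merge order; this is a tested
property. SGs without a framework member are appended after the
framework-anchored SGs, ordered by their earliest member's coordinates,
and are excluded from the coordinate-based block logic.

Occupancy classes partition `1..n`: core (= n), soft-core
(`ceil(0.9 n) <= occ < n`; the ceiling reproduces the 67..73 soft-core
range at n = 74), private (= 1), dispensable (the rest).

## Haplotypes and HDG

A haplotype is a distinct member protein string — exact equality, no
similarity threshold. Exactness is the only parameter-free reading of
"compressing" within-gene coding variation, and it makes haplotype keys a
partition. Keys are numbered by descending frequency (ties by
lexicographically smaller sequence) for determinism.

Ancestral labels follow a fixed group-priority scheme: the k-th priority
group may bind the k-th label (hapI..hapV) to its dominant key, provided
the key has in-group frequency ≥ 3 and is not already bound; otherwise the
label is skipped and set as missing. Remaining present members are
compressed to hapR for display. The priority order changes only the
labels, never the divergence statistics, because HDG is computed on raw
keys: collapsing rare keys to hapR before measuring divergence would
spuriously lower it.

HDG between populations A and B is the mean cross-pair disagreement,
computed in closed form `1 − Σ_k f_A(k) f_B(k)`; the two forms are
identical and both are tested against a brute-force pair enumeration. SGs
present in fewer than 10 genomes (counted across the whole panel, not just
the two populations) get `NA`, as do SGs absent from either population.
Absent genomes never enter the pair enumeration — absence is
presence/absence variation, measured by `pav_bias()`, not divergence.

## Introgression blocks and the clustering test

Candidate blocks are maximal runs of consecutive framework SGs with
HDG < 0.5 (strict), at least 10 SGs long. `NA`-HDG SGs keep their position
in the track but cannot be low, so a single unmeasured SG breaks a run —
this avoids blocks silently spanning unmeasured regions; a `max_gap`
tolerance exists but defaults to 0. Block ids number blocks per chromosome
by descending genomic length (`"chr1#1"` …).

The clustering test asks whether low-HDG SGs cluster more than uniform
placement explains (introgression) rather than scattering (incomplete
lineage sorting). Per chromosome, the observed number of low SGs is
redrawn uniformly without replacement 100,000 times; for each sliding
window of 10 SGs (step 1), the empirical P is the fraction of draws with
an in-window count strictly higher than observed. Blocks overlapped by at
least one window with P ≤ 0.01 are reported as significant.

Two statistical notes, both verified by exact computation in the tests:

* The strict "higher than observed" rule is **anti-conservative** under
  sparse nulls: a window sitting exactly on the discrete rejection
  boundary is still called significant, so the null fraction of windows
  with P < 0.05 equals `P(X ≥ t)` with
  `t = min{v : P(X > v) < 0.05}` for the hypergeometric window count X —
  always ≥ 0.05 and typically 0.07–0.12 depending on panel shape. The rule
  is kept because it is the reference behaviour; `cluster_test(inclusive =
  TRUE)` switches to the tie-counting `P(X ≥ obs)` rule, which guarantees
  `P(p < α) ≤ α`, and `pseudocount = TRUE` applies the `(r+1)/(n+1)`
  small-sample correction.
* The permutation machinery itself is unbiased: on instances small enough
  to enumerate (`C(n,k) ≤ 10,000`), empirical P values agree with the
  exact enumeration at the binomial convergence rate.

## The synthetic panel generator

`simulate_panel()` emulates the statistical structure of a large
multi-genome panel; it is the test bed for every stage, with full ground
truth. Defaults, chosen once:

* **Occupancy mixture** 7.9 % core / 8.2 % soft-core / 35.6 % dispensable
  / 48.3 % private — the class proportions of a published 74-genome SG
  pan-genome.
* **Haplotype structure**: each population has its own dominant allele at
  frequency 0.9, the remaining mass spread over the other alleles;
  expected background HDG between two populations is 0.82, matching the
  "high divergence" regime (HDG > 0.8) that dominates real
  inter-subspecies comparisons. Alleles are the ancestral random protein
  (lengths 100–500 aa) with allele-specific substitutions, so allele
  identity is exact string identity. A per-lineage substitution rate
  (default 0.001/site) adds rare private haplotypes; substitutions are
  uniform over a 20-letter alphabet with no indels, the simplest model
  that exercises the exact-identity rule.
* **Planted introgression**: inside configured SG ranges, every population
  draws from the donor population's allele frequencies, forcing expected
  HDG to `1 − Σ f_d² = 0.18` < 0.2.
* **Layout**: genes are non-overlapping with geometric intergenic spacing
  (mean 5 kb), so the 200 kb chaining cap is exercisable; tandem
  duplicates are inserted per present gene copy with probability 0.02.
* Fabricated hit tables give every true homolog pair a bitscore
  decreasing in the number of substitutions between the proteins, with
  optional false-positive, false-negative and paralog noise.

What the generator does *not* emulate: rearrangements and translocations
(gene order is shared across genomes), indels, codon-level evolution and
selection, assembly or annotation error. Passing tests therefore show the
*method* is implemented correctly and recovers planted structure under
clean conditions; they do not certify performance on real assemblies with
annotation noise and structural variation.

## Problem sizes used in validation

The bundled validation runs at desk scale, chosen so each property is
measured with useful precision: the planted-introgression benchmark uses
two populations × 15 genomes, 2,000 SGs on one chromosome and three
planted blocks of 31–100 SGs under a core-heavy mixture (0.9/0.1) so the
presence filter leaves no `NA` gaps inside planted runs; merge-order
invariance uses 10 genomes × 500 SGs over 20 random orders; the chaining
DP is checked against exhaustive subsequence enumeration on 200 instances
of ≤ 10 anchors; the null calibration uses 100 chromosomes of 60 SGs with
12 low SGs at 10,000 replicates. Headline published quantities (e.g.
175,528 SGs from 74 rice genomes, 73 introgression blocks totalling
23.38 Mbp, mean HDG 0.667) derive from full-scale assemblies and are not
reproducible at this scale; the package validates the machinery, not those
numbers.

## Known limitations

* The merge never fuses SGs, so early spurious splits (e.g. from missed
  pairwise links) persist; with noisy hits the SG count is biased slightly
  upward rather than downward.
* Framework-absent SGs carry no coordinates and are invisible to block
  detection, mirroring the reference-anchored design of the original
  analysis.
* The chain extractor's stopping rule is greedy (see above).
* Haplotype identity at the protein level ignores synonymous and
  non-coding variation entirely.
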