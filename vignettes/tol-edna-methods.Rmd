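---
title: "Methods: multi-assay eDNA metabarcoding with toledna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-assay eDNA metabarcoding with toledna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toledna)
```

## The problem

A single "universal" PCR assay cannot audit the biodiversity of a seawater
sample: every primer set amplifies some lineages well and misses others, and
reference databases resolve some groups to species while leaving others at
family or above. `toledna` implements the analysis side of a *tree-of-life*
(ToL) metabarcoding survey, in which many fusion-tag PCR assays are run on
the same environmental DNA extracts and their detections are aggregated into
one multi-rank picture of the community. It also implements the step beyond
taxon lists: screening the reads assigned to a single target genus down to
reproducible haplotypes and arranging them in a minimum spanning network.

The package is organised as a pipeline of small, composable functions, and
ships a synthetic-data generator so that the full pipeline — demultiplexing
through haplotype networks — runs, and is tested, entirely offline.

## Demultiplexing and quality control

Fusion-tag libraries carry the sequencer adaptor, a sample/assay index and
the template-specific primer on every read, so demultiplexing is a pure
string problem. `demultiplex()` assigns a read if and only if its 5' end is
an **exact** match to the `adaptor + index + fwd_primer` of exactly one assay;
one mismatch anywhere in the construct rejects the read. Exactness is
deliberate: fusion-tag designs put the index inside the primer construct, so
tolerating mismatches there invites index hopping between samples. The
reverse primer is trimmed only when present as an exact match at the 3' end;
unidirectionally sequenced reads without it are tolerated.

`quality_filter()` removes reads whose mean Phred score is **less than or
equal to** 25 (the boundary is inclusive on removal) and reads containing any
base outside A/C/G/T. After per-library dereplication, unique sequences seen
only once in their library are removed (`remove_singletons()`); duplicate PCR
products of the same water sample are then combined by summing counts
(`combine_pcr_replicates()`).

The order of operations is a design decision: filters are applied per
replicate library *before* replicates are combined, so a sequencing artefact
must survive in a single library on its own to be counted, and singleton
status is judged at the library level where the error process operates. A
chimera-removal hook (`remove_chimeras()`) preserves the position where an
external chimera detector would run; it is a no-op here.

## LCA assignment and the conservative species rule

Each unique sequence is searched against a reference barcode collection and
the resulting hit table is reduced in two steps (`filter_hits()`): hits with
score below `min_score = 100` are dropped, and among the survivors with best
score `B`, hits scoring at least `B * (1 - top_percent/100)` (default
`top_percent = 10`) are retained. Both boundaries are inclusive — a hit at
exactly the minimum score, or exactly at the window floor, is kept — matching
the usual semantics of LCA classifiers. `assign_lca()` then assigns the
lowest taxonomy node ancestral to every retained subject; conflicting hits
collapse the assignment to genus, family or higher. The operation is
set-based, so tied best scores need no tie-break and hit order is
irrelevant.

Species-rank assignments then face a conservative three-clause rule
(`apply_species_rule()`), kept at species only if:

1. some retained hit to that species has 100% identity;
2. at least one *congener* (another species of the same genus) is present in
   the reference collection for comparison, and no retained hit shows that
   congener at 100% identity; and
3. the species is on an explicit regional checklist.

Otherwise the call is demoted to its genus. The rule can only lower
resolution, never raise it. Clause 2 is operationalised against the local
reference database — a congener record exists and is not identical to the
query — because what it guards against is a genus with a single referenced
species, where a 100% match is uninformative about congeneric alternatives.
Clause 3 takes a checklist file rather than querying a biodiversity service:
range checks in practice are curated lookups, and an explicit file keeps the
analysis reproducible.

Negative controls are handled per assay (`subtract_controls()`): a taxon
detected in an assay's control is removed from every sample under that assay,
but remains reportable under other assays, whose reagents and amplicons are
independent.

## Aggregation across assays

`build_detection_matrix()` sums read counts per (assay, taxon at its achieved
rank); the detection threshold defaults to 1 read and is configurable, since
silently requiring more reads is a filtering decision the analyst should own.
`rank_counts()` counts, for each rank, the distinct ancestors at that rank of
each assay's detections, plus a combined row over the union of assays. A
taxon resolved only to family contributes to family and above — deeper ranks
are left blank, not imputed. `multiple_hits()` counts rank-level taxa seen
under at least two assays, the natural cross-validation of a multi-assay
design.

Rarefaction is analytic (`analytic_rarefaction()`): the expected richness in
a uniform subsample of size $n$ from per-taxon counts $N_i$ (total $N$) is

$$E[S_n] = \sum_i \left(1 - \binom{N - N_i}{n} \middle/ \binom{N}{n}\right),$$

computed with log-gamma binomials so totals of $10^6$ reads do not overflow.
`rarefy_matrix()` performs the corresponding empirical normalisation —
seeded, without replacement (multivariate hypergeometric) — and the two agree
in expectation, which the tests verify. Differences in per-sample richness
between assays are tested with the standard tie-corrected Kruskal–Wallis rank
test (`rank_test()`, delegating to `stats::kruskal.test`).

## Haplotypes within a target genus

Error variants generated during PCR and sequencing outnumber true haplotypes
in any amplicon library, so the haplotype workflow first *measures* the error
process. Single-source libraries (one specimen each) are sequenced under the
same protocol; in each library the dominant unique sequence is taken as the
true haplotype and the most abundant *other* sequence, as a percentage of the
dominant's count, is that library's error rate (`estimate_error_rate()`).
The summary is the mean ± sample (n−1) standard deviation across libraries;
a library with a single unique sequence contributes 0. The estimate is
scale-invariant in library depth.

eDNA sequences assigned to the target genus are then filtered
(`filter_haplotypes()`): within each water sample a candidate passes when its
count is **strictly greater than** `error_threshold` percent of the count of
that sample's most abundant candidate (the threshold is an error ceiling —
equal-to-error is indistinguishable from noise — and the per-sample dominant
passes by definition); a candidate is retained when it passes in at least
`min_samples = 2` of the water samples. "Replicated across multiple
libraries" is read as at least two of the nine samples and is configurable.

Note a structural property of this filter: when the threshold is the *mean*
of per-library maximum artefact frequencies, roughly half of the libraries
have artefacts above it, so occasional error variants can pass in individual
samples; the replication rule is what makes passing twice unlikely. The
parameter-recovery tests therefore state their guarantee under an error rate
low enough that the largest artefact stays below threshold in every sample.

For the network, the aligned haplotypes (optionally including flagged
reference barcodes) are compared by Hamming distance after gap recoding.
`recode_gaps()` collapses each maximal run of gap-containing columns to a
single column in which an all-gap stretch becomes one symbol and each
distinct insertion its own symbol, so one contiguous indel event costs
exactly one mutational step; collapsing the run (rather than recoding each
column) is a design choice — the per-column alternative would charge a
k-base indel k steps — and can be disabled by recoding manually.
`build_network()` builds a minimum spanning network: weights are processed in
ascending order and at each weight *all* edges joining currently distinct
components are added before any merging, so tied alternative paths are kept;
the edge set always contains a minimum spanning tree. OTU clustering at a
98% identity threshold (`cluster_otus()`) is greedy centroid clustering in
decreasing-abundance order with lexicographic tie-breaks, making the result
independent of input order.

## The synthetic-data generator

`gen_taxonomy()` builds a rooted seven-rank taxonomy with a configurable
fan-out and, per species and marker, one reference barcode. Barcodes derive
from per-family ancestor sequences, mutated per genus and per species with
disjoint mutation-site blocks where the barcode length allows (random sites
with rejection otherwise). Defaults give congeneric species a distance of 8
bases on a 151-base barcode and genera within a family a distance of 20.
The floor of 7+ differences between any two references is load-bearing: with
a perfect-match score of `2 * 151 = 302` and a 10% score window, a reference
within 6 mismatches (score ≥ 272) of a query's true barcode would enter the
retained hit set and collapse every assignment to genus, so clean
species-level geometry requires congeners at least 7 apart. The
`congener_coverage` parameter controls the fraction of genera holding a
second referenced species, which is the lever the species rule's clause 2
responds to.

`gen_community_reads()` emits, per sample and assay,
`depth_per_sample` fusion-tag reads drawn multinomially from the community
profile, with i.i.d. per-base substitutions on the template at `error_rate`
and a truth table recording every read's source and substitution count. The
study design it emulates is nine 1 L water samples; the default read depth
(about 10^3 per sample and assay) keeps tests fast while leaving dominant
taxa hundreds of reads deep. Qualities are Phred 40 throughout except for a
configurable fraction of reads emitted at Phred 20 to exercise the mean-Q
filter; the error model is substitution-only — indel haplotypes for the gap
recoding are injected explicitly as alternative templates where needed. The
per-read error process of a real instrument is not asserted: `error_rate` is
a free parameter, and the calibration workflow estimates its observable
consequence rather than assuming a canonical value.

`gen_hit_table()` is the alignment oracle: every query is compared to every
same-marker reference, with `pct_identity = 100 * matches / length` and a
proxy score `2 * matches − 3 * mismatches` (monotone in identity, and placing
the default `min_score = 100` at roughly 50 matched bases); hits under 70%
identity are suppressed, as a real search would not report them.

What the generator does **not** emulate bounds what green tests show about
real data: no chimeras, no primer-bias or GC amplification curves, no
cycle-dependent quality profiles, no length variation within a marker, and
substitutions only. Passing the parameter-recovery and end-to-end tests
demonstrates the *logic* of the pipeline — filters, LCA geometry,
aggregation arithmetic, network construction — not robustness to every
artefact of a sequencing run.

## Numerical choices and degenerate inputs

* Rarefaction uses `lchoose` differences; impossible subsamples
  (`n > N − N_i`) contribute probability 0 via `exp(-Inf)`.
* `rarefy_matrix()` draws sequential conditional hypergeometrics, avoiding
  materialising read-level vectors at large depths; assays shallower than
  the target depth are dropped with a message.
* Dereplication orders by decreasing count then sequence, so all downstream
  greedy steps are deterministic.
* Empty inputs: an empty candidate set filters to an empty set (not an
  error); a network on fewer than two haplotypes is returned as a single
  node with a message; an empty retained-hit set yields `basis =
  "unassigned"`.
* All generators take an integer seed and restore the caller's RNG state;
  identical seeds replay byte-identically.

## Problem sizes

The test-suite and validation battery run on: a 96-species / 3-phylum
taxonomy (fan-out 2 at every rank); communities of 12–20 species over 9
samples at 300–1500 reads per sample and assay; 13 single-source calibration
libraries at depth 5000 and per-base error 0.005; planted-haplotype recovery
with K ∈ {1, 3, 5} haplotypes over 20 seeds at depth 1200 and error 0.001;
Monte-Carlo rarefaction with 10^5 replicates; and exhaustive network oracles
on up to 6 nodes. These sizes were chosen so every distributional check has
comfortable statistical margin while the whole battery completes in a few
minutes on one core.

## Known limitations

* The species rule's range check is only as good as the supplied checklist.
* The error-threshold filter assumes the calibration libraries and the
  survey share an error process; a threshold calibrated on a different
  marker or chemistry transfers poorly.
* The MSN is one network convention; median-joining or TCS networks are out
  of scope, as is alignment construction (input haplotypes are pre-aligned).
* Negative-control subtraction removes exact taxon nodes; a contaminant
  detected at genus level in the control does not remove its species-level
  detections in samples.
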