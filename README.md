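# toledna

Multi-assay ("tree of life") environmental DNA metabarcoding analysis in R.

A single "universal" PCR assay sees only a slice of the biodiversity in a
seawater sample. Tree-of-life metabarcoding runs many fusion-tag PCR assays —
universal and taxon-specific — on the same eDNA extracts and aggregates their
detections into one multi-rank inventory, and can go further than taxon
lists: down to reproducible within-genus haplotypes. `toledna` implements
that analysis end to end for people doing marine (or any) eDNA biomonitoring:

* **Demultiplexing & QC** — exact-match assignment of fusion-tag reads
  (`adaptor + index + fwd_primer`, 100% identity required), removal of reads
  with mean Phred ≤ 25 or ambiguous bases, per-library dereplication and
  singleton removal, combining of duplicate PCR replicates.
* **Taxonomic assignment** — score-filtered lowest-common-ancestor (LCA)
  classification of alignment hit tables (Min Score 100, Top Percent 10), a
  conservative species rule (species calls need a 100% identity hit, a
  referenced congener for comparison, and presence on a regional checklist —
  otherwise they are demoted to genus), and per-assay negative-control
  subtraction.
* **Biodiversity aggregation** — assay × taxon detection matrices, per-rank
  taxon counts with a combined row, taxa detected by more than one assay,
  analytic (hypergeometric) rarefaction
  `E[S_n] = Σ_i (1 − C(N−N_i, n)/C(N, n))`, seeded rarefying of detections to
  a common depth, and the tie-corrected Kruskal–Wallis test between assays.
* **Haplotype diversity** — amplicon error-rate calibration from
  single-source libraries (the most abundant erroneous sequence as a
  percentage of the dominant haplotype, averaged across libraries),
  per-sample frequency filtering against that threshold plus a
  replicate-presence rule, greedy 98% OTU clustering, gap recoding that makes
  one indel event one mutational step, and minimum spanning haplotype
  networks (all tied component-joining edges kept).
* **Synthetic data** — seeded generators for multi-rank taxonomies, reference
  barcodes with controlled distance geometry, assay panels, truth-annotated
  community and single-source read sets, and oracle hit tables, so the whole
  pipeline runs and is tested with no external downloads.

## Worked example

Simulate a 9-sample community survey against a 96-species reference
taxonomy, run QC, assign taxa, and summarise:

```r
library(toledna)

tx <- gen_taxonomy(3, c(2, 2), congener_coverage = 1, seed = 7)
species <- tx$tree$node_id[tx$tree$rank == "species"]
set.seed(7)
members <- data.frame(taxon_id = sample(species, 6), abundance = 0.6^(0:5))
panel <- make_assay_panel("16S", seed = 7)
sim <- gen_community_reads(
  community_spec(members, n_samples = 9, depth_per_sample = 500,
                 error_rate = 0.002, seed = 7), panel, tx$refdb)

qc <- qc_pipeline(sim$reads, panel)
qc$report
#>                 step reads
#> 1              input  4500
#> 2           assigned  4500
#> 3     rejected_demux     0
#> 4      removed_low_q     0
#> 5  removed_ambiguous     0
#> 6 removed_singletons  1034
#> 7     retained_reads  3466

uniq <- unique(qc$derep$sequence)
names(uniq) <- sprintf("u%d", seq_along(uniq))
retained <- filter_hits(gen_hit_table(uniq, tx$refdb, "16S"), lca_params())
asn <- apply_species_rule(assign_lca(retained, tx$tree), retained,
                          tx$refdb, checklist = species, tx$tree)
table(asn$basis)
#> species_rule_demoted    species_rule_pass
#>                   29                   54
```

All six community species pass the species rule (54 unique sequences map to
them at 100% identity with congeners available for comparison); the 29
demoted sequences are error variants lacking a perfect hit — exactly the
conservative behaviour the rule is designed for. Joining counts and building
the detection matrix:

```r
asn <- merge(asn, data.frame(query_id = names(uniq), sequence = unname(uniq)),
             by = "query_id")
asn <- merge(asn, qc$derep, by = "sequence")
m <- build_detection_matrix(asn)
rc <- rank_counts(m, tx$tree)
rc[rc$assay == "combined", ]
#>       assay    rank n_taxa
#> 7  combined  phylum      3
#> 8  combined   class      5
#> 9  combined   order      6
#> 10 combined  family      6
#> 11 combined   genus      6
#> 12 combined species      6
```

The community's six species span three phyla; the per-rank counts read
exactly like a survey summary table (a taxon resolved only to genus would
count at genus and above, leaving species blank).

## The analysis workflow

Numbered drivers under `analysis/` run a full simulated survey and write
tables under `results/` (large intermediates go to `scratch/`):

```sh
Rscript analysis/01_simulate_community.R   # taxonomy, panel, reads, controls
Rscript analysis/02_qc_demultiplex.R       # QC report, dereplicated sets
Rscript analysis/03_taxonomic_assignment.R # LCA + species rule + controls
Rscript analysis/04_biodiversity_summaries.R # rank counts, rarefaction, KW test
Rscript analysis/05_haplotype_network.R    # error rate, haplotypes, network
```

Step 5, for example, calibrates an amplicon error rate from 13 single-source
libraries (`0.46% ± 0.03` at a per-base error of 0.005), filters the target
genus' sequences against it, and writes the haplotype network as an edge
list and as NEXUS with a per-sample traits block.

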