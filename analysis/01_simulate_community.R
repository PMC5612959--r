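#!/usr/bin/env Rscript
# Step 1: simulate the study system.
#
# A 96-species, three-phylum taxonomy with full congener coverage and one
# reference barcode per species for three markers; a three-assay fusion-tag
# panel; nine 1 L water samples amplified in duplicate (two PCR replicates per
# sample per assay) at moderate per-base error, with a small fraction of
# low-quality reads; one negative-control library carrying a contaminant; and
# thirteen single-source calibration libraries for the error-rate estimate.
#
# Large intermediates go to scratch/ (regenerated on demand); small summary
# tables go to results/.

suppressPackageStartupMessages(library(toledna))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

SEED <- 20170925L

tx <- gen_taxonomy(3, c(2, 2), congener_coverage = 1,
                   markers = c("16S", "18S", "COI"), seed = SEED)
species <- tx$tree$node_id[tx$tree$rank == "species"]
message("taxonomy: ", nrow(tx$tree), " nodes, ", length(species),
        " species, ", nrow(tx$refdb), " reference barcodes")

panel <- make_assay_panel(c("16S", "18S", "COI"), seed = SEED)

# community: 20 species, geometric-ish rank-abundance profile
set.seed(SEED)
members <- data.frame(taxon_id = sample(species, 20),
                      abundance = 0.7^(0:19))

simulate_replicate <- function(tag, seed) {
  sim <- gen_community_reads(
    community_spec(members, n_samples = 9, depth_per_sample = 1500,
                   error_rate = 0.004, low_q_frac = 0.02, seed = seed),
    panel, tx$refdb)
  sim$reads$sample_id <- paste0(sim$reads$sample_id, tag)
  sim$truth$sample_id <- paste0(sim$truth$sample_id, tag)
  sim
}
rep_a <- simulate_replicate("a", SEED + 1)
rep_b <- simulate_replicate("b", SEED + 2)

# negative control: one contaminant taxon amplified in every assay
contaminant <- setdiff(species, members$taxon_id)[1]
ctrl <- gen_community_reads(
  community_spec(data.frame(taxon_id = contaminant, abundance = 1),
                 n_samples = 1, depth_per_sample = 200, error_rate = 0,
                 seed = SEED + 3), panel, tx$refdb)
ctrl$reads$sample_id <- "CTRL"
ctrl$truth$sample_id <- "CTRL"
message("negative control carries contaminant ", contaminant)

reads <- rbind(rep_a$reads, rep_b$reads, ctrl$reads)
truth <- rbind(rep_a$truth, rep_b$truth, ctrl$truth)
message("simulated ", nrow(reads), " reads over ",
        length(unique(reads$sample_id)), " libraries x ", nrow(panel),
        " assays")

# single-source calibration libraries: 13 species from 12 families
fam <- setNames(tx$tree$parent_id, tx$tree$node_id)
families <- unname(fam[unname(fam[species])])
pick_fams <- sample(unique(families), 12)
sp13 <- c(vapply(pick_fams, function(f) species[families == f][1],
                 character(1)),
          species[families == pick_fams[1]][2])
calib <- gen_single_source_reads(tx$refdb, sp13, "16S", depth = 5000,
                                 error_rate = 0.005, seed = SEED + 4)
message("calibration: ", length(sp13), " single-source libraries at depth 5000")

write_taxonomy(tx$tree, "results/taxonomy.tsv")
write_refdb_fasta(tx$refdb, "results/reference_barcodes.fasta")
write.table(panel, "results/assay_panel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(members, "results/community_members.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(tx = tx, panel = panel, members = members, reads = reads,
             truth = truth, calib = calib, sp13 = sp13,
             contaminant = contaminant, seed = SEED),
        "scratch/01_simulation.rds")
message("wrote scratch/01_simulation.rds and results/ summaries")
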