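# Readers and writers for the package's on-disk formats: FASTQ (Phred+33),
# reference FASTA with "taxon_id|marker" headers, taxonomy / truth / hit-table
# TSVs, dereplicated FASTA with ";size=" annotations, and network exports
# (edge-list TSV and NEXUS with a traits block).

write_tsv_ <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_ <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Data frame with `read_id`, `sequence`, `quality`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  # the constructor warns about dropping (empty) metadata columns; benign
  suppressWarnings({
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(reads$sequence,
                                               reads$read_id)),
      Biostrings::PhredQuality(reads$quality))
    Biostrings::writeQualityScaledXStringSet(x, path)
  })
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @param sample_id Sample label attached to every read.
#' @return Reads data frame: `read_id`, `sample_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  # benign constructor warning about empty metadata columns
  suppressWarnings(x <- Biostrings::readQualityScaledDNAStringSet(path))
  out <- data.frame(read_id = names(x), sample_id = sample_id,
                    sequence = as.character(x),
                    quality = as.character(Biostrings::quality(x)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a reference barcode database as FASTA
#'
#' Headers are `taxon_id|marker`.
#'
#' @param db Reference database data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_refdb_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(
    db$sequence, paste(db$taxon_id, db$marker, sep = "|")))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference barcode database from FASTA
#'
#' @param path FASTA file with `taxon_id|marker` headers.
#' @return Reference database data frame.
#' @export
read_refdb_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  out <- data.frame(taxon_id = vapply(parts, `[`, character(1), 1L),
                    marker = vapply(parts, `[`, character(1), 2L),
                    sequence = unname(as.character(x)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a dereplicated set as annotated FASTA
#'
#' One record per unique sequence with `;size=count` header annotations, per
#' (sample, assay).
#'
#' @param derep Dereplicated set.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_derep_fasta <- function(derep, path) {
  hdr <- sprintf("%s_%s_u%d;size=%d", derep$sample_id, derep$assay,
                 seq_len(nrow(derep)), derep$count)
  x <- Biostrings::DNAStringSet(stats::setNames(derep$sequence, hdr))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read a taxonomy table as TSV
#'
#' Columns `node_id`, `parent_id`, `rank`, `name`; the root has
#' `parent_id == node_id`.
#'
#' @param tree Taxonomy data frame.
#' @param path File path.
#' @return The path (writer) or the taxonomy (reader).
#' @export
write_taxonomy <- function(tree, path) {
  write_tsv_(tree[, c("node_id", "parent_id", "rank", "name")], path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  validate_taxonomy(read_tsv_(path))
}

#' Write / read a hit table as TSV
#'
#' Columns `query_id`, `subject_taxon_id`, `pct_identity`, `score` -- a
#' declared subset of BLAST tabular (outfmt 6) dialect.
#'
#' @param hits Hit table data frame.
#' @param path File path.
#' @return The path (writer) or the hit table (reader).
#' @export
write_hit_table <- function(hits, path) {
  write_tsv_(hits[, c("query_id", "subject_taxon_id", "pct_identity",
                      "score")], path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  read_tsv_(path)
}

#' Write a haplotype network as an edge-list TSV
#'
#' @param net A `haplotype_network`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_network_edges <- function(net, path) {
  write_tsv_(net$edges, path)
}

#' Write a haplotype network as NEXUS with a traits block
#'
#' Emits a TAXA block, a CHARACTERS block holding the aligned haplotypes and,
#' when per-sample counts are available, a TRAITS block with one trait per
#' sample -- the layout popular haplotype-network viewers consume.
#'
#' @param net A `haplotype_network`.
#' @param alignment Named character vector of the aligned haplotypes.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_nexus_network <- function(net, alignment, path) {
  taxa <- net$nodes$haplotype
  lines <- c("#NEXUS", "",
             "BEGIN TAXA;",
             sprintf("DIMENSIONS NTAX=%d;", length(taxa)),
             "TAXLABELS",
             paste0(taxa, collapse = " "),
             ";", "END;", "",
             "BEGIN CHARACTERS;",
             sprintf("DIMENSIONS NCHAR=%d;", unique(nchar(alignment))[1L]),
             "FORMAT DATATYPE=DNA MISSING=? GAP=-;",
             "MATRIX")
  lines <- c(lines, sprintf("%s %s", taxa, unname(alignment[taxa])),
             ";", "END;")
  sc <- net$sample_counts
  if (!is.null(sc) && nrow(sc)) {
    samples <- sort(unique(sc$sample_id))
    lines <- c(lines, "",
               "BEGIN TRAITS;",
               sprintf("Dimensions NTRAITS=%d;", length(samples)),
               "Format labels=yes missing=? separator=Comma;",
               sprintf("TraitLabels %s;", paste(samples, collapse = " ")),
               "Matrix")
    for (h in taxa) {
      cnt <- vapply(samples, function(s) {
        v <- sc$count[sc$haplotype == h & sc$sample_id == s]
        if (length(v)) sum(v) else 0L
      }, integer(1))
      lines <- c(lines, sprintf("%s %s", h, paste(cnt, collapse = ",")))
    }
    lines <- c(lines, ";", "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read the bundled per-phylum rank-count transcription
#'
#' Loads the package's transcription of the published per-phylum biodiversity
#' table (eukaryotic taxa per rank within each phylum) from `inst/extdata`.
#' Blank cells (ranks with nothing resolved that deep) are `NA`.
#'
#' @return Data frame: `kingdom`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @export
read_phylum_table <- function() {
  path <- system.file("extdata", "table1_eukaryote_ranks.tsv",
                      package = "toledna", mustWork = TRUE)
  read_tsv_(path)
}
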