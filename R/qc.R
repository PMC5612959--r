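# Demultiplexing and quality control of fusion-tag amplicon reads.
# Pipeline order: demultiplex -> mean-Q filter -> ambiguous-base filter ->
# dereplicate -> singleton removal -> PCR-replicate combining. Singleton
# removal is per (sample, assay) and happens before replicates are combined,
# mirroring per-sample processing of raw libraries.

#' Quality-control parameters
#'
#' @param max_mean_q_removed Reads with mean Phred score less than or equal to
#'   this threshold are removed (default 25; the boundary is inclusive on
#'   removal, so a read at exactly 25.0 is dropped).
#' @param drop_ambiguous Remove reads containing ambiguous bases (anything
#'   outside A/C/G/T).
#' @param drop_singletons Remove unique sequences seen only once within a
#'   (sample, assay) after dereplication.
#' @return A `qc_params` list.
#' @export
qc_params <- function(max_mean_q_removed = 25, drop_ambiguous = TRUE,
                      drop_singletons = TRUE) {
  stopifnot(max_mean_q_removed >= 0)
  structure(list(max_mean_q_removed = max_mean_q_removed,
                 drop_ambiguous = isTRUE(drop_ambiguous),
                 drop_singletons = isTRUE(drop_singletons)),
            class = "qc_params")
}

mean_phred <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Demultiplex fusion-tag reads by exact prefix match
#'
#' A read is assigned if and only if its 5' end equals the concatenated
#' `adaptor + index + fwd_primer` of exactly one assay (100% match; one
#' mismatch anywhere in the construct rejects the read). Assigned reads are
#' trimmed to the template: the fusion prefix is removed, and the reverse
#' primer is removed when present as an exact match at the 3' end
#' (unidirectionally sequenced reads without it are tolerated).
#'
#' @param reads Data frame with columns `read_id`, `sample_id`, `sequence`,
#'   `quality`.
#' @param panel Assay panel (see [make_assay_panel()]); prefixes must be
#'   unique.
#' @return List with `assigned` (reads plus an `assay` column, trimmed to the
#'   template) and `rejected` (count of unassigned reads).
#' @export
demultiplex <- function(reads, panel) {
  validate_panel(panel)
  stopifnot(all(c("read_id", "sample_id", "sequence", "quality") %in%
                  names(reads)))
  prefixes <- paste0(panel$adaptor, panel$index, panel$fwd_primer)
  match_mat <- vapply(prefixes, function(p) startsWith(reads$sequence, p),
                      logical(nrow(reads)))
  match_mat <- matrix(match_mat, nrow = nrow(reads))
  n_match <- rowSums(match_mat)
  take <- n_match == 1L
  assigned <- reads[take, , drop = FALSE]
  which_assay <- apply(match_mat[take, , drop = FALSE], 1L, which.max)
  if (nrow(assigned)) {
    assigned$assay <- panel$name[which_assay]
    pre_len <- nchar(prefixes)[which_assay]
    assigned$sequence <- substring(assigned$sequence, pre_len + 1L)
    assigned$quality <- substring(assigned$quality, pre_len + 1L)
    rev_p <- panel$rev_primer[which_assay]
    has_rev <- nzchar(rev_p) &
      substring(assigned$sequence,
                nchar(assigned$sequence) - nchar(rev_p) + 1L) == rev_p
    keep_len <- ifelse(has_rev, nchar(assigned$sequence) - nchar(rev_p),
                       nchar(assigned$sequence))
    assigned$sequence <- substring(assigned$sequence, 1L, keep_len)
    assigned$quality <- substring(assigned$quality, 1L, keep_len)
  } else {
    assigned$assay <- character(0)
  }
  rownames(assigned) <- NULL
  list(assigned = assigned, rejected = sum(!take))
}

#' Filter reads on mean quality and ambiguous bases
#'
#' Removes reads whose mean Phred score is less than or equal to
#' `max_mean_q_removed` and (when `drop_ambiguous`) reads containing any base
#' outside A/C/G/T. Singleton removal is a separate, post-dereplication step
#' (see [remove_singletons()]). The filter is idempotent and its output is
#' always a subset of its input.
#'
#' @param reads Demultiplexed reads data frame.
#' @param params A [qc_params()] object.
#' @return The retained reads, with attributes `removed_low_q` and
#'   `removed_ambiguous` holding the per-rule removal counts.
#' @export
quality_filter <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"),
            all(nchar(reads$sequence) == nchar(reads$quality)))
  low <- mean_phred(reads$quality) <= params$max_mean_q_removed
  ambig <- if (params$drop_ambiguous) {
    grepl("[^ACGT]", reads$sequence)
  } else {
    rep(FALSE, nrow(reads))
  }
  out <- reads[!low & !ambig, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_low_q") <- sum(low)
  attr(out, "removed_ambiguous") <- sum(ambig & !low)
  out
}

#' Dereplicate reads within each (sample, assay)
#'
#' @param reads Demultiplexed (and typically quality-filtered) reads.
#' @return Data frame with columns `sample_id`, `assay`, `sequence`, `count`,
#'   one row per unique sequence per (sample, assay), ordered by decreasing
#'   count then sequence.
#' @export
dereplicate <- function(reads) {
  stopifnot(all(c("sample_id", "assay", "sequence") %in% names(reads)))
  if (!nrow(reads)) {
    return(data.frame(sample_id = character(0), assay = character(0),
                      sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(reads))),
    by = list(sample_id = reads$sample_id, assay = reads$assay,
              sequence = reads$sequence),
    FUN = sum)
  agg <- agg[order(agg$sample_id, agg$assay, -agg$count, agg$sequence), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Remove singleton sequences from a dereplicated set
#'
#' A unique sequence observed only once within its (sample, assay) is removed.
#'
#' @param derep Dereplicated set from [dereplicate()].
#' @param min_count Minimum retained count (default 2).
#' @return The filtered dereplicated set.
#' @export
remove_singletons <- function(derep, min_count = 2L) {
  out <- derep[derep$count >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine PCR replicates into per-sample dereplicated sets
#'
#' Duplicate PCR products amplified from the same water sample are combined by
#' summing the counts of each unique sequence across the sample's replicates.
#'
#' @param derep Dereplicated set whose `sample_id` column holds replicate ids.
#' @param replicate_map Named character vector mapping replicate id to sample
#'   id; must cover every replicate present.
#' @return Dereplicated set keyed by sample id.
#' @export
combine_pcr_replicates <- function(derep, replicate_map) {
  reps <- unique(derep$sample_id)
  unknown <- setdiff(reps, names(replicate_map))
  if (length(unknown)) {
    stop("configuration error: replicate(s) not in replicate_map: ",
         paste(unknown, collapse = ", "))
  }
  if (!nrow(derep)) return(derep)
  derep$sample_id <- unname(replicate_map[derep$sample_id])
  agg <- stats::aggregate(list(count = derep$count),
                          by = list(sample_id = derep$sample_id,
                                    assay = derep$assay,
                                    sequence = derep$sequence),
                          FUN = sum)
  agg <- agg[order(agg$sample_id, agg$assay, -agg$count, agg$sequence), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Chimera-removal hook
#'
#' Placeholder preserving the pipeline position of chimera detection; returns
#' its input unchanged.
#'
#' @param derep Dereplicated set.
#' @return `derep`, unchanged.
#' @export
remove_chimeras <- function(derep) {
  derep
}

#' Run the full QC pipeline
#'
#' [demultiplex()] then [quality_filter()], [dereplicate()],
#' [remove_singletons()] (per replicate) and, when `replicate_map` is given,
#' [combine_pcr_replicates()].
#'
#' @param reads Raw reads data frame.
#' @param panel Assay panel.
#' @param params [qc_params()].
#' @param replicate_map Optional replicate-to-sample map.
#' @return List with `derep` (final dereplicated set) and `report` (data frame
#'   of per-step read counts).
#' @export
qc_pipeline <- function(reads, panel, params = qc_params(),
                        replicate_map = NULL) {
  dm <- demultiplex(reads, panel)
  filt <- quality_filter(dm$assigned, params)
  derep <- dereplicate(filt)
  pre_singleton_reads <- sum(derep$count)
  if (params$drop_singletons) derep <- remove_singletons(derep)
  derep <- remove_chimeras(derep)
  if (!is.null(replicate_map)) {
    derep <- combine_pcr_replicates(derep, replicate_map)
  }
  report <- data.frame(
    step = c("input", "assigned", "rejected_demux", "removed_low_q",
             "removed_ambiguous", "removed_singletons", "retained_reads"),
    reads = c(nrow(reads), nrow(dm$assigned), dm$rejected,
              attr(filt, "removed_low_q"), attr(filt, "removed_ambiguous"),
              pre_singleton_reads - sum(derep$count), sum(derep$count)),
    stringsAsFactors = FALSE)
  list(derep = derep, report = report)
}
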