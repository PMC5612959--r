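# Score-filtered lowest-common-ancestor taxonomic assignment, the
# conservative species rule, and negative-control subtraction.

#' LCA filtering parameters
#'
#' @param min_score Hits scoring below this are dropped (inclusive at the
#'   boundary: a hit at exactly `min_score` is retained). Default 100.
#' @param top_percent Among surviving hits with best score B, hits scoring at
#'   least `B * (1 - top_percent / 100)` are retained (inclusive). Default 10.
#' @return An `lca_params` list.
#' @export
lca_params <- function(min_score = 100, top_percent = 10) {
  stopifnot(min_score >= 0, top_percent >= 0, top_percent <= 100)
  structure(list(min_score = min_score, top_percent = top_percent),
            class = "lca_params")
}

#' Filter alignment hits by score and top-percent window
#'
#' Applied independently per query: hits with `score < min_score` are dropped;
#' among the survivors with best score B, hits with
#' `score >= B * (1 - top_percent / 100)` are retained.
#'
#' @param hits Hit table (`query_id`, `subject_taxon_id`, `pct_identity`,
#'   `score`).
#' @param params [lca_params()].
#' @return The retained hits.
#' @export
filter_hits <- function(hits, params = lca_params()) {
  stopifnot(inherits(params, "lca_params"))
  hits <- hits[hits$score >= params$min_score, , drop = FALSE]
  if (!nrow(hits)) {
    rownames(hits) <- NULL
    return(hits)
  }
  best <- tapply(hits$score, hits$query_id, max)
  thr <- best[hits$query_id] * (1 - params$top_percent / 100)
  out <- hits[hits$score >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# LCA of a set of node ids: deepest node ancestral-or-self to all of them.
lca_node <- function(tree, node_ids) {
  node_ids <- unique(node_ids)
  paths <- lapply(node_ids, function(id) lineage(tree, id))
  common <- Reduce(intersect, paths)
  if (!length(common)) stop("taxonomy error: no common ancestor")
  common[length(common)]  # lineages are root-down, so last common = deepest
}

#' Assign dereplicated sequences to taxa by lowest common ancestor
#'
#' For each query, the assigned taxon is the lowest taxonomy node that is an
#' ancestor-or-self of every retained hit's subject. Queries present in
#' `query_ids` but with no retained hits are reported as unassigned.
#'
#' @param retained Retained hits (after [filter_hits()]).
#' @param tree Taxonomy data frame.
#' @param query_ids Optional character vector of all queries that were
#'   searched; defaults to the queries present in `retained`.
#' @return Assignment data frame: `query_id`, `taxon_id`, `rank`, `basis`
#'   (`"lca"` or `"unassigned"`; `taxon_id` is `NA` iff unassigned).
#' @export
assign_lca <- function(retained, tree, query_ids = NULL) {
  if (is.null(query_ids)) query_ids <- unique(retained$query_id)
  missing <- setdiff(retained$subject_taxon_id, tree$node_id)
  if (length(missing)) {
    stop("taxonomy error: subject taxa not in tree: ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(query_id = query_ids, taxon_id = NA_character_,
                    rank = NA_character_, basis = "unassigned",
                    stringsAsFactors = FALSE)
  if (nrow(retained)) {
    by_q <- split(retained$subject_taxon_id, retained$query_id)
    for (q in names(by_q)) {
      i <- match(q, out$query_id)
      if (is.na(i)) next
      node <- lca_node(tree, by_q[[q]])
      out$taxon_id[i] <- node
      out$rank[i] <- taxon_rank(tree, node)
      out$basis[i] <- "lca"
    }
  }
  out
}

#' Apply the conservative species-assignment rule
#'
#' A species-rank assignment is kept at species level only if all three
#' clauses hold: (i) some retained hit to that species has 100% identity;
#' (ii) the reference database holds at least one congener (another species of
#' the same genus) for comparison, and no retained hit shows that congener at
#' 100% identity; and (iii) the species appears in the regional checklist.
#' Otherwise the assignment is demoted to its genus
#' (`basis = "species_rule_demoted"`). Assignments above species rank pass
#' through unchanged; resolution is never raised.
#'
#' @param assignments Output of [assign_lca()].
#' @param hits The retained hits the assignments were derived from.
#' @param db Reference barcode database.
#' @param checklist Character vector of species node ids known from the
#'   region.
#' @param tree Taxonomy data frame.
#' @param marker Optional marker name restricting which reference records
#'   count as congeners; by default, any marker counts.
#' @return The revised assignments (`basis` becomes `"species_rule_pass"` or
#'   `"species_rule_demoted"` for species-rank inputs).
#' @export
apply_species_rule <- function(assignments, hits, db, checklist, tree,
                               marker = NULL) {
  ref <- if (is.null(marker)) db else db[db$marker == marker, , drop = FALSE]
  parent <- stats::setNames(tree$parent_id, tree$node_id)
  sp_rows <- which(assignments$rank == "species" & !is.na(assignments$rank))
  for (i in sp_rows) {
    sp <- assignments$taxon_id[i]
    q <- assignments$query_id[i]
    qhits <- hits[hits$query_id == q, , drop = FALSE]
    genus <- parent[[sp]]
    congeners <- unique(ref$taxon_id[ref$taxon_id != sp])
    congeners <- congeners[congeners %in% tree$node_id &
                             vapply(congeners,
                                    function(x) parent[[x]] == genus,
                                    logical(1))]
    exact_self <- any(qhits$subject_taxon_id == sp & qhits$pct_identity == 100)
    congener_ok <- length(congeners) > 0 &&
      !any(qhits$subject_taxon_id %in% congeners & qhits$pct_identity == 100)
    in_checklist <- sp %in% checklist
    if (exact_self && congener_ok && in_checklist) {
      assignments$basis[i] <- "species_rule_pass"
    } else {
      assignments$taxon_id[i] <- genus
      assignments$rank[i] <- "genus"
      assignments$basis[i] <- "species_rule_demoted"
    }
  }
  assignments
}

#' Subtract taxa detected in negative controls
#'
#' Any taxon (exact node) detected in a control sample is removed from every
#' sample's assignments for that assay. Subtraction is scoped per assay
#' (controls are run per assay; a taxon flagged in assay A's control stays
#' reportable under assay B). Control-sample rows are dropped from the output.
#'
#' @param assignments Data frame with at least `sample_id`, `assay`,
#'   `taxon_id` columns.
#' @param control_samples Character vector of control sample ids.
#' @return The filtered assignments.
#' @export
subtract_controls <- function(assignments, control_samples) {
  if (!length(control_samples)) return(assignments)
  ctrl <- assignments[assignments$sample_id %in% control_samples, ,
                      drop = FALSE]
  out <- assignments[!assignments$sample_id %in% control_samples, ,
                     drop = FALSE]
  if (nrow(ctrl)) {
    bad <- unique(paste(ctrl$assay, ctrl$taxon_id, sep = "\r"))
    out <- out[!(paste(out$assay, out$taxon_id, sep = "\r") %in% bad), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
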