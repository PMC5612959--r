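# Multi-assay detection matrix and biodiversity summaries: per-rank taxon
# counts, multiple-assay hits, analytic rarefaction, depth normalisation and
# the between-assay rank test.

#' Build the assay-by-taxon detection matrix
#'
#' Read counts are summed per (assay, taxon); each taxon is recorded at its
#' achieved rank node. A taxon is "detected" when its count reaches
#' `min_reads_detect` (default 1; taxa below the threshold stay in the counts
#' but are excluded by [detections()]).
#'
#' @param assignments Assignment data frame with `assay`, `taxon_id`, `rank`
#'   and `count` columns (unassigned rows are ignored).
#' @param min_reads_detect Detection threshold in reads.
#' @return Data frame (`assay`, `taxon_id`, `rank`, `count`) with attribute
#'   `min_reads_detect`.
#' @export
build_detection_matrix <- function(assignments, min_reads_detect = 1L) {
  a <- assignments[!is.na(assignments$taxon_id), , drop = FALSE]
  if (!("count" %in% names(a))) a$count <- 1L
  if (!nrow(a)) {
    out <- data.frame(assay = character(0), taxon_id = character(0),
                      rank = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- stats::aggregate(list(count = a$count),
                            by = list(assay = a$assay, taxon_id = a$taxon_id,
                                      rank = a$rank),
                            FUN = sum)
    out <- out[order(out$assay, -out$count, out$taxon_id), ,
               drop = FALSE]
    out <- out[, c("assay", "taxon_id", "rank", "count")]
    rownames(out) <- NULL
  }
  attr(out, "min_reads_detect") <- min_reads_detect
  out
}

#' Detected entries of a detection matrix
#'
#' @param m Detection matrix from [build_detection_matrix()].
#' @return Rows whose count reaches the matrix's detection threshold.
#' @export
detections <- function(m) {
  thr <- attr(m, "min_reads_detect")
  if (is.null(thr)) thr <- 1L
  out <- m[m$count >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Distinct rank-r ancestors of the detected taxa of one assay. A taxon
# contributes to rank r only when its achieved rank is at least as deep as r
# (taxa resolved above r are excluded, not imputed).
rank_nodes <- function(taxa, tree, rank) {
  anc <- vapply(taxa, function(t) ancestor_at_rank(tree, t, rank),
                character(1))
  unique(anc[!is.na(anc)])
}

#' Per-rank taxon counts per assay, with a combined row
#'
#' For each assay and each rank, counts the distinct ancestors at that rank of
#' the assay's detected taxa (taxa resolved only to a shallower rank do not
#' contribute). The `combined` row counts distinct ancestors over the union of
#' all assays' detections.
#'
#' @param m Detection matrix.
#' @param tree Taxonomy data frame.
#' @param ranks Ranks to tabulate (default all of [TAX_RANKS] below kingdom).
#' @return Long data frame: `assay` (including `"combined"`), `rank`,
#'   `n_taxa`.
#' @export
rank_counts <- function(m, tree, ranks = TAX_RANKS[-1]) {
  det <- detections(m)
  assays <- unique(det$assay)
  sets <- c(stats::setNames(
    lapply(assays, function(a) unique(det$taxon_id[det$assay == a])), assays),
    list(combined = unique(det$taxon_id)))
  out <- do.call(rbind, lapply(names(sets), function(a) {
    data.frame(assay = a, rank = ranks,
               n_taxa = vapply(ranks, function(r) {
                 length(rank_nodes(sets[[a]], tree, r))
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Taxa detected by more than one assay, per rank
#'
#' A rank-r node counts when it is among the rank-r ancestors of the detected
#' taxa of at least two distinct assays (same per-rank semantics as
#' [rank_counts()]).
#'
#' @param m Detection matrix covering at least two assays.
#' @param tree Taxonomy data frame.
#' @param ranks Ranks to tabulate.
#' @return Data frame: `rank`, `n_taxa`.
#' @export
multiple_hits <- function(m, tree, ranks = TAX_RANKS[-1]) {
  det <- detections(m)
  assays <- unique(det$assay)
  if (length(assays) < 2L) {
    stop("multiple_hits needs a detection matrix with >= 2 assays")
  }
  out <- data.frame(rank = ranks, n_taxa = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ranks)) {
    per_assay <- lapply(assays, function(a) {
      rank_nodes(unique(det$taxon_id[det$assay == a]), tree, ranks[i])
    })
    nodes <- unlist(per_assay)
    out$n_taxa[i] <- sum(table(nodes) >= 2L)
  }
  out
}

#' Analytic (hypergeometric) rarefaction
#'
#' Expected number of taxa observed in a uniform random subsample of `n` reads
#' drawn without replacement from a community with per-taxon read counts
#' `counts` (total N): `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`,
#' computed with log-gamma binomials so large N does not overflow.
#'
#' @param counts Non-negative per-taxon read counts.
#' @param n Subsample size, `0 <= n <= sum(counts)`.
#' @return Expected taxon richness at depth `n`.
#' @export
analytic_rarefaction <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (n < 0 || n > N) stop("subsample size must be in [0, total reads]")
  if (n == 0) return(0)
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

# Multivariate hypergeometric draw: subsample `n` reads without replacement
# from per-taxon counts, by sequential conditional rhyper draws.
rmvhyper <- function(counts, n) {
  k <- length(counts)
  out <- integer(k)
  remaining <- sum(counts)
  for (i in seq_len(k)) {
    if (n == 0L) break
    if (i == k) {
      out[i] <- n
      break
    }
    x <- stats::rhyper(1L, counts[i], remaining - counts[i], n)
    out[i] <- x
    n <- n - x
    remaining <- remaining - counts[i]
  }
  out
}

#' Rarefy a detection matrix to a common depth
#'
#' Per assay, reads are subsampled without replacement (multivariate
#' hypergeometric) to `depth` and detections recomputed. Assays whose total
#' count is below `depth` are dropped with a message.
#'
#' @param m Detection matrix.
#' @param depth Target read depth per assay.
#' @param seed Integer seed.
#' @return A rarefied detection matrix (same threshold attribute).
#' @export
rarefy_matrix <- function(m, depth, seed = 1L) {
  thr <- attr(m, "min_reads_detect")
  with_seed(seed, {
    keep <- vector("list", 0L)
    for (a in unique(m$assay)) {
      sub <- m[m$assay == a, , drop = FALSE]
      total <- sum(sub$count)
      if (total < depth) {
        message("dropping assay ", a, ": total count ", total, " < depth ",
                depth)
        next
      }
      sub$count <- rmvhyper(sub$count, as.integer(depth))
      keep[[length(keep) + 1L]] <- sub[sub$count > 0L, , drop = FALSE]
    }
    out <- if (length(keep)) do.call(rbind, keep) else m[0L, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "min_reads_detect") <- thr
    out
  })
}

#' Kruskal-Wallis rank test across assays
#'
#' Standard Kruskal-Wallis H with tie correction and a chi-squared p-value on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups List of numeric vectors (one per assay), each non-empty.
#' @return List with `H`, `df` and `p_value`.
#' @export
rank_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("rank_test needs >= 2 groups")
  }
  if (any(!vapply(groups, length, integer(1)))) {
    stop("rank_test groups must be non-empty")
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Column totals of a per-phylum rank-count table
#'
#' Takes a table shaped like the per-phylum biodiversity summary (one row per
#' phylum; numeric columns `class`, `order`, `family`, `genus`, `species`
#' with `NA` for blank cells) and returns the totals row: the number of
#' phylum rows plus each column's sum.
#'
#' @param tbl Per-phylum rank-count data frame.
#' @return Named numeric vector: `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @export
rank_table_totals <- function(tbl) {
  cols <- c("class", "order", "family", "genus", "species")
  stopifnot(all(cols %in% names(tbl)))
  c(phylum = nrow(tbl),
    vapply(cols, function(cl) sum(tbl[[cl]], na.rm = TRUE), numeric(1)))
}

#' Per-phylum rank-count summary of a detection matrix
#'
#' The package's analogue of a per-phylum biodiversity table: one row per
#' detected phylum with the number of distinct classes, orders, families,
#' genera and species detected within it (blank where nothing resolved that
#' deep).
#'
#' @param m Detection matrix.
#' @param tree Taxonomy data frame.
#' @return Data frame: `kingdom`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @export
phylum_rank_table <- function(m, tree) {
  det <- detections(m)
  taxa <- unique(det$taxon_id)
  phyla <- vapply(taxa, function(t) ancestor_at_rank(tree, t, "phylum"),
                  character(1))
  rows <- lapply(unique(phyla[!is.na(phyla)]), function(p) {
    in_p <- taxa[!is.na(phyla) & phyla == p]
    counts <- vapply(TAX_RANKS[-(1:2)], function(r) {
      n <- length(rank_nodes(in_p, tree, r))
      if (n == 0L) NA_real_ else n
    }, numeric(1))
    king <- ancestor_at_rank(tree, p, "kingdom")
    data.frame(kingdom = king, phylum = p, t(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Share of combined taxa recovered by one assay
#'
#' @param n_taxa Taxa detected by the assay.
#' @param n_combined Taxa detected across all assays combined.
#' @return Percentage, `100 * n_taxa / n_combined`.
#' @export
assay_share <- function(n_taxa, n_combined) {
  stopifnot(n_combined > 0)
  100 * n_taxa / n_combined
}

#' Shotgun assignment composition arithmetic
#'
#' Converts the assignment-fraction bookkeeping of an environmental shotgun
#' library into overall fractions of the sequenced reads: a domain assigned
#' `pct_of_assigned`% of assignments, with `pct_assigned`% of all reads
#' assigned, holds `pct_assigned * pct_of_assigned / 100`% of all reads.
#'
#' @param pct_assigned Percentage of all reads assigned to any taxon.
#' @param domain_pcts Named numeric vector: percentage of assignments per
#'   domain.
#' @return Data frame: `domain`, `pct_of_assigned`, `pct_of_total`.
#' @export
shotgun_composition <- function(pct_assigned, domain_pcts) {
  stopifnot(pct_assigned >= 0, pct_assigned <= 100, all(domain_pcts >= 0))
  data.frame(domain = names(domain_pcts),
             pct_of_assigned = unname(domain_pcts),
             pct_of_total = unname(pct_assigned * domain_pcts / 100),
             stringsAsFactors = FALSE)
}
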