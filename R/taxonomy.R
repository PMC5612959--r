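#' Taxonomic ranks used throughout the package
#'
#' Ordered from shallowest to deepest. Every taxonomy handled by the package is
#' a rooted tree whose ranks strictly deepen along any root-to-leaf path.
#'
#' @format Character vector of length 7.
#' @export
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family",
               "genus", "species")

rank_depth <- function(rank) {
  match(rank, TAX_RANKS)
}

#' Validate a taxonomy table
#'
#' A taxonomy is a data frame with columns `node_id`, `parent_id`, `rank` and
#' `name`. The root points to itself (`parent_id == node_id`). Checks: unique
#' ids, a single root, known ranks, every parent chain reaches the root, and
#' rank strictly deepening from parent to child.
#'
#' @param tree Taxonomy data frame.
#' @return The taxonomy, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_taxonomy <- function(tree) {
  stopifnot(is.data.frame(tree),
            all(c("node_id", "parent_id", "rank", "name") %in% names(tree)))
  if (anyDuplicated(tree$node_id)) {
    stop("taxonomy node_ids must be unique")
  }
  if (!all(tree$rank %in% TAX_RANKS)) {
    stop("unknown rank(s): ",
         paste(setdiff(tree$rank, TAX_RANKS), collapse = ", "))
  }
  root <- tree$node_id[tree$parent_id == tree$node_id]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (parent_id == node_id)")
  }
  parent <- stats::setNames(tree$parent_id, tree$node_id)
  if (!all(tree$parent_id %in% tree$node_id)) {
    stop("parent_id values missing from node_id")
  }
  depth <- rank_depth(stats::setNames(tree$rank, tree$node_id))
  names(depth) <- tree$node_id
  nonroot <- tree$node_id != root
  if (any(depth[tree$node_id[nonroot]] <=
          depth[tree$parent_id[nonroot]])) {
    stop("rank must strictly deepen from parent to child")
  }
  # every chain reaches the root: walk with a step bound
  for (id in tree$node_id) {
    cur <- id
    for (i in seq_len(length(TAX_RANKS) + 1L)) {
      if (cur == root) break
      cur <- parent[[cur]]
    }
    if (cur != root) stop("parent chain of ", id, " does not reach the root")
  }
  invisible(tree)
}

#' Root-to-node lineage of a taxonomy node
#'
#' @param tree Taxonomy data frame.
#' @param node_id A node id present in `tree`.
#' @return Character vector of node ids from the root down to `node_id`
#'   (inclusive).
#' @export
lineage <- function(tree, node_id) {
  parent <- stats::setNames(tree$parent_id, tree$node_id)
  if (!node_id %in% names(parent)) {
    stop("node not in taxonomy: ", node_id)
  }
  path <- character(0)
  cur <- node_id
  repeat {
    path <- c(cur, path)
    nxt <- parent[[cur]]
    if (nxt == cur) break
    cur <- nxt
  }
  path
}

#' Rank of a taxonomy node
#'
#' @param tree Taxonomy data frame.
#' @param node_id Node id(s).
#' @return Character vector of ranks.
#' @export
taxon_rank <- function(tree, node_id) {
  r <- stats::setNames(tree$rank, tree$node_id)
  unname(r[node_id])
}

#' Ancestor of a node at a given rank
#'
#' Returns the ancestor-or-self of `node_id` at rank `rank`, or `NA` when the
#' node's own rank is shallower than `rank` (a taxon resolved only to family
#' has no genus ancestor).
#'
#' @param tree Taxonomy data frame.
#' @param node_id Node id.
#' @param rank Target rank, one of [TAX_RANKS].
#' @return Node id of the ancestor, or `NA_character_`.
#' @export
ancestor_at_rank <- function(tree, node_id, rank) {
  stopifnot(rank %in% TAX_RANKS)
  path <- lineage(tree, node_id)
  ranks <- taxon_rank(tree, path)
  hit <- path[ranks == rank]
  if (length(hit)) hit else NA_character_
}
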