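# Shared fixtures and independent oracles, built in code at test time.

# A small hand-built taxonomy: two phyla; family f1 holds two genera, one of
# them (g1) with two species.
toy_tree <- function() {
  data.frame(
    node_id = c("k1", "p1", "p2", "c1", "c2", "o1", "o2", "f1", "f2",
                "g1", "g2", "g3", "s1", "s2", "s3", "s4"),
    parent_id = c("k1", "k1", "k1", "p1", "p2", "c1", "c2", "o1", "o2",
                  "f1", "f1", "f2", "g1", "g1", "g2", "g3"),
    rank = c("kingdom", "phylum", "phylum", "class", "class", "order",
             "order", "family", "family", "genus", "genus", "genus",
             "species", "species", "species", "species"),
    name = c("k1", "p1", "p2", "c1", "c2", "o1", "o2", "f1", "f2",
             "g1", "g2", "g3", "s1", "s2", "s3", "s4"),
    stringsAsFactors = FALSE)
}

# Brute-force LCA oracle: intersect full ancestor sets and take the node of
# maximum rank depth (independent of lineage() ordering assumptions).
oracle_lca <- function(tree, node_ids) {
  parent <- setNames(tree$parent_id, tree$node_id)
  depth <- setNames(match(tree$rank, TAX_RANKS), tree$node_id)
  ancestors <- function(id) {
    out <- id
    while (parent[[id]] != id) {
      id <- parent[[id]]
      out <- c(out, id)
    }
    out
  }
  common <- Reduce(intersect, lapply(unique(node_ids), ancestors))
  common[which.max(depth[common])]
}

# Hand-written tie-corrected Kruskal-Wallis H (closed form), used as the
# independent cross-check for rank_test().
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Hamming distance without touching package internals.
oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Build a reads data frame from bare sequences (uniform quality).
reads_df <- function(sequences, sample_id = "S1", q = "I") {
  data.frame(read_id = sprintf("r%d", seq_along(sequences)),
             sample_id = rep(sample_id, length(sequences)),
             sequence = sequences,
             quality = strrep(q, nchar(sequences)),
             stringsAsFactors = FALSE)
}

# A one-assay panel with short, fixed tags (easy to reason about in tests).
fixed_panel <- function() {
  data.frame(name = c("A", "B"),
             adaptor = c("AATT", "AATT"),
             index = c("CCGG", "GGCC"),
             fwd_primer = c("ACGTAC", "TGCATG"),
             rev_primer = c("TTTAAA", "GGGCCC"),
             marker = c("16S", "18S"),
             stringsAsFactors = FALSE)
}

# Exhaustive MSN oracle: an edge belongs to the minimum spanning network iff
# its endpoints are disconnected in the graph restricted to strictly smaller
# weights (checked by BFS over an adjacency list).
oracle_msn_edges <- function(d) {
  n <- nrow(d)
  connected_below <- function(u, v, w) {
    adj <- function(x) which(d[x, ] < w & d[x, ] > 0 & seq_len(n) != x)
    seen <- rep(FALSE, n)
    queue <- u
    seen[u] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (nb in adj(cur)) {
        if (!seen[nb]) {
          if (nb == v) return(TRUE)
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    seen[v]
  }
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > 0 && !connected_below(i, j, d[i, j])) {
        out <- rbind(out, c(i, j, d[i, j]))
      }
    }
  }
  out
}
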