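rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

test_that("greedy OTU clustering applies the identity threshold", {
  set.seed(5)
  base <- rand_seq(1, 100)
  near <- mutate_at(base, 10, if (substr(base, 10, 10) == "A") "C" else "A")
  cl <- cluster_otus(c(base, near), c(10L, 5L), threshold = 0.98)
  expect_equal(length(unique(cl$otu)), 1L)     # 99% identity joins

  far <- base
  for (p in c(10, 20, 30)) {
    far <- mutate_at(far, p, if (substr(far, p, p) == "A") "C" else "A")
  }
  cl2 <- cluster_otus(c(base, far), c(10L, 5L), threshold = 0.98)
  expect_equal(length(unique(cl2$otu)), 2L)    # 97% founds a new OTU

  # deterministic under input order (counts fixed)
  seqs <- c(base, near, far)
  counts <- c(10L, 5L, 3L)
  perm <- c(3L, 1L, 2L)
  a <- cluster_otus(seqs, counts)
  b <- cluster_otus(seqs[perm], counts[perm])
  expect_equal(length(unique(a$otu)), length(unique(b$otu)))
  expect_equal(sort(unique(a$centroid)), sort(unique(b$centroid)))
})

test_that("the error-rate estimator follows its definition", {
  lib <- data.frame(species = "sp", sequence = c("AAA", "AAT", "ATT"),
                    count = c(980L, 15L, 5L), stringsAsFactors = FALSE)
  e <- estimate_error_rate(lib)
  expect_equal(e$per_species$rate_pct, 100 * 15 / 980, tolerance = 1e-12)

  # a library with one unique sequence contributes rate 0
  one <- data.frame(species = "solo", sequence = "CCC", count = 500L)
  expect_equal(estimate_error_rate(one)$per_species$rate_pct, 0)

  # mean and sample sd across species: rates {1, 3} -> 2 +/- sqrt(2)
  two <- data.frame(species = c("a", "a", "b", "b"),
                    sequence = c("AAA", "AAT", "CCC", "CCT"),
                    count = c(100L, 1L, 100L, 3L))
  e2 <- estimate_error_rate(two)
  expect_equal(e2$mean, 2)
  expect_equal(e2$sd, sqrt(2), tolerance = 1e-12)

  # scale invariance: multiplying a library's counts leaves its rate alone
  scaled <- lib
  scaled$count <- scaled$count * 17L
  expect_equal(estimate_error_rate(scaled)$per_species$rate_pct,
               e$per_species$rate_pct)

  expect_error(estimate_error_rate(lib[0, ]), "empty")
})

test_that("haplotype filtering enforces frequency and replication rules", {
  p <- network_params(error_threshold = 1.79, min_samples = 2)

  # 20/1000 = 2.0% > 1.79% in two samples: retained
  cand <- data.frame(sequence = rep(c("AA", "AT"), each = 2),
                     sample_id = rep(c("S1", "S2"), 2),
                     count = c(1000L, 900L, 20L, 18L))
  f <- filter_haplotypes(cand, p)
  expect_setequal(f$retained, c("AA", "AT"))

  # 1.5% everywhere: removed; the per-sample dominant passes by definition
  low <- cand
  low$count <- c(1000L, 900L, 15L, 13L)
  f2 <- filter_haplotypes(low, p)
  expect_equal(f2$retained, "AA")

  # strong in a single sample only: removed by the replication rule
  once <- data.frame(sequence = c("AA", "AT"), sample_id = "S1",
                     count = c(1000L, 25L))
  f3 <- filter_haplotypes(once, p)
  expect_equal(f3$retained, character(0))
  expect_true(f3$table$passed_frequency[f3$table$sequence == "AT"])
  expect_false(f3$table$passed_replication[f3$table$sequence == "AT"])

  # the frequency comparison is strict: exactly at threshold is noise
  border <- data.frame(sequence = rep(c("AA", "AT"), each = 2),
                       sample_id = rep(c("S1", "S2"), 2),
                       count = c(1000L, 1000L, 17L, 17L))
  expect_equal(filter_haplotypes(border,
                                 network_params(1.7, 2))$retained, "AA")

  # empty candidate set is not an error
  f4 <- filter_haplotypes(cand[0, ], p)
  expect_equal(f4$retained, character(0))

  # monotone in the threshold: raising it never adds haplotypes
  set.seed(13)
  cand2 <- data.frame(sequence = rep(rand_seq(6, 8), each = 3),
                      sample_id = rep(c("S1", "S2", "S3"), 6),
                      count = sample(1:500, 18, replace = TRUE))
  prev <- NULL
  for (thr in c(0.5, 2, 5, 20, 60)) {
    cur <- filter_haplotypes(cand2, network_params(thr, 2))$retained
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("gap recoding makes one indel event one step", {
  # single-column gap
  r1 <- recode_gaps(c(a = "ACG-T", b = "ACGAT"))
  expect_equal(oracle_hamming(r1[["a"]], r1[["b"]]), 1)

  # a two-column gap run collapses to one informative column
  r2 <- recode_gaps(c(a = "A--T", b = "AGGT"))
  expect_equal(nchar(r2[["a"]]), 3L)
  expect_equal(oracle_hamming(r2[["a"]], r2[["b"]]), 1)

  # distinct insertions in the same run stay distinguishable
  r3 <- recode_gaps(c(a = "A--T", b = "AGGT", c = "AGCT"))
  expect_equal(oracle_hamming(r3[["b"]], r3[["c"]]), 1)
  expect_equal(oracle_hamming(r3[["a"]], r3[["b"]]), 1)

  # gap-free alignments are untouched
  aln <- c(a = "ACGT", b = "AGGT")
  expect_identical(recode_gaps(aln), aln)

  expect_error(recode_gaps(c("ACGT", "ACG")), "ragged")
})

test_that("the minimum spanning network keeps tied joining edges", {
  # chain: A-B=1, B-C=1, A-C=2 -> an MST suffices
  net <- build_network(c(A = "AAAA", B = "AAAT", C = "AATT"),
                       network_params(0, gap_recode = FALSE))
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "B C"))

  # four haplotypes at mutual distance 1: all six tie edges join distinct
  # components before any merge, so all are kept
  net4 <- build_network(c(w = "A", x = "C", y = "G", z = "T"),
                        network_params(0, gap_recode = FALSE))
  expect_equal(nrow(net4$edges), 6L)

  # degenerate input: single node, no edges
  expect_message(net1 <- build_network(c(only = "ACGT")), "degenerate")
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(nrow(net1$edges), 0L)
})

test_that("network structure invariants hold", {
  set.seed(17)
  seqs <- unique(rand_seq(8, 12))
  names(seqs) <- sprintf("h%d", seq_along(seqs))
  net <- build_network(seqs, network_params(0, gap_recode = FALSE))
  expect_equal(nrow(net$nodes), length(seqs))
  expect_true(all(net$edges$weight >= 1))
  expect_true(all(net$edges$from != net$edges$to))
  expect_true(isSymmetric(net$dist))
})

test_that("the MSN matches the exhaustive oracle and contains an MST", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    seqs <- unique(rand_seq(n, 10))
    while (length(seqs) < n) seqs <- unique(c(seqs, rand_seq(1, 10)))
    names(seqs) <- sprintf("h%d", seq_len(n))
    net <- build_network(seqs, network_params(0, gap_recode = FALSE))

    d <- net$dist
    oracle <- oracle_msn_edges(d)
    got <- net$edges
    got_keys <- sort(paste(pmin(match(got$from, names(seqs)),
                                match(got$to, names(seqs))),
                           pmax(match(got$from, names(seqs)),
                                match(got$to, names(seqs)))))
    oracle_keys <- sort(paste(oracle[, 1], oracle[, 2]))
    expect_equal(got_keys, oracle_keys)

    # the edge set contains a minimum spanning tree: an MST restricted to
    # the MSN subgraph has the same total weight as the global MST
    g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                  weighted = TRUE)
    w_full <- sum(igraph::E(igraph::mst(g_full))$weight)
    g_msn <- igraph::graph_from_data_frame(got, directed = FALSE,
                                           vertices = names(seqs))
    expect_true(igraph::is_connected(g_msn))
    igraph::E(g_msn)$weight <- got$weight
    w_msn <- sum(igraph::E(igraph::mst(g_msn))$weight)
    expect_equal(w_msn, w_full)
  }
})
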