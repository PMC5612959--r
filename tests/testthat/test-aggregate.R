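asn_row <- function(assay, taxon, rank, count, sample = "S1") {
  data.frame(query_id = paste0("q_", taxon, "_", assay, "_", sample),
             sample_id = sample, assay = assay, taxon_id = taxon,
             rank = rank, count = count, stringsAsFactors = FALSE)
}

test_that("detection matrix sums counts and applies its threshold", {
  empty <- build_detection_matrix(
    data.frame(assay = character(0), taxon_id = character(0),
               rank = character(0), count = integer(0)))
  expect_equal(nrow(empty), 0L)

  asn <- rbind(asn_row("A", "s1", "species", 3, "S1"),
               asn_row("A", "s1", "species", 3, "S2"),
               asn_row("A", "s2", "species", 1, "S1"))
  m <- build_detection_matrix(asn, min_reads_detect = 2)
  expect_equal(m$count[m$taxon_id == "s1"], 6)
  # below threshold: present in counts, absent from detections
  expect_true("s2" %in% m$taxon_id)
  expect_false("s2" %in% detections(m)$taxon_id)
})

test_that("per-rank counts follow achieved-rank semantics", {
  tree <- toy_tree()
  # one detected species contributes one taxon at every rank
  m1 <- build_detection_matrix(asn_row("A", "s1", "species", 5))
  rc1 <- rank_counts(m1, tree)
  expect_true(all(rc1$n_taxa[rc1$assay == "A"] == 1))

  # two congeners: genus 1, species 2
  m2 <- build_detection_matrix(rbind(asn_row("A", "s1", "species", 5),
                                     asn_row("A", "s2", "species", 5)))
  rc2 <- rank_counts(m2, tree)
  expect_equal(rc2$n_taxa[rc2$assay == "A" & rc2$rank == "genus"], 1)
  expect_equal(rc2$n_taxa[rc2$assay == "A" & rc2$rank == "species"], 2)

  # a family-level assignment counts at family and above, not below
  m3 <- build_detection_matrix(asn_row("A", "f1", "family", 5))
  rc3 <- rank_counts(m3, tree)
  expect_equal(rc3$n_taxa[rc3$assay == "A" & rc3$rank == "family"], 1)
  expect_equal(rc3$n_taxa[rc3$assay == "A" & rc3$rank == "genus"], 0)
  expect_equal(rc3$n_taxa[rc3$assay == "A" & rc3$rank == "species"], 0)

  # combined row equals rank_counts of the assay-union matrix
  m4 <- build_detection_matrix(rbind(asn_row("A", "s1", "species", 5),
                                     asn_row("B", "s4", "species", 5)))
  rc4 <- rank_counts(m4, tree)
  union_m <- build_detection_matrix(rbind(asn_row("U", "s1", "species", 5),
                                          asn_row("U", "s4", "species", 5)))
  rcu <- rank_counts(union_m, tree)
  expect_equal(rc4$n_taxa[rc4$assay == "combined"],
               rcu$n_taxa[rcu$assay == "U"])
})

test_that("multiple-assay hits mirror rank-count semantics", {
  tree <- toy_tree()
  m <- build_detection_matrix(rbind(asn_row("A", "s1", "species", 5),
                                    asn_row("B", "s1", "species", 5),
                                    asn_row("B", "s4", "species", 5)))
  mh <- multiple_hits(m, tree)
  expect_equal(mh$n_taxa[mh$rank == "species"], 1)  # s1 in A and B; s4 only B

  single <- build_detection_matrix(asn_row("A", "s1", "species", 5))
  expect_error(multiple_hits(single, tree), ">= 2 assays")

  # brute-force check on a 3-assay toy matrix: congeners under different
  # assays meet at genus rank
  m3 <- build_detection_matrix(rbind(asn_row("A", "s1", "species", 5),
                                     asn_row("B", "s2", "species", 5),
                                     asn_row("C", "s4", "species", 5)))
  mh3 <- multiple_hits(m3, tree)
  det <- detections(m3)
  for (r in TAX_RANKS[-1]) {
    per_assay <- lapply(split(det$taxon_id, det$assay), function(tt) {
      anc <- vapply(tt, function(t) ancestor_at_rank(tree, t, r),
                    character(1))
      unique(anc[!is.na(anc)])
    })
    nodes <- unlist(per_assay)
    expect_equal(mh3$n_taxa[mh3$rank == r],
                 sum(table(nodes) >= 2), info = r)
    # and never exceeds the combined count
    expect_lte(mh3$n_taxa[mh3$rank == r], length(unique(nodes)))
  }
})

test_that("analytic rarefaction matches closed-form and Monte Carlo", {
  # full depth returns observed richness
  expect_equal(analytic_rarefaction(c(5, 5), 10), 2)
  # exactly one taxon shows up in a single draw
  expect_equal(analytic_rarefaction(c(9, 1), 1), 1)
  expect_equal(analytic_rarefaction(c(4, 3, 2, 1), 0), 0)
  expect_error(analytic_rarefaction(c(4, 3), 10), "subsample")

  # Monte-Carlo oracle
  counts <- c(4, 3, 2, 1)
  pool <- rep(seq_along(counts), counts)
  set.seed(7)
  reps <- 2e4
  sims <- vapply(seq_len(reps),
                 function(i) length(unique(sample(pool, 5))), numeric(1))
  se <- stats::sd(sims) / sqrt(reps)
  expect_lt(abs(analytic_rarefaction(counts, 5) - mean(sims)), 3 * se)

  # monotone non-decreasing in n, bounded by min(n, S)
  counts2 <- c(12, 5, 5, 2, 1, 1)
  vals <- vapply(0:sum(counts2),
                 function(n) analytic_rarefaction(counts2, n), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals <= pmin(0:sum(counts2), length(counts2)) + 1e-12))
  expect_equal(vals[length(vals)], length(counts2))
})

test_that("matrix rarefaction subsamples without replacement", {
  asn <- rbind(asn_row("A", "s1", "species", 30),
               asn_row("A", "s2", "species", 10),
               asn_row("B", "s4", "species", 5))
  m <- build_detection_matrix(asn)

  # depth equal to an assay's total leaves it unchanged
  r1 <- rarefy_matrix(m, 5, seed = 1)
  expect_equal(sum(r1$count[r1$assay == "B"]), 5)
  expect_equal(tapply(r1$count, r1$assay, sum)[["A"]], 5)

  # depth 0 empties the detections
  suppressMessages(r0 <- rarefy_matrix(m, 0, seed = 1))
  expect_equal(nrow(detections(r0)), 0L)

  # assays shallower than the target depth are dropped with a message
  expect_message(rarefy_matrix(m, 20, seed = 1), "dropping assay B")

  # mean rarefied richness across seeds tracks the analytic expectation
  tree <- toy_tree()
  asn2 <- rbind(asn_row("A", "s1", "species", 12),
                asn_row("A", "s2", "species", 6),
                asn_row("A", "s3", "species", 2))
  m2 <- build_detection_matrix(asn2)
  rich <- vapply(1:100, function(s) {
    rm <- rarefy_matrix(m2, 6, seed = s)
    length(unique(detections(rm)$taxon_id))
  }, numeric(1))
  expected <- analytic_rarefaction(c(12, 6, 2), 6)
  se <- stats::sd(rich) / sqrt(length(rich))
  expect_lt(abs(mean(rich) - expected), 3 * se)
})

test_that("the between-assay rank test matches the closed form", {
  # balanced identical groups carry no signal
  same <- rank_test(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0, tolerance = 1e-12)

  # tie-free hand computation: H = 3.857 for {1,2,3} vs {4,5,6}
  r <- rank_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$H, 27 / 7, tolerance = 1e-10)
  expect_equal(r$df, 1)

  expect_error(rank_test(list(c(1, 2))), ">= 2 groups")
  expect_error(rank_test(list(c(1, 2), numeric(0))), "non-empty")

  # oracle equivalence on random instances (with ties)
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k),
                     function(j) sample(1:8, sample(3:7, 1), replace = TRUE))
    expect_equal(rank_test(groups)$H, oracle_kw_h(groups),
                 tolerance = 1e-10)
  }
})

test_that("summary arithmetic helpers reproduce simple bookkeeping", {
  tbl <- data.frame(kingdom = "K", phylum = c("P1", "P2"),
                    class = c(2, 1), order = c(3, NA), family = c(4, 1),
                    genus = c(2, NA), species = c(1, NA))
  tot <- rank_table_totals(tbl)
  expect_equal(unname(tot["phylum"]), 2)
  expect_equal(unname(tot["order"]), 3)
  expect_equal(unname(tot["family"]), 5)

  expect_equal(assay_share(191, 434), 100 * 191 / 434)

  comp <- shotgun_composition(50, c(a = 10, b = 90))
  expect_equal(comp$pct_of_total, c(5, 45))
})

test_that("the per-phylum rank table reports blanks above achieved rank", {
  tree <- toy_tree()
  m <- build_detection_matrix(rbind(asn_row("A", "s1", "species", 5),
                                    asn_row("A", "f2", "family", 5)))
  tbl <- phylum_rank_table(m, tree)
  expect_equal(nrow(tbl), 2L)
  p2 <- tbl[tbl$phylum == "p2", ]
  expect_equal(p2$family, 1)
  expect_true(is.na(p2$genus) && is.na(p2$species))
  tot <- rank_table_totals(tbl)
  expect_equal(unname(tot["phylum"]), 2)
  expect_equal(unname(tot["family"]), 2)
})
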