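# Synthetic-data generator: taxonomies, reference barcodes, assay panels,
# community and single-source read sets, and oracle hit tables. Everything is
# seeded so identical parameters replay byte-identically.

DNA_BASES <- c("A", "C", "G", "T")

# Run expr under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute the bases at `sites` of `chars` (a character vector of bases) with
# different bases, one substitution per site.
substitute_sites <- function(chars, sites) {
  for (p in sites) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

string_dist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Generate a synthetic taxonomy and reference barcode database
#'
#' Builds a rooted seven-rank taxonomy (one kingdom root, `n_phyla` phyla, and
#' a configurable fan-out below) together with one reference barcode per
#' species per marker. A fraction `congener_coverage` of genera carry two or
#' more referenced species (congeners); the rest carry exactly one.
#'
#' Barcodes are generated by mutating a per-genus ancestor sequence, which in
#' turn derives from a per-family ancestor. Mutation sites are allocated in
#' disjoint blocks whenever the barcode is long enough, so that congeneric
#' species differ at `2 * species_mut` positions and genera within a family at
#' `2 * genus_mut + 2 * species_mut`; otherwise sites are drawn at random and
#' the minimum-distance floors (congeners differ at >= 1 position, species in
#' different families at >= 5) are enforced by rejection.
#'
#' @param n_phyla Number of phyla (>= 1).
#' @param children_per_node Integer range `c(lo, hi)`: children per node at
#'   each internal rank below phylum.
#' @param congener_coverage Fraction in `[0, 1]` of genera holding >= 2
#'   referenced species.
#' @param markers Character vector of marker (assay locus) names; one barcode
#'   per species per marker.
#' @param barcode_length Barcode length in bases (default 151).
#' @param genus_mut,species_mut Mutations separating a genus ancestor from its
#'   family ancestor, and a species barcode from its genus ancestor.
#' @param seed Integer seed; identical inputs replay identically.
#' @return List with `tree` (taxonomy data frame: `node_id`, `parent_id`,
#'   `rank`, `name`) and `refdb` (data frame: `taxon_id`, `marker`,
#'   `sequence`), plus the realised `congener_coverage`.
#' @export
gen_taxonomy <- function(n_phyla, children_per_node = c(2L, 2L),
                         congener_coverage = 1, markers = "16S",
                         barcode_length = 151L, genus_mut = 6L,
                         species_mut = 4L, seed = 1L) {
  if (n_phyla < 1L) stop("n_phyla must be >= 1")
  if (congener_coverage < 0 || congener_coverage > 1) {
    stop("congener_coverage must be in [0, 1]")
  }
  lo <- as.integer(children_per_node[1L])
  hi <- as.integer(children_per_node[length(children_per_node)])
  if (lo < 1L || hi < lo) stop("invalid children_per_node range")
  with_seed(seed, {
    nodes <- data.frame(node_id = "k1", parent_id = "k1",
                        rank = "kingdom", name = "k1",
                        stringsAsFactors = FALSE)
    counters <- stats::setNames(rep(0L, 6L),
                                c("phylum", "class", "order", "family",
                                  "genus", "species"))
    prefixes <- c(phylum = "phy", class = "cls", order = "ord",
                  family = "fam", genus = "gen", species = "sp")
    add_children <- function(parents, rank, n_children) {
      ids <- character(0)
      pid <- character(0)
      for (p in parents) {
        k <- n_children(p)
        new <- sprintf("%s%04d", prefixes[[rank]],
                       counters[[rank]] + seq_len(k))
        counters[rank] <<- counters[[rank]] + k
        ids <- c(ids, new)
        pid <- c(pid, rep(p, k))
      }
      nodes <<- rbind(nodes, data.frame(node_id = ids, parent_id = pid,
                                        rank = rank, name = ids,
                                        stringsAsFactors = FALSE))
      ids
    }
    draw_k <- function(p) if (lo == hi) lo else sample(lo:hi, 1L)
    phyla <- add_children("k1", "phylum", function(p) n_phyla)
    classes <- add_children(phyla, "class", draw_k)
    orders <- add_children(classes, "order", draw_k)
    families <- add_children(orders, "family", draw_k)
    genera <- add_children(families, "genus", draw_k)
    n_cong <- round(congener_coverage * length(genera))
    cong <- if (n_cong > 0) sample(genera, n_cong) else character(0)
    species <- add_children(genera, "species", function(g) {
      if (g %in% cong) max(2L, draw_k(g)) else 1L
    })
    refdb <- gen_barcodes(nodes, markers, barcode_length,
                          genus_mut, species_mut)
    validate_taxonomy(nodes)
    list(tree = nodes, refdb = refdb,
         congener_coverage = congener_coverage)
  })
}

# One barcode per species per marker; see gen_taxonomy() for the geometry.
gen_barcodes <- function(nodes, markers, len, genus_mut, species_mut) {
  fam_of <- stats::setNames(nodes$parent_id, nodes$node_id)
  genera <- nodes$node_id[nodes$rank == "genus"]
  species <- nodes$node_id[nodes$rank == "species"]
  out <- vector("list", length(markers))
  for (mi in seq_along(markers)) {
    recs <- data.frame(taxon_id = character(0), marker = character(0),
                       sequence = character(0), stringsAsFactors = FALSE)
    families <- unique(fam_of[genera])
    fam_anc <- stats::setNames(random_dna(length(families), len), families)
    # family ancestors must be far apart; random sequences essentially are,
    # but enforce the floor by resampling
    if (length(families) > 1L) {
      for (tries in 1:100) {
        d <- utils::combn(families, 2L, function(p) {
          string_dist(fam_anc[[p[1L]]], fam_anc[[p[2L]]])
        })
        if (min(d) >= max(5L, 2L * (genus_mut + species_mut) + 1L)) break
        fam_anc <- stats::setNames(random_dna(length(families), len),
                                   families)
      }
    }
    for (fam in families) {
      gen_in_fam <- genera[fam_of[genera] == fam]
      sp_in_fam <- species[fam_of[species] %in% gen_in_fam]
      need <- length(gen_in_fam) * genus_mut + length(sp_in_fam) * species_mut
      anc_chars <- strsplit(fam_anc[[fam]], "")[[1]]
      if (need <= len) {
        pool <- sample.int(len, need)           # disjoint site blocks
        at <- 0L
        take <- function(k) {
          s <- pool[(at + 1L):(at + k)]
          at <<- at + k
          s
        }
        for (g in gen_in_fam) {
          g_chars <- substitute_sites(anc_chars, take(genus_mut))
          for (sp in species[fam_of[species] == g]) {
            s_chars <- substitute_sites(g_chars, take(species_mut))
            recs <- rbind(recs, data.frame(
              taxon_id = sp, marker = markers[mi],
              sequence = paste(s_chars, collapse = ""),
              stringsAsFactors = FALSE))
          }
        }
      } else {
        # fallback: random sites, rejection on the distance floors
        for (tries in 1:100) {
          cand <- data.frame(taxon_id = character(0), marker = character(0),
                             sequence = character(0), stringsAsFactors = FALSE)
          for (g in gen_in_fam) {
            g_chars <- substitute_sites(anc_chars,
                                        sample.int(len, genus_mut))
            for (sp in species[fam_of[species] == g]) {
              s_chars <- substitute_sites(g_chars,
                                          sample.int(len, species_mut))
              cand <- rbind(cand, data.frame(
                taxon_id = sp, marker = markers[mi],
                sequence = paste(s_chars, collapse = ""),
                stringsAsFactors = FALSE))
            }
          }
          if (nrow(cand) < 2L || min(utils::combn(nrow(cand), 2L, function(p) {
            string_dist(cand$sequence[p[1L]], cand$sequence[p[2L]])
          })) >= 1L) break
          if (tries == 100L) stop("could not satisfy barcode distance floors")
        }
        recs <- rbind(recs, cand)
      }
    }
    out[[mi]] <- recs
  }
  do.call(rbind, out)
}

#' Define a panel of fusion-tag metabarcoding assays
#'
#' Each assay is a fusion-tag construct: sequencer adaptor + sample index +
#' template-specific forward primer, plus a reverse primer and the marker the
#' assay amplifies. The concatenated `adaptor+index+fwd_primer` prefix must be
#' unique across the panel (demultiplexing is exact-match on this prefix).
#'
#' @param markers Marker name per assay (recycled names give multi-assay
#'   panels over the same locus distinct indexes).
#' @param adaptor Shared sequencer adaptor.
#' @param prefix_length Length of the per-assay index.
#' @param primer_length Length of the template-specific primers.
#' @param seed Integer seed.
#' @return Data frame with columns `name`, `adaptor`, `index`, `fwd_primer`,
#'   `rev_primer`, `marker`.
#' @export
make_assay_panel <- function(markers, adaptor = "ACACTCTTTCCCTACACGACG",
                             prefix_length = 8L, primer_length = 20L,
                             seed = 1L) {
  with_seed(seed, {
    n <- length(markers)
    repeat {
      idx <- random_dna(n, prefix_length)
      fwd <- random_dna(n, primer_length)
      rev <- random_dna(n, primer_length)
      if (!anyDuplicated(paste0(adaptor, idx, fwd))) break
    }
    panel <- data.frame(
      name = sprintf("assay_%s_%d", markers, seq_len(n)),
      adaptor = adaptor, index = idx, fwd_primer = fwd, rev_primer = rev,
      marker = markers, stringsAsFactors = FALSE)
    validate_panel(panel)
    panel
  })
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("name", "adaptor", "index", "fwd_primer", "rev_primer",
                  "marker") %in% names(panel)))
  pref <- paste0(panel$adaptor, panel$index, panel$fwd_primer)
  if (any(!nzchar(panel$adaptor)) || any(!nzchar(panel$index)) ||
      any(!nzchar(panel$fwd_primer))) {
    stop("assay adaptor, index and fwd_primer must be non-empty")
  }
  if (anyDuplicated(pref)) {
    stop("duplicate adaptor+index+fwd_primer prefixes in panel")
  }
  invisible(panel)
}

#' Specify a synthetic eDNA community
#'
#' @param members Data frame with columns `taxon_id` (species nodes) and
#'   `abundance` (non-negative relative abundances; normalised to sum to 1).
#' @param n_samples Number of water samples (the study design has 9).
#' @param depth_per_sample Reads per sample per assay (>= 1).
#' @param error_rate Per-base substitution probability in `[0, 1)` applied to
#'   the template only (stands in for PCR, cluster-formation and sequencing
#'   error).
#' @param low_q_frac Fraction of reads emitted with low (mean Q 20) base
#'   qualities to exercise the QC filter; all other bases are Q40.
#' @param seed Integer seed.
#' @return A `community_spec` list.
#' @export
community_spec <- function(members, n_samples = 9L, depth_per_sample = 1000L,
                           error_rate = 0, low_q_frac = 0, seed = 1L) {
  stopifnot(is.data.frame(members),
            all(c("taxon_id", "abundance") %in% names(members)),
            all(members$abundance >= 0), sum(members$abundance) > 0,
            n_samples >= 1L, depth_per_sample >= 1L,
            error_rate >= 0, error_rate < 1,
            low_q_frac >= 0, low_q_frac <= 1)
  members$abundance <- members$abundance / sum(members$abundance)
  structure(list(members = members, n_samples = as.integer(n_samples),
                 depth_per_sample = as.integer(depth_per_sample),
                 error_rate = error_rate, low_q_frac = low_q_frac,
                 seed = as.integer(seed)),
            class = "community_spec")
}

Q_HIGH <- "I"  # Phred 40, offset 33
Q_LOW <- "5"   # Phred 20

# Emit n error-prone copies of a template; returns list(seq=..., nsub=...).
mutate_template <- function(template, n, error_rate) {
  len <- nchar(template)
  nsub <- if (error_rate > 0) stats::rbinom(n, len, error_rate) else
    integer(n)
  seqs <- rep(template, n)
  hit <- which(nsub > 0L)
  if (length(hit)) {
    chars0 <- strsplit(template, "")[[1]]
    for (i in hit) {
      seqs[i] <- paste(substitute_sites(chars0,
                                        sample.int(len, nsub[i])),
                       collapse = "")
    }
  }
  list(seq = seqs, nsub = nsub)
}

#' Simulate multi-assay fusion-tag community reads
#'
#' For every sample and every assay in the panel, `depth_per_sample` reads are
#' drawn from the community profile (multinomial over member abundances). Each
#' read is `adaptor + index + fwd_primer + template`, with i.i.d. per-base
#' substitutions at `error_rate` applied to the template only. A truth table
#' records the source species and substitution count of every read.
#'
#' @param spec A [community_spec()].
#' @param panel Assay panel from [make_assay_panel()].
#' @param db Reference barcode database (`taxon_id`, `marker`, `sequence`).
#' @return List with `reads` (data frame: `read_id`, `sample_id`, `sequence`,
#'   `quality`) and `truth` (data frame: `read_id`, `taxon_id`, `sample_id`,
#'   `assay`, `n_substitutions`).
#' @export
gen_community_reads <- function(spec, panel, db) {
  stopifnot(inherits(spec, "community_spec"))
  validate_panel(panel)
  for (m in unique(panel$marker)) {
    have <- db$taxon_id[db$marker == m]
    missing <- setdiff(spec$members$taxon_id, have)
    if (length(missing)) {
      stop("reference coverage error: no ", m, " barcode for ",
           paste(missing, collapse = ", "))
    }
  }
  with_seed(spec$seed, {
    reads <- vector("list", spec$n_samples * nrow(panel))
    truth <- vector("list", spec$n_samples * nrow(panel))
    block <- 0L
    for (s in seq_len(spec$n_samples)) {
      sample_id <- sprintf("S%d", s)
      for (a in seq_len(nrow(panel))) {
        block <- block + 1L
        marker <- panel$marker[a]
        prefix <- paste0(panel$adaptor[a], panel$index[a],
                         panel$fwd_primer[a])
        counts <- as.vector(stats::rmultinom(1L, spec$depth_per_sample,
                                             spec$members$abundance))
        seqs <- character(spec$depth_per_sample)
        nsub <- integer(spec$depth_per_sample)
        taxa <- character(spec$depth_per_sample)
        at <- 0L
        for (j in seq_len(nrow(spec$members))) {
          if (counts[j] == 0L) next
          tmpl <- db$sequence[db$marker == marker &
                              db$taxon_id == spec$members$taxon_id[j]][1L]
          mt <- mutate_template(tmpl, counts[j], spec$error_rate)
          sl <- (at + 1L):(at + counts[j])
          seqs[sl] <- mt$seq
          nsub[sl] <- mt$nsub
          taxa[sl] <- spec$members$taxon_id[j]
          at <- at + counts[j]
        }
        read_len <- nchar(prefix) + nchar(seqs)
        low <- stats::runif(spec$depth_per_sample) < spec$low_q_frac
        qual <- ifelse(low, strrep(Q_LOW, read_len), strrep(Q_HIGH, read_len))
        ids <- sprintf("%s_%s_r%06d", sample_id, panel$name[a],
                       seq_len(spec$depth_per_sample))
        reads[[block]] <- data.frame(
          read_id = ids, sample_id = sample_id,
          sequence = paste0(prefix, seqs), quality = qual,
          stringsAsFactors = FALSE)
        truth[[block]] <- data.frame(
          read_id = ids, taxon_id = taxa, sample_id = sample_id,
          assay = panel$name[a], n_substitutions = nsub,
          stringsAsFactors = FALSE)
      }
    }
    list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
  })
}

#' Simulate single-source calibration libraries
#'
#' One library per species, each holding `depth` reads of that species'
#' barcode for `marker` under the same substitution error model as
#' [gen_community_reads()]. These libraries model individually amplified
#' single-source amplicons (already demultiplexed), so reads are bare
#' templates without fusion-tag prefixes.
#'
#' @param db Reference barcode database.
#' @param species Character vector of species node ids.
#' @param marker Marker name.
#' @param depth Reads per library.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List with `reads` (data frame: `read_id`, `library`, `sequence`,
#'   `quality`) and `truth` (as in [gen_community_reads()], with the library
#'   id in `sample_id`).
#' @export
gen_single_source_reads <- function(db, species, marker, depth,
                                    error_rate = 0, seed = 1L) {
  species <- unname(species)
  for (sp in species) {
    if (!any(db$marker == marker & db$taxon_id == sp)) {
      stop("reference coverage error: no ", marker, " barcode for ", sp)
    }
  }
  with_seed(seed, {
    reads <- vector("list", length(species))
    truth <- vector("list", length(species))
    for (i in seq_along(species)) {
      tmpl <- db$sequence[db$marker == marker &
                          db$taxon_id == species[i]][1L]
      mt <- mutate_template(tmpl, depth, error_rate)
      ids <- sprintf("%s_r%06d", species[i], seq_len(depth))
      reads[[i]] <- data.frame(
        read_id = ids, library = species[i], sequence = mt$seq,
        quality = strrep(Q_HIGH, nchar(mt$seq)), stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        read_id = ids, taxon_id = species[i], sample_id = species[i],
        assay = marker, n_substitutions = mt$nsub, stringsAsFactors = FALSE)
    }
    list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
  })
}

#' Oracle alignment-hit table for dereplicated sequences
#'
#' Compares each query against every reference barcode of the same marker
#' (equal template lengths are required) and emits one hit per reference with
#' `pct_identity = 100 * matches / length` and a proxy alignment score
#' `2 * matches - 3 * mismatches`. Hits below 70% identity are suppressed.
#'
#' @param seqs Character vector of query sequences; names are used as query
#'   ids (auto-generated `q1..qn` when absent).
#' @param db Reference barcode database.
#' @param marker Marker whose references are searched.
#' @return Hit table data frame: `query_id`, `subject_taxon_id`,
#'   `pct_identity`, `score`.
#' @export
gen_hit_table <- function(seqs, db, marker) {
  refs <- db[db$marker == marker, , drop = FALSE]
  if (!nrow(refs)) stop("no references for marker ", marker)
  if (is.null(names(seqs))) names(seqs) <- sprintf("q%d", seq_along(seqs))
  len <- unique(nchar(refs$sequence))
  if (length(len) != 1L || any(nchar(seqs) != len)) {
    stop("oracle error: query and reference template lengths differ")
  }
  refmat <- do.call(rbind, strsplit(refs$sequence, ""))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    q <- strsplit(seqs[[i]], "")[[1]]
    mm <- rowSums(refmat != matrix(q, nrow(refmat), len, byrow = TRUE))
    ident <- 100 * (len - mm) / len
    keep <- ident >= 70
    if (!any(keep)) next
    out[[i]] <- data.frame(
      query_id = names(seqs)[i], subject_taxon_id = refs$taxon_id[keep],
      pct_identity = ident[keep],
      score = 2 * (len - mm[keep]) - 3 * mm[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(query_id = character(0),
                      subject_taxon_id = character(0),
                      pct_identity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
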