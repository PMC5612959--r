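# Haplotype workflow: greedy OTU clustering, amplicon error-rate calibration
# from single-source libraries, frequency/replicate haplotype filtering,
# gap-aware recoding and minimum spanning haplotype networks.

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  if (length(x) != length(y)) stop("sequences differ in length")
  sum(x != y)
}

# Pairwise Hamming distances of a character vector of equal-length strings.
pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  lens <- unique(nchar(seqs))
  if (length(lens) > 1L) stop("sequences differ in length")
  mat <- do.call(rbind, lapply(seqs, utf8ToInt))
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
      }
    }
  }
  d
}

#' Greedy centroid OTU clustering
#'
#' Sequences are processed in decreasing count order (ties broken
#' lexicographically by sequence). Each sequence joins the existing centroid
#' with the highest identity when that identity reaches `threshold` (ties go
#' to the earliest-founded centroid); otherwise it founds a new OTU. Identity
#' between equal-length sequences is `1 - hamming / length`.
#'
#' @param seqs Character vector of dereplicated sequences (same marker, equal
#'   length).
#' @param counts Integer read counts, parallel to `seqs`.
#' @param threshold Identity threshold in `[0, 1]` (default 0.98).
#' @return Data frame: `sequence`, `count`, `otu` (integer cluster id),
#'   `centroid` (the cluster's founding sequence).
#' @export
cluster_otus <- function(seqs, counts, threshold = 0.98) {
  stopifnot(length(seqs) == length(counts), threshold >= 0, threshold <= 1)
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]
  counts <- counts[ord]
  len <- unique(nchar(seqs))
  if (length(len) > 1L) stop("sequences differ in length")
  centroids <- character(0)
  otu <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    if (length(centroids)) {
      ident <- vapply(centroids,
                      function(ctr) 1 - hamming(seqs[i], ctr) / len,
                      numeric(1), USE.NAMES = FALSE)
      best <- which.max(ident)  # earliest centroid wins ties
      if (ident[best] >= threshold) {
        otu[i] <- best
        next
      }
    }
    centroids <- c(centroids, seqs[i])
    otu[i] <- length(centroids)
  }
  data.frame(sequence = seqs, count = counts, otu = otu,
             centroid = centroids[otu], stringsAsFactors = FALSE)
}

#' Estimate the amplicon error rate from single-source libraries
#'
#' Each library derives from a single known source, so its dominant unique
#' sequence (highest count; ties broken lexicographically) is taken as the
#' true haplotype and everything else as error. The per-species rate is the
#' count of the most abundant erroneous sequence as a percentage of the true
#' haplotype's count; libraries holding a single unique sequence contribute
#' rate 0. The summary is the mean and sample (n-1) standard deviation across
#' species.
#'
#' @param libraries Data frame with columns `species`, `sequence`, `count`
#'   (one row per unique sequence per library).
#' @return An `error_rate_estimate` list: `per_species` (data frame:
#'   `species`, `dominant_count`, `top_error_count`, `rate_pct`), `mean`,
#'   `sd`.
#' @export
estimate_error_rate <- function(libraries) {
  stopifnot(is.data.frame(libraries),
            all(c("species", "sequence", "count") %in% names(libraries)))
  if (!nrow(libraries)) stop("data error: empty library set")
  per <- lapply(split(libraries, libraries$species), function(lib) {
    if (!nrow(lib) || all(lib$count <= 0)) {
      stop("data error: empty library for species ", lib$species[1])
    }
    lib <- lib[order(-lib$count, lib$sequence), , drop = FALSE]
    dom <- lib$count[1L]
    top_err <- if (nrow(lib) > 1L) lib$count[2L] else 0L
    data.frame(species = lib$species[1L], dominant_count = dom,
               top_error_count = top_err, rate_pct = 100 * top_err / dom,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(per_species = per, mean = mean(per$rate_pct),
                 sd = stats::sd(per$rate_pct)),
            class = "error_rate_estimate")
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf("Amplicon error rate: %.2f%% +/- %.2f (n = %d species)\n",
              x$mean, if (is.na(x$sd)) 0 else x$sd, nrow(x$per_species)))
  invisible(x)
}

#' Haplotype network parameters
#'
#' @param error_threshold Frequency threshold in percent; candidates at or
#'   below it (relative to the sample's most abundant candidate) are treated
#'   as error. An [estimate_error_rate()] result may be passed, in which case
#'   its mean is used.
#' @param min_samples Minimum number of samples in which a candidate must pass
#'   the frequency test to be retained (>= 2: a haplotype must be replicated
#'   across water samples).
#' @param gap_recode Recode alignment gaps before computing distances (see
#'   [recode_gaps()]).
#' @return A `network_params` list.
#' @export
network_params <- function(error_threshold, min_samples = 2L,
                           gap_recode = TRUE) {
  if (inherits(error_threshold, "error_rate_estimate")) {
    error_threshold <- error_threshold$mean
  }
  stopifnot(error_threshold >= 0, min_samples >= 2L)
  structure(list(error_threshold = error_threshold,
                 min_samples = as.integer(min_samples),
                 gap_recode = isTRUE(gap_recode)),
            class = "network_params")
}

#' Filter candidate haplotypes by frequency and replicate presence
#'
#' Within each sample, a candidate passes the frequency test when its count,
#' as a percentage of the count of that sample's most abundant candidate, is
#' strictly greater than `error_threshold` (the threshold is an error
#' ceiling: a candidate at exactly the error frequency is indistinguishable
#' from noise; the per-sample dominant passes by definition at 100%). A
#' candidate is retained when it passes the frequency test in at least
#' `min_samples` samples.
#'
#' @param candidates Data frame with columns `sequence`, `sample_id`, `count`
#'   (candidates restricted to one target genus).
#' @param params [network_params()].
#' @return List with `table` (per-candidate summary: `sequence`,
#'   `n_samples_passed`, `total_count`, `passed_frequency`,
#'   `passed_replication`, `retained`) and `retained` (character vector of
#'   retained sequences).
#' @export
filter_haplotypes <- function(candidates, params) {
  stopifnot(inherits(params, "network_params"))
  if (!nrow(candidates)) {
    tab <- data.frame(sequence = character(0), n_samples_passed = integer(0),
                      total_count = integer(0), passed_frequency = logical(0),
                      passed_replication = logical(0), retained = logical(0),
                      stringsAsFactors = FALSE)
    return(list(table = tab, retained = character(0)))
  }
  dom <- tapply(candidates$count, candidates$sample_id, max)
  freq_pct <- 100 * candidates$count /
    as.numeric(dom[candidates$sample_id])
  pass <- freq_pct > params$error_threshold
  n_pass <- tapply(pass, candidates$sequence, sum)
  total <- tapply(candidates$count, candidates$sequence, sum)
  tab <- data.frame(sequence = names(n_pass),
                    n_samples_passed = as.integer(n_pass),
                    total_count = as.integer(total[names(n_pass)]),
                    stringsAsFactors = FALSE)
  tab$passed_frequency <- tab$n_samples_passed >= 1L
  tab$passed_replication <- tab$n_samples_passed >= params$min_samples
  tab$retained <- tab$passed_frequency & tab$passed_replication
  tab <- tab[order(-tab$total_count, tab$sequence), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, retained = tab$sequence[tab$retained])
}

#' Recode alignment gaps so one indel event is one mutational step
#'
#' Network software that cannot treat the gap as a fifth character state would
#' either ignore indels or count a k-column gap as k steps. This recoding
#' collapses each maximal run of gap-containing columns to a single column in
#' which an all-gap stretch becomes the symbol `-` and each distinct
#' non-gap content string becomes its own single-character symbol, so one
#' contiguous indel costs exactly one step in a Hamming distance.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @return The recoded alignment (named character vector; columns without
#'   gaps are untouched).
#' @export
recode_gaps <- function(alignment) {
  lens <- unique(nchar(alignment))
  if (length(lens) != 1L) stop("format error: ragged alignment")
  mat <- do.call(rbind, strsplit(alignment, ""))
  gap_col <- apply(mat == "-", 2L, any)
  if (!any(gap_col)) return(alignment)
  runs <- rle(gap_col)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pieces <- vector("list", length(runs$lengths))
  symbol_pool <- c(letters, as.character(0:9))
  for (k in seq_along(runs$lengths)) {
    block <- mat[, starts[k]:ends[k], drop = FALSE]
    if (!runs$values[k]) {
      pieces[[k]] <- block
      next
    }
    content <- apply(block, 1L, paste, collapse = "")
    sym <- character(length(content))
    sym[grepl("^-+$", content)] <- "-"
    todo <- unique(content[sym == ""])
    for (i in seq_along(todo)) {
      s <- if (nchar(todo[i]) == 1L) todo[i] else symbol_pool[i]
      sym[content == todo[i]] <- s
    }
    pieces[[k]] <- matrix(sym, ncol = 1L)
  }
  recoded <- do.call(cbind, pieces)
  out <- apply(recoded, 1L, paste, collapse = "")
  names(out) <- names(alignment)
  out
}

#' Build a minimum spanning haplotype network
#'
#' Pairwise distances are Hamming distances on the (optionally gap-recoded)
#' alignment. The network is the minimum spanning network: edge weights are
#' processed in ascending order and, at each weight, all edges of that weight
#' joining currently distinct components are added before any merging, so
#' tied alternative connections are kept. The edge set therefore contains at
#' least one minimum spanning tree.
#'
#' @param haplotypes Named character vector of aligned haplotypes (retained
#'   eDNA haplotypes plus any reference haplotypes).
#' @param params [network_params()] (controls gap recoding).
#' @param provenance Optional character vector parallel to `haplotypes`
#'   (e.g. `"eDNA"` / `"reference"`).
#' @param sample_counts Optional data frame (`haplotype`, `sample_id`,
#'   `count`) carried into the result for export.
#' @return A `haplotype_network` list: `nodes` (data frame: `haplotype`,
#'   `provenance`), `edges` (data frame: `from`, `to`, `weight`), `dist`
#'   (distance matrix), `sample_counts`.
#' @export
build_network <- function(haplotypes, params = network_params(0),
                          provenance = NULL, sample_counts = NULL) {
  if (is.null(names(haplotypes))) {
    names(haplotypes) <- sprintf("h%d", seq_along(haplotypes))
  }
  if (is.null(provenance)) provenance <- rep("eDNA", length(haplotypes))
  nodes <- data.frame(haplotype = names(haplotypes),
                      provenance = provenance, stringsAsFactors = FALSE)
  if (length(haplotypes) < 2L) {
    message("degenerate input: fewer than 2 haplotypes; ",
            "returning a single-node network")
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             weight = integer(0),
                                             stringsAsFactors = FALSE),
                          dist = matrix(0L, length(haplotypes),
                                        length(haplotypes)),
                          sample_counts = sample_counts),
                     class = "haplotype_network"))
  }
  aligned <- if (params$gap_recode) recode_gaps(haplotypes) else haplotypes
  d <- pairwise_hamming(aligned)
  n <- length(haplotypes)
  # union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  edges <- data.frame(from = character(0), to = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w_of <- d[pairs]
  for (w in sort(unique(w_of))) {
    if (w == 0L) next   # identical haplotypes are not linked by a step
    at_w <- pairs[w_of == w, , drop = FALSE]
    joining <- at_w[apply(at_w, 1L, function(p) {
      find(p[1L]) != find(p[2L])
    }), , drop = FALSE]
    if (nrow(joining)) {
      edges <- rbind(edges, data.frame(
        from = nodes$haplotype[joining[, 1L]],
        to = nodes$haplotype[joining[, 2L]],
        weight = w, stringsAsFactors = FALSE))
      for (r in seq_len(nrow(joining))) {     # merge after collecting ties
        ra <- find(joining[r, 1L])
        rb <- find(joining[r, 2L])
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1L) break
  }
  structure(list(nodes = nodes, edges = edges, dist = d,
                 sample_counts = sample_counts),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("Haplotype network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
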