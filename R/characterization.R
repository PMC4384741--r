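#' Sequence-context model of editing
#'
#' Per (5', 3') neighbour combination, the probability that an A with that
#' context is edited: the number of edited A's with the context divided by
#' the number of A's with the context in the coding regions. Sixteen
#' combinations; values in [0, 1]. Used as acceptance probabilities by the
#' context-preserving randomization.
#'
#' @param probs 4x4 numeric matrix (rows = 5' base, cols = 3' base, dimnames
#'   A/C/G/T).
#' @param genomic_context_counts 4x4 integer matrix of A counts per context.
#' @return A `context_model`.
#' @export
context_model <- function(probs, genomic_context_counts = NULL) {
  check_that(is.matrix(probs) && all(dim(probs) == c(4, 4)),
             "probs must be a 4x4 matrix")
  if (is.null(dimnames(probs))) dimnames(probs) <- list(BASES, BASES)
  check_that(all(probs >= 0 & probs <= 1, na.rm = TRUE),
             "context probabilities must be in [0,1]")
  structure(list(probs = probs,
                 genomic_context_counts = genomic_context_counts),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  cat("<context_model> P(edited | 5',3'):\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Neighbour preference of editing sites
#'
#' Tallies the 5' and 3' neighbouring nucleotides of A-to-G sites, compares
#' them with the background of all A's in the coding regions, and builds the
#' [context_model] used by the randomization null. Sites at ORF boundaries
#' are excluded from the affected flank count. For each flank and nucleotide
#' an enrichment ratio (observed/expected fraction) and a two-sided binomial
#' p-value are reported.
#'
#' @param sites Site table; only `mismatch_type == type` rows are used.
#' @param orfs An [orf_set].
#' @param type Mismatch type to profile (default `"A>G"`).
#' @return List with `enrichment` (data.table: `flank`, `base`, `observed`,
#'   `n`, `expected_fraction`, `ratio`, `p_value`), `model` (a
#'   [context_model]) and `site_context_counts` (4x4).
#' @export
neighbor_preference <- function(sites, orfs, type = "A>G") {
  s <- data.table::as.data.table(sites)[mismatch_type == type]
  check_that(nrow(s) > 0, "no sites of the requested type")
  seqs <- orfs$seq[s$orf_id]
  len <- nchar(seqs)
  five <- ifelse(s$pos >= 1, substr(seqs, s$pos, s$pos), NA)
  three <- ifelse(s$pos + 2 <= len, substr(seqs, s$pos + 2, s$pos + 2), NA)

  bg <- orf_a_contexts(orfs)
  check_that(nrow(bg) > 0, "ORF set contains no eligible A bases")
  g_counts <- table(factor(bg$five, BASES), factor(bg$three, BASES))
  both <- !is.na(five) & !is.na(three) & five %in% BASES & three %in% BASES
  s_counts <- table(factor(five[both], BASES), factor(three[both], BASES))
  probs <- matrix(pmin(1, as.numeric(s_counts) /
                         pmax(1, as.numeric(g_counts))), 4, 4,
                  dimnames = list(BASES, BASES))

  enrich <- function(obs_bases, bg_bases, flank) {
    obs_bases <- obs_bases[!is.na(obs_bases) & obs_bases %in% BASES]
    n <- length(obs_bases)
    ot <- table(factor(obs_bases, BASES))
    et <- prop.table(table(factor(bg_bases, BASES)))
    data.table::rbindlist(lapply(BASES, function(b) {
      pv <- stats::binom.test(ot[[b]], n, p = et[[b]])$p.value
      data.table::data.table(flank = flank, base = b, observed = ot[[b]],
                             n = n, expected_fraction = et[[b]],
                             ratio = (ot[[b]] / n) / et[[b]], p_value = pv)
    }))
  }
  enr <- data.table::rbindlist(list(enrich(five, bg$five, "5prime"),
                                    enrich(three, bg$three, "3prime")))
  list(enrichment = enr,
       model = context_model(probs, unclass(g_counts)),
       site_context_counts = unclass(s_counts))
}

#' Clusters of consecutive same-type sites along ORFs
#'
#' Finds maximal runs of at least `min_run` called sites of one mismatch type
#' within an ORF with no intervening called site of a different type between
#' consecutive members (intervening unmodified bases are allowed, with no
#' maximum gap; set `max_gap` for a sensitivity variant bounding the distance
#' between consecutive members).
#'
#' @param sites Site table sorted by (orf, pos) (sorted internally anyway).
#' @param min_run Minimum run length (default 3).
#' @param max_gap Optional maximum distance (nt) between consecutive cluster
#'   members.
#' @return List with `clusters` (data.table: `cluster_id`, `orf_id`,
#'   `start_pos`, `end_pos`, `n_sites`, `mismatch_type`), `members` (site
#'   rows with `cluster_id`), and `per_type` (cluster and clustered-site
#'   counts per type).
#' @export
find_site_clusters <- function(sites, min_run = 3, max_gap = NULL) {
  s <- data.table::as.data.table(sites)
  data.table::setorder(s, orf_id, pos)
  if (nrow(s) == 0) {
    return(list(clusters = data.table::data.table(
      cluster_id = integer(0), orf_id = character(0), start_pos = integer(0),
      end_pos = integer(0), n_sites = integer(0),
      mismatch_type = character(0)), members = s,
      per_type = data.table::data.table(mismatch_type = character(0),
                                        n_clusters = integer(0),
                                        n_sites = integer(0))))
  }
  new_run <- s$mismatch_type != data.table::shift(s$mismatch_type, fill = "") |
    s$orf_id != data.table::shift(s$orf_id, fill = "")
  if (!is.null(max_gap))
    new_run <- new_run |
      (s$pos - data.table::shift(s$pos, fill = -1L)) > max_gap
  run <- cumsum(new_run)
  s[, run_id := run]
  runs <- s[, .(orf_id = orf_id[1], start_pos = min(pos), end_pos = max(pos),
                n_sites = .N, mismatch_type = mismatch_type[1]),
            by = run_id]
  clusters <- runs[n_sites >= min_run]
  clusters[, cluster_id := seq_len(.N)]
  members <- s[run_id %in% clusters$run_id]
  members[, cluster_id := match(run_id, clusters$run_id)]
  members[, run_id := NULL]
  per_type <- clusters[, .(n_clusters = .N, n_sites = sum(n_sites)),
                       by = mismatch_type]
  clusters[, run_id := NULL]
  data.table::setcolorder(clusters, c("cluster_id", "orf_id", "start_pos",
                                      "end_pos", "n_sites", "mismatch_type"))
  list(clusters = clusters[], members = members[], per_type = per_type[])
}

#' Reads carrying consecutive identical mismatches
#'
#' Counts, per mismatch type, the reads containing at least `min_run`
#' mismatches of that type that are consecutive in the sense that no mismatch
#' of another type occurs between them within the read (matching bases in
#' between are allowed). Only quality-filtered A/C/G/T bases are considered.
#'
#' @param aln An [alignment_table] (or list pooled).
#' @param orfs An [orf_set].
#' @param min_run Minimum run length(s); may be a vector (e.g. `3:5`).
#' @param q_min Base-quality cutoff.
#' @return data.table: `min_run`, `mismatch_type`, `n_reads`.
#' @export
find_read_level_clusters <- function(aln, orfs, min_run = 3, q_min = 30) {
  if (inherits(aln, "data.frame")) aln <- list(aln)
  parts <- lapply(aln, function(a) expand_alignments(
    data.table::as.data.table(a)))
  b <- data.table::rbindlist(parts, idcol = "tab")
  grid <- data.table::CJ(min_run = min_run, mismatch_type = mismatch_types())
  if (nrow(b) == 0)
    return(grid[, .(min_run, mismatch_type, n_reads = 0L)])
  refchars <- lapply(orfs$seq, function(x) strsplit(x, "", fixed = TRUE)[[1]])
  b <- b[qual >= q_min & base %chin% BASES & orf_id %chin% names(refchars)]
  b[, ref := refchars[[orf_id[1]]][pos + 1L], by = orf_id]
  mm <- b[base != ref & ref %chin% BASES]
  if (nrow(mm) == 0)
    return(grid[, .(min_run, mismatch_type, n_reads = 0L)])
  mm[, type := paste0(ref, ">", base)]
  data.table::setorder(mm, tab, rec, read_off)
  longest <- mm[, {
    r <- rle(type)
    .(type = r$values, len = r$lengths)
  }, by = .(tab, rec)][, .(maxrun = max(len)), by = .(tab, rec, type)]
  counts <- data.table::rbindlist(lapply(min_run, function(k)
    longest[maxrun >= k, .(min_run = k, n_reads = data.table::uniqueN(
      paste(tab, rec))), by = .(mismatch_type = type)]))
  out <- counts[grid, on = c("min_run", "mismatch_type")]
  out[is.na(n_reads), n_reads := 0L]
  data.table::setorder(out, min_run, mismatch_type)
  out[]
}

#' Editing-level histograms
#'
#' Distribution of editing levels per category (weak/strong) and per type
#' group (A-to-G vs non-A-to-G).
#'
#' @param sites Site table.
#' @param breaks Histogram bin edges (default deciles).
#' @return data.table: `group`, `category`, `bin`, `lo`, `hi`, `count`.
#' @export
level_distribution <- function(sites, breaks = seq(0, 1, 0.1)) {
  s <- data.table::as.data.table(sites)[!is.na(editing_level)]
  nb <- length(breaks) - 1L
  bin <- function(x) {
    b <- cut(x, breaks, include.lowest = TRUE, right = FALSE, labels = FALSE)
    b[x >= breaks[length(breaks)]] <- nb
    b
  }
  if (nrow(s) == 0)
    return(data.table::data.table(group = character(0),
                                  category = character(0), bin = integer(0),
                                  lo = numeric(0), hi = numeric(0),
                                  count = integer(0)))
  s[, `:=`(group = data.table::fifelse(mismatch_type == "A>G", "A>G",
                                       "non-A>G"),
           b = bin(editing_level))]
  grid <- data.table::CJ(group = unique(s$group),
                         category = unique(s$category), b = seq_len(nb))
  cnt <- s[, .(count = .N), by = .(group, category, b)]
  out <- cnt[grid, on = c("group", "category", "b")]
  out[is.na(count), count := 0L]
  out[, `:=`(lo = breaks[b], hi = breaks[b + 1L])]
  data.table::setnames(out, "b", "bin")
  data.table::setcolorder(out, c("group", "category", "bin", "lo", "hi",
                                 "count"))
  data.table::setorder(out, group, category, bin)
  out[]
}

#' Recurrence of sites between two site tables
#'
#' Among sites of `sites_a` whose editing level lies in `[lo, hi)`, the
#' fraction whose (orf, pos, mismatch type) also appears in `sites_b` —
#' e.g. the replication of putative polymorphism-driven ~50%-level sites
#' between two tissues of one animal.
#'
#' @param sites_a,sites_b Site tables.
#' @param lo,hi Editing-level range applied to `sites_a` (default all).
#' @return Fraction in [0, 1], or NA when no site of `sites_a` is in range.
#' @export
recurrence_fraction <- function(sites_a, sites_b, lo = 0, hi = 1 + 1e-9) {
  a <- data.table::as.data.table(sites_a)
  a <- a[!is.na(editing_level) & editing_level >= lo & editing_level < hi]
  if (nrow(a) == 0) return(NA_real_)
  b <- data.table::as.data.table(sites_b)
  key_a <- paste(a$orf_id, a$pos, a$mismatch_type)
  key_b <- paste(b$orf_id, b$pos, b$mismatch_type)
  mean(key_a %in% key_b)
}

#' Detection saturation under read subsampling
#'
#' Re-runs detection on Bernoulli-subsampled read sets and counts detected
#' A-to-G sites, separately thinning the RNA reads (weak-site saturation) and
#' the DNA reads (strong-site dependence and polymorphism filtering).
#'
#' @param orfs An [orf_set].
#' @param rna,dna [alignment_table]s.
#' @param fractions Subsampling fractions in (0, 1].
#' @param seeds Integer seeds; each (fraction, seed) pair is one run.
#' @param config A [detection_config].
#' @param q_min Base-quality cutoff.
#' @param modes Which read set to thin (`"rna"`, `"dna"` or both).
#' @return data.table: `mode`, `fraction`, `seed`, `n_weak_ag`,
#'   `n_strong_ag`, `n_sites`.
#' @export
saturation_analysis <- function(orfs, rna, dna, fractions = c(0.25, 0.5, 1),
                                seeds = 1:3, config = detection_config(),
                                q_min = 30, modes = c("rna", "dna")) {
  check_that(all(fractions > 0 & fractions <= 1),
             "fractions must be in (0,1]")
  rna <- data.table::as.data.table(rna)
  dna <- data.table::as.data.table(dna)
  one <- function(mode, f, sd) {
    sub <- function(a) a[with_seed(sd, stats::runif(nrow(a))) <= f]
    r <- if (mode == "rna") sub(rna) else rna
    d <- if (mode == "dna") sub(dna) else dna
    pu <- build_pileup(orfs, r, d, q_min = q_min)
    res <- detect_sites(pu, config)
    ssum <- res$summary
    data.table::data.table(
      mode = mode, fraction = f, seed = sd,
      n_weak_ag = ssum[mismatch_type == "A>G" & category == "weak", count],
      n_strong_ag = ssum[mismatch_type == "A>G" & category == "strong",
                         count],
      n_sites = nrow(res$sites))
  }
  grid <- expand.grid(mode = modes, fraction = fractions, seed = seeds,
                      stringsAsFactors = FALSE)
  out <- data.table::rbindlist(lapply(seq_len(nrow(grid)), function(i)
    one(grid$mode[i], grid$fraction[i], grid$seed[i])))
  data.table::setorder(out, mode, fraction, seed)
  out[]
}

#' Detected sites per ORF as a function of RNA coverage
#'
#' ORFs are sorted by mean coding-region RNA coverage and divided into
#' `n_bins` equal bins; the mean A-to-G site count per ORF is reported per
#' bin.
#'
#' @param sites Site table.
#' @param pileup A [build_pileup] result (provides coverage).
#' @param orfs An [orf_set].
#' @param n_bins Number of coverage bins (default 10).
#' @return data.table: `bin`, `mean_coverage`, `mean_sites`, `n_orfs`.
#' @export
coverage_site_bins <- function(sites, pileup, orfs, n_bins = 10) {
  cds <- data.table::as.data.table(orfs$cds)
  cov <- data.table::as.data.table(pileup)[, .(covsum = sum(rna_total)),
                                           by = orf_id]
  cov <- cov[cds, on = "orf_id"]
  cov[is.na(covsum), covsum := 0]
  cov[, mean_cov := covsum / pmax(1L, cds_end - cds_start)]
  s <- data.table::as.data.table(sites)[mismatch_type == "A>G",
                                        .(n_sites = .N), by = orf_id]
  cov <- s[cov, on = "orf_id"]
  cov[is.na(n_sites), n_sites := 0L]
  data.table::setorder(cov, mean_cov)
  cov[, bin := ceiling(seq_len(.N) / (.N / n_bins))]
  out <- cov[, .(mean_coverage = mean(mean_cov), mean_sites = mean(n_sites),
                 n_orfs = .N), by = bin]
  data.table::setorder(out, bin)
  out[]
}
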