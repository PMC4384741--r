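#' Default 5'/3' context bias of editing sites
#'
#' Relative weight of each (5', 3') neighbour combination for placing
#' simulated editing sites, the product of marginal 5' and 3' weights chosen
#' to emulate the neighbour preference observed around real A-to-I sites:
#' G depleted 5' of the site and enriched 3' of it, A/T enriched 5'.
#'
#' @return 4x4 numeric matrix (rows 5' base, cols 3' base).
#' @export
default_context_bias <- function() {
  w5 <- c(A = 0.485, C = 0.150, G = 0.079, T = 0.286)
  w3 <- c(A = 0.187, C = 0.187, G = 0.440, T = 0.186)
  outer(w5, w3)
}

#' Simulation configuration
#'
#' Defines the conditions a simulated dataset emulates: ORFs with codon
#' structure, context-biased A-to-I editing sites with per-site levels,
#' heterozygous SNPs (present at 50% in both DNA and RNA reads), per-base
#' sequencing errors at the expected 0.1% rate with a two-component quality
#' model (so the Q30 filter is exercised), paired DNA/RNA coverage, and
#' optional introns producing soft-clipped DNA reads.
#'
#' @param n_orfs Number of ORFs.
#' @param orf_length ORF length in codons (start and stop included).
#' @param editing_site_density Editing sites per kb of coding sequence.
#' @param level_distribution List `list(family = "beta", shape1, shape2)` or
#'   `list(family = "fixed", level)` for the per-site editing level.
#' @param context_bias 4x4 relative-weight matrix for site placement.
#' @param snp_het_rate Heterozygous SNP rate per bp.
#' @param error_rate Per-base sequencing error probability.
#' @param rna_coverage,dna_coverage Mean read depth.
#' @param read_length Read length (nt).
#' @param n_tissues Number of RNA tissues.
#' @param tissue_level_effects Per-tissue multiplicative factor on editing
#'   levels (length `n_tissues`; default all 1 = no tissue differences).
#' @param intron_rate Probability that an ORF's genomic locus carries one
#'   intron.
#' @param intron_length Intron length (nt).
#' @param nonunique_rate Fraction of reads emitted with sub-maximal mapping
#'   quality (exercises the unique-alignment filter).
#' @param quality_model List `p_low`, `q_low` (range), `q_high` (range) for
#'   the two-component base-quality model.
#' @param seed Integer seed; identical configurations give identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_orfs = 30, orf_length = 100,
                       editing_site_density = 5,
                       level_distribution = list(family = "beta",
                                                 shape1 = 1, shape2 = 3),
                       context_bias = default_context_bias(),
                       snp_het_rate = 0.001, error_rate = 0.001,
                       rna_coverage = 100, dna_coverage = 30,
                       read_length = 100, n_tissues = 1,
                       tissue_level_effects = NULL,
                       intron_rate = 0, intron_length = 150,
                       nonunique_rate = 0,
                       quality_model = list(p_low = 0.1, q_low = c(15, 25),
                                            q_high = c(35, 40)),
                       seed = 1) {
  if (is.null(tissue_level_effects))
    tissue_level_effects <- rep(1, n_tissues)
  cfg <- as.list(environment())
  check_that(all(c(snp_het_rate, error_rate, intron_rate, nonunique_rate,
                   quality_model$p_low) >= 0 &
                 c(snp_het_rate, error_rate, intron_rate, nonunique_rate,
                   quality_model$p_low) <= 1), "rates must be in [0,1]")
  check_that(rna_coverage > 0 && dna_coverage >= 0, "coverages must be > 0")
  check_that(3 * orf_length >= read_length,
             "ORFs must be at least one read long")
  check_that(length(tissue_level_effects) == n_tissues,
             "tissue_level_effects must have length n_tissues")
  structure(cfg, class = "sim_config")
}

## draw per-site editing levels in (0, 1]
draw_levels <- function(dist, n) {
  lv <- switch(dist$family,
               beta = stats::rbeta(n, dist$shape1, dist$shape2),
               fixed = rep(dist$level, n),
               stop("unknown level_distribution family: ", dist$family))
  pmin(pmax(lv, 1e-6), 1)
}

RAW_BASES <- charToRaw("ACGT")

## random coding sequences with start/stop discipline
random_orfs <- function(n_orfs, orf_length) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  stops <- names(gc)[gc == "*"]
  seqs <- vapply(seq_len(n_orfs), function(i)
    paste0("ATG",
           paste(sample(sense, orf_length - 2, replace = TRUE),
                 collapse = ""),
           sample(stops, 1)), "")
  names(seqs) <- sprintf("ORF%03d", seq_len(n_orfs))
  seqs
}

## mutate a raw base matrix (read_length x n_reads) at (offset, read) pairs:
## set base where hit, given per-event probability and new base
apply_events <- function(M, read, offset, prob, new_base) {
  if (length(read) == 0) return(M)
  hit <- stats::runif(length(read)) < prob
  if (any(hit))
    M[cbind(offset[hit] + 1L, read[hit])] <-
      charToRaw(paste(new_base[hit], collapse = ""))
  M
}

## sequencing errors: each base flips to one of the other three
apply_errors <- function(M, error_rate) {
  idx <- which(stats::runif(length(M)) < error_rate)
  if (length(idx)) {
    cur <- match(M[idx], RAW_BASES)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    M[idx] <- RAW_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  M
}

## two-component quality strings for n_reads reads of length L
draw_quals <- function(n_bases, qm) {
  low <- stats::runif(n_bases) < qm$p_low
  q <- integer(n_bases)
  q[low] <- sample(qm$q_low[1]:qm$q_low[2], sum(low), replace = TRUE)
  q[!low] <- sample(qm$q_high[1]:qm$q_high[2], sum(!low), replace = TRUE)
  q
}

raw_to_strings <- function(M) {
  L <- nrow(M); n <- ncol(M)
  big <- rawToChar(as.vector(M))
  substring(big, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
}

#' Simulate a matched DNA/RNA editing dataset with ground truth
#'
#' Generates random coding ORFs, places context-biased editing sites with
#' per-site levels and heterozygous SNPs, and emits already-aligned DNA and
#' per-tissue RNA reads (bypassing an aligner, so the output is deterministic
#' given the seed): RNA reads carry G at edited positions with the per-site,
#' per-tissue probability; both DNA and RNA reads carry either allele of a
#' heterozygous SNP with probability 1/2; sequencing errors hit every base
#' with `error_rate` and base qualities follow the two-component model.
#' When `intron_rate > 0`, affected ORFs get one intron in their genomic
#' locus and DNA reads spanning the junction are emitted soft-clipped
#' (reads anchored with fewer than 20 aligned bases, or falling entirely
#' within the intron, are dropped as unmappable).
#'
#' @param config A [sim_config].
#' @return List with `orfs` (an [orf_set]), `dna` (an [alignment_table]),
#'   `rna` (named list of [alignment_table], one per tissue), and `truth`
#'   (list `edited_sites` — `orf_id`, `pos`, `level`, plus one
#'   `level_<tissue>` column per tissue —, `snp_sites`, `introns`).
#' @export
simulate_dataset <- function(config) {
  check_that(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  seqs <- random_orfs(cfg$n_orfs, cfg$orf_length)
  orfs <- orf_set(seqs)
  L <- 3L * cfg$orf_length
  rl <- cfg$read_length

  ## --- truth: editing sites (context-weighted), SNPs, introns ------------
  elig <- orf_a_contexts(orfs)
  w <- cfg$context_bias[cbind(elig$five, elig$three)]
  n_edit <- min(round(sum(nchar(seqs)) / 1000 * cfg$editing_site_density),
                sum(w > 0))
  edited <- elig[sample.int(nrow(elig), n_edit, prob = w)][order(orf_id, pos)]
  edited[, level := draw_levels(cfg$level_distribution, .N)]
  tissue_names <- sprintf("t%d", seq_len(cfg$n_tissues))
  for (ti in seq_len(cfg$n_tissues))
    edited[, (paste0("level_", tissue_names[ti])) :=
             pmin(1, level * cfg$tissue_level_effects[ti])]

  cdspos <- orf_cds_positions(orfs)
  is_snp <- stats::runif(nrow(cdspos)) < cfg$snp_het_rate
  snps <- cdspos[is_snp][!edited, on = c("orf_id", "pos")]
  if (nrow(snps) > 0) {
    snps[, alt := vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")]
  } else snps[, alt := character(0)]

  introns <- data.table::data.table(orf_id = character(0), pos = integer(0),
                                    seq = character(0))
  if (cfg$intron_rate > 0) {
    has <- stats::runif(cfg$n_orfs) < cfg$intron_rate
    if (any(has)) {
      ipos <- sample(40:(L - 40), sum(has), replace = TRUE)
      iseq <- vapply(seq_len(sum(has)), function(i)
        paste(sample(BASES, cfg$intron_length, replace = TRUE),
              collapse = ""), "")
      introns <- data.table::data.table(orf_id = names(seqs)[has],
                                        pos = ipos, seq = iseq)
    }
  }

  qm <- cfg$quality_model

  ## uniform read starts over one ORF; returns read-level table
  draw_starts <- function(orf_names, lens, coverage) {
    n_reads <- pmax(1L, as.integer(ceiling(coverage * lens / rl)))
    data.table::data.table(
      orf_id = rep(orf_names, n_reads),
      start = unlist(lapply(seq_along(orf_names), function(i)
        sample.int(lens[i] - rl + 1L, n_reads[i], replace = TRUE) - 1L)))
  }

  ## build an alignment table from read frames on a given sequence set,
  ## with site/SNP events expressed in that coordinate system
  make_reads <- function(frames, seqset, events, prefix) {
    n <- nrow(frames)
    if (n == 0)
      return(alignment_table(character(0), character(0), integer(0),
                             integer(0), integer(0), character(0),
                             character(0), character(0)))
    reads <- substring(seqset[frames$orf_id], frames$start + 1L,
                       frames$start + rl)
    M <- matrix(charToRaw(paste(reads, collapse = "")), nrow = rl)
    frames[, read := .I]
    frames[, end := start + rl - 1L]
    for (ev in events) {
      if (nrow(ev) == 0) next
      hit <- ev[frames, on = .(orf_id, pos >= start, pos <= end),
                nomatch = NULL,
                .(read = i.read, offset = x.pos - i.start, prob, new_base)]
      M <- apply_events(M, hit$read, hit$offset, hit$prob, hit$new_base)
    }
    M <- apply_errors(M, cfg$error_rate)
    q <- draw_quals(rl * n, qm)
    Q <- matrix(as.raw(q + 33L), nrow = rl)
    mapq <- rep(60L, n)
    if (cfg$nonunique_rate > 0)
      mapq[stats::runif(n) < cfg$nonunique_rate] <- 10L
    alignment_table(
      read_id = sprintf("%s_r%06d", prefix, seq_len(n)),
      orf_id = frames$orf_id, start = frames$align_start %||% frames$start,
      mapq = mapq, flag = 0L,
      cigar = frames$cigar %||% sprintf("%dM", rl),
      seq = raw_to_strings(M), qual = raw_to_strings(Q))
  }

  snp_events <- if (nrow(snps) > 0)
    snps[, .(orf_id, pos, prob = 0.5, new_base = alt)]
  else data.table::data.table(orf_id = character(0), pos = integer(0),
                              prob = numeric(0), new_base = character(0))

  ## --- RNA reads per tissue ---------------------------------------------
  lens <- setNames(nchar(seqs), names(seqs))
  rna <- list()
  for (ti in seq_len(cfg$n_tissues)) {
    frames <- draw_starts(names(seqs), lens, cfg$rna_coverage)
    edit_events <- edited[, .(orf_id, pos,
                              prob = get(paste0("level_",
                                                tissue_names[ti])),
                              new_base = "G")]
    rna[[tissue_names[ti]]] <-
      make_reads(frames, seqs, list(edit_events, snp_events),
                 paste0("rna_", tissue_names[ti]))
  }

  ## --- DNA reads ---------------------------------------------------------
  plain_orfs <- setdiff(names(seqs), introns$orf_id)
  dna_parts <- list()
  if (length(plain_orfs) > 0 && cfg$dna_coverage > 0) {
    frames <- draw_starts(plain_orfs, lens[plain_orfs], cfg$dna_coverage)
    dna_parts$plain <- make_reads(frames, seqs, list(snp_events), "dna")
  }
  if (nrow(introns) > 0 && cfg$dna_coverage > 0) {
    dna_parts$intronic <- simulate_intron_dna(cfg, seqs, introns,
                                              snp_events, qm)
  }
  dna <- if (length(dna_parts) > 0) data.table::rbindlist(dna_parts)
         else make_reads(data.table::data.table(orf_id = character(0),
                                                start = integer(0)),
                         seqs, list(), "dna")
  data.table::setattr(dna, "class",
                      c("alignment_table", class(data.table::data.table())))

  truth <- list(
    edited_sites = edited[, c("orf_id", "pos", "five", "three", "level",
                              paste0("level_", tissue_names)),
                          with = FALSE],
    snp_sites = snps[, .(orf_id, pos, ref, alt)],
    introns = introns)
  list(orfs = orfs, dna = dna[], rna = rna, truth = truth,
       config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## DNA reads over intron-containing loci: reads are drawn from the genomic
## sequence (exon1 + intron + exon2) and mapped back to ORF coordinates with
## soft clips at the junction; reads anchored < 20 nt or entirely intronic
## are dropped as unmappable.
simulate_intron_dna <- function(cfg, seqs, introns, snp_events, qm,
                                min_anchor = 20L) {
  rl <- cfg$read_length
  frames_list <- vector("list", nrow(introns))
  gseqs <- character(nrow(introns))
  for (i in seq_len(nrow(introns))) {
    oid <- introns$orf_id[i]
    ipos <- introns$pos[i]
    ilen <- nchar(introns$seq[i])
    oseq <- seqs[[oid]]
    gseq <- paste0(substr(oseq, 1, ipos), introns$seq[i],
                   substr(oseq, ipos + 1, nchar(oseq)))
    gseqs[i] <- gseq
    GL <- nchar(gseq)
    n <- max(1L, as.integer(ceiling(cfg$dna_coverage * GL / rl)))
    g <- sample.int(GL - rl + 1L, n, replace = TRUE) - 1L
    a <- pmax(0L, pmin(ipos - g, rl))          # aligned exon1 bases
    b <- pmax(0L, pmin(g + rl - (ipos + ilen), rl))  # aligned exon2 bases
    type <- data.table::fifelse(
      a == rl, "plain1",
      data.table::fifelse(b == rl, "plain2",
        data.table::fifelse(a == 0L & b == 0L, "drop",
          data.table::fifelse(a >= b, "clip3", "clip5"))))
    keep <- !(type == "drop" | (type == "clip3" & a < min_anchor) |
                (type == "clip5" & b < min_anchor))
    fr <- data.table::data.table(orf_id = oid, gstart = g[keep],
                                 a = a[keep], b = b[keep],
                                 type = type[keep], ipos = ipos,
                                 ilen = ilen)
    frames_list[[i]] <- fr
  }
  frames <- data.table::rbindlist(frames_list)
  if (nrow(frames) == 0)
    return(alignment_table(character(0), character(0), integer(0),
                           integer(0), integer(0), character(0),
                           character(0), character(0)))
  frames[, align_start := data.table::fifelse(
    type == "plain1", gstart,
    data.table::fifelse(type == "plain2", gstart - ilen,
      data.table::fifelse(type == "clip3", gstart, ipos)))]
  frames[, cigar := data.table::fifelse(
    type %in% c("plain1", "plain2"), sprintf("%dM", rl),
    data.table::fifelse(type == "clip3", sprintf("%dM%dS", a, rl - a),
                        sprintf("%dS%dM", rl - b, b)))]
  names(gseqs) <- introns$orf_id

  ## genomic-coordinate SNP events for these loci
  snp_g <- snp_events[orf_id %in% introns$orf_id]
  if (nrow(snp_g) > 0) {
    m <- match(snp_g$orf_id, introns$orf_id)
    snp_g[, pos := pos + data.table::fifelse(pos >= introns$pos[m],
                                             nchar(introns$seq[m]), 0L)]
  }
  fr2 <- frames[, .(orf_id, start = gstart, align_start, cigar)]
  n <- nrow(fr2)
  reads <- substring(gseqs[fr2$orf_id], fr2$start + 1L, fr2$start + rl)
  M <- matrix(charToRaw(paste(reads, collapse = "")), nrow = rl)
  fr2[, read := .I]
  fr2[, end := start + rl - 1L]
  if (nrow(snp_g) > 0) {
    hit <- snp_g[fr2, on = .(orf_id, pos >= start, pos <= end),
                 nomatch = NULL,
                 .(read = i.read, offset = x.pos - i.start, prob, new_base)]
    M <- apply_events(M, hit$read, hit$offset, hit$prob, hit$new_base)
  }
  M <- apply_errors(M, cfg$error_rate)
  Q <- matrix(as.raw(draw_quals(rl * n, qm) + 33L), nrow = rl)
  mapq <- rep(60L, n)
  if (cfg$nonunique_rate > 0)
    mapq[stats::runif(n) < cfg$nonunique_rate] <- 10L
  alignment_table(
    read_id = sprintf("dnaJ_r%06d", seq_len(n)),
    orf_id = fr2$orf_id, start = fr2$align_start, mapq = mapq, flag = 0L,
    cigar = fr2$cigar, seq = raw_to_strings(M), qual = raw_to_strings(Q))
}

#' Majority-vote consensus from RNA reads
#'
#' Stands in for de novo assembly: per position, the most frequent RNA base
#' (all bases, no quality filter — assembly sees every read) replaces the
#' reference; ties and zero-coverage positions keep the reference base.
#' Sites with true editing level above 0.5 thereby become G in the consensus,
#' turning them into strong-site candidates.
#'
#' @param orfs The [orf_set] the reads are aligned to.
#' @param rna An [alignment_table] or list of them (pooled).
#' @return A new [orf_set] with the consensus sequences (same CDS table).
#' @export
build_consensus_from_rna <- function(orfs, rna) {
  if (inherits(rna, "data.frame")) rna <- list(rna)
  b <- data.table::rbindlist(lapply(rna, function(a)
    expand_alignments(data.table::as.data.table(a))))
  b <- b[base %chin% BASES]
  newseqs <- orfs$seq
  if (nrow(b) > 0) {
    cnt <- b[, .N, by = .(orf_id, pos, base)]
    wide <- data.table::dcast(cnt, orf_id + pos ~ base, value.var = "N",
                              fill = 0L)
    for (cc in BASES) if (!cc %in% names(wide)) wide[, (cc) := 0L]
    cm <- as.matrix(wide[, BASES, with = FALSE])
    refchars <- lapply(orfs$seq, function(s)
      strsplit(s, "", fixed = TRUE)[[1]])
    wide[, ref := refchars[[orf_id[1]]][pos + 1L], by = orf_id]
    mx <- apply(cm, 1, max)
    ref_idx <- match(wide$ref, BASES)
    ref_cnt <- cm[cbind(seq_len(nrow(cm)), ifelse(is.na(ref_idx), 1L,
                                                  ref_idx))]
    ref_is_max <- !is.na(ref_idx) & ref_cnt == mx
    winner <- ifelse(ref_is_max, wide$ref, BASES[max.col(cm, "first")])
    wide[, new := winner]
    changed <- wide[new != ref]
    for (oid in unique(changed$orf_id)) {
      ch <- refchars[[oid]]
      rows <- changed[orf_id == oid]
      ch[rows$pos + 1L] <- rows$new
      newseqs[[oid]] <- paste(ch, collapse = "")
    }
  }
  orf_set(newseqs, orfs$cds)
}
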