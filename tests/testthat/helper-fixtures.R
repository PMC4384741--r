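## Shared fixtures and independent brute-force oracles.
## Fixtures are built in code; the heavier simulated datasets are memoised so
## several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## default-condition simulated dataset (the headline integration fixture)
default_sim <- function() cached("default_sim", {
  simulate_dataset(sim_config(seed = 42))
})

## quality string of constant Phred q
qstr <- function(q, n) strrep(rawToChar(as.raw(q + 33L)), n)

## hand-build an alignment table from read strings (all mapq 60, cigar all-M
## unless given)
make_aln <- function(orf_id, start, seq, qual = NULL, cigar = NULL,
                     mapq = 60L, prefix = "r") {
  n <- length(seq)
  if (is.null(qual)) qual <- vapply(nchar(seq), function(L) qstr(40, L), "")
  if (is.null(cigar)) cigar <- sprintf("%dM", nchar(seq))
  alignment_table(read_id = sprintf("%s%03d", prefix, seq_len(n)),
                  orf_id = rep_len(orf_id, n), start = start,
                  mapq = rep_len(mapq, n), flag = 0L, cigar = cigar,
                  seq = seq, qual = qual)
}

## ---- brute-force pileup recount (loops over reads and positions) --------
brute_pileup_counts <- function(orfs, aln, q_min = 30) {
  out <- list()
  keep <- aln[aln$mapq == max(aln$mapq), ]
  for (i in seq_len(nrow(keep))) {
    sq <- strsplit(keep$seq[i], "")[[1]]
    qu <- utf8ToInt(keep$qual[i]) - 33L
    ## all-M cigars only (fixture constraint)
    stopifnot(grepl("^[0-9]+M$", keep$cigar[i]))
    for (j in seq_along(sq)) {
      p <- keep$start[i] + j - 1L
      if (qu[j] < q_min || !sq[j] %in% c("A", "C", "G", "T")) next
      k <- paste(keep$orf_id[i], p, sq[j])
      out[[k]] <- (out[[k]] %||% 0L) + 1L
    }
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- brute-force weak/strong calling ------------------------------------
## Operates on a pileup data.frame; direct enumeration with hand-rolled
## binomial tail sums and an explicit step-up loop, sharing no code with the
## package's callers.
brute_binom_upper <- function(k, n, p) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

brute_stepup <- function(p, fdr) {
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * fdr / m) kmax <- k
  rej <- rep(FALSE, m)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}

brute_weak_calls <- function(pu, error_prob = 0.001, fdr = 0.10,
                             tol = 0, min_dna = 0) {
  pu <- as.data.frame(pu)
  rows <- list()
  for (i in seq_len(nrow(pu))) {
    if (!pu$ref[i] %in% c("A", "C", "G", "T")) next
    if (pu$rna_total[i] == 0) next
    for (alt in setdiff(c("A", "C", "G", "T"), pu$ref[i])) {
      k <- pu[[paste0("rna_", alt)]][i]
      rows[[length(rows) + 1]] <- data.frame(
        i = i, alt = alt, k = k,
        p = brute_binom_upper(k, pu$rna_total[i], error_prob))
    }
  }
  if (!length(rows)) return(data.frame())
  h <- do.call(rbind, rows)
  h$rej <- brute_stepup(h$p, fdr)
  h <- h[h$rej & h$k > 0, , drop = FALSE]
  keep <- logical(nrow(h))
  for (r in seq_len(nrow(h))) {
    i <- h$i[r]
    disc <- pu$dna_total[i] - pu[[paste0("dna_", pu$ref[i])]][i]
    frac <- if (pu$dna_total[i] > 0) disc / pu$dna_total[i] else 0
    keep[r] <- frac <= tol && pu$dna_total[i] >= min_dna
  }
  h <- h[keep, , drop = FALSE]
  data.frame(orf_id = pu$orf_id[h$i], pos = pu$pos[h$i],
             ref = pu$ref[h$i], alt = h$alt, p = h$p)
}

brute_strong_calls <- function(pu, snp_prior = 0.001, fdr = 0.10,
                               support = "any") {
  pu <- as.data.frame(pu)
  rows <- list()
  for (i in seq_len(nrow(pu))) {
    if (!pu$ref[i] %in% c("A", "C", "G", "T")) next
    if (pu$dna_total[i] < 1) next
    for (b in setdiff(c("A", "C", "G", "T"), pu$ref[i])) {
      if (pu[[paste0("dna_", b)]][i] == pu$dna_total[i]) {
        rows[[length(rows) + 1]] <- data.frame(
          i = i, dna_base = b, p = snp_prior * 0.5^pu$dna_total[i])
      }
    }
  }
  if (!length(rows)) return(data.frame())
  h <- do.call(rbind, rows)
  h$rej <- brute_stepup(h$p, fdr)
  h <- h[h$rej, , drop = FALSE]
  keep <- logical(nrow(h))
  for (r in seq_len(nrow(h))) {
    i <- h$i[r]
    keep[r] <- if (support == "any") pu$rna_total[i] > 0
               else pu[[paste0("rna_", pu$ref[i])]][i] > 0
  }
  h <- h[keep, , drop = FALSE]
  data.frame(orf_id = pu$orf_id[h$i], pos = pu$pos[h$i],
             ref = h$dna_base, alt = pu$ref[h$i], p = h$p)
}

## random tiny pileup fixture: <= n_pos positions x <= n_reads reads
random_tiny_pileup <- function(seed, n_pos = 12, n_reads = 20) {
  set.seed(seed)
  L <- n_pos
  refseq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  orfs <- orf_set(setNames(refseq, "tiny"))
  mut <- function(s, rate, alt_pool = c("A", "C", "G", "T")) {
    ch <- strsplit(s, "")[[1]]
    flip <- runif(length(ch)) < rate
    ch[flip] <- vapply(ch[flip], function(b)
      sample(setdiff(alt_pool, b), 1), "")
    paste(ch, collapse = "")
  }
  nr <- sample.int(n_reads, 1)
  nd <- sample.int(8, 1)
  rna <- make_aln("tiny", rep(0L, nr),
                  vapply(seq_len(nr), function(i) mut(refseq, 0.15), ""),
                  qual = vapply(seq_len(nr), function(i)
                    paste(sample(c(qstr(40, 1), qstr(20, 1)), L, TRUE,
                                 prob = c(0.9, 0.1)), collapse = ""), ""),
                  prefix = "rna")
  dna <- make_aln("tiny", rep(0L, nd),
                  vapply(seq_len(nd), function(i) mut(refseq, 0.05), ""),
                  prefix = "dna")
  list(orfs = orfs, rna = rna, dna = dna)
}
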