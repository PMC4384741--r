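#' Infer intron positions from soft-clipped DNA reads
#'
#' DNA reads spanning an exon--exon junction of the (intron-containing)
#' genomic locus align to the transcriptome ORF only partially; the local
#' aligner clips the overhanging flank. The procedure: (a) record every DNA
#' read whose beginning or end was clipped; (b) discard flanks that can be
#' aligned against the ORF set (exact scan of the first `seed_len` clipped
#' bases, both orientations of the set's forward strand are not considered —
#' ORFs are mRNA models); (c) report every (ORF, position, side) where at
#' least `min_support` reads show the same clipped flank starting at the
#' same position.
#'
#' Flank identity is tested on the first `min(flank_len, length)` clipped
#' bases adjacent to the junction; shorter flanks are grouped with longer
#' ones sharing that prefix.
#'
#' @param dna An [alignment_table] of DNA reads.
#' @param orfs An [orf_set].
#' @param min_support Minimum identical-flank read count (default 3).
#' @param flank_len Flank comparison length (default 20).
#' @param seed_len Exact-match seed length for the realignability filter
#'   (default 20); flanks shorter than this cannot be cleared and are kept.
#' @return data.table: `orf_id`, `pos` (0-based junction position: first
#'   reference base after the clip for prefix clips, first unaligned base
#'   for suffix clips), `side` (`"5prime"` clip before the alignment,
#'   `"3prime"` after), `flank` (adjacent-first clipped bases), `support`.
#' @export
infer_junctions <- function(dna, orfs, min_support = 3, flank_len = 20,
                            seed_len = 20) {
  at <- soft_clips(data.table::as.data.table(dna))
  at[, rw := GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)]
  rev_chars <- function(s) vapply(s, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
  pre <- at[nchar(clip_prefix) > 0,
            .(orf_id, pos = start, side = "5prime",
              ## adjacent-first: last clipped base is next to the junction
              flank = rev_chars(clip_prefix))]
  suf <- at[nchar(clip_suffix) > 0,
            .(orf_id, pos = start + rw, side = "3prime",
              flank = clip_suffix)]
  cand <- data.table::rbindlist(list(pre, suf))
  if (nrow(cand) == 0)
    return(data.table::data.table(orf_id = character(0), pos = integer(0),
                                  side = character(0), flank = character(0),
                                  support = integer(0)))
  cand[, kstr := substr(flank, 1L, flank_len)]
  ## group; merge shorter flanks that are prefixes of a longer key
  grp <- cand[, .(support = .N), by = .(orf_id, pos, side, kstr)]
  grp <- grp[, {
    k <- kstr; n <- support
    full <- k[nchar(k) == max(nchar(k))]
    if (length(k) > 1) {
      tgt <- vapply(k, function(x) {
        cands <- k[startsWith(k, x)]
        cands[which.max(nchar(cands))]
      }, "")
      agg <- tapply(n, tgt, sum)
      data.table::data.table(kstr = names(agg), support = as.integer(agg))
    } else data.table::data.table(kstr = k, support = n)
  }, by = .(orf_id, pos, side)]
  out <- grp[support >= min_support]
  if (nrow(out) == 0)
    return(data.table::data.table(orf_id = character(0), pos = integer(0),
                                  side = character(0), flank = character(0),
                                  support = integer(0)))
  ## realignability filter: drop flanks whose seed matches the ORF set.
  ## For 5' clips the stored flank is adjacent-first (reversed), so the
  ## genomic-orientation seed is the reversed key.
  seedseq <- data.table::fifelse(out$side == "5prime",
                                 rev_chars(out$kstr), out$kstr)
  seedseq <- substr(seedseq, 1L, seed_len)
  long_enough <- nchar(seedseq) >= seed_len
  subj <- Biostrings::DNAStringSet(orfs$seq)
  hits <- vapply(seq_along(seedseq), function(i) {
    if (!long_enough[i]) return(FALSE)
    sum(Biostrings::vcountPattern(seedseq[i], subj)) > 0
  }, logical(1))
  out <- out[!hits]
  data.table::setnames(out, "kstr", "flank")
  data.table::setcolorder(out, c("orf_id", "pos", "side", "flank",
                                 "support"))
  data.table::setorder(out, orf_id, pos, side)
  out[]
}

#' Catalog regions where gDNA and cDNA amplify differentially
#'
#' For each inferred junction, the window of the ORF around it within which
#' an intron-spanning (gDNA-specific) or junction-spanning (cDNA-specific)
#' primer could be placed, together with the editing sites the window
#' contains.
#'
#' @param junctions Output of [infer_junctions].
#' @param sites Site table.
#' @param window Half-width of the region around the junction (nt,
#'   default 200).
#' @return List with `regions` (data.table: junction columns plus
#'   `region_start`, `region_end`, `n_sites`, `gdna_primer_possible`,
#'   `cdna_primer_possible`), `region_sites` (sites with `region_id`), and
#'   `fraction_sites_in_regions`.
#' @export
primer_region_catalog <- function(junctions, sites, window = 200) {
  j <- data.table::as.data.table(junctions)
  s <- data.table::as.data.table(sites)
  if (nrow(j) == 0)
    return(list(regions = data.table::data.table(),
                region_sites = data.table::data.table(),
                fraction_sites_in_regions = 0))
  j[, region_id := seq_len(.N)]
  j[, `:=`(region_start = pmax(0L, pos - as.integer(window)),
           region_end = pos + as.integer(window))]
  ## a junction with a recovered intron flank supports both primer designs:
  ## gDNA primers sit in the intron, cDNA primers span the junction
  j[, `:=`(gdna_primer_possible = nchar(flank) > 0,
           cdna_primer_possible = TRUE)]
  if (nrow(s) > 0) {
    hits <- s[j, on = .(orf_id, pos >= region_start, pos < region_end),
              nomatch = NULL,
              .(region_id = i.region_id, orf_id, pos = x.pos,
                mismatch_type = x.mismatch_type)]
  } else {
    hits <- data.table::data.table(region_id = integer(0),
                                   orf_id = character(0), pos = integer(0),
                                   mismatch_type = character(0))
  }
  nh <- hits[, .(n_sites = .N), by = region_id]
  j <- nh[j, on = "region_id"]
  j[is.na(n_sites), n_sites := 0L]
  frac <- if (nrow(s) > 0)
    mean(paste(s$orf_id, s$pos) %in% paste(hits$orf_id, hits$pos)) else 0
  data.table::setcolorder(j, c("region_id", "orf_id", "pos", "side",
                               "flank", "support", "region_start",
                               "region_end", "n_sites"))
  list(regions = j[], region_sites = hits[],
       fraction_sites_in_regions = frac)
}

#' Write junctions as a BED-like table
#'
#' Columns: `orf_id`, `pos`, `pos + 1` (0-based half-open), `flank`,
#' `support`, `side`.
#'
#' @param junctions Output of [infer_junctions].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  j <- data.table::as.data.table(junctions)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", j$orf_id, j$pos, j$pos + 1L,
                   j$flank, j$support, j$side)
  writeLines(lines, path)
  invisible(path)
}
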