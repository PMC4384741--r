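#' Build quality-filtered RNA/DNA pileups over ORF coding regions
#'
#' Tallies, for every coding position covered by at least one read, the number
#' of uniquely-aligned RNA and DNA bases of each nucleotide with base quality
#' `>= q_min` (bases below the cutoff are discarded, default Q30). Positions
#' under a deletion contribute nothing and inserted bases are ignored — only
#' substitutions are considered. Read ends are *not* trimmed by default
#' (`trim_ends = 0`); the RNA mismatch read-offset record is kept for QC.
#'
#' @param orfs An [orf_set].
#' @param rna An [alignment_table] of RNA reads, or a list of them (pooled).
#' @param dna Optional [alignment_table] of DNA reads.
#' @param q_min Minimum base quality (Phred) for a base to be counted.
#' @param unique_only Apply the maximal-mapping-quality unique filter to each
#'   input table (a no-op on tables already filtered at read time).
#' @param min_mapq Optional explicit mapping-quality cutoff.
#' @param trim_ends Ignore bases within this many positions of either read
#'   end (off by default).
#' @return A `pileup`: a `data.table` with columns `orf_id`, `pos` (0-based),
#'   `ref`, `rna_A`..`rna_T`, `rna_total`, `dna_A`..`dna_T`, `dna_total`,
#'   sorted by (`orf_id`, `pos`), with attribute `mismatch_offsets` (a
#'   data.table of RNA mismatch read offsets: `orf_id`, `pos`, `ref`, `base`,
#'   `read_off`) for QC.
#' @export
build_pileup <- function(orfs, rna, dna = NULL, q_min = 30, unique_only = TRUE,
                         min_mapq = NULL, trim_ends = 0) {
  tally <- function(aln_list, prefix) {
    if (is.null(aln_list)) aln_list <- list()
    if (inherits(aln_list, "data.frame")) aln_list <- list(aln_list)
    parts <- lapply(aln_list, function(a) {
      a <- filter_unique(data.table::as.data.table(a),
                         unique_only = unique_only, min_mapq = min_mapq)
      b <- expand_alignments(a)
      b <- b[qual >= q_min & base %chin% BASES]
      if (trim_ends > 0) {
        rl <- nchar(a$seq)[b$rec]
        b <- b[b$read_off >= trim_ends & b$read_off < rl - trim_ends]
      }
      b
    })
    out <- data.table::rbindlist(parts)
    if (ncol(out) == 0)
      out <- data.table::data.table(rec = integer(0), orf_id = character(0),
                                    pos = integer(0), read_off = integer(0),
                                    base = character(0), qual = integer(0))
    out
  }
  rna_b <- tally(rna, "rna")
  dna_b <- tally(dna, "dna")
  bases <- data.table::rbindlist(list(
    rna_b[, .(orf_id, pos, read_off, base, is_rna = TRUE)],
    dna_b[, .(orf_id, pos, read_off, base, is_rna = FALSE)]))
  if (nrow(bases) == 0) return(empty_pileup())

  ## restrict to CDS
  cds <- data.table::as.data.table(orfs$cds)
  bases <- cds[bases, on = "orf_id", nomatch = NULL
               ][pos >= cds_start & pos < cds_end,
                 .(orf_id, pos, read_off, base, is_rna)]
  if (nrow(bases) == 0) return(empty_pileup())

  cnt <- bases[, .N, by = .(orf_id, pos, base, is_rna)]
  cnt[, col := paste0(data.table::fifelse(is_rna, "rna_", "dna_"), base)]
  wide <- data.table::dcast(cnt, orf_id + pos ~ col, value.var = "N",
                            fill = 0L)
  for (cc in c(paste0("rna_", BASES), paste0("dna_", BASES)))
    if (!cc %in% names(wide)) wide[, (cc) := 0L]
  wide[, rna_total := rna_A + rna_C + rna_G + rna_T]
  wide[, dna_total := dna_A + dna_C + dna_G + dna_T]

  ## reference base per position
  refchars <- lapply(orfs$seq, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  wide[, ref := refchars[[orf_id[1]]][pos + 1L], by = orf_id]
  data.table::setcolorder(wide, c("orf_id", "pos", "ref",
                                  paste0("rna_", BASES), "rna_total",
                                  paste0("dna_", BASES), "dna_total"))
  data.table::setkeyv(wide, c("orf_id", "pos"))

  ## RNA mismatch read offsets for QC
  mm <- bases[(is_rna)]
  if (nrow(mm) > 0) {
    mm[, ref := refchars[[orf_id[1]]][pos + 1L], by = orf_id]
    mm <- mm[base != ref & ref %chin% BASES,
             .(orf_id, pos, ref, base, read_off)]
    data.table::setorder(mm, orf_id, pos, base, read_off)
  } else {
    mm <- data.table::data.table(orf_id = character(0), pos = integer(0),
                                 ref = character(0), base = character(0),
                                 read_off = integer(0))
  }
  data.table::setattr(wide, "mismatch_offsets", mm)
  data.table::setattr(wide, "class", c("pileup", class(data.table::data.table())))
  wide[]
}

empty_pileup <- function() {
  w <- data.table::data.table(orf_id = character(0), pos = integer(0),
                              ref = character(0))
  for (cc in c(paste0("rna_", BASES), "rna_total",
               paste0("dna_", BASES), "dna_total")) w[, (cc) := integer(0)]
  data.table::setattr(w, "mismatch_offsets",
                      data.table::data.table(orf_id = character(0),
                                             pos = integer(0),
                                             ref = character(0),
                                             base = character(0),
                                             read_off = integer(0)))
  data.table::setattr(w, "class", c("pileup", class(data.table::data.table())))
  w[]
}

#' Histogram of mismatch positions inside reads
#'
#' Counts RNA mismatches as a function of the 0-based offset inside the read,
#' per mismatch type. A QC display only — no filtering is derived from it
#' (read ends are deliberately not trimmed by the detection pipeline).
#'
#' @param pileup A [build_pileup] result.
#' @return data.table with columns `mismatch_type`, `read_off`, `count`.
#' @export
mismatch_read_position_histogram <- function(pileup) {
  mm <- attr(pileup, "mismatch_offsets")
  if (is.null(mm) || nrow(mm) == 0)
    return(data.table::data.table(mismatch_type = character(0),
                                  read_off = integer(0), count = integer(0)))
  h <- mm[, .(count = .N), by = .(mismatch_type = paste0(ref, ">", base),
                                  read_off)]
  data.table::setkeyv(h, c("mismatch_type", "read_off"))
  h[]
}

#' Dump a pileup as TSV
#'
#' Positions are written 1-based inclusive (stated in the header).
#'
#' @param pileup A [build_pileup] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  out <- data.table::as.data.table(pileup)
  out[, pos := pos + 1L]
  hdr <- paste0("#", paste(names(out), collapse = "\t"),
                "  (pos is 1-based inclusive)")
  writeLines(hdr, path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}
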