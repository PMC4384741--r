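#' Alignment tables
#'
#' Reads aligned against the ORF set are carried as a plain `data.table` with
#' one row per alignment record and columns `read_id`, `orf_id`, `start`
#' (0-based leftmost aligned reference position), `mapq`, `flag`, `cigar`,
#' `seq` (full read sequence, soft-clipped bases included) and `qual`
#' (Phred+33 string). Mate pairs are treated as independent reads.
#'
#' @param read_id,orf_id,start,mapq,flag,cigar,seq,qual Per-record vectors.
#' @return An `alignment_table` (a `data.table`).
#' @export
alignment_table <- function(read_id, orf_id, start, mapq, flag, cigar,
                            seq, qual) {
  at <- data.table::data.table(
    read_id = as.character(read_id), orf_id = as.character(orf_id),
    start = as.integer(start), mapq = as.integer(mapq),
    flag = as.integer(flag), cigar = as.character(cigar),
    seq = as.character(seq), qual = as.character(qual))
  check_that(all(at$start >= 0, na.rm = TRUE), "negative alignment start")
  check_that(all(nchar(at$seq) == nchar(at$qual)),
             "seq and qual lengths differ")
  data.table::setattr(at, "class",
                      c("alignment_table", class(data.table::data.table())))
  at[]
}

#' Read alignments from a SAM/BAM file
#'
#' Unmapped records are dropped. With `unique_only = TRUE` (the default),
#' records below the maximal mapping quality observed in the file are
#' discarded — the aligner-agnostic operationalization of "uniquely aligned";
#' `min_mapq` overrides that with an explicit cutoff. Records referencing
#' sequences absent from `orfs` are skipped with a counted warning.
#'
#' @param path SAM (text) or BAM file.
#' @param orfs Optional [orf_set] used to validate reference names.
#' @param unique_only Keep only maximal-mapping-quality records.
#' @param min_mapq Optional explicit mapping-quality cutoff (overrides
#'   `unique_only`'s max rule).
#' @return An [alignment_table].
#' @export
read_alignments <- function(path, orfs = NULL, unique_only = TRUE,
                            min_mapq = NULL) {
  check_that(file.exists(path), paste0("no such file: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  keep <- !is.na(res$pos) & !bitwAnd(res$flag, 4L)
  at <- alignment_table(read_id = res$qname[keep],
                        orf_id = as.character(res$rname[keep]),
                        start = res$pos[keep] - 1L,
                        mapq = res$mapq[keep], flag = res$flag[keep],
                        cigar = res$cigar[keep],
                        seq = as.character(res$seq[keep]),
                        qual = as.character(res$qual[keep]))
  if (!is.null(orfs)) {
    unknown <- !(at$orf_id %in% names(orfs$seq))
    if (any(unknown)) {
      warning(sum(unknown), " record(s) reference sequences absent from the ",
              "ORF set; skipped")
      at <- at[!unknown]
    }
  }
  filter_unique(at, unique_only = unique_only, min_mapq = min_mapq)
}

## apply the unique-alignment filter to an alignment table
filter_unique <- function(at, unique_only = TRUE, min_mapq = NULL) {
  if (!is.null(min_mapq)) return(at[mapq >= min_mapq])
  if (unique_only && nrow(at) > 0) return(at[mapq == max(at$mapq)])
  at
}

#' Write an alignment table as SAM
#'
#' Emits a valid SAM file (with `@SQ` header lines from `orfs`) so simulated
#' alignments can round-trip through standard tooling.
#'
#' @param aln An [alignment_table].
#' @param orfs The [orf_set] the alignments refer to.
#' @param path Output file (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, orfs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(orfs$seq), nchar(orfs$seq)))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 aln$read_id, aln$flag, aln$orf_id, aln$start + 1L,
                 aln$mapq, aln$cigar, aln$seq, aln$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Soft-clipped flanks of alignment records
#'
#' @param aln An [alignment_table].
#' @return data.table with one row per record: `clip_prefix`, `clip_suffix`
#'   (possibly empty strings) alongside the record columns.
#' @export
soft_clips <- function(aln) {
  ops <- GenomicAlignments::explodeCigarOps(aln$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)
  pre <- mapply(function(o, l) if (length(o) && o[1] == "S") l[1] else 0L,
                ops, lens, USE.NAMES = FALSE)
  suf <- mapply(function(o, l) {
    n <- length(o)
    if (n && o[n] == "S") l[n] else 0L
  }, ops, lens, USE.NAMES = FALSE)
  L <- nchar(aln$seq)
  out <- data.table::as.data.table(aln)
  out[, `:=`(clip_prefix = substr(seq, 1L, pre),
             clip_suffix = substr(seq, L - suf + 1L, L))]
  out[]
}

## Expand alignments to one row per aligned (M/=/X) base.
## Returns data.table: rec (row index into aln), orf_id, pos (0-based ref),
## read_off (0-based offset in the full read, soft clips included),
## base (character), qual (integer Phred).
expand_alignments <- function(aln) {
  n <- nrow(aln)
  if (n == 0)
    return(data.table::data.table(rec = integer(0), orf_id = character(0),
                                  pos = integer(0), read_off = integer(0),
                                  base = character(0), qual = integer(0)))
  ops <- c("M", "=", "X")
  ## local reference-space ranges (1-based within each alignment), shifted
  ## to absolute coordinates with the record start below
  rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(aln$cigar,
                                                            ops = ops)
  rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(
    aln$cigar, ops = ops)   # query space includes soft-clipped bases
  n_rng <- S4Vectors::elementNROWS(rref)
  fr <- unlist(rref, use.names = FALSE)
  fq <- unlist(rqry, use.names = FALSE)
  w <- IRanges::width(fr)
  rng_rec <- rep.int(seq_len(n), n_rng)   # record of each range
  rec <- rep.int(rng_rec, w)              # record of each base
  refpos0 <- sequence(w, from = IRanges::start(fr)) - 1L + aln$start[rec]
  qpos1 <- sequence(w, from = IRanges::start(fq))
  off <- c(0L, cumsum(nchar(aln$seq)))[rec]
  idx <- qpos1 + off
  sraw <- charToRaw(paste(aln$seq, collapse = ""))
  qraw <- charToRaw(paste(aln$qual, collapse = ""))
  ## byte -> base lookup; non-ACGT bases (e.g. N) become NA
  lut <- rep(NA_character_, 256)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- BASES
  data.table::data.table(
    rec = rec,
    orf_id = aln$orf_id[rec],
    pos = refpos0,
    read_off = qpos1 - 1L,
    base = lut[as.integer(sraw[idx]) + 1L],
    qual = as.integer(qraw[idx]) - 33L)
}
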