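#' ORF set: transcriptome open reading frames with coding annotation
#'
#' Container for the de novo transcriptome ORFs that all detection stages work
#' against. Sequences are single-stranded mRNA models (no reverse-complement
#' logic anywhere downstream: A-to-G on the ORF strand is the editing
#' signature). Coordinates are 0-based half-open.
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`) of
#'   ORF sequences; alphabet A/C/G/T/N, `U` normalized to `T`, uppercased.
#' @param cds Optional data.frame with columns `orf_id`, `cds_start`,
#'   `cds_end`, `frame_offset` (0-based half-open, frame in 0..2). Absent rows
#'   (or a `NULL` table) mean the whole sequence is coding in frame 0.
#' @return An object of class `orf_set` with elements `seq` (named character
#'   vector) and `cds` (data.frame, one row per ORF).
#' @export
orf_set <- function(sequences, cds = NULL) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  check_that(is.character(sequences) && length(sequences) > 0 &&
               !is.null(names(sequences)) && !anyNA(names(sequences)),
             "sequences must be a non-empty named character vector")
  sequences <- chartr("u", "t", sequences)
  sequences <- chartr("U", "T", sequences)
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN characters in ORF sequence(s): ",
         paste(head(names(sequences)[bad], 3), collapse = ", "))
  ids <- names(sequences)
  check_that(!anyDuplicated(ids), "duplicated ORF ids")
  len <- nchar(sequences)
  full <- data.frame(orf_id = ids, cds_start = 0L, cds_end = len,
                     frame_offset = 0L, stringsAsFactors = FALSE)
  if (!is.null(cds)) {
    cds <- as.data.frame(cds)
    check_that(all(c("orf_id", "cds_start", "cds_end", "frame_offset")
                   %in% names(cds)), "cds table missing required columns")
    check_that(all(cds$orf_id %in% ids), "cds table names unknown ORF id(s)")
    check_that(!anyDuplicated(cds$orf_id), "duplicated orf_id in cds table")
    m <- match(cds$orf_id, full$orf_id)
    full[m, c("cds_start", "cds_end", "frame_offset")] <-
      cds[, c("cds_start", "cds_end", "frame_offset")]
  }
  check_that(all(full$cds_start >= 0) && all(full$cds_end <= len) &&
               all(full$cds_start <= full$cds_end),
             "CDS bounds outside sequence")
  check_that(all(full$frame_offset %in% 0:2), "frame_offset must be 0, 1 or 2")
  structure(list(seq = sequences, cds = full), class = "orf_set")
}

#' @export
print.orf_set <- function(x, ...) {
  cat("<orf_set> ", length(x$seq), " ORFs, total ",
      sum(nchar(x$seq)), " nt (mean ",
      round(mean(nchar(x$seq))), ")\n", sep = "")
  invisible(x)
}

#' @export
length.orf_set <- function(x) length(x$seq)

#' Read ORF sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is normalized to `T`. An empty file yields
#' an empty ORF set with a warning.
#'
#' @param path FASTA file.
#' @param cds_path Optional companion TSV `orf_id cds_start cds_end
#'   frame_offset` (0-based half-open); when absent the whole sequence is
#'   treated as coding in frame 0.
#' @return An [orf_set].
#' @export
read_orf_fasta <- function(path, cds_path = NULL) {
  check_that(file.exists(path), paste0("no such file: ", path))
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e)
                   stop("FASTA parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (length(ss) == 0) {
    warning("empty FASTA: ", path)
    return(structure(list(seq = setNames(character(0), character(0)),
                          cds = data.frame(orf_id = character(0),
                                           cds_start = integer(0),
                                           cds_end = integer(0),
                                           frame_offset = integer(0))),
                     class = "orf_set"))
  }
  ## keep only the first whitespace-delimited token of each header
  names(ss) <- sub("\\s.*$", "", names(ss))
  cds <- if (!is.null(cds_path)) read_cds_table(cds_path) else NULL
  orf_set(ss, cds)
}

#' Write an ORF set to FASTA
#' @param orfs An [orf_set].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(orfs$seq), path)
  invisible(path)
}

#' Read a coding-frame annotation table
#'
#' TSV with columns `orf_id`, `cds_start`, `cds_end`, `frame_offset`
#' (0-based half-open coordinates). Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_cds_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("orf_id", "cds_start", "cds_end",
                                        "frame_offset"))
  df$cds_start <- as.integer(df$cds_start)
  df$cds_end <- as.integer(df$cds_end)
  df$frame_offset <- as.integer(df$frame_offset)
  df
}

## base at 0-based position(s) of one ORF
orf_base <- function(orfs, orf_id, pos0) {
  s <- orfs$seq[[orf_id]]
  substring(s, pos0 + 1L, pos0 + 1L)
}

## data.table of every position of every ORF's CDS with its reference base:
## columns orf_id, pos (0-based), ref
orf_cds_positions <- function(orfs) {
  cds <- orfs$cds
  out <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    if (cds$cds_end[i] <= cds$cds_start[i]) next
    p <- cds$cds_start[i]:(cds$cds_end[i] - 1L)
    ch <- strsplit(substr(orfs$seq[[cds$orf_id[i]]],
                          cds$cds_start[i] + 1L, cds$cds_end[i]), "",
                   fixed = TRUE)[[1]]
    out[[i]] <- data.table::data.table(orf_id = cds$orf_id[i], pos = p,
                                       ref = ch)
  }
  data.table::rbindlist(out)
}

## All A positions inside CDSs that have both a 5' and a 3' neighbour within
## the ORF, with their neighbours: columns orf_id, pos, five, three.
## Used by the sequence-context analyses and the randomization null.
orf_a_contexts <- function(orfs) {
  cds <- orfs$cds
  out <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    s <- orfs$seq[[cds$orf_id[i]]]
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    lo <- max(cds$cds_start[i], 1L)              # need a 5' neighbour
    hi <- min(cds$cds_end[i], length(ch) - 1L)   # need a 3' neighbour
    if (hi <= lo) next
    p <- lo:(hi - 1L)                            # 0-based positions
    isa <- ch[p + 1L] == "A"
    p <- p[isa]
    if (!length(p)) next
    out[[i]] <- data.table::data.table(orf_id = cds$orf_id[i], pos = p,
                                       five = ch[p], three = ch[p + 2L])
  }
  data.table::rbindlist(out)
}
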