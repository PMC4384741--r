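#' Write a site table as TSV
#'
#' One row per called site, `#`-prefixed header, rows sorted by
#' (`orf_id`, `pos`). Positions are written 1-based inclusive (the header says
#' so); numeric columns keep full precision so the round trip through
#' [read_site_table] is lossless.
#'
#' @param sites Site table (as returned by the calling functions).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  s <- data.table::as.data.table(sites)
  if (nrow(s) > 0) {
    dup <- duplicated(s, by = c("orf_id", "pos", "mismatch_type"))
    if (any(dup))
      stop("duplicate (orf_id, pos, mismatch_type) rows in site table")
    data.table::setorder(s, orf_id, pos)
    s <- data.table::copy(s)
    s[, pos := pos + 1L]
  }
  hdr <- paste0("#", paste(names(s), collapse = "\t"),
                "  (pos is 1-based inclusive)")
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  if (nrow(s) > 0)
    data.table::fwrite(s, path, sep = "\t", append = TRUE, quote = FALSE,
                       col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a site table written by [write_site_table]
#'
#' @param path TSV file.
#' @return Site table (`data.table`) with 0-based `pos`.
#' @export
read_site_table <- function(path) {
  check_that(file.exists(path), paste0("no such file: ", path))
  hdr <- readLines(path, n = 1)
  check_that(startsWith(hdr, "#"), "site table must start with a # header")
  cols <- strsplit(sub("^#", "", sub("  \\(.*$", "", hdr)), "\t")[[1]]
  body <- data.table::fread(path, sep = "\t", skip = 1, header = FALSE,
                            na.strings = "NA",
                            colClasses = list(character = which(cols %in%
                              c("orf_id", "ref_base", "alt_base",
                                "consensus_base", "mismatch_type", "category",
                                "codon_effect", "aa_from", "aa_to"))))
  if (nrow(body) == 0) {
    s <- empty_sites()
    return(s[])
  }
  data.table::setnames(body, cols)
  body[, pos := as.integer(pos) - 1L]
  dup <- duplicated(body, by = c("orf_id", "pos", "mismatch_type"))
  if (any(dup)) stop("duplicate (orf_id, pos, mismatch_type) rows in ", path)
  data.table::setkeyv(body, c("orf_id", "pos"))
  body[]
}

#' Read a per-position amino-acid substitution score table
#'
#' TSV with columns `orf_id`, `aa_pos` (1-based amino-acid position), `aa`
#' (single-letter code of the substituting amino acid) and integer `score`.
#' Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return data.table.
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("orf_id", "aa_pos", "aa", "score"))
  df <- data.table::as.data.table(df)
  df[, aa_pos := as.integer(aa_pos)]
  df[, score := as.integer(score)]
  df[]
}
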