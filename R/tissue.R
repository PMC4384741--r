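#' Quantify editing levels of known sites across tissues
#'
#' No re-calling: for every previously called site, the quality-filtered RNA
#' counts of the edited allele and of all alleles are tallied per tissue. A
#' site uncovered in a tissue gets total 0 and an undefined (NA) level.
#'
#' @param sites Site table (defines the sites and their edited allele).
#' @param tissue_alignments Named list of [alignment_table]s, one per tissue.
#' @param orfs An [orf_set].
#' @param q_min Base-quality cutoff.
#' @param unique_only,min_mapq Unique-alignment filter, as in [build_pileup].
#' @return A `tissue_site_matrix`: list with `sites` (key columns `orf_id`,
#'   `pos`, `mismatch_type`, `alt_base`), `tissues`, and matrices `alt`,
#'   `total` (sites x tissues).
#' @export
quantify_levels <- function(sites, tissue_alignments, orfs, q_min = 30,
                            unique_only = TRUE, min_mapq = NULL) {
  s <- data.table::as.data.table(sites)
  check_that(nrow(s) > 0, "no sites to quantify")
  check_that(is.list(tissue_alignments) && length(tissue_alignments) > 0,
             "need at least one tissue alignment table")
  tn <- names(tissue_alignments)
  if (is.null(tn)) tn <- paste0("tissue", seq_along(tissue_alignments))
  key <- s[, .(orf_id, pos, mismatch_type, alt_base)]
  alt <- total <- matrix(0L, nrow(s), length(tn),
                         dimnames = list(NULL, tn))
  for (j in seq_along(tn)) {
    pu <- build_pileup(orfs, tissue_alignments[[j]], dna = NULL,
                       q_min = q_min, unique_only = unique_only,
                       min_mapq = min_mapq)
    m <- data.table::as.data.table(pu)[key, on = c("orf_id", "pos")]
    altc <- mapply(function(b, ra, rc, rg, rt) switch(b, A = ra, C = rc,
                                                      G = rg, T = rt, 0L),
                   key$alt_base, m$rna_A, m$rna_C, m$rna_G, m$rna_T)
    alt[, j] <- data.table::fifelse(is.na(m$rna_total), 0L,
                                    as.integer(altc))
    total[, j] <- data.table::fifelse(is.na(m$rna_total), 0L, m$rna_total)
  }
  structure(list(sites = key, tissues = tn, alt = alt, total = total),
            class = "tissue_site_matrix")
}

#' @export
print.tissue_site_matrix <- function(x, ...) {
  cat("<tissue_site_matrix> ", nrow(x$sites), " sites x ",
      length(x$tissues), " tissues (",
      paste(x$tissues, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Editing-level matrix of a tissue_site_matrix
#'
#' @param x A [quantify_levels] result.
#' @return Numeric matrix of levels (NA where a site is uncovered).
#' @export
tissue_levels <- function(x) {
  lv <- x$alt / x$total
  lv[x$total == 0] <- NA_real_
  colnames(lv) <- x$tissues
  lv
}

## two-sided binomial p-value of k successes in n at probability p,
## two-sidedness by doubling the smaller tail (capped at 1); vectorized
binom_two_sided <- function(k, n, p) {
  lo <- stats::pbinom(k, n, p)
  hi <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

#' Test for tissue differences in editing level
#'
#' For every site and tissue pair with coverage in both tissues, a two-sided
#' binomial analysis of each tissue's edited-read count against the pooled
#' level (the smaller of the two tissue p-values is taken), or an exact
#' Fisher test on the 2x2 count table. Bonferroni correction is over all
#' (site, pair) tests actually performed; a site is "variable" when any of
#' its pair tests stays below the corrected cutoff.
#'
#' @param x A [quantify_levels] result (at least two tissues).
#' @param alpha Family-wise significance cutoff (default 0.05,
#'   Bonferroni-corrected).
#' @param test `"binomial"` (pooled-level binomial analysis) or `"fisher"`.
#' @return List with `pairs` (data.table: site key, `tissue1`, `tissue2`,
#'   `p_value`, `p_bonferroni`, `significant`, `direction`), `per_site`
#'   (logical `variable` per site), `n_tests`, and `variable_fraction`.
#' @export
compare_tissues <- function(x, alpha = 0.05, test = c("binomial", "fisher")) {
  test <- match.arg(test)
  nt <- length(x$tissues)
  check_that(nt >= 2, "need at least two tissues")
  prs <- utils::combn(nt, 2)
  out <- vector("list", ncol(prs))
  for (c_i in seq_len(ncol(prs))) {
    i <- prs[1, c_i]; j <- prs[2, c_i]
    ai <- x$alt[, i]; ni <- x$total[, i]
    aj <- x$alt[, j]; nj <- x$total[, j]
    tested <- ni > 0 & nj > 0
    pv <- rep(NA_real_, nrow(x$sites))
    if (test == "binomial") {
      pool <- (ai + aj) / (ni + nj)
      pv[tested] <- pmin(binom_two_sided(ai, ni, pool),
                         binom_two_sided(aj, nj, pool))[tested]
    } else {
      idx <- which(tested)
      pv[idx] <- vapply(idx, function(r)
        stats::fisher.test(matrix(c(ai[r], ni[r] - ai[r],
                                    aj[r], nj[r] - aj[r]), 2))$p.value,
        numeric(1))
    }
    out[[c_i]] <- data.table::data.table(
      x$sites, tissue1 = x$tissues[i], tissue2 = x$tissues[j],
      tested = tested, p_value = pv,
      direction = data.table::fifelse(ai / pmax(1, ni) > aj / pmax(1, nj),
                                      "tissue1>tissue2", "tissue1<tissue2"))
  }
  pairs <- data.table::rbindlist(out)
  n_tests <- sum(pairs$tested)
  pairs[, p_bonferroni := pmin(1, p_value * n_tests)]
  pairs[, significant := tested & !is.na(p_bonferroni) &
          p_bonferroni < alpha]
  per_site <- pairs[, .(variable = any(significant),
                        tested = any(tested)),
                    by = .(orf_id, pos, mismatch_type)]
  vf <- if (any(per_site$tested)) mean(per_site$variable[per_site$tested])
        else NA_real_
  list(pairs = pairs[], per_site = per_site[], n_tests = n_tests,
       variable_fraction = vf)
}

#' Summary line for a tissue comparison
#'
#' Formats a variable-site count as the percentage of all quantified sites,
#' e.g. `"19% (16425 out of 87574) of sites differ significantly"`.
#'
#' @param n_variable,n_total Counts (numerator and denominator).
#' @return List with `percent` (numeric, whole percent) and `text`.
#' @export
tissue_difference_summary <- function(n_variable, n_total) {
  pct <- fraction_percent(n_variable, n_total)
  list(percent = pct,
       text = sprintf(
         "%d%% (%d out of %d) of sites differ significantly between tissues",
         pct, n_variable, n_total))
}

#' Hierarchical clustering of tissue-variable sites
#'
#' Average-linkage hierarchical clustering with Euclidean distance of the
#' editing-level vectors, of sites (rows) and tissues (columns). Undefined
#' levels (uncovered cells) are imputed by the site's mean level across the
#' covered tissues; sites uncovered everywhere are dropped. Deterministic
#' given the input.
#'
#' @param x A [quantify_levels] result.
#' @param variable Logical vector marking the sites to cluster (e.g.
#'   `per_site$variable` of [compare_tissues]); default all sites.
#' @return List `site_hclust`, `tissue_hclust` (both `hclust`, tissue one NULL
#'   if fewer than 2 tissues), `levels` (imputed matrix, rows in cluster
#'   order), `sites` (key rows in the same order).
#' @export
cluster_variable_sites <- function(x, variable = NULL) {
  lv <- tissue_levels(x)
  keep <- if (is.null(variable)) rep(TRUE, nrow(lv)) else variable
  keep <- keep & rowSums(!is.na(lv)) > 0
  check_that(any(keep), "no sites to cluster")
  lv <- lv[keep, , drop = FALSE]
  key <- x$sites[keep]
  rm_na <- is.na(lv)
  if (any(rm_na)) {
    rmean <- rowMeans(lv, na.rm = TRUE)
    lv[rm_na] <- rmean[row(lv)[rm_na]]
  }
  site_h <- if (nrow(lv) >= 2)
    stats::hclust(stats::dist(lv, method = "euclidean"), method = "average")
  else NULL
  tissue_h <- if (ncol(lv) >= 2)
    stats::hclust(stats::dist(t(lv), method = "euclidean"),
                  method = "average")
  else NULL
  ord <- if (!is.null(site_h)) site_h$order else seq_len(nrow(lv))
  list(site_hclust = site_h, tissue_hclust = tissue_h,
       levels = lv[ord, , drop = FALSE], sites = key[ord])
}
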