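#' Detection configuration
#'
#' Parameters of the two calling procedures. Defaults reproduce the published
#' analysis settings: expected sequencing error 0.1% among Q>=30 bases, 10%
#' Benjamini--Hochberg FDR in each procedure, SNP prior 0.001, zero tolerance
#' for discordant DNA reads at weak sites (the validation-study variant allows
#' discordance up to the sequencing error rate, i.e. `dna_discordance_tolerance
#' = 0.001`), and exclusion of strong sites without any high-quality
#' uniquely-aligned supporting RNA read.
#'
#' @param error_prob Expected per-base sequencing error probability among
#'   quality-filtered bases.
#' @param fdr Benjamini--Hochberg false-discovery rate, applied separately to
#'   the weak and the strong hypothesis families.
#' @param snp_prior Prior probability that a position is a SNP.
#' @param dna_discordance_tolerance Maximum tolerated fraction of DNA bases
#'   disagreeing with the consensus at a weak site (0 = any discordant DNA
#'   read vetoes the site).
#' @param require_strong_rna_support Drop strong candidates lacking RNA
#'   support (see `strong_support_mode`).
#' @param strong_support_mode `"any"`: at least one quality-filtered RNA base
#'   of any allele at the site; `"alt"`: at least one RNA base carrying the
#'   edited (consensus) allele.
#' @param min_dna_cov Minimum DNA coverage required at weak sites (default 0:
#'   the DNA-agreement filter passes vacuously at uncovered positions).
#' @return A `detection_config` list.
#' @export
detection_config <- function(error_prob = 0.001, fdr = 0.10,
                             snp_prior = 0.001,
                             dna_discordance_tolerance = 0,
                             require_strong_rna_support = TRUE,
                             strong_support_mode = c("any", "alt"),
                             min_dna_cov = 0) {
  strong_support_mode <- match.arg(strong_support_mode)
  cfg <- list(error_prob = error_prob, fdr = fdr, snp_prior = snp_prior,
              dna_discordance_tolerance = dna_discordance_tolerance,
              require_strong_rna_support = require_strong_rna_support,
              strong_support_mode = strong_support_mode,
              min_dna_cov = min_dna_cov)
  probs <- unlist(cfg[c("error_prob", "fdr", "snp_prior",
                        "dna_discordance_tolerance")])
  check_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  structure(cfg, class = "detection_config")
}

#' Upper-tail binomial p-value for a weak editing site
#'
#' `P(X >= k)` for `X ~ Binomial(n, error_prob)`: the probability of observing
#' at least `k` mismatching RNA reads among `n` by sequencing error alone.
#' Vectorized over `k` and `n`.
#'
#' @param k Mismatching RNA read count(s).
#' @param n Total RNA read count(s) at the position; must be >= 1.
#' @param error_prob Per-base error probability.
#' @return p-value(s).
#' @export
weak_site_pvalue <- function(k, n, error_prob = 0.001) {
  check_that(all(n >= 1), "site with n = 0 is not testable")
  check_that(all(k >= 0 & k <= n), "need 0 <= k <= n")
  stats::pbinom(k - 1, n, error_prob, lower.tail = FALSE)
}

#' SNP probability for a strong editing site
#'
#' The probability that a position where every one of `d` DNA reads disagrees
#' with the RNA consensus is a heterozygous SNP rather than an editing site:
#' `snp_prior * (1/2)^d` (assuming no allele-specific expression).
#'
#' @param d DNA read count(s); must be >= 1.
#' @param snp_prior Prior probability of a SNP.
#' @return p-value(s).
#' @export
strong_site_pvalue <- function(d, snp_prior = 0.001) {
  check_that(all(d >= 1), "strong site needs at least one DNA read")
  snp_prior * 0.5^d
}

#' Benjamini--Hochberg step-up FDR control
#'
#' Standard step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' reject hypotheses `1..k` for the largest `k` with `p_(k) <= k * fdr / m`.
#' q-values are the usual monotone BH-adjusted p-values
#' (`stats::p.adjust(method = "BH")`); rejection is `q <= fdr`.
#'
#' @param p_values Vector of p-values.
#' @param fdr Target false-discovery rate.
#' @return List with `q_values` and logical `reject`.
#' @export
benjamini_hochberg <- function(p_values, fdr = 0.10) {
  if (length(p_values) == 0)
    return(list(q_values = numeric(0), reject = logical(0)))
  check_that(all(p_values >= 0 & p_values <= 1), "p-values must be in [0,1]")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = q <= fdr)
}

## columns of a site table, in emitted order
SITE_COLS <- c("orf_id", "pos", "ref_base", "alt_base", "consensus_base",
               "mismatch_type", "category", "rna_alt", "rna_total",
               "dna_alt", "dna_ref", "dna_total", "p_value", "q_value",
               "editing_level", "codon_effect", "aa_from", "aa_to")

empty_sites <- function() {
  s <- data.table::data.table(
    orf_id = character(0), pos = integer(0), ref_base = character(0),
    alt_base = character(0), consensus_base = character(0),
    mismatch_type = character(0), category = character(0),
    rna_alt = integer(0), rna_total = integer(0), dna_alt = integer(0),
    dna_ref = integer(0), dna_total = integer(0), p_value = numeric(0),
    q_value = numeric(0), editing_level = numeric(0),
    codon_effect = character(0), aa_from = character(0), aa_to = character(0))
  s
}

#' Call weak editing sites
#'
#' For every covered coding position with an A/C/G/T consensus, each of the
#' three alternative bases is a hypothesis; the binomial test of
#' [weak_site_pvalue] is applied to its quality-filtered RNA mismatch count
#' (alternatives with zero mismatches enter the BH family with p = 1).
#' After BH correction at `config$fdr`, significant sites are kept only if
#' the fraction of DNA bases disagreeing with the consensus is at most
#' `config$dna_discordance_tolerance` (default 0: any discordant DNA read
#' removes the site) and DNA coverage is at least `config$min_dna_cov`.
#'
#' In the emitted table `ref_base` is the genomic base (here the consensus),
#' `alt_base` the edited base, and `editing_level = rna_alt / rna_total`.
#'
#' @param pileup A [build_pileup] result.
#' @param config A [detection_config].
#' @param orfs Optional [orf_set]; when supplied, codon consequences are
#'   annotated.
#' @return Site table (`data.table`, one row per called site).
#' @export
call_weak_sites <- function(pileup, config = detection_config(), orfs = NULL) {
  pu <- data.table::as.data.table(pileup)
  pu <- pu[ref %chin% BASES & rna_total > 0]
  if (nrow(pu) == 0) return(empty_sites())
  ## long form: one row per (position, alt base)
  long <- data.table::rbindlist(lapply(BASES, function(b)
    pu[ref != b,
       .(orf_id, pos, ref, alt = b, k = get(paste0("rna_", b)), n = rna_total,
         dna_alt = get(paste0("dna_", b)),
         dna_ref_n = data.table::fifelse(ref == "A", dna_A,
                       data.table::fifelse(ref == "C", dna_C,
                         data.table::fifelse(ref == "G", dna_G, dna_T))),
         dna_total)]))
  long[, p_value := 1.0]
  long[k > 0, p_value := weak_site_pvalue(k, n, config$error_prob)]
  bh <- benjamini_hochberg(long$p_value, config$fdr)
  long[, q_value := bh$q_values]
  long <- long[bh$reject & k > 0]
  if (nrow(long) == 0) return(empty_sites())
  ## DNA agreement filter (vacuous when no DNA coverage)
  long[, dna_disc := data.table::fifelse(dna_total > 0,
                                         (dna_total - dna_ref_n) / dna_total,
                                         0)]
  long <- long[dna_disc <= config$dna_discordance_tolerance &
                 dna_total >= config$min_dna_cov]
  if (nrow(long) == 0) return(empty_sites())
  s <- long[, .(orf_id, pos, ref_base = ref, alt_base = alt,
                consensus_base = ref,
                mismatch_type = paste0(ref, ">", alt), category = "weak",
                rna_alt = k, rna_total = n, dna_alt,
                dna_ref = dna_ref_n, dna_total, p_value, q_value,
                editing_level = k / n)]
  finish_sites(s, orfs)
}

#' Call strong editing sites
#'
#' Candidates are coding positions with at least one DNA read where *all*
#' quality-filtered DNA bases carry one identical base different from the RNA
#' consensus. Each candidate is scored with [strong_site_pvalue] on its DNA
#' coverage and corrected by BH at `config$fdr`. When
#' `config$require_strong_rna_support` is on, candidates without supporting
#' RNA reads are dropped (`strong_support_mode = "any"`: no quality-filtered
#' RNA base at all; `"alt"`: no RNA base carrying the consensus, i.e. edited,
#' allele).
#'
#' In the emitted table `ref_base` is the inferred genomic base (the unanimous
#' DNA allele), `alt_base` the edited base (the consensus), so a strong
#' A-to-I site appears as mismatch type `A>G`; `editing_level` is the fraction
#' of RNA reads carrying the edited base.
#'
#' @inheritParams call_weak_sites
#' @return Site table (`data.table`, one row per called site).
#' @export
call_strong_sites <- function(pileup, config = detection_config(),
                              orfs = NULL) {
  pu <- data.table::as.data.table(pileup)
  pu <- pu[ref %chin% BASES & dna_total >= 1]
  if (nrow(pu) == 0) return(empty_sites())
  cm <- as.matrix(pu[, paste0("dna_", BASES), with = FALSE])
  top <- max.col(cm, ties.method = "first")
  unanimous <- cm[cbind(seq_len(nrow(cm)), top)] == pu$dna_total
  dna_base <- BASES[top]
  cand <- pu[unanimous & dna_base != ref]
  cand[, genomic := BASES[max.col(as.matrix(.SD), ties.method = "first")],
       .SDcols = paste0("dna_", BASES)]
  if (nrow(cand) == 0) return(empty_sites())
  cand[, p_value := strong_site_pvalue(dna_total, config$snp_prior)]
  bh <- benjamini_hochberg(cand$p_value, config$fdr)
  cand[, q_value := bh$q_values]
  cand <- cand[bh$reject]
  if (nrow(cand) == 0) return(empty_sites())
  ## RNA-support exclusion
  cand[, rna_cons := data.table::fifelse(ref == "A", rna_A,
                       data.table::fifelse(ref == "C", rna_C,
                         data.table::fifelse(ref == "G", rna_G, rna_T)))]
  if (isTRUE(config$require_strong_rna_support)) {
    cand <- if (config$strong_support_mode == "alt")
      cand[rna_cons > 0] else cand[rna_total > 0]
  }
  if (nrow(cand) == 0) return(empty_sites())
  s <- cand[, .(orf_id, pos, ref_base = genomic, alt_base = ref,
                consensus_base = ref,
                mismatch_type = paste0(genomic, ">", ref),
                category = "strong",
                rna_alt = rna_cons, rna_total,
                dna_alt = 0L, dna_ref = dna_total, dna_total,
                p_value, q_value,
                editing_level = data.table::fifelse(rna_total > 0,
                                                    rna_cons / rna_total,
                                                    NA_real_))]
  finish_sites(s, orfs)
}

## annotate codon consequences (if orfs given) and order columns
finish_sites <- function(s, orfs) {
  if (!is.null(orfs)) {
    eff <- codon_effect(orfs, s$orf_id, s$pos, s$alt_base, ref = s$ref_base)
    s[, `:=`(codon_effect = eff$effect, aa_from = eff$aa_from,
             aa_to = eff$aa_to)]
  } else {
    s[, `:=`(codon_effect = NA_character_, aa_from = NA_character_,
             aa_to = NA_character_)]
  }
  data.table::setcolorder(s, SITE_COLS)
  data.table::setkeyv(s, c("orf_id", "pos"))
  s[]
}

#' Merge weak and strong calls and summarize by mismatch type
#'
#' Concatenates the two call sets, deduplicating positions called by both
#' procedures in favour of the strong call (with a message), and tabulates
#' counts per mismatch type and category.
#'
#' @param weak,strong Site tables from [call_weak_sites] / [call_strong_sites].
#' @return List with `sites` (merged table) and `summary` (data.table:
#'   `mismatch_type`, `category`, `count`, all 12 x 2 combinations).
#' @export
classify_and_merge <- function(weak, strong) {
  sites <- data.table::rbindlist(list(weak, strong))
  if (nrow(sites) > 0) {
    data.table::setorder(sites, orf_id, pos, category)  # strong < weak
    dup <- duplicated(sites, by = c("orf_id", "pos"))
    if (any(dup)) {
      message(sum(dup), " position(s) called by both procedures; ",
              "strong call kept")
      sites <- sites[!dup]
    }
    data.table::setkeyv(sites, c("orf_id", "pos"))
  }
  grid <- data.table::CJ(mismatch_type = mismatch_types(),
                         category = c("weak", "strong"))
  cnt <- if (nrow(sites) > 0)
    sites[, .(count = .N), by = .(mismatch_type, category)]
  else data.table::data.table(mismatch_type = character(0),
                              category = character(0), count = integer(0))
  summary <- cnt[grid, on = c("mismatch_type", "category")]
  summary[is.na(count), count := 0L]
  data.table::setorder(summary, mismatch_type, -category)
  list(sites = sites, summary = summary[])
}

#' Estimate detection noise rates from a mismatch-type summary
#'
#' A-to-I editing produces only A-to-G mismatches; the 11 other mismatch types
#' arise from noise (assembly errors, SNPs, somatic mutations,
#' mis-alignments). Assuming noise contributes equally to all 12 types, the
#' false-positive rate of each procedure is estimated as the ratio of
#' non-A-to-G to A-to-G calls. On the published summary counts this gives
#' 15% (weak), 4% (strong) and an 87% A-to-G fraction.
#'
#' @param summary Either the `summary` data.table of [classify_and_merge], or
#'   a named numeric vector with elements `AG_weak`, `nonAG_weak`,
#'   `AG_strong`, `nonAG_strong`.
#' @return List `weak_fp_rate`, `strong_fp_rate`, `atog_fraction` (NA where a
#'   denominator is zero, with a warning).
#' @export
estimate_noise_rates <- function(summary) {
  if (is.data.frame(summary)) {
    sdt <- data.table::as.data.table(summary)
    g <- function(cat, ag) sum(sdt[category == cat &
                                     (mismatch_type == "A>G") == ag, count])
    counts <- c(AG_weak = g("weak", TRUE), nonAG_weak = g("weak", FALSE),
                AG_strong = g("strong", TRUE),
                nonAG_strong = g("strong", FALSE))
  } else {
    check_that(all(c("AG_weak", "nonAG_weak", "AG_strong", "nonAG_strong")
                   %in% names(summary)), "summary counts missing")
    counts <- summary
  }
  rate <- function(num, den) {
    if (den == 0) { warning("zero denominator in noise-rate estimate"); NA_real_ }
    else unname(num / den)
  }
  list(weak_fp_rate = rate(counts[["nonAG_weak"]], counts[["AG_weak"]]),
       strong_fp_rate = rate(counts[["nonAG_strong"]], counts[["AG_strong"]]),
       atog_fraction = rate(counts[["AG_weak"]] + counts[["AG_strong"]],
                            sum(counts)))
}

#' Full detection pass: pileup in, merged site table out
#'
#' Convenience wrapper running [call_weak_sites], [call_strong_sites] and
#' [classify_and_merge] with one configuration.
#'
#' @inheritParams call_weak_sites
#' @return List `sites`, `summary`, `noise_rates`, `config`.
#' @export
detect_sites <- function(pileup, config = detection_config(), orfs = NULL) {
  weak <- call_weak_sites(pileup, config, orfs)
  strong <- call_strong_sites(pileup, config, orfs)
  merged <- classify_and_merge(weak, strong)
  nr <- withCallingHandlers(estimate_noise_rates(merged$summary),
                            warning = function(w) invokeRestart("muffleWarning"))
  c(merged, list(noise_rates = nr, config = config))
}
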