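#' Codon consequence of a single-base change
#'
#' Determines, under the standard genetic code, whether changing the base at
#' `pos` from `ref` to `alt` is synonymous, nonsynonymous, stop-affecting, or
#' outside the coding frame. The surrounding codon is taken from the ORF
#' consensus; `ref` defaults to the consensus base itself (pass the inferred
#' genomic base for strong sites, where the consensus already carries the
#' edited allele). Vectorized over sites.
#'
#' @param orfs An [orf_set].
#' @param orf_id,pos Site coordinates (0-based `pos`).
#' @param alt The substituted (edited) base.
#' @param ref The original base; defaults to the consensus base at `pos`.
#' @param genetic_code Named character vector mapping codons to amino acids
#'   (default `Biostrings::GENETIC_CODE`; pass an alternative code, e.g. the
#'   invertebrate mitochondrial one, for organellar ORFs).
#' @return data.table with columns `effect` (`synonymous`, `nonsynonymous`,
#'   `stop-gain`, `stop-loss`, `noncoding`, or NA when the codon contains N),
#'   `aa_from`, `aa_to`.
#' @export
codon_effect <- function(orfs, orf_id, pos, alt, ref = NULL,
                         genetic_code = Biostrings::GENETIC_CODE) {
  n <- length(pos)
  if (length(alt) == 1) alt <- rep(alt, n)
  if (length(ref) == 1) ref <- rep(ref, n)
  if (length(orf_id) == 1) orf_id <- rep(orf_id, n)
  check_that(length(orf_id) == n && length(alt) == n,
             "orf_id, pos, alt must have equal length")
  cds <- orfs$cds
  m <- match(orf_id, cds$orf_id)
  check_that(!anyNA(m), "unknown ORF id in codon_effect")
  cs <- cds$cds_start[m] + cds$frame_offset[m]
  ce <- cds$cds_end[m]
  codon_idx <- (pos - cs) %/% 3L
  codon_start <- cs + 3L * codon_idx
  coding <- pos >= cs & pos < ce & (codon_start + 3L) <= ce
  offset <- pos - codon_start          # 0,1,2 within codon

  seqs <- orfs$seq[orf_id]
  codon <- ifelse(coding,
                  substr(seqs, codon_start + 1L, codon_start + 3L), NA)
  if (is.null(ref)) ref <- ifelse(coding,
                                  substr(seqs, pos + 1L, pos + 1L), NA)
  sub_at <- function(codon, at, b) {
    out <- codon
    substr(out, at + 1L, at + 1L) <- b
    out
  }
  from_codon <- ifelse(coding, sub_at(codon, offset, ref), NA)
  to_codon <- ifelse(coding, sub_at(codon, offset, alt), NA)
  ok <- coding & !grepl("N", from_codon) & !grepl("N", to_codon)
  aa_from <- ifelse(ok, unname(genetic_code[from_codon]), NA)
  aa_to <- ifelse(ok, unname(genetic_code[to_codon]), NA)
  effect <- rep(NA_character_, n)
  effect[!coding] <- "noncoding"
  effect[ok & aa_from == aa_to] <- "synonymous"
  effect[ok & aa_from != aa_to & aa_to == "*"] <- "stop-gain"
  effect[ok & aa_from != aa_to & aa_from == "*" & aa_to != "*"] <- "stop-loss"
  effect[ok & aa_from != aa_to & aa_from != "*" & aa_to != "*"] <-
    "nonsynonymous"
  data.table::data.table(effect = effect, aa_from = aa_from, aa_to = aa_to)
}

## effects counted as recoding (amino-acid altering)
RECODING_EFFECTS <- c("nonsynonymous", "stop-gain", "stop-loss")

is_recoding_site <- function(sites) {
  sites$mismatch_type == "A>G" & sites$codon_effect %in% RECODING_EFFECTS
}

#' Context-preserving randomization of editing sites
#'
#' The null model for recoding analyses: adenosines are "edited" at random,
#' respecting the observed 5'/3' neighbour preference. All A positions inside
#' the coding regions (with both neighbours available) are screened in a
#' random order; each is accepted with the context-specific probability of
#' the supplied [context_model] (observed edited fraction of A's with that
#' context). Passes are repeated, without replacement, until `n_sites`
#' positions are accepted. Codon effects of the A-to-G change at the accepted
#' positions give the expected nonsynonymous fraction and amino-acid change
#' spectrum.
#'
#' @param orfs An [orf_set].
#' @param context_model A [context_model] (4x4 acceptance probabilities).
#' @param n_sites Number of sites to draw (must not exceed the number of
#'   eligible A's with non-zero acceptance probability).
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return List with `sites` (data.table `orf_id`, `pos`, `effect`, `aa_from`,
#'   `aa_to`), `nonsyn_fraction` (fraction of coding draws that are
#'   recoding), and `aa_change_spectrum` (counts per `aa_from>aa_to`).
#' @export
context_preserving_randomization <- function(orfs, context_model, n_sites,
                                             seed = NULL) {
  elig <- orf_a_contexts(orfs)
  check_that(nrow(elig) > 0, "no eligible A bases in the ORF set")
  pr <- context_model$probs[cbind(elig$five, elig$three)]
  pr[is.na(pr)] <- 0
  check_that(sum(pr > 0) >= n_sites,
             "n_sites exceeds the number of A bases with non-zero acceptance")
  draw <- function() {
    sel <- integer(0)
    remaining <- which(pr > 0)
    while (length(sel) < n_sites) {
      ord <- sample(remaining)
      acc <- ord[stats::runif(length(ord)) < pr[ord]]
      if (length(acc) == 0 && length(remaining) == length(ord) &&
          all(pr[remaining] == 0)) stop("acceptance probabilities all zero")
      take <- head(acc, n_sites - length(sel))
      sel <- c(sel, take)
      remaining <- setdiff(remaining, take)
    }
    sel
  }
  sel <- if (is.null(seed)) draw() else with_seed(seed, draw())
  picked <- elig[sel]
  eff <- codon_effect(orfs, picked$orf_id, picked$pos, alt = "G", ref = "A")
  sites <- data.table::data.table(orf_id = picked$orf_id, pos = picked$pos,
                                  five = picked$five, three = picked$three,
                                  effect = eff$effect, aa_from = eff$aa_from,
                                  aa_to = eff$aa_to)
  coding <- sites[!is.na(effect) & effect != "noncoding"]
  spec <- coding[effect %in% RECODING_EFFECTS,
                 .(count = .N), by = .(change = paste0(aa_from, ">", aa_to))]
  list(sites = sites,
       nonsyn_fraction = if (nrow(coding) > 0)
         mean(coding$effect %in% RECODING_EFFECTS) else NA_real_,
       aa_change_spectrum = spec[order(-count)])
}

#' Observed vs expected nonsynonymous fraction by editing level
#'
#' Bins A-to-G sites by editing level and compares the observed fraction of
#' recoding (nonsynonymous, including stop-affecting) changes in each bin
#' with the fraction expected from context-preserving randomizations matched
#' in site count. Each null run draws as many random sites as there are
#' observed sites and partitions them randomly into groups of the observed
#' bin sizes; empirical two-sided p-values are reported per bin.
#'
#' @param sites Site table (annotated with codon effects and levels).
#' @param orfs An [orf_set].
#' @param context_model A [context_model].
#' @param breaks Level bin edges (default deciles).
#' @param null_runs Number of randomization runs.
#' @param seed Optional seed.
#' @return data.table: `bin`, `lo`, `hi`, `n`, `observed`, `expected`,
#'   `p_value`; attribute `null` holds the runs x bins null fractions.
#' @export
nonsyn_fraction_by_level <- function(sites, orfs, context_model,
                                     breaks = seq(0, 1, 0.1),
                                     null_runs = 1000, seed = NULL) {
  s <- data.table::as.data.table(sites)
  s <- s[mismatch_type == "A>G" & !is.na(editing_level) &
           codon_effect %in% c(RECODING_EFFECTS, "synonymous")]
  check_that(nrow(s) > 0, "no codon-annotated A>G sites")
  bin <- cut(s$editing_level, breaks, include.lowest = TRUE, right = FALSE,
             labels = FALSE)
  bin[s$editing_level >= breaks[length(breaks)]] <- length(breaks) - 1L
  nb <- length(breaks) - 1L
  n_per <- tabulate(bin, nbins = nb)
  obs <- vapply(seq_len(nb), function(b)
    if (n_per[b] > 0) mean(is_recoding_site(s[bin == b])) else NA_real_,
    numeric(1))
  ntot <- nrow(s)
  run_once <- function() {
    r <- context_preserving_randomization(orfs, context_model, ntot)
    nonsyn <- r$sites$effect %in% RECODING_EFFECTS
    coding <- !is.na(r$sites$effect) & r$sites$effect != "noncoding"
    grp <- sample(rep.int(seq_len(nb), n_per))
    vapply(seq_len(nb), function(b) {
      cc <- coding & grp == b
      if (any(cc)) sum(nonsyn[cc]) / sum(cc) else NA_real_
    }, numeric(1))
  }
  runs <- if (is.null(seed)) replicate(null_runs, run_once())
          else with_seed(seed, replicate(null_runs, run_once()))
  null <- if (is.matrix(runs)) t(runs) else matrix(runs, ncol = nb)
  expected <- colMeans(null, na.rm = TRUE)
  pv <- vapply(seq_len(nb), function(b) {
    if (n_per[b] == 0) return(NA_real_)
    eps <- 1e-9 * (abs(obs[b]) + 1)
    lo <- (1 + sum(null[, b] <= obs[b] + eps, na.rm = TRUE)) / (1 + null_runs)
    hi <- (1 + sum(null[, b] >= obs[b] - eps, na.rm = TRUE)) / (1 + null_runs)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  out <- data.table::data.table(bin = seq_len(nb),
                                lo = breaks[-length(breaks)],
                                hi = breaks[-1], n = n_per,
                                observed = obs, expected = expected,
                                p_value = pv)
  data.table::setattr(out, "null", null)
  out[]
}

#' Per-ORF recoding summary
#'
#' Counts recoding sites (nonsynonymous A-to-G, stop-affecting included) per
#' ORF and the cumulative recoding level — the editing level summed over all
#' recoding sites of the ORF. An ORF is "heavily edited" when that sum
#' exceeds unity (at least one amino acid expected altered per molecule).
#'
#' @param sites Site table with codon effects and levels.
#' @param orfs Optional [orf_set]; when given, ORFs without recoding sites are
#'   included with zero counts.
#' @param level_threshold Only count sites with editing level above this
#'   (default 0 = all sites; e.g. 0.1 restricts to levels > 10%).
#' @return data.table: `orf_id`, `n_recoding_sites`,
#'   `cumulative_recoding_level`, `heavily_edited`.
#' @export
recoding_summary <- function(sites, orfs = NULL, level_threshold = 0) {
  s <- data.table::as.data.table(sites)
  rec <- s[is_recoding_site(s) & !is.na(editing_level) &
             editing_level > level_threshold]
  per <- rec[, .(n_recoding_sites = .N,
                 cumulative_recoding_level = sum(editing_level)),
             by = orf_id]
  if (!is.null(orfs)) {
    all_orfs <- data.table::data.table(orf_id = names(orfs$seq))
    per <- per[all_orfs, on = "orf_id"]
    per[is.na(n_recoding_sites),
        `:=`(n_recoding_sites = 0L, cumulative_recoding_level = 0)]
  }
  per[, heavily_edited := cumulative_recoding_level > 1]
  data.table::setorder(per, orf_id)
  per[]
}

#' Fraction of ORFs with at least `k` recoding sites
#'
#' @param per_orf Output of [recoding_summary].
#' @param k Site-count thresholds (default `c(1, 3, 10)`).
#' @return Named numeric vector of fractions.
#' @export
multi_site_fraction <- function(per_orf, k = c(1, 3, 10)) {
  setNames(vapply(k, function(x) mean(per_orf$n_recoding_sites >= x),
                  numeric(1)),
           paste0(">=", k))
}

#' Substitution-score analyses of recoding sites
#'
#' Joins recoding sites to an externally supplied per-position amino-acid
#' substitution score table (e.g. PSSM scores from conserved-domain
#' alignments) and computes three views: mean editing level per score,
#' recoding-site count per score, and mean score per editing-level bin. Null
#' bands for the level-based views come from shuffling editing levels within
#' recoding type (preserving both the recoding-type spectrum and each type's
#' level distribution); the null for the count-per-score distribution — when
#' `orfs` and `context_model` are supplied — comes from context-preserving
#' random site sets of matched size.
#'
#' @param sites Site table with codon effects and levels.
#' @param score_table data.table from [read_score_table]
#'   (`orf_id`, `aa_pos` 1-based, `aa`, `score`).
#' @param orfs An [orf_set] (needed to map sites to amino-acid positions).
#' @param shuffle_runs Number of shuffles / random draws.
#' @param level_breaks Editing-level bin edges (default <10%, 10--50%, >50%).
#' @param context_model Optional [context_model] enabling the random-sites
#'   null for the score distribution.
#' @param seed Optional seed.
#' @return List `by_score`, `by_level`, `score_distribution` (each a
#'   data.table with observed values, null band and empirical p-values where
#'   defined) and `n_unscored` (sites absent from the score table).
#' @export
substitution_score_analysis <- function(sites, score_table, orfs,
                                        shuffle_runs = 1000,
                                        level_breaks = c(0, 0.1, 0.5, 1),
                                        context_model = NULL, seed = NULL) {
  s <- data.table::as.data.table(sites)
  rec <- s[is_recoding_site(s) & !is.na(editing_level)]
  check_that(nrow(rec) > 0, "no recoding sites to score")
  cds <- orfs$cds
  m <- match(rec$orf_id, cds$orf_id)
  rec[, aa_pos := (pos - cds$cds_start[m] - cds$frame_offset[m]) %/% 3L + 1L]
  st <- data.table::as.data.table(score_table)
  scored <- st[rec, on = c("orf_id", "aa_pos", aa = "aa_to"), nomatch = NULL]
  n_unscored <- nrow(rec) - nrow(scored)
  check_that(nrow(scored) > 0, "no overlap between sites and score table")
  scored[, type := paste0(aa_from, ">", aa)]

  do_curves <- function(lv) {
    bs <- data.table::data.table(score = scored$score, level = lv)[
      , .(mean_level = mean(level), n = .N), by = score]
    bin <- cut(lv, level_breaks, include.lowest = TRUE, right = FALSE,
               labels = FALSE)
    bin[lv >= level_breaks[length(level_breaks)]] <-
      length(level_breaks) - 1L
    bl <- data.table::data.table(score = scored$score, bin = bin)[
      , .(mean_score = mean(score), n = .N), by = bin]
    list(by_score = bs, by_level = bl)
  }
  obs <- do_curves(scored$editing_level)

  shuffle_one <- function() {
    perm <- stats::ave(scored$editing_level, scored$type,
                       FUN = function(x) x[sample.int(length(x))])
    do_curves(perm)
  }
  run_all <- function() {
    sh <- replicate(shuffle_runs, shuffle_one(), simplify = FALSE)
    dist_null <- NULL
    if (!is.null(context_model)) {
      dist_null <- replicate(shuffle_runs, {
        r <- context_preserving_randomization(orfs, context_model,
                                              nrow(rec))
        rs <- r$sites[effect %in% RECODING_EFFECTS]
        mm <- match(rs$orf_id, cds$orf_id)
        rs[, aa_pos := (pos - cds$cds_start[mm] -
                          cds$frame_offset[mm]) %/% 3L + 1L]
        j <- st[rs, on = c("orf_id", "aa_pos", aa = "aa_to"), nomatch = NULL]
        j$score
      }, simplify = FALSE)
    }
    list(sh = sh, dist_null = dist_null)
  }
  nulls <- if (is.null(seed)) run_all() else with_seed(seed, run_all())

  band <- function(key, value, obs_tab) {
    mat <- sapply(nulls$sh, function(r) {
      tb <- r[[key]]
      tb[[value]][match(obs_tab[[names(obs_tab)[1]]],
                        tb[[names(tb)[1]]])]
    })
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(obs_tab))
    obs_tab$null_lo <- apply(mat, 1, stats::quantile, 0.025, na.rm = TRUE)
    obs_tab$null_hi <- apply(mat, 1, stats::quantile, 0.975, na.rm = TRUE)
    ov <- obs_tab[[value]]
    obs_tab$p_value <- vapply(seq_len(nrow(obs_tab)), function(i) {
      v <- mat[i, ]
      eps <- 1e-9 * (abs(ov[i]) + 1)
      lo <- (1 + sum(v <= ov[i] + eps, na.rm = TRUE)) / (1 + shuffle_runs)
      hi <- (1 + sum(v >= ov[i] - eps, na.rm = TRUE)) / (1 + shuffle_runs)
      min(1, 2 * min(lo, hi))
    }, numeric(1))
    obs_tab
  }
  by_score <- band("by_score", "mean_level", obs$by_score[order(score)])
  by_level <- band("by_level", "mean_score", obs$by_level[order(bin)])

  sdist <- scored[, .(count = .N), by = score][order(score)]
  if (!is.null(nulls$dist_null)) {
    cnts <- sapply(nulls$dist_null, function(v)
      vapply(sdist$score, function(x) sum(v == x), numeric(1)))
    if (is.null(dim(cnts))) cnts <- matrix(cnts, nrow = nrow(sdist))
    sdist[, null_lo := apply(cnts, 1, stats::quantile, 0.025)]
    sdist[, null_hi := apply(cnts, 1, stats::quantile, 0.975)]
  }
  list(by_score = by_score, by_level = by_level, score_distribution = sdist,
       n_unscored = n_unscored)
}
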