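test_that("codon effects agree with an independent 64-codon truth table", {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  orfs <- orf_set(setNames(codons, paste0("c_", codons)))
  ## independent oracle: Biostrings translation of the two codons
  for (at in 0:2) {
    for (alt in bases) {
      eff <- codon_effect(orfs, paste0("c_", codons), rep(at, 64), alt)
      for (i in seq_along(codons)) {
        from <- codons[i]
        to <- from
        substr(to, at + 1, at + 1) <- alt
        aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(from),
                                                  no.init.codon = TRUE))
        aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(to),
                                                  no.init.codon = TRUE))
        want <- if (aa1 == aa2) "synonymous"
                else if (aa2 == "*") "stop-gain"
                else if (aa1 == "*") "stop-loss"
                else "nonsynonymous"
        expect_identical(eff$effect[i], want,
                         label = paste(from, "->", to))
      }
    }
  }
})

test_that("codon effect handles spec worked examples and frame boundaries", {
  orfs <- orf_set(c(o = "AAAATA"))
  e <- codon_effect(orfs, "o", c(2L, 1L, 3L), "G")
  expect_identical(e$effect,
                   c("synonymous", "nonsynonymous", "nonsynonymous"))
  expect_identical(e$aa_from, c("K", "K", "I"))
  expect_identical(e$aa_to, c("K", "R", "V"))
  ## position outside the CDS is noncoding
  orfs2 <- orf_set(c(o = "TTAAAATATT"),
                   data.frame(orf_id = "o", cds_start = 2, cds_end = 8,
                              frame_offset = 0))
  expect_identical(codon_effect(orfs2, "o", 0L, "G")$effect, "noncoding")
  expect_identical(codon_effect(orfs2, "o", 9L, "G")$effect, "noncoding")
  expect_identical(codon_effect(orfs2, "o", 3L, "G")$effect,
                   "nonsynonymous")
})

test_that("AAA-only ORF randomization converges to 2/3 nonsynonymous", {
  orfs <- orf_set(c(toy = paste(rep("AAA", 5000), collapse = "")))
  cm <- context_model(matrix(0.5, 4, 4))
  r <- context_preserving_randomization(orfs, cm, 10000, seed = 3)
  expect_equal(r$nonsyn_fraction, 2 / 3, tolerance = 0.02)
  ## zero-probability context is never accepted
  pr <- matrix(0.5, 4, 4, dimnames = list(BASES <- c("A", "C", "G", "T"),
                                          BASES))
  pr["G", ] <- 0
  sim <- default_sim()
  r2 <- context_preserving_randomization(sim$orfs, context_model(pr), 200,
                                         seed = 4)
  expect_false(any(r2$sites$five == "G"))
  ## asking for more sites than eligible A's errors
  expect_error(context_preserving_randomization(
    orf_set(c(o = "CCCCCC")), cm, 5), "eligible|exceeds")
})

test_that("randomization preserves the context histogram of the real site set", {
  ## >= 1000 context-biased sites; the null draws a matched number, so its
  ## expected context histogram is the site set's own histogram
  sim <- cached("ctx_sim2", simulate_dataset(
    sim_config(n_orfs = 60, editing_site_density = 60, seed = 12)))
  tr <- sim$truth$edited_sites
  expect_gte(nrow(tr), 1000)
  s <- data.table::data.table(orf_id = tr$orf_id, pos = tr$pos,
                              mismatch_type = "A>G", category = "weak",
                              editing_level = tr$level)
  np <- neighbor_preference(s, sim$orfs)
  r <- context_preserving_randomization(sim$orfs, np$model, nrow(tr),
                                        seed = 6)
  lev <- as.vector(outer(c("A", "C", "G", "T"),
                         c("A", "C", "G", "T"), paste))
  obs <- table(factor(paste(r$sites$five, r$sites$three), levels = lev))
  expected <- table(factor(paste(tr$five, tr$three), levels = lev))
  keep <- expected > 0
  gof <- suppressWarnings(chisq.test(
    as.vector(obs)[keep],
    p = as.vector(expected)[keep] / sum(expected[keep]),
    simulate.p.value = TRUE, B = 2000))
  expect_gt(gof$p.value, 0.01)
})

test_that("nonsyn-by-level bins compare observed against matched nulls", {
  sim <- default_sim()
  pu <- build_pileup(sim$orfs, sim$rna, sim$dna)
  res <- detect_sites(pu, detection_config(), orfs = sim$orfs)
  np <- neighbor_preference(res$sites, sim$orfs)
  nf <- nonsyn_fraction_by_level(res$sites, sim$orfs, np$model,
                                 breaks = c(0, 0.2, 0.5, 1),
                                 null_runs = 60, seed = 5)
  expect_identical(nrow(nf), 3L)
  occupied <- nf[nf$n > 0, ]
  expect_true(all(is.finite(occupied$observed)))
  expect_true(all(occupied$expected > 0.3 & occupied$expected < 0.9))
  expect_true(all(occupied$p_value > 0 & occupied$p_value <= 1))
  ## all-synonymous input gives observed 0 in every occupied bin
  syn <- res$sites[res$sites$codon_effect == "synonymous", ]
  if (nrow(syn) >= 2) {
    nf0 <- nonsyn_fraction_by_level(syn, sim$orfs, np$model,
                                    breaks = c(0, 1), null_runs = 20,
                                    seed = 5)
    expect_equal(nf0$observed[nf0$n > 0], 0)
  }
})

test_that("recoding summary computes cumulative levels and heavy editing", {
  s <- data.table::data.table(
    orf_id = c("o1", "o1", "o2", "o3"), pos = c(1L, 5L, 1L, 1L),
    mismatch_type = "A>G", category = "weak",
    editing_level = c(0.6, 0.5, 0.2, 0.9),
    codon_effect = c("nonsynonymous", "stop-loss", "synonymous",
                     "nonsynonymous"))
  rs <- recoding_summary(s)
  o1 <- rs[rs$orf_id == "o1", ]
  expect_identical(o1$n_recoding_sites, 2L)
  expect_equal(o1$cumulative_recoding_level, 1.1)
  expect_true(o1$heavily_edited)
  expect_false("o2" %in% rs$orf_id)   # synonymous only
  ## with an orf_set, unedited ORFs appear with zeros
  orfs <- orf_set(c(o1 = strrep("AAA", 10), o2 = strrep("AAA", 10),
                    o3 = strrep("AAA", 10), o4 = strrep("AAA", 10)))
  rs2 <- recoding_summary(s, orfs)
  expect_identical(nrow(rs2), 4L)
  expect_identical(rs2[rs2$orf_id == "o4", ]$n_recoding_sites, 0L)
  expect_equal(unname(multi_site_fraction(rs2, k = c(1, 2))),
               c(0.5, 0.25))
  ## level threshold restricts the counted sites
  rs3 <- recoding_summary(s, level_threshold = 0.55)
  expect_identical(rs3[rs3$orf_id == "o1", ]$n_recoding_sites, 1L)
})

test_that("substitution-score analysis separates planted level-score coupling", {
  sim <- default_sim()
  pu <- build_pileup(sim$orfs, sim$rna, sim$dna)
  res <- detect_sites(pu, detection_config(), orfs = sim$orfs)
  rec <- res$sites[res$sites$codon_effect %in%
                     c("nonsynonymous", "stop-gain", "stop-loss"), ]
  expect_gt(nrow(rec), 5)
  cds <- sim$orfs$cds
  m <- match(rec$orf_id, cds$orf_id)
  aa_pos <- (rec$pos - cds$cds_start[m]) %/% 3 + 1
  ## planted coupling: low scores go with low levels
  score <- ifelse(rec$editing_level < stats::median(rec$editing_level),
                  -4L, 3L)
  st <- data.table::data.table(orf_id = rec$orf_id, aa_pos = aa_pos,
                               aa = rec$aa_to, score = score)
  sa <- substitution_score_analysis(res$sites, st, sim$orfs,
                                    shuffle_runs = 200, seed = 8)
  bs <- sa$by_score
  expect_identical(sort(bs$score), sort(unique(score)))
  lo <- bs[bs$score == -4L, ]
  expect_lt(lo$mean_level, lo$null_lo)    # below the shuffled band
  expect_lt(lo$p_value, 0.05)
  expect_identical(sa$n_unscored, 0L)
  ## all-equal scores: flat observed curve, bands contain it
  st2 <- data.table::copy(st)[, score := 1L]
  sa2 <- substitution_score_analysis(res$sites, st2, sim$orfs,
                                     shuffle_runs = 50, seed = 8)
  expect_identical(nrow(sa2$by_score), 1L)
  expect_gte(sa2$by_score$p_value, 0.9)
  ## determinism under a fixed seed
  sa3 <- substitution_score_analysis(res$sites, st, sim$orfs,
                                     shuffle_runs = 200, seed = 8)
  expect_equal(sa$by_score, sa3$by_score)
  ## no overlap errors out
  st_none <- data.table::data.table(orf_id = "zzz", aa_pos = 1L, aa = "K",
                                    score = 0L)
  expect_error(substitution_score_analysis(res$sites, st_none, sim$orfs),
               "overlap")
})

test_that("score tables read from TSV join as expected", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("# orf_id\taa_pos\taa\tscore", "o1\t3\tR\t-2", "o1\t4\tK\t5"),
             tmp)
  st <- read_score_table(tmp)
  expect_identical(st$score, c(-2L, 5L))
  expect_identical(st$aa, c("R", "K"))
})
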