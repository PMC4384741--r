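test_that("weak-site p-value matches closed forms and brute summation", {
  expect_equal(weak_site_pvalue(0, 5), 1.0)
  expect_equal(weak_site_pvalue(2, 2, 0.001), 1e-6, tolerance = 1e-12)
  expect_equal(weak_site_pvalue(1, 1000, 0.001), 1 - 0.999^1000,
               tolerance = 1e-12)
  ## brute-force tail summation oracle
  expect_equal(weak_site_pvalue(3, 1000, 0.001),
               brute_binom_upper(3, 1000, 0.001), tolerance = 1e-10)
  expect_equal(weak_site_pvalue(3, 1000, 0.001), 0.0802, tolerance = 1e-3)
  expect_error(weak_site_pvalue(1, 0), "not testable")
  ## monotone non-increasing in k at fixed n
  p <- weak_site_pvalue(0:50, 50, 0.001)
  expect_true(all(diff(p) <= 0))
})

test_that("strong-site p-value is snp_prior x 2^-d", {
  expect_equal(strong_site_pvalue(1), 5e-4)
  expect_equal(strong_site_pvalue(10), 9.765625e-7)
  expect_error(strong_site_pvalue(0), "at least one")
  d <- 1:30
  expect_true(all(diff(strong_site_pvalue(d)) < 0))
})

test_that("Benjamini-Hochberg step-up matches hand calculations", {
  r <- benjamini_hochberg(0.01, fdr = 0.1)
  expect_true(r$reject)
  r <- benjamini_hochberg(c(0.001, 0.02, 0.9), fdr = 0.1)
  expect_identical(r$reject, c(TRUE, TRUE, FALSE))  # 0.02 <= 2*0.1/3
  r <- benjamini_hochberg(rep(1, 10), fdr = 0.1)
  expect_false(any(r$reject))
  expect_identical(benjamini_hochberg(numeric(0))$reject, logical(0))
})

test_that("weak calling detects a clear minority mismatch and applies the DNA veto", {
  orfs <- orf_set(c(o = strrep("A", 12)))
  rna <- make_aln("o", rep(0L, 100),
                  c(rep(paste0("G", strrep("A", 11)), 5),
                    rep(strrep("A", 12), 95)), prefix = "rna")
  dna_clean <- make_aln("o", rep(0L, 20), rep(strrep("A", 12), 20),
                        prefix = "dna")
  pu <- build_pileup(orfs, rna, dna_clean)
  s <- call_weak_sites(pu, detection_config())
  expect_identical(nrow(s), 1L)
  expect_identical(s$mismatch_type, "A>G")
  expect_identical(s$pos, 0L)
  expect_equal(s$editing_level, 0.05)
  expect_equal(s$p_value, brute_binom_upper(5, 100, 0.001), tolerance = 1e-10)
  ## one discordant DNA read vetoes the site at tolerance 0
  dna_dirty <- make_aln("o", rep(0L, 20),
                        c(paste0("G", strrep("A", 11)),
                          rep(strrep("A", 12), 19)), prefix = "dna")
  pu2 <- build_pileup(orfs, rna, dna_dirty)
  expect_identical(nrow(call_weak_sites(pu2, detection_config())), 0L)
  ## ... but survives with the validation-study tolerance
  cfg <- detection_config(dna_discordance_tolerance = 0.1)
  expect_identical(nrow(call_weak_sites(pu2, cfg)), 1L)
})

test_that("a single mismatching read among 1000 is not significant", {
  orfs <- orf_set(c(o = strrep("A", 4)))
  rna <- make_aln("o", rep(0L, 1000),
                  c("GAAA", rep("AAAA", 999)), prefix = "rna")
  pu <- build_pileup(orfs, rna)
  expect_identical(nrow(call_weak_sites(pu, detection_config())), 0L)
})

test_that("strong calling requires unanimous DNA and RNA support", {
  orfs <- orf_set(c(o = strrep("G", 9)))   # consensus carries the edit
  rna <- make_aln("o", rep(0L, 30), rep(strrep("G", 9), 30), prefix = "rna")
  dna_all <- make_aln("o", rep(0L, 15), rep(strrep("A", 9), 15),
                      prefix = "dna")
  pu <- build_pileup(orfs, rna, dna_all)
  s <- call_strong_sites(pu, detection_config())
  expect_identical(nrow(s), 9L)
  expect_identical(unique(s$mismatch_type), "A>G")  # genomic A -> RNA G
  expect_identical(unique(s$ref_base), "A")
  expect_identical(unique(s$consensus_base), "G")
  expect_equal(unique(s$p_value), 0.001 * 2^-15)
  expect_equal(unique(s$editing_level), 1)
  ## one agreeing DNA read breaks unanimity
  dna_mixed <- make_aln("o", rep(0L, 15),
                        c(strrep("G", 9), rep(strrep("A", 9), 14)),
                        prefix = "dna")
  pu2 <- build_pileup(orfs, rna, dna_mixed)
  expect_identical(nrow(call_strong_sites(pu2, detection_config())), 0L)
  ## no RNA coverage at all -> excluded under require_strong_rna_support
  pu3 <- build_pileup(orfs, make_aln("o", 0L, "G", qual = qstr(10, 1)),
                      dna_all)
  expect_identical(nrow(call_strong_sites(pu3, detection_config())), 0L)
  cfg_off <- detection_config(require_strong_rna_support = FALSE)
  expect_identical(nrow(call_strong_sites(pu3, cfg_off)), 9L)
})

test_that("weak/strong calling matches brute-force enumeration on random tiny pileups", {
  for (seed in 1:12) {
    fx <- random_tiny_pileup(seed)
    pu <- build_pileup(fx$orfs, fx$rna, fx$dna)
    cfg <- detection_config()
    w <- call_weak_sites(pu, cfg)
    bw <- brute_weak_calls(pu, cfg$error_prob, cfg$fdr,
                           cfg$dna_discordance_tolerance, cfg$min_dna_cov)
    expect_identical(nrow(w), nrow(bw), label = paste("weak n, seed", seed))
    if (nrow(w) > 0) {
      ow <- order(w$pos, w$alt_base); ob <- order(bw$pos, bw$alt)
      expect_identical(w$pos[ow], bw$pos[ob])
      expect_identical(w$alt_base[ow], bw$alt[ob])
      expect_equal(w$p_value[ow], bw$p[ob], tolerance = 1e-9)
    }
    s <- call_strong_sites(pu, cfg)
    bs <- brute_strong_calls(pu, cfg$snp_prior, cfg$fdr,
                             cfg$strong_support_mode)
    expect_identical(nrow(s), nrow(bs), label = paste("strong n, seed", seed))
    if (nrow(s) > 0) {
      os <- order(s$pos); obs <- order(bs$pos)
      expect_identical(s$pos[os], bs$pos[obs])
      expect_identical(s$ref_base[os], bs$ref[obs])
      expect_equal(s$p_value[os], bs$p[obs], tolerance = 1e-12)
    }
  }
})

test_that("merging keeps the strong call at doubly-called positions", {
  w <- call_weak_sites(build_pileup(
    orf_set(c(o = strrep("A", 12))),
    make_aln("o", rep(0L, 100), c(rep(paste0("G", strrep("A", 11)), 10),
                                  rep(strrep("A", 12), 90)))),
    detection_config())
  s <- data.table::copy(w)
  s[, `:=`(category = "strong", ref_base = "A", alt_base = "G")]
  expect_message(m <- classify_and_merge(w, s), "strong call kept")
  expect_identical(m$sites$category, "strong")
  expect_identical(nrow(m$summary), 24L)
  expect_identical(sum(m$summary$count), 1L)
})

test_that("noise rates reproduce the published worked examples", {
  nr <- estimate_noise_rates(c(AG_weak = 81930, nonAG_weak = 12403,
                               AG_strong = 5644, nonAG_strong = 219))
  expect_equal(round(100 * nr$weak_fp_rate), 15)
  expect_equal(round(100 * nr$strong_fp_rate), 4)
  expect_equal(round(100 * nr$atog_fraction), 87)
  ## zero denominator flagged
  expect_warning(
    nr0 <- estimate_noise_rates(c(AG_weak = 0, nonAG_weak = 5,
                                  AG_strong = 1, nonAG_strong = 0)),
    "denominator")
  expect_true(is.na(nr0$weak_fp_rate))
})

test_that("detection on a simulated dataset recovers truth within tolerance", {
  sim <- default_sim()
  pu <- build_pileup(sim$orfs, sim$rna, sim$dna)
  res <- detect_sites(pu, detection_config(), orfs = sim$orfs)
  expect_gt(nrow(res$sites), 0)
  ## summary counts match the merged table
  expect_identical(sum(res$summary$count), nrow(res$sites))
  perf <- detection_performance(res$sites, sim$truth)
  expect_gte(perf$precision, 0.9)
  expect_gte(perf$recall, 0.7)
})
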