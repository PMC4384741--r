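## brute-force cluster enumeration for the oracle check
brute_clusters <- function(sites, min_run) {
  s <- as.data.frame(sites)[order(sites$orf_id, sites$pos), ]
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    if (!is.null(cur) && nrow(cur) >= min_run)
      out[[length(out) + 1]] <<- cur
  }
  for (i in seq_len(nrow(s))) {
    if (is.null(cur) || s$orf_id[i] != cur$orf_id[1] ||
        s$mismatch_type[i] != cur$mismatch_type[1]) {
      flush(cur); cur <- s[i, , drop = FALSE]
    } else cur <- rbind(cur, s[i, , drop = FALSE])
  }
  flush(cur)
  out
}

fake_sites <- function(orf_id, pos, type) {
  data.table::data.table(orf_id = orf_id, pos = as.integer(pos),
                         mismatch_type = type, category = "weak",
                         editing_level = 0.2)
}

test_that("site clusters match hand and brute-force enumeration", {
  s <- fake_sites("o1", c(10, 14, 20), "A>G")
  cl <- find_site_clusters(s, min_run = 3)
  expect_identical(nrow(cl$clusters), 1L)
  expect_identical(cl$clusters$n_sites, 3L)
  ## interleaved other-type mismatch breaks the run
  s2 <- fake_sites("o1", c(10, 14, 20), c("A>G", "C>T", "A>G"))
  expect_identical(nrow(find_site_clusters(s2, min_run = 3)$clusters), 0L)
  ## oracle on random site sets over short ORFs
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:25, 1)
    rs <- fake_sites(sample(c("a", "b"), n, TRUE),
                     sample.int(50, n),
                     sample(c("A>G", "C>T", "G>A"), n, TRUE, c(.6, .2, .2)))
    rs <- unique(rs, by = c("orf_id", "pos"))
    cl <- find_site_clusters(rs, min_run = 3)
    br <- brute_clusters(rs, 3)
    expect_identical(nrow(cl$clusters), length(br),
                     label = paste("cluster count, seed", seed))
    if (length(br) > 0)
      expect_identical(sort(cl$clusters$start_pos),
                       sort(vapply(br, function(x) min(x$pos), integer(1))))
  }
})

test_that("max_gap variant bounds the distance between cluster members", {
  s <- fake_sites("o1", c(10, 14, 200), "A>G")
  expect_identical(nrow(find_site_clusters(s, 3)$clusters), 1L)
  expect_identical(nrow(find_site_clusters(s, 3, max_gap = 50)$clusters), 0L)
})

test_that("read-level clusters count runs of identical mismatch types", {
  orfs <- orf_set(c(o = strrep("A", 30)))
  ## read with G at three A positions, nothing else
  r1 <- make_aln("o", 0L, paste0("G", "AAA", "G", "AAA", "G",
                                 strrep("A", 21)))
  cl <- find_read_level_clusters(r1, orfs, min_run = 3)
  expect_identical(cl[cl$mismatch_type == "A>G", ]$n_reads, 1L)
  ## A>G, A>G, A>C, A>G: longest A>G run is 2
  r2 <- make_aln("o", 0L, paste0("G", "A", "G", "A", "C", "A", "G",
                                 strrep("A", 23)))
  cl2 <- find_read_level_clusters(r2, orfs, min_run = 3)
  expect_identical(cl2[cl2$mismatch_type == "A>G", ]$n_reads, 0L)
  expect_identical(sum(cl2$n_reads), 0L)
  ## several thresholds at once
  cl3 <- find_read_level_clusters(r1, orfs, min_run = 2:4)
  expect_identical(cl3[cl3$mismatch_type == "A>G", ]$n_reads,
                   c(1L, 1L, 0L))
})

test_that("triple-mismatch reads under the error null match the analytic expectation", {
  sim <- cached("err_sim", simulate_dataset(
    sim_config(n_orfs = 10, editing_site_density = 0, snp_het_rate = 0,
               rna_coverage = 200, dna_coverage = 0, seed = 21)))
  cl <- find_read_level_clusters(sim$rna[[1]], sim$orfs, min_run = 3,
                                 q_min = 0)
  n_reads <- nrow(sim$rna[[1]])
  ## P(>=3 errors of one identical type in a 100 nt read) is bounded above by
  ## P(Binom(100, 0.001) >= 3) ~ 1.6e-4; with ~6000 reads expect ~ 0 - 2 such
  ## reads in total across all 12 types
  expect_lte(sum(cl$n_reads),
             qbinom(1 - 1e-6, n_reads, pbinom(2, 100, 0.001,
                                              lower.tail = FALSE)))
})

test_that("neighbour preference recovers planted context composition", {
  ## all sites preceded by T: 5' T fraction 1
  orfs <- orf_set(c(o = paste0("C", strrep("TAG", 20), "C")))
  pos <- seq(2, 59, by = 3)   # the A of each TAG repeat
  s <- fake_sites("o", pos, "A>G")
  np <- neighbor_preference(s, orfs)
  e5 <- np$enrichment[np$enrichment$flank == "5prime", ]
  expect_identical(e5$observed[e5$base == "T"], length(pos))
  expect_identical(sum(e5$observed), length(pos))
  ## model probabilities: every TA_G context A is edited
  expect_equal(np$model$probs["T", "G"], 1)
  expect_true(all(np$model$probs[c("A", "C", "G"), ] == 0))
})

test_that("uniform null gives enrichment ratios near 1", {
  sim <- default_sim()
  ## uniform-context truth: resample sites ignoring context
  set.seed(1)
  ctx <- editcall:::orf_a_contexts(sim$orfs)
  pick <- ctx[sample.int(nrow(ctx), 400)]
  s <- fake_sites(pick$orf_id, pick$pos, "A>G")
  np <- neighbor_preference(s, sim$orfs)
  expect_true(all(abs(np$enrichment$ratio - 1) < 0.35))
  expect_gt(min(np$enrichment$p_value), 1e-4)
})

test_that("simulator context bias shows up as the planted enrichment", {
  sim <- cached("ctx_sim", simulate_dataset(
    sim_config(n_orfs = 30, editing_site_density = 60, seed = 33)))
  pu <- build_pileup(sim$orfs, sim$rna, sim$dna)
  res <- detect_sites(pu, detection_config(), orfs = sim$orfs)
  np <- neighbor_preference(res$sites, sim$orfs)
  e5 <- np$enrichment[np$enrichment$flank == "5prime", ]
  e3 <- np$enrichment[np$enrichment$flank == "3prime", ]
  ## planted bias: G depleted 5', G enriched 3'
  expect_lt(e5$ratio[e5$base == "G"], 0.7)
  expect_gt(e3$ratio[e3$base == "G"], 1.3)
})

test_that("level histogram and recurrence behave on known inputs", {
  s <- fake_sites("o", 1:3, "A>G")
  s$editing_level <- c(0.05, 0.55, 0.55)
  ld <- level_distribution(s)
  expect_identical(ld$count[ld$bin == 1], 1L)
  expect_identical(ld$count[ld$bin == 6], 2L)
  expect_identical(sum(ld$count), 3L)
  ## recurrence of identical tables is 1 in every range
  expect_equal(recurrence_fraction(s, s), 1)
  expect_equal(recurrence_fraction(s, s, lo = 0.5, hi = 0.6), 1)
  expect_equal(recurrence_fraction(s, s[1, ], lo = 0.5, hi = 0.6), 0)
  expect_true(is.na(recurrence_fraction(s, s, lo = 0.8, hi = 0.9)))
})

test_that("heterozygous SNPs without DNA coverage leak in near 50% level", {
  sim <- cached("snp_sim", simulate_dataset(
    sim_config(n_orfs = 20, editing_site_density = 0, snp_het_rate = 0.01,
               dna_coverage = 0, seed = 55)))
  pu <- build_pileup(sim$orfs, sim$rna, dna = NULL)
  res <- detect_sites(pu, detection_config(), orfs = sim$orfs)
  leaked <- res$sites
  expect_gt(nrow(leaked), 5)
  ## leaked het SNPs cluster around level 0.5
  expect_gt(mean(leaked$editing_level > 0.35 & leaked$editing_level < 0.65),
            0.8)
  ## with DNA coverage the same loci are filtered out
  sim2 <- cached("snp_sim_cov", simulate_dataset(
    sim_config(n_orfs = 20, editing_site_density = 0, snp_het_rate = 0.01,
               dna_coverage = 30, seed = 55)))
  pu2 <- build_pileup(sim2$orfs, sim2$rna, sim2$dna)
  res2 <- detect_sites(pu2, detection_config(), orfs = sim2$orfs)
  expect_lt(nrow(res2$sites), nrow(leaked) / 4)
})

test_that("saturation: full fraction equals the full run and counts rise with reads", {
  sim <- cached("small_sim", simulate_dataset(sim_config(n_orfs = 4,
                                                         seed = 9)))
  sat <- saturation_analysis(sim$orfs, sim$rna[[1]], sim$dna,
                             fractions = c(0.2, 0.6, 1), seeds = 1:2,
                             modes = "rna")
  full <- detect_sites(build_pileup(sim$orfs, sim$rna[[1]], sim$dna),
                       detection_config())
  full_ag <- full$summary[mismatch_type == "A>G" & category == "weak",
                          count]
  expect_true(all(sat[sat$fraction == 1, ]$n_weak_ag == full_ag))
  m <- tapply(sat$n_weak_ag, sat$fraction, mean)
  expect_true(all(diff(m) >= 0))
  expect_gt(cor(sat$fraction, sat$n_weak_ag, method = "spearman"), 0)
})

test_that("per-ORF site counts rise with RNA coverage bins", {
  sim <- default_sim()
  pu <- build_pileup(sim$orfs, sim$rna, sim$dna)
  res <- detect_sites(pu, detection_config())
  cb <- coverage_site_bins(res$sites, pu, sim$orfs, n_bins = 5)
  expect_identical(nrow(cb), 5L)
  expect_identical(sum(cb$n_orfs), length(sim$orfs))
})
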