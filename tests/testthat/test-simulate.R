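test_that("sim_config validates its invariants", {
  expect_s3_class(small_sim_config(1), "sim_config")
  expect_error(small_sim_config(1, n_clusters = 10, n_loci = 5),
               class = "glyconet_bad_config")
  expect_error(small_sim_config(1, cohort_n = c(100, -5, 100, 100)),
               class = "glyconet_bad_sample_size")
  expect_error(small_sim_config(1, eaf_range = c(0, 0.5)),
               class = "glyconet_bad_eaf")
  expect_error(small_sim_config(1, noise_sd = -1), class = "glyconet_bad_config")
  expect_error(sim_config(), class = "glyconet_missing_seed")
})

test_that("simulated p-values are the exact two-sided normal tail of beta/se", {
  gw <- simulate_multicohort_gwas(small_sim_config(5))
  ss <- gw$sumstats
  expect_equal(ss$p, 2 * pnorm(-abs(ss$beta / ss$se)), tolerance = 1e-12)
  expect_equal(ss$se, 1 / sqrt(2 * ss$eaf * (1 - ss$eaf) * ss$n),
               tolerance = 1e-12)
})

test_that("same-cluster zero-noise loci have rank-identical z vectors", {
  gw <- simulate_multicohort_gwas(
    small_sim_config(9, noise_sd = 0, n_loci = 4, n_clusters = 2,
                     background_pool_size = 0)
  )
  truth <- gw$truth
  cl1 <- truth$loci[truth$loci$cluster_id == truth$loci$cluster_id[1], ]
  leads <- cl1$lead_snp[1:2]
  z1 <- truth$beta_true[leads[1], ]
  z2 <- truth$beta_true[leads[2], ]
  expect_equal(cor(z1, z2, method = "spearman"), 1, tolerance = 1e-12)
})

test_that("background SNPs are null: ~5% of p-values below 0.05", {
  gw <- simulate_multicohort_gwas(
    small_sim_config(13, n_loci = 1, n_clusters = 1, snps_per_locus = 1,
                     background_pool_size = 10000, n_traits_direct = 1,
                     n_derived = 1, n_cohorts = 1, cohort_n = 1000)
  )
  bg <- gw$truth$snps$snp[is.na(gw$truth$snps$locus_id)]
  pv <- gw$sumstats$p[gw$sumstats$snp %in% bg]
  frac <- mean(pv < 0.05)
  # binomial error at pool size 10,000: 0.05 +/- 4 * sqrt(.05*.95/1e4)
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / 1e4))
})

test_that("regenerating with the same seed is byte-identical", {
  cfg <- small_sim_config(101)
  g1 <- simulate_multicohort_gwas(cfg)
  g2 <- simulate_multicohort_gwas(cfg)
  expect_identical(g1$sumstats, g2$sumstats)
  expect_identical(g1$truth$beta_true, g2$truth$beta_true)
  g3 <- simulate_multicohort_gwas(small_sim_config(102))
  expect_false(identical(g1$sumstats$beta, g3$sumstats$beta))
})

test_that("derived traits re-scale their parents and are labelled", {
  gw <- simulate_multicohort_gwas(small_sim_config(7, n_traits_direct = 20))
  der <- derive_normalized_traits(gw$sumstats, n_derived = 5, noise_sd = 0,
                                  seed = 8)
  expect_equal(length(unique(der$sumstats$trait_id)), 25)
  expect_equal(sum(der$trait_meta$derived), 5)
  # zero noise: derived z rank-identical to its parent
  meta <- der$trait_meta[der$trait_meta$derived, ][1, ]
  child <- der$sumstats[der$sumstats$trait_id == meta$trait_id &
                          der$sumstats$cohort_id == "cohort1", ]
  parent <- der$sumstats[der$sumstats$trait_id == meta$parent &
                           der$sumstats$cohort_id == "cohort1", ]
  child <- child[match(parent$snp, child$snp), ]
  expect_equal(cor(child$beta / child$se, parent$beta / parent$se,
                   method = "spearman"), 1, tolerance = 1e-12)
  # constant-zero parent stays null in the child
  zero_parent <- dplyr::mutate(parent, beta = 0)
  der0 <- derive_normalized_traits(zero_parent, n_derived = 1, noise_sd = 0,
                                   seed = 9)
  expect_equal(der0$sumstats$beta[der0$sumstats$trait_id == "D01"],
               rep(0, nrow(parent)))
  expect_error(derive_normalized_traits(gw$sumstats, n_derived = 50, seed = 1),
               class = "glyconet_bad_config")
})

test_that("ld panel attains the target within-block correlation", {
  p0 <- simulate_ld_panel(2, 10, 0, 800, seed = 3)
  cm0 <- cor(p0$genotypes)
  off <- abs(cm0[upper.tri(cm0)])
  expect_lt(mean(off), 0.05)

  p9 <- simulate_ld_panel(2, 10, 0.9, 2000, seed = 4)
  cm9 <- cor(p9$genotypes)
  within <- c(cm9[1:10, 1:10][upper.tri(diag(10))],
              cm9[11:20, 11:20][upper.tri(diag(10))])
  expect_gt(mean(within), 0.85)
  expect_lt(mean(within), 0.95)
  cross <- cm9[1:10, 11:20]
  expect_lt(mean(abs(cross)), 0.05)

  p1 <- simulate_ld_panel(1, 1, 0.5, 100, seed = 5)
  expect_equal(dim(cor(p1$genotypes)), c(1L, 1L))
  expect_equal(unname(cor(p1$genotypes)[1, 1]), 1)
  expect_true(all(p9$genotypes %in% 0:2))
  expect_error(simulate_ld_panel(1, 0, 0.5, 10, seed = 1),
               class = "glyconet_bad_config")
})

test_that("eqtl scenarios record their truth and reject impossible setups", {
  for (s in c("shared", "linkage", "null")) {
    sc <- simulate_eqtl_scenario(s, n = 500, block_size = 6, seed = 10)
    expect_equal(sc$scenario, s)
    expect_equal(length(sc$causal), switch(s, shared = 1L, linkage = 2L, null = 0L))
    expect_equal(dim(sc$ld), c(6L, 6L))
  }
  expect_error(simulate_eqtl_scenario("linkage", block_size = 1, seed = 1),
               class = "glyconet_bad_config")
})

test_that("tfbs dataset plants disruption at the requested fold and never alt == ref", {
  td <- simulate_tfbs_dataset(n_assoc = 100, n_nonassoc = 100,
                              planted_fold = 1, base_rate = 0.3, seed = 6)
  expect_true(all(td$flanks$alt != td$flanks$ref))
  pa <- mean(td$flanks$planted[td$flanks$class == "assoc"])
  pn <- mean(td$flanks$planted[td$flanks$class == "nonassoc"])
  # planted_fold = 1: equal planting rates up to binomial error
  expect_lt(abs(pa - pn), 4 * sqrt(2 * 0.3 * 0.7 / 100))
  expect_error(simulate_tfbs_dataset(planted_fold = 0.5, seed = 1),
               class = "glyconet_bad_config")
  expect_error(
    simulate_tfbs_dataset(pwm = planted_motif(length = 30, seed = 2),
                          flank_width = 21, seed = 3),
    class = "glyconet_short_flank"
  )
})

test_that("flank FASTA round-trips with its sidecar TSV", {
  td <- simulate_tfbs_dataset(n_assoc = 5, n_nonassoc = 5, planted_fold = 2,
                              seed = 12)
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  write_flanks_fasta(td$flanks, fa, tsv)
  back <- read_flanks_fasta(fa, tsv)
  expect_equal(back$seq, td$flanks$seq)
  expect_equal(back$ref, td$flanks$ref)
  expect_equal(back$snp_offset, td$flanks$snp_offset)
})
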