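test_that("build_effect_vectors assembles z = beta/se and excludes traits", {
  meta <- tidyr::expand_grid(snp = c("s1", "s2"),
                             trait_id = c("t1", "t2", "t3")) |>
    dplyr::mutate(beta = c(0.2, 0, 0.1, -0.3, 0.05, 0),
                  se = 0.1)
  v <- build_effect_vectors(meta, c("s1", "s2"), exclude_traits = "t3")
  expect_equal(dim(v), c(2L, 2L))
  expect_equal(v["s1", "t1"], 2)
  expect_false("t3" %in% colnames(v))

  expect_error(
    build_effect_vectors(meta[-1, ], c("s1", "s2")),
    regexp = "s1.*t1", class = "glyconet_missing_result"
  )
})

test_that("spearman_edge matches hand-computed and boundary cases", {
  v <- c(1, 2, 3, 4)
  expect_equal(spearman_edge(v, v)$rho, 1)
  expect_equal(spearman_edge(v, -v)$rho, -1)
  expect_equal(spearman_edge(v, -v)$abs_rho, 1)
  # Sum d^2 = 4 -> rho = 1 - 6*4/(4*15) = 0.6
  e <- spearman_edge(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(e$rho, 0.6, tolerance = 1e-12)
  expect_error(spearman_edge(c(1, 1, 1, 1), v),
               class = "glyconet_degenerate_vector")
})

test_that("spearman matches a rank-then-Pearson oracle on tied vectors", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, sd = 0.01 * (i %% 2))
    y <- sample(1:6, n, replace = TRUE)
    e <- spearman_edge(x, y)
    oracle <- cor(rank(x), rank(y))
    expect_equal(e$rho, oracle, tolerance = 1e-12)
    tstat <- oracle * sqrt((n - 2) / (1 - oracle^2))
    expect_equal(e$p_edge, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  }
})

test_that("build_network emits n(n-1)/2 symmetric edges", {
  set.seed(19)
  v <- matrix(rnorm(5 * 10), nrow = 5,
              dimnames = list(paste0("s", 1:5), NULL))
  edges <- build_network(v)
  expect_equal(nrow(edges), 10)
  e12 <- spearman_edge(v[1, ], v[2, ])
  e21 <- spearman_edge(v[2, ], v[1, ])
  expect_equal(e12$rho, e21$rho)

  two <- build_network(v[1:2, ])
  expect_equal(nrow(two), 1)
})

test_that("prune_network keeps the Bonferroni-significant edges, monotone in alpha", {
  set.seed(23)
  edges <- tibble::tibble(snp_a = "a", snp_b = paste0("b", 1:351),
                          rho = 0.5, abs_rho = 0.5,
                          p_edge = runif(351))
  pr <- prune_network(edges)
  expect_equal(attr(pr, "p_threshold"), 0.05 / 351)
  expect_true(all(pr$p_edge <= 0.05 / 351))
  pr_wide <- prune_network(edges, alpha = 0.5)
  expect_true(all(pr$p_edge %in% pr_wide$p_edge))

  none <- prune_network(dplyr::mutate(edges, p_edge = 1))
  expect_equal(nrow(none), 0)
})

test_that("permutation pool bookkeeping subtracts locus members then p-filtered SNPs", {
  snps <- tibble::tibble(snp = paste0("s", 1:10),
                         min_p = c(rep(0.5, 8), 1e-6, 1e-7))
  pool <- build_permutation_pool(snps, locus_members = c("s1", "s2", "s3"))
  expect_equal(pool$provenance$n_snps, c(10, 7, 5))
  expect_setequal(pool$pool, paste0("s", 4:8))

  all_in <- build_permutation_pool(snps[1:8, ], locus_members = character())
  expect_equal(all_in$pool, snps$snp[1:8])
  expect_error(build_permutation_pool(snps[9:10, ], character()),
               class = "glyconet_empty_pool")
})

test_that("permutation_null is seed-deterministic and exhaustive at k = pool", {
  set.seed(29)
  top <- matrix(rnorm(3 * 12), nrow = 3, dimnames = list(paste0("t", 1:3), NULL))
  poolv <- matrix(rnorm(50 * 12), nrow = 50,
                  dimnames = list(paste0("n", 1:50), NULL))
  n1 <- permutation_null(top, poolv, rownames(poolv), k = 20, seed = 7)
  n2 <- permutation_null(top, poolv, rownames(poolv), k = 20, seed = 7)
  expect_identical(n1$null, n2$null)

  ex1 <- permutation_null(top, poolv, rownames(poolv), k = 50, seed = 1)
  ex2 <- permutation_null(top, poolv, rownames(poolv), k = 50, seed = 99)
  expect_equal(ex1$null, ex2$null)   # exhaustive: order-independent

  expect_error(permutation_null(top, poolv, rownames(poolv), k = 51, seed = 1),
               class = "glyconet_k_too_large")
})

test_that("null_quantile is the upper-tail fraction", {
  null101 <- seq(0, 1, length.out = 101)
  expect_equal(null_quantile(median(null101), null101), 51 / 101)
  expect_equal(null_quantile(2, null101), 0)     # above every null value
  expect_equal(null_quantile(-1, null101), 1)    # below every null value
})

test_that("zero-noise planted clusters are recovered exactly (ARI = 1)", {
  cfg <- small_sim_config(31, n_loci = 9, n_clusters = 3, noise_sd = 0,
                          background_pool_size = 0)
  gw <- simulate_multicohort_gwas(cfg)
  meta <- ivw_meta(gw$sumstats)
  vectors <- build_effect_vectors(meta, gw$truth$loci$lead_snp)
  edges <- build_network(vectors)
  mat <- diag(9)
  rownames(mat) <- colnames(mat) <- rownames(vectors)
  for (i in seq_len(nrow(edges))) {
    mat[edges$snp_a[i], edges$snp_b[i]] <- edges$abs_rho[i]
    mat[edges$snp_b[i], edges$snp_a[i]] <- edges$abs_rho[i]
  }
  cl <- cluster_loci(mat, k = 3)
  truth <- gw$truth$loci$cluster_id[match(names(cl$labels),
                                          gw$truth$loci$lead_snp)]
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  # and agrees with the reference ARI implementation
  expect_equal(adjusted_rand_index(cl$labels, truth),
               mclust::adjustedRandIndex(cl$labels, truth))
})

test_that("cluster_loci handles identical rows, single locus, asymmetry", {
  m <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  cl <- cluster_loci(m, k = 2)
  expect_equal(cl$hclust$height[1], 0)           # identical rows merge at 0
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_true(all(diff(cl$hclust$height) >= 0))

  single <- cluster_loci(matrix(1, 1, 1, dimnames = list("x", "x")))
  expect_equal(single$labels, c(x = 1L))

  bad <- m
  bad[1, 2] <- 0.2
  expect_error(cluster_loci(bad), class = "glyconet_asymmetric_matrix")
})

test_that("including derived traits inflates within-parent-pair correlation", {
  cfg <- small_sim_config(37, n_loci = 4, n_clusters = 4,
                          background_pool_size = 0, n_traits_direct = 20)
  gw <- simulate_multicohort_gwas(cfg)
  der <- derive_normalized_traits(gw$sumstats, n_derived = 10, noise_sd = 0,
                                  seed = 38)
  meta <- ivw_meta(der$sumstats)
  leads <- gw$truth$loci$lead_snp
  derived <- der$trait_meta$trait_id[der$trait_meta$derived]
  with_derived <- build_network(build_effect_vectors(meta, leads))
  without <- build_network(build_effect_vectors(meta, leads,
                                                exclude_traits = derived))
  # duplicated (rescaled) traits up-weight shared rank structure
  expect_gt(mean(with_derived$abs_rho), mean(without$abs_rho))
  expect_equal(ncol(build_effect_vectors(meta, leads,
                                         exclude_traits = derived)), 20)
})

test_that("network export round-trips through GraphML and TSV", {
  edges <- tibble::tibble(snp_a = c("a", "a", "b"), snp_b = c("b", "c", "c"),
                          rho = c(0.9, -0.8, 0.7), abs_rho = c(0.9, 0.8, 0.7),
                          p_edge = c(1e-6, 1e-5, 1e-4), significant = TRUE)
  nodes <- tibble::tibble(snp = c("a", "b", "c"), gene = c("G1", "G2", "G3"))
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  export_network(edges, nodes, gml, tsv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$name, nodes$snp)
  expect_equal(sort(igraph::E(g)$rho2), sort(edges$rho^2))
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$rho, edges$rho)

  empty <- export_network(edges[0, ], nodes, tempfile(), tempfile())
  expect_equal(igraph::ecount(empty), 0)
  expect_error(export_network(edges, nodes[c(1, 1, 2), ], tempfile(), tempfile()),
               class = "glyconet_duplicate_nodes")
})
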