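# End-to-end orchestration: simulate -> meta-analyze -> map loci -> network
# -> permutation -> clustering -> report tables, under one seed.

#' Pipeline configuration
#'
#' One declarative configuration for a full synthetic-data run. The global
#' seed fans out to per-stage seeds by a fixed derivation so any stage can be
#' rerun in isolation and reproduce its output.
#'
#' @param seed Global integer seed (mandatory).
#' @param sim A [sim_config()]; its seed is derived from `seed` when omitted.
#' @param genome_wide,suggestive Significance tiers (defaults 2.4e-9 and
#'   2.4e-8: 5e-8 and 5e-7 Bonferroni-corrected for 21 independent traits).
#' @param gc Apply per-cohort genomic-control correction.
#' @param r2_min,max_span Locus-definition parameters.
#' @param k_perm Permutation sample size (capped at the null-pool size).
#' @param cluster_k Dendrogram cut for locus clustering.
#' @param alpha_edges Family-wise error rate for edge pruning.
#' @param joint_effects_path Optional TSV of external joint (conditional)
#'   effect estimates for the joint variance totals; must exist when given.
#' @return A list of class `glyco_config`.
#' @export
glyco_config <- function(seed,
                         sim = NULL,
                         genome_wide = GENOME_WIDE_P,
                         suggestive = SUGGESTIVE_P,
                         gc = TRUE,
                         r2_min = 0.5, max_span = 1e6,
                         k_perm = 1e4,
                         cluster_k = 3,
                         alpha_edges = 0.05,
                         joint_effects_path = NULL) {
  if (missing(seed)) abort_glyco("seed is mandatory", "missing_seed")
  seed <- as.integer(seed)
  # fixed per-stage seed derivation from the global seed
  stage_seeds <- (seed * 1000L + c(sim = 1L, derive = 2L, perm = 3L)) %% .Machine$integer.max
  if (is.null(sim)) sim <- sim_config(seed = stage_seeds[["sim"]])
  cfg <- list(seed = seed, stage_seeds = stage_seeds, sim = sim,
              genome_wide = genome_wide, suggestive = suggestive, gc = gc,
              r2_min = r2_min, max_span = max_span, k_perm = k_perm,
              cluster_k = cluster_k, alpha_edges = alpha_edges,
              joint_effects_path = joint_effects_path)
  if (genome_wide <= 0 || suggestive <= 0 || genome_wide >= suggestive) {
    abort_glyco("thresholds must be positive with genome_wide < suggestive",
                "bad_config")
  }
  if (!is.null(joint_effects_path) && !file.exists(joint_effects_path)) {
    abort_glyco(paste0("missing input: ", joint_effects_path), "missing_input")
  }
  structure(cfg, class = "glyco_config")
}

#' Run the full synthetic pipeline
#'
#' Stages, in dependency order: simulate multi-cohort GWAS with planted
#' cluster structure; add derived traits; genomic-control-correct each
#' cohort-trait scan and pool by fixed-effect inverse-variance meta-analysis;
#' classify associations and define/merge loci; build glycome-wide effect
#' vectors for the lead SNPs (derived traits excluded); build, prune and
#' permutation-validate the Spearman network; cluster loci; compute
#' univariate explained-variance totals; render report tables. A failed
#' stage halts the run, reporting the stage name; outputs of completed
#' stages are returned with a `partial` marker.
#'
#' @param config A [glyco_config()].
#' @return List of class `glyco_run`: stage outputs (`sim`, `meta`, `loci`,
#'   `network`, `clusters`, `variance`, `reports`) plus `manifest` (seeds,
#'   parameters, output digests).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "glyco_config"))
  if (!is.null(config$joint_effects_path) &&
      !file.exists(config$joint_effects_path)) {
    abort_glyco(paste0("missing input: ", config$joint_effects_path),
                "missing_input")
  }
  out <- list(partial = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_glyco(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                  "stage_failure")
    })
  }

  out$sim <- stage("simulate", {
    gw <- simulate_multicohort_gwas(config$sim)
    der <- derive_normalized_traits(gw$sumstats,
                                    n_derived = config$sim$n_derived,
                                    noise_sd = 0,
                                    seed = config$stage_seeds[["derive"]])
    gw$sumstats <- der$sumstats
    gw$trait_meta <- der$trait_meta
    gw
  })

  out$meta <- stage("meta", {
    ss <- out$sim$sumstats
    if (config$gc) {
      ss <- ss |>
        dplyr::group_by(.data$cohort_id, .data$trait_id) |>
        dplyr::group_modify(function(d, key) {
          lam <- gc_lambda(d$beta / d$se, min_snps = min(100, nrow(d)))
          gc_correct(d, lam$lambda_gc)
        }) |>
        dplyr::ungroup()
    }
    ivw_meta(ss)
  })

  out$loci <- stage("loci", {
    calls <- classify_association(out$meta, config$genome_wide, config$suggestive)
    snp_min <- calls |>
      dplyr::group_by(.data$snp) |>
      dplyr::summarise(p = min(.data$p), .groups = "drop") |>
      dplyr::left_join(dplyr::distinct(out$sim$truth$snps, .data$snp, .data$chr,
                                       .data$pos),
                       by = "snp")
    assoc <- snp_min |>
      dplyr::semi_join(dplyr::filter(calls, .data$tier != "none"), by = "snp")
    loci <- suppressWarnings(
      define_loci(assoc, out$sim$ld, config$r2_min, config$max_span)
    ) |>
      merge_overlapping()
    leads <- purrr::map_dfr(loci$members, select_lead_snp, meta = out$meta)
    loci$lead_trait <- leads$trait_id
    loci$n_other_glycans <- purrr::map2_int(
      loci$members, loci$lead_trait,
      function(m, lt) count_locus_glycans(m, calls, lt)
    )
    list(calls = calls, loci = loci, snp_min_p = snp_min)
  })

  out$network <- stage("network", {
    derived <- out$sim$trait_meta$trait_id[out$sim$trait_meta$derived]
    vectors <- build_effect_vectors(out$meta, out$loci$loci$lead_snp,
                                    exclude_traits = derived)
    edges <- build_network(vectors)
    pruned <- prune_network(edges, config$alpha_edges)
    pool <- build_permutation_pool(
      dplyr::rename(out$loci$snp_min_p, min_p = "p"),
      locus_members = unlist(out$loci$loci$members)
    )
    pool_vectors <- build_effect_vectors(out$meta, pool$pool,
                                         exclude_traits = derived)
    k <- min(config$k_perm, length(pool$pool))
    nulls <- permutation_null(vectors, pool_vectors, pool$pool, k = k,
                              seed = config$stage_seeds[["perm"]])
    edges_q <- pruned |>
      dplyr::mutate(
        quant_a = purrr::map2_dbl(.data$abs_rho, .data$snp_a, null_quantile,
                                  null = nulls),
        quant_b = purrr::map2_dbl(.data$abs_rho, .data$snp_b, null_quantile,
                                  null = nulls)
      )
    list(vectors = vectors, edges = edges, pruned = edges_q, pool = pool,
         nulls = nulls)
  })

  out$clusters <- stage("cluster", {
    vecs <- out$network$vectors
    n <- nrow(vecs)
    mat <- diag(n)
    rownames(mat) <- colnames(mat) <- rownames(vecs)
    for (i in seq_len(nrow(out$network$edges))) {
      e <- out$network$edges[i, ]
      mat[e$snp_a, e$snp_b] <- mat[e$snp_b, e$snp_a] <- e$abs_rho
    }
    cl <- cluster_loci(mat, k = config$cluster_k)
    list(matrix = mat, result = cl)
  })

  out$variance <- stage("variance", {
    sig_leads <- out$loci$calls |>
      dplyr::filter(.data$snp %in% out$loci$loci$lead_snp,
                    .data$tier == "significant") |>
      dplyr::transmute(snp = .data$snp, trait_id = .data$trait_id,
                       maf = fold_maf(.data$eaf), beta_u = .data$beta)
    per_glycan_totals(sig_leads, mode = "univariate")
  })

  out$reports <- stage("report", report_tables(out))
  out$partial <- FALSE
  out$manifest <- list(
    seed = config$seed,
    stage_seeds = config$stage_seeds,
    parameters = config[setdiff(names(config), c("sim", "stage_seeds"))],
    sim_parameters = unclass(config$sim),
    digests = list(
      meta = rlang::hash(out$meta),
      loci = rlang::hash(out$loci$loci),
      edges = rlang::hash(out$network$pruned),
      clusters = rlang::hash(out$clusters$result$labels),
      variance = rlang::hash(out$variance)
    )
  )
  class(out) <- "glyco_run"
  out
}

#' Render report tables from a pipeline run
#'
#' Three tab-ready tibbles: a locus report (locus rendered as
#' "chromosome:start-end", lead SNP with alleles and frequency, lead glycan,
#' count of other associated glycans, effect and p-value), an edge report
#' (SNP pair, correlation, per-SNP null quantiles), and the per-glycan
#' explained-variance totals.
#'
#' @param run A `glyco_run` (or the partial stage list during a run).
#' @return List of tibbles: `locus_report`, `edge_report`,
#'   `variance_report`.
#' @export
report_tables <- function(run) {
  need <- c("meta", "loci", "network")
  for (s in need) {
    if (is.null(run[[s]])) abort_glyco(paste0("missing upstream output: ", s),
                                       "missing_stage")
  }
  loci <- run$loci$loci
  lead_meta <- run$meta |>
    dplyr::semi_join(tibble::tibble(snp = loci$lead_snp,
                                    trait_id = loci$lead_trait),
                     by = c("snp", "trait_id")) |>
    dplyr::select("snp", "trait_id", "ea", "oa", "eaf", "beta", "p")
  locus_report <- loci |>
    dplyr::mutate(locus = locus_string(.data$chr, .data$start, .data$end)) |>
    dplyr::left_join(lead_meta,
                     by = c(lead_snp = "snp", lead_trait = "trait_id")) |>
    dplyr::select("locus", "lead_snp", "ea", "oa", "eaf",
                  glycan = "lead_trait", n_other_glycans = "n_other_glycans",
                  "beta", "p")
  edge_report <- run$network$pruned |>
    dplyr::select("snp_a", "snp_b", corr = "rho",
                  dplyr::any_of(c("quant_a", "quant_b")))
  variance_report <- run$variance %||% tibble::tibble()
  list(locus_report = locus_report, edge_report = edge_report,
       variance_report = variance_report)
}
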