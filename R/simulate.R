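# Synthetic-data generation with full ground truth: multi-cohort multi-trait
# GWAS summary statistics carrying a planted cluster structure, LD panels,
# shared/linkage/null eQTL scenario pairs, and motif-disruption datasets.

#' Simulation configuration
#'
#' Collects and validates every knob of the multi-cohort GWAS generator. The
#' defaults emulate the discovery study design: four cohorts of 849, 802,
#' 1960 and 4479 samples (8090 in total), 62 directly modelled glycan traits
#' (15 derived re-normalizations are added separately by
#' [derive_normalized_traits()]), 27 associated loci grouped into 3 latent
#' regulatory clusters, and a genome-wide background pool of null SNPs.
#'
#' @param n_cohorts Number of discovery cohorts.
#' @param cohort_n Integer vector of per-cohort sample sizes (length
#'   `n_cohorts`).
#' @param n_traits_direct Number of directly modelled glycan traits.
#' @param n_derived Number of derived traits added downstream (bookkeeping
#'   only here; must not exceed `n_traits_direct`).
#' @param n_loci Number of associated loci.
#' @param n_clusters Number of latent regulatory clusters
#'   (`<= n_loci`).
#' @param snps_per_locus SNPs per locus (lead plus LD partners).
#' @param background_pool_size Null background SNPs.
#' @param effect_scale Standard deviation of cluster template effects, in
#'   standardized-trait units per effect allele.
#' @param noise_sd Per-locus-per-trait deviation from the cluster template
#'   (standardized units, >= 0).
#' @param eaf_range Effect-allele frequency interval, strictly inside (0,1).
#' @param seed Integer seed (mandatory).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 4,
                       cohort_n = c(849, 802, 1960, 4479),
                       n_traits_direct = 62,
                       n_derived = 15,
                       n_loci = 27,
                       n_clusters = 3,
                       snps_per_locus = 5,
                       background_pool_size = 10000,
                       effect_scale = 0.1,
                       noise_sd = 0.01,
                       eaf_range = c(0.05, 0.95),
                       seed) {
  if (missing(seed)) abort_glyco("seed is mandatory", "missing_seed")
  cfg <- list(n_cohorts = n_cohorts, cohort_n = cohort_n,
              n_traits_direct = n_traits_direct, n_derived = n_derived,
              n_loci = n_loci, n_clusters = n_clusters,
              snps_per_locus = snps_per_locus,
              background_pool_size = background_pool_size,
              effect_scale = effect_scale, noise_sd = noise_sd,
              eaf_range = eaf_range, seed = as.integer(seed))
  counts <- c(n_cohorts, n_traits_direct, n_loci, n_clusters, snps_per_locus)
  if (any(counts < 1)) abort_glyco("all counts must be >= 1", "bad_config")
  if (background_pool_size < 0) abort_glyco("background pool must be >= 0", "bad_config")
  if (length(cohort_n) != n_cohorts) {
    abort_glyco("cohort_n must have length n_cohorts", "bad_config")
  }
  if (any(cohort_n <= 0)) abort_glyco("non-positive sample size", "bad_sample_size")
  if (n_clusters > n_loci) abort_glyco("n_clusters must be <= n_loci", "bad_config")
  if (n_derived > n_traits_direct) {
    abort_glyco("more derived traits than direct parents", "bad_config")
  }
  if (eaf_range[1] <= 0 || eaf_range[2] >= 1 || eaf_range[1] >= eaf_range[2]) {
    abort_glyco("eaf_range must be an interval inside (0,1)", "bad_eaf")
  }
  if (noise_sd < 0) abort_glyco("noise_sd must be >= 0", "bad_config")
  structure(cfg, class = "sim_config")
}

trait_ids <- function(n) sprintf("G%02d", seq_len(n))
derived_ids <- function(n) sprintf("D%02d", seq_len(n))

#' Simulate multi-cohort GWAS summary statistics with planted structure
#'
#' Each of `n_clusters` latent regulatory clusters has a template effect
#' vector over traits, drawn once from `Normal(0, effect_scale^2)`. Locus `l`
#' in cluster `c` loads on the template with `a_l ~ |Normal(1, 0.2)|`, so its
#' lead SNP's true effect on trait `t` is `a_l * w_ct + eps`,
#' `eps ~ Normal(0, noise_sd^2)`. Non-lead locus SNPs carry the lead effect
#' attenuated by their correlation `r` with the lead; background SNPs are
#' null. Per cohort, the observed effect is the true effect plus sampling
#' noise with `se = 1/sqrt(2*p*q*N)` (standardized traits), and the p-value
#' is the two-sided normal tail of `beta/se`.
#'
#' @param config A [sim_config()].
#' @return List with `sumstats` (long tibble: `cohort_id`, `trait_id`, `snp`,
#'   `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `n`, `info`), `ld`
#'   (within-locus pairwise `snp_a`, `snp_b`, `r2`), and `truth` (loci,
#'   per-SNP assignments, templates, true effect matrix).
#' @export
simulate_multicohort_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_traits <- config$n_traits_direct
  traits <- trait_ids(n_traits)

  templates <- matrix(stats::rnorm(config$n_clusters * n_traits,
                                   sd = config$effect_scale),
                      nrow = config$n_clusters,
                      dimnames = list(NULL, traits))
  cluster_of <- sample(rep_len(seq_len(config$n_clusters), config$n_loci))
  a_l <- abs(stats::rnorm(config$n_loci, mean = 1, sd = 0.2))

  n_locus_snps <- config$n_loci * config$snps_per_locus
  n_snps <- n_locus_snps + config$background_pool_size
  snp <- sprintf("rs%06d", seq_len(n_snps))
  locus_id <- c(rep(sprintf("L%02d", seq_len(config$n_loci)),
                    each = config$snps_per_locus),
                rep(NA_character_, config$background_pool_size))
  is_lead <- c(rep(c(TRUE, rep(FALSE, config$snps_per_locus - 1)),
                   config$n_loci),
               rep(FALSE, config$background_pool_size))

  # Locus geography: loci spread over chromosomes, members within 50 kb of
  # the lead; background SNPs are placed anywhere.
  locus_chr <- as.character(sample(1:22, config$n_loci, replace = TRUE))
  locus_center <- sample.int(2e8, config$n_loci)
  chr <- c(rep(locus_chr, each = config$snps_per_locus),
           as.character(sample(1:22, config$background_pool_size, replace = TRUE)))
  offset <- stats::rnorm(n_locus_snps, sd = 2e4)
  offset[is_lead[seq_len(n_locus_snps)]] <- 0
  pos <- c(rep(locus_center, each = config$snps_per_locus) + round(offset),
           sample.int(2e8, config$background_pool_size, replace = TRUE))

  # LD of each member with its lead; leads have r = 1.
  r_to_lead <- rep(1, n_snps)
  nonlead_in_locus <- !is_lead & !is.na(locus_id)
  r_to_lead[nonlead_in_locus] <-
    sqrt(stats::runif(sum(nonlead_in_locus), 0.55, 0.95))

  eaf <- stats::runif(n_snps, config$eaf_range[1], config$eaf_range[2])
  alleles <- t(vapply(seq_len(n_snps),
                      function(i) sample(BASES, 2), character(2)))

  beta_true <- matrix(0, nrow = n_snps, ncol = n_traits,
                      dimnames = list(snp, traits))
  lead_rows <- which(is_lead)
  lead_beta <- a_l * templates[cluster_of, , drop = FALSE] +
    matrix(stats::rnorm(config$n_loci * n_traits, sd = config$noise_sd),
           nrow = config$n_loci)
  for (l in seq_len(config$n_loci)) {
    rows <- which(locus_id == sprintf("L%02d", l))
    beta_true[rows, ] <- outer(r_to_lead[rows], lead_beta[l, ])
  }

  cohorts <- sprintf("cohort%d", seq_len(config$n_cohorts))
  tables <- vector("list", config$n_cohorts)
  for (k in seq_len(config$n_cohorts)) {
    N <- config$cohort_n[k]
    se_snp <- 1 / sqrt(2 * eaf * (1 - eaf) * N)
    beta_hat <- beta_true + matrix(stats::rnorm(n_snps * n_traits),
                                   nrow = n_snps) * se_snp
    z <- beta_hat / se_snp
    tables[[k]] <- tibble::tibble(
      cohort_id = cohorts[k],
      trait_id = rep(traits, each = n_snps),
      snp = rep(snp, n_traits),
      chr = rep(chr, n_traits),
      pos = rep(pos, n_traits),
      ea = rep(alleles[, 1], n_traits),
      oa = rep(alleles[, 2], n_traits),
      eaf = rep(eaf, n_traits),
      beta = as.vector(beta_hat),
      se = rep(se_snp, n_traits),
      p = p_from_z(as.vector(z)),
      n = N,
      info = 1
    )
  }

  # Within-locus pairwise LD implied by the single-lead structure:
  # r(i, j) = r_i * r_j through the lead haplotype.
  ld <- purrr::map_dfr(seq_len(config$n_loci), function(l) {
    rows <- which(locus_id == sprintf("L%02d", l))
    if (length(rows) < 2) return(NULL)
    pr <- utils::combn(rows, 2)
    tibble::tibble(snp_a = snp[pr[1, ]], snp_b = snp[pr[2, ]],
                   r2 = (r_to_lead[pr[1, ]] * r_to_lead[pr[2, ]])^2)
  })
  if (nrow(ld) == 0) {
    ld <- tibble::tibble(snp_a = character(), snp_b = character(),
                         r2 = numeric())
  }

  truth <- list(
    loci = tibble::tibble(
      locus_id = sprintf("L%02d", seq_len(config$n_loci)),
      cluster_id = cluster_of,
      lead_snp = snp[lead_rows],
      a_l = a_l,
      chr = locus_chr,
      center = locus_center
    ),
    snps = tibble::tibble(snp = snp, locus_id = locus_id, is_lead = is_lead,
                          r_to_lead = r_to_lead, chr = chr, pos = pos,
                          eaf = eaf, ea = alleles[, 1], oa = alleles[, 2]),
    templates = templates,
    beta_true = beta_true,
    trait_meta = tibble::tibble(trait_id = traits, derived = FALSE,
                                parent = NA_character_)
  )
  list(sumstats = dplyr::bind_rows(tables), ld = ld, truth = truth)
}

#' Add derived re-normalized traits to a summary table
#'
#' Each derived trait is a noisy affine re-scaling of one directly measured
#' parent trait (parents are the first `n_derived` direct traits): its
#' summary effect is `b * beta_parent + Normal(0, noise_sd)` with a positive
#' per-trait scale `b`, the standard error is inherited, and z/p are
#' recomputed. Derived trait ids (`D01`, ...) carry a `derived` flag in the
#' returned trait metadata so the downstream exclusion step is testable.
#'
#' @param sumstats Long summary tibble from [simulate_multicohort_gwas()].
#' @param n_derived Number of derived traits (at most the number of direct
#'   traits present).
#' @param noise_sd Added effect noise in standardized units (default 0).
#' @param seed Integer seed.
#' @return List with `sumstats` (direct plus derived rows) and `trait_meta`
#'   (`trait_id`, `derived`, `parent`).
#' @export
derive_normalized_traits <- function(sumstats, n_derived = 15, noise_sd = 0,
                                     seed) {
  stopifnot(!missing(seed))
  direct <- sort(unique(sumstats$trait_id))
  if (n_derived > length(direct)) {
    abort_glyco("more derived traits requested than direct parents", "bad_config")
  }
  set.seed(seed)
  scale_b <- stats::runif(n_derived, 0.6, 1.4)
  ids <- derived_ids(n_derived)
  derived_rows <- purrr::map_dfr(seq_len(n_derived), function(d) {
    parent <- sumstats[sumstats$trait_id == direct[d], ]
    parent$trait_id <- ids[d]
    parent$beta <- scale_b[d] * parent$beta +
      stats::rnorm(nrow(parent), sd = noise_sd)
    parent$p <- p_from_z(parent$beta / parent$se)
    parent
  })
  trait_meta <- tibble::tibble(
    trait_id = c(direct, ids),
    derived = c(rep(FALSE, length(direct)), rep(TRUE, n_derived)),
    parent = c(rep(NA_character_, length(direct)), direct[seq_len(n_derived)])
  )
  list(sumstats = dplyr::bind_rows(sumstats, derived_rows),
       trait_meta = trait_meta)
}

#' Simulate a block-structured LD reference panel
#'
#' Haplotypes within a block share an ancestral allele with probability
#' `sqrt(r)`, giving every within-block SNP pair an expected genotype
#' correlation of `within_block_r`; blocks are mutually independent. All
#' SNPs in one block share the block's allele frequency (drawn from
#' `maf_range`). Genotypes are allele counts in {0, 1, 2}.
#'
#' @param n_blocks,block_size Block layout (`block_size >= 1`).
#' @param within_block_r Target within-block correlation, in \[0, 1).
#' @param n_individuals Panel size.
#' @param seed Integer seed.
#' @param maf_range Per-block allele-frequency interval.
#' @return List with `genotypes` (individuals x SNPs integer matrix) and
#'   `snps` (tibble: `snp`, `block`, `pos`, `maf`).
#' @export
simulate_ld_panel <- function(n_blocks, block_size, within_block_r,
                              n_individuals, seed, maf_range = c(0.15, 0.5)) {
  if (block_size < 1) abort_glyco("block_size must be >= 1", "bad_config")
  if (within_block_r < 0 || within_block_r >= 1) {
    abort_glyco("within_block_r must lie in [0, 1)", "bad_config")
  }
  set.seed(seed)
  s <- sqrt(within_block_r)
  blocks <- vector("list", n_blocks)
  mafs <- stats::runif(n_blocks, maf_range[1], maf_range[2])
  hap_block <- function(p, m) {
    # one haplotype set: ancestral allele per haplotype, copied with prob s
    anc <- stats::rbinom(n_individuals, 1, p)
    copy <- matrix(stats::runif(n_individuals * m) < s, n_individuals, m)
    fresh <- matrix(stats::rbinom(n_individuals * m, 1, p), n_individuals, m)
    ifelse(copy, anc, fresh)
  }
  for (b in seq_len(n_blocks)) {
    blocks[[b]] <- hap_block(mafs[b], block_size) + hap_block(mafs[b], block_size)
  }
  geno <- do.call(cbind, blocks)
  snps <- tibble::tibble(
    snp = sprintf("blk%02d_snp%03d", rep(seq_len(n_blocks), each = block_size),
                  rep(seq_len(block_size), n_blocks)),
    block = rep(seq_len(n_blocks), each = block_size),
    pos = seq_len(n_blocks * block_size) * 1000L,
    maf = rep(mafs, each = block_size)
  )
  colnames(geno) <- snps$snp
  list(genotypes = geno, snps = snps)
}

# Marginal per-SNP regression summary statistics of phenotype on genotypes.
marginal_sumstats <- function(geno, pheno) {
  n <- length(pheno)
  gm <- colMeans(geno)
  gc <- sweep(geno, 2, gm)
  vg <- unname(colSums(gc^2))
  beta <- as.vector(crossprod(gc, pheno - mean(pheno))) / vg
  # residual variance of y ~ g per SNP
  vy <- sum((pheno - mean(pheno))^2)
  rss <- vy - beta^2 * vg
  se <- sqrt(pmax(rss, 0) / ((n - 2) * vg))
  tibble::tibble(snp = colnames(geno), beta = beta, se = se,
                 p = p_from_z(beta / se))
}

#' Simulate a paired exposure/outcome eQTL scenario
#'
#' Generates one LD block in two independent samples (exposure, e.g. gene
#' expression; outcome, e.g. a glycan trait) and plants one of three causal
#' configurations: `shared` (one SNP drives both traits), `linkage` (two
#' distinct SNPs in LD drive one trait each), or `null` (the outcome is
#' unassociated). Region-wide marginal summary statistics for both traits,
#' the reference LD correlation matrix, and the truth label are returned.
#'
#' @param scenario One of `"shared"`, `"linkage"`, `"null"`.
#' @param n Sample size per trait.
#' @param block_size SNPs in the region (>= 2 for `linkage`).
#' @param within_block_r Within-region LD (genotype correlation).
#' @param b_exp,b_out Causal allele effects (standardized-trait units per
#'   allele copy).
#' @param seed Integer seed.
#' @return List: `exposure`, `outcome` (summary tibbles), `ld` (signed r
#'   matrix from the exposure panel), `top_snp` (strongest exposure SNP),
#'   `causal` (planted causal SNP ids), `scenario`.
#' @export
simulate_eqtl_scenario <- function(scenario = c("shared", "linkage", "null"),
                                   n = 5000, block_size = 20,
                                   within_block_r = 0.6,
                                   b_exp = 0.3, b_out = 0.3, seed) {
  scenario <- match.arg(scenario)
  stopifnot(!missing(seed))
  if (scenario == "linkage" && block_size < 2) {
    abort_glyco("linkage scenario requires at least two SNPs in the block",
                "bad_config")
  }
  set.seed(seed)
  pe <- simulate_ld_panel(1, block_size, within_block_r, n,
                          seed = sample.int(.Machine$integer.max, 1))
  po <- simulate_ld_panel(1, block_size, within_block_r, n,
                          seed = sample.int(.Machine$integer.max, 1))
  j1 <- ceiling(block_size / 2)
  j2 <- if (block_size >= 2) max(1L, j1 - 1L) else j1
  x <- pe$genotypes[, j1] * b_exp + stats::rnorm(n)
  y <- switch(scenario,
    shared = po$genotypes[, j1] * b_out + stats::rnorm(n),
    linkage = po$genotypes[, j2] * b_out + stats::rnorm(n),
    null = stats::rnorm(n)
  )
  exposure <- marginal_sumstats(pe$genotypes, x)
  outcome <- marginal_sumstats(po$genotypes, y)
  ld <- stats::cor(pe$genotypes)
  top_snp <- exposure$snp[which.min(exposure$p)]
  list(
    exposure = exposure, outcome = outcome, ld = ld, top_snp = top_snp,
    causal = switch(scenario,
                    shared = pe$snps$snp[j1],
                    linkage = c(pe$snps$snp[j1], pe$snps$snp[j2]),
                    null = character(0)),
    scenario = scenario
  )
}

#' Build a sharply informative planted motif
#'
#' A count matrix with 997 observations of the consensus base and 1 of each
#' alternative at every position; at length 14 the consensus probability
#' under a uniform background (0.25^14 ~ 3.7e-9) clears the genome-wide
#' binding-score significance threshold of 1.8e-8.
#'
#' @param length Motif length (default 14).
#' @param seed Integer seed for the consensus sequence.
#' @param tf Motif name.
#' @return A `glyco_pwm`.
#' @export
planted_motif <- function(length = 14, seed, tf = "PLANTED") {
  stopifnot(!missing(seed))
  set.seed(seed)
  consensus <- sample(BASES, length, replace = TRUE)
  counts <- matrix(1, nrow = 4, ncol = length, dimnames = list(BASES, NULL))
  counts[cbind(match(consensus, BASES), seq_len(length))] <- 997
  new_pwm(tf, counts, rep(0.25, 4), pseudocount = 1)
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, width, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a motif-disruption dataset
#'
#' Builds SNP flanking sequences for an "associated" and a "nonassociated"
#' class. Nonassociated SNPs disrupt the planted motif at `base_rate`;
#' associated SNPs at `planted_fold * base_rate`. A disrupting SNP has the
#' motif consensus embedded across its position with the reference allele on
#' the consensus base and the alternate allele on the worst-scoring base of
#' that column; other SNPs sit in random sequence. The alternate allele never
#' equals the reference.
#'
#' @param pwm A `glyco_pwm` to plant (default [planted_motif()]).
#' @param n_assoc,n_nonassoc SNPs per class.
#' @param planted_fold Enrichment of disruption among associated SNPs
#'   (>= 1).
#' @param base_rate Disruption rate among nonassociated SNPs (default 0.1;
#'   `planted_fold * base_rate` must not exceed 1).
#' @param flank_width Flank length in bases (odd; SNP at the center; must be
#'   at least the motif length).
#' @param seed Integer seed.
#' @return List with `flanks` (tibble: `snp`, `class`, `seq`, `snp_offset`,
#'   `ref`, `alt`, `planted`), `pwm`, and `truth` (per-SNP planted flags).
#' @export
simulate_tfbs_dataset <- function(pwm = NULL, n_assoc = 500, n_nonassoc = 500,
                                  planted_fold = 4, base_rate = 0.1,
                                  flank_width = 41, seed) {
  stopifnot(!missing(seed))
  if (planted_fold < 1) abort_glyco("planted_fold must be >= 1", "bad_config")
  set.seed(seed)
  if (is.null(pwm)) pwm <- planted_motif(seed = sample.int(1e6, 1))
  L <- pwm$length
  if (L > flank_width) abort_glyco("motif longer than flank", "short_flank")
  if (planted_fold * base_rate > 1) {
    abort_glyco("planted_fold * base_rate exceeds 1", "bad_config")
  }
  consensus <- BASES[apply(pwm$counts, 2, which.max)]
  center <- (flank_width + 1) %/% 2
  make_class <- function(n, rate, class, id0) {
    planted <- stats::runif(n) < rate
    seqs <- random_dna(n, flank_width)
    ref <- alt <- character(n)
    for (i in seq_len(n)) {
      if (planted[i]) {
        # motif column placed on the SNP, constrained to keep the embedded
        # motif inside the flank
        ok_cols <- seq(max(1L, center - (flank_width - L)), min(L, center))
        col <- if (length(ok_cols) == 1) ok_cols else sample(ok_cols, 1)
        start <- center - col + 1
        substr(seqs[i], start, start + L - 1) <- paste(consensus, collapse = "")
        ref[i] <- consensus[col]
        alt[i] <- BASES[which.min(pwm$log_odds[, col])]
      } else {
        ref[i] <- substr(seqs[i], center, center)
        alt[i] <- sample(setdiff(BASES, ref[i]), 1)
      }
    }
    tibble::tibble(
      snp = sprintf("%s%04d", class, id0 + seq_len(n)),
      class = class, seq = seqs, snp_offset = center,
      ref = ref, alt = alt, planted = planted
    )
  }
  flanks <- dplyr::bind_rows(
    make_class(n_assoc, planted_fold * base_rate, "assoc", 0),
    make_class(n_nonassoc, base_rate, "nonassoc", 0)
  )
  list(flanks = flanks, pwm = pwm,
       truth = dplyr::select(flanks, "snp", "class", "planted"))
}
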