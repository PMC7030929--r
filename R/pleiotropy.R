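# Summary-based Mendelian randomization and a HEIDI-style heterogeneity test:
# does a glycan trait and a second trait (gene expression or disease) share
# one causal variant, or do distinct variants in LD drive each?

# HLA region, GRCh37: excluded by default because of its complex LD.
HLA_REGION <- list(chr = "6", start = 29570005, end = 33377657)

in_hla <- function(chr, pos) {
  as.character(chr) == HLA_REGION$chr & pos >= HLA_REGION$start & pos <= HLA_REGION$end
}

#' Summary-based Mendelian randomization test at one SNP
#'
#' The ratio estimate `b_xy = beta_outcome / beta_exposure` measures the
#' outcome change per unit exposure under a shared-instrument model. The test
#' statistic `t_smr = z_exp^2 * z_out^2 / (z_exp^2 + z_out^2)` is referred to
#' the upper tail of a chi-square with 1 degree of freedom.
#'
#' @param beta_exp,se_exp Exposure effect and standard error at the top SNP.
#' @param beta_out,se_out Outcome effect and standard error at the same SNP.
#' @return One-row tibble: `b_xy`, `t_smr`, `p_smr`.
#' @export
smr_test <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) abort_glyco("undefined ratio: exposure beta is zero",
                                      "zero_exposure")
  z_exp <- beta_exp / se_exp
  z_out <- beta_out / se_out
  t_smr <- ifelse(z_exp^2 + z_out^2 == 0, 0,
                  z_exp^2 * z_out^2 / (z_exp^2 + z_out^2))
  tibble::tibble(
    b_xy = beta_out / beta_exp,
    t_smr = t_smr,
    p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  )
}

#' HEIDI-style heterogeneity test across a region
#'
#' Under a single shared causal variant, the ratio estimate `b_xy` is the
#' same at every SNP in LD with it; under distinct causal variants in LD the
#' ratios disagree. For each eligible non-top SNP the deviation
#' `d_i = b_xy(i) - b_xy(top)` is standardized by a delta-method variance
#' that propagates both traits' sampling error and the LD-induced covariance
#' with the top SNP, and `sum(z_d^2)` is referred to a chi-square with as
#' many degrees of freedom as eligible SNPs.
#'
#' Eligibility: exposure p-value below `p_floor`, squared correlation with
#' the top SNP inside `[r2_lo, r2_hi]`, strongest exposure associations
#' first, at most `max_snps`.
#'
#' @param exposure,outcome Tibbles with `snp`, `beta`, `se` covering the
#'   region (exposure and outcome measured in independent samples).
#' @param ld Square correlation matrix (r, signed) with SNP ids as dimnames.
#' @param top_snp SNP id of the SMR instrument.
#' @param p_floor Exposure significance floor for eligibility (default
#'   1.6e-4).
#' @param r2_lo,r2_hi Eligible LD window with the top SNP (defaults 0.05 and
#'   0.90).
#' @param max_snps Maximum eligible SNPs, strongest exposure first (default
#'   20).
#' @return One-row tibble: `p_heidi`, `n_heidi_snps`, `testable` (fewer than
#'   3 eligible SNPs yields `testable = FALSE` and `p_heidi = NA`).
#' @export
heidi_test <- function(exposure, outcome, ld, top_snp, p_floor = 1.6e-4,
                       r2_lo = 0.05, r2_hi = 0.90, max_snps = 20) {
  stopifnot(top_snp %in% exposure$snp, top_snp %in% outcome$snp,
            top_snp %in% rownames(ld))
  df <- dplyr::inner_join(
    dplyr::select(exposure, "snp", b_exp = "beta", se_exp = "se"),
    dplyr::select(outcome, "snp", b_out = "beta", se_out = "se"),
    by = "snp"
  ) |>
    dplyr::filter(.data$snp %in% rownames(ld)) |>
    dplyr::mutate(z_exp = .data$b_exp / .data$se_exp,
                  p_exp = p_from_z(.data$z_exp))
  top <- df[df$snp == top_snp, ]
  rest <- df[df$snp != top_snp, ]
  r_top <- ld[top_snp, rest$snp]
  eligible <- rest$p_exp < p_floor & r_top^2 >= r2_lo & r_top^2 <= r2_hi
  rest <- rest[eligible, , drop = FALSE]
  r_top <- r_top[eligible]
  if (nrow(rest) > max_snps) {
    keep <- order(rest$p_exp)[seq_len(max_snps)]
    rest <- rest[keep, , drop = FALSE]
    r_top <- r_top[keep]
  }
  if (nrow(rest) < 3) {
    return(tibble::tibble(p_heidi = NA_real_, n_heidi_snps = nrow(rest),
                          testable = FALSE))
  }
  bxy_top <- top$b_out / top$b_exp
  bxy_i <- rest$b_out / rest$b_exp
  d <- bxy_i - bxy_top
  # Delta-method variance of each b_xy and the LD-induced covariance of
  # b_xy(i) with b_xy(top); exposure and outcome samples are independent, so
  # no cross-trait covariance term.
  var_bxy <- function(b_exp, se_exp, b_out, se_out) {
    se_out^2 / b_exp^2 + b_out^2 * se_exp^2 / b_exp^4
  }
  v_i <- var_bxy(rest$b_exp, rest$se_exp, rest$b_out, rest$se_out)
  v_top <- var_bxy(top$b_exp, top$se_exp, top$b_out, top$se_out)
  cov_it <- r_top * rest$se_out * top$se_out / (rest$b_exp * top$b_exp) +
    rest$b_out * top$b_out * r_top * rest$se_exp * top$se_exp /
      (rest$b_exp^2 * top$b_exp^2)
  var_d <- pmax(v_i + v_top - 2 * cov_it, .Machine$double.eps)
  stat <- sum(d^2 / var_d)
  tibble::tibble(
    p_heidi = stats::pchisq(stat, df = nrow(rest), lower.tail = FALSE),
    n_heidi_snps = nrow(rest),
    testable = TRUE
  )
}

# Context-specific SMR significance: Bonferroni-corrected thresholds for the
# expression (2622 regions) and complex-trait screens.
SMR_ALPHA <- c(expression = 1.9e-5, complex_trait = 9.1e-4)

#' Classify a locus as pleiotropy, linkage, or not significant
#'
#' A significant SMR test with a passing heterogeneity test
#' (`p_heidi >= 0.05`) indicates one shared causal variant (pleiotropy); a
#' significant SMR test with heterogeneity (`p_heidi < 0.05`) indicates
#' distinct causal variants in LD (linkage); a non-significant SMR test is
#' `not_significant`. A significant SMR result whose HEIDI test could not be
#' run is `not_testable`.
#'
#' @param p_smr SMR p-value.
#' @param p_heidi HEIDI p-value (may be `NA` when not testable).
#' @param context `"expression"` (alpha 1.9e-5) or `"complex_trait"`
#'   (alpha 9.1e-4).
#' @param alpha Override the context threshold.
#' @param heidi_alpha Heterogeneity threshold (default 0.05).
#' @return Character verdict.
#' @export
classify_pleiotropy <- function(p_smr, p_heidi,
                                context = c("expression", "complex_trait"),
                                alpha = NULL, heidi_alpha = 0.05) {
  context <- match.arg(context)
  if (is.null(alpha)) alpha <- SMR_ALPHA[[context]]
  dplyr::case_when(
    p_smr > alpha ~ "not_significant",
    is.na(p_heidi) ~ "not_testable",
    p_heidi >= heidi_alpha ~ "pleiotropy",
    TRUE ~ "linkage"
  )
}

#' Run the SMR/HEIDI pipeline for one locus-outcome pair
#'
#' Convenience wrapper: SMR at the top SNP, HEIDI across the region, verdict
#' and effect direction. Loci inside the HLA region (chr6:29570005-33377657,
#' GRCh37) are rejected by default because of its complex LD structure.
#'
#' @param exposure,outcome Regional summary tibbles (`snp`, `beta`, `se`).
#' @param ld Signed SNP correlation matrix.
#' @param top_snp Instrument SNP id.
#' @param context `"expression"` or `"complex_trait"`.
#' @param chr,pos Optional top-SNP coordinates for the HLA guard.
#' @param exclude_hla Reject HLA-region inputs (default `TRUE`).
#' @param ... Passed to [heidi_test()].
#' @return One-row tibble: `top_snp`, `b_xy`, `t_smr`, `p_smr`, `p_heidi`,
#'   `n_heidi_snps`, `verdict`, `direction`.
#' @export
smr_heidi <- function(exposure, outcome, ld, top_snp,
                      context = c("expression", "complex_trait"),
                      chr = NULL, pos = NULL, exclude_hla = TRUE, ...) {
  context <- match.arg(context)
  if (exclude_hla && !is.null(chr) && !is.null(pos) && in_hla(chr, pos)) {
    abort_glyco("top SNP lies in the HLA region, excluded by default", "hla_region")
  }
  e_top <- exposure[exposure$snp == top_snp, ]
  o_top <- outcome[outcome$snp == top_snp, ]
  stopifnot(nrow(e_top) == 1, nrow(o_top) == 1)
  smr <- smr_test(e_top$beta, e_top$se, o_top$beta, o_top$se)
  heidi <- heidi_test(exposure, outcome, ld, top_snp, ...)
  tibble::tibble(
    top_snp = top_snp,
    b_xy = smr$b_xy, t_smr = smr$t_smr, p_smr = smr$p_smr,
    p_heidi = heidi$p_heidi, n_heidi_snps = heidi$n_heidi_snps,
    verdict = classify_pleiotropy(smr$p_smr, heidi$p_heidi, context),
    direction = ifelse(smr$b_xy > 0, "+", "-")
  )
}

#' Tabulate SMR effect directions per locus and outcome
#'
#' @param results Tibble of [smr_heidi()] rows with `locus` and `outcome`
#'   columns added by the caller.
#' @return Wide tibble: one row per locus, one column per outcome, cells
#'   "+"/"-" (empty when untested).
#' @export
direction_report <- function(results) {
  stopifnot(all(c("locus", "outcome") %in% names(results)))
  results |>
    dplyr::select("locus", "outcome", "direction") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "direction",
                       values_fill = "")
}
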