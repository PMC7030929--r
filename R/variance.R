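# Explained phenotypic variance from marginal and joint effect estimates.
# Traits are rank-normalized (unit variance), so 2*p*q*beta^2 is directly the
# trait-variance fraction attributable to an additive biallelic SNP.

# Fold a frequency to the minor allele; the formula is symmetric in p,q but
# the convention keeps reports comparable across sources.
fold_maf <- function(p_freq) {
  stopifnot(all(p_freq > 0 & p_freq < 1))
  pmin(p_freq, 1 - p_freq)
}

#' Univariate explained variance of a SNP
#'
#' `sigma_u = 2 * p * q * beta^2`, where `p` and `q` are the minor and major
#' allele frequencies and `beta` the marginal (univariate) effect on a
#' standardized trait. Effect sign is irrelevant; frequencies are folded to
#' the minor allele before use.
#'
#' @param p_freq Allele frequency in (0,1) (folded internally).
#' @param beta_u Marginal effect estimate.
#' @return Explained trait-variance fraction (>= 0).
#' @export
univariate_variance <- function(p_freq, beta_u) {
  p <- fold_maf(p_freq)
  2 * p * (1 - p) * beta_u^2
}

#' Joint contribution of a SNP to explained variance
#'
#' `sigma_J = 2 * p * q * beta_u * beta_J`, combining the marginal estimate
#' with the joint (conditional) estimate from an external stepwise analysis.
#' When the two estimates disagree in sign the contribution is negative; it is
#' reported as-is, never clipped.
#'
#' @param p_freq Allele frequency in (0,1) (folded internally).
#' @param beta_u Marginal effect estimate.
#' @param beta_j Joint effect estimate; missing values are an error.
#' @return Signed variance contribution.
#' @export
joint_variance <- function(p_freq, beta_u, beta_j) {
  if (any(is.na(beta_j))) abort_glyco("missing joint effect estimate", "missing_beta_j")
  p <- fold_maf(p_freq)
  2 * p * (1 - p) * beta_u * beta_j
}

#' Per-glycan totals of explained variance
#'
#' Sums per-SNP explained-variance terms per trait. In `"univariate"` mode the
#' SNP set is the significant top SNPs and the term is `2pq beta_u^2`; in
#' `"joint"` mode all independently contributing SNPs enter with
#' `2pq beta_u beta_J`. Traits with an empty SNP set are absent from the
#' output.
#'
#' @param records Tibble with `snp`, `trait_id`, `maf`, `beta_u`, and (for
#'   joint mode) `beta_j`.
#' @param mode `"univariate"` or `"joint"`.
#' @return Tibble of `trait_id`, `n_snps`, `total_variance`.
#' @export
per_glycan_totals <- function(records, mode = c("univariate", "joint")) {
  mode <- match.arg(mode)
  sigma <- if (mode == "univariate") {
    univariate_variance(records$maf, records$beta_u)
  } else {
    joint_variance(records$maf, records$beta_u, records$beta_j)
  }
  records |>
    dplyr::mutate(`..sigma` = sigma) |>
    dplyr::group_by(.data$trait_id) |>
    dplyr::summarise(n_snps = dplyr::n(),
                     total_variance = sum(.data$`..sigma`),
                     .groups = "drop")
}
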