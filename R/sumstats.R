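#' Read GWAS summary statistics from a delimited file
#'
#' Reads one cohort-trait association table (optionally gzip-compressed),
#' maps its columns onto the standard layout, validates every row against the
#' record invariants, and returns the valid rows as a tibble. Invalid rows are
#' not silently dropped: their count and per-reason breakdown are attached as
#' the `"rejected"` attribute and reported via a message.
#'
#' The standard columns are `snp` (identifier), `chr`, `pos` (1-based),
#' `ea`/`oa` (effect and other allele, single bases A/C/G/T), `eaf` (effect
#' allele frequency, in (0,1)), `beta` (effect in standardized-trait units),
#' `se` (> 0), `p` (in (0,1]), `n` (sample size), `info` (imputation quality
#' in \[0,1\]).
#'
#' @param path Path to a tab-separated file, plain or gzipped.
#' @param col_map Named character vector mapping standard names to the file's
#'   header names, e.g. `c(snp = "MarkerName", beta = "Effect")`. Standard
#'   names absent from the map are assumed to appear verbatim in the header.
#' @param trait_id,cohort_id Optional labels attached to every record.
#' @return A tibble of validated records with attribute `"rejected"`, a tibble
#'   of `(reason, n)` counts for the rows that failed validation.
#' @export
read_sumstats <- function(path, col_map = character(), trait_id = NULL,
                          cohort_id = NULL) {
  if (!file.exists(path)) {
    abort_glyco(paste0("file not found: ", path), "io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  std <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n", "info")
  file_name <- function(std_name) {
    if (std_name %in% names(col_map)) col_map[[std_name]] else std_name
  }
  missing <- std[!vapply(std, function(s) file_name(s) %in% names(raw), logical(1))]
  if (length(missing) > 0) {
    abort_glyco(paste0("missing mandatory column(s): ",
                       paste(vapply(missing, file_name, character(1)), collapse = ", ")),
                "missing_column")
  }
  df <- tibble::tibble(
    snp = raw[[file_name("snp")]],
    chr = raw[[file_name("chr")]],
    pos = suppressWarnings(as.integer(raw[[file_name("pos")]])),
    ea = toupper(raw[[file_name("ea")]]),
    oa = toupper(raw[[file_name("oa")]]),
    eaf = suppressWarnings(as.numeric(raw[[file_name("eaf")]])),
    beta = suppressWarnings(as.numeric(raw[[file_name("beta")]])),
    se = suppressWarnings(as.numeric(raw[[file_name("se")]])),
    p = suppressWarnings(as.numeric(raw[[file_name("p")]])),
    n = suppressWarnings(as.numeric(raw[[file_name("n")]])),
    info = suppressWarnings(as.numeric(raw[[file_name("info")]]))
  )
  validated <- validate_sumstats(df)
  out <- validated$records
  if (!is.null(trait_id)) out$trait_id <- trait_id
  if (!is.null(cohort_id)) out$cohort_id <- cohort_id
  if (nrow(validated$rejected) > 0) {
    rlang::inform(paste0(sum(validated$rejected$n_rows), " row(s) rejected while reading ",
                         path))
  }
  attr(out, "rejected") <- validated$rejected
  out
}

# Row-level validation against the SumStatRecord invariants. Returns the valid
# records and a per-reason rejection count.
validate_sumstats <- function(df) {
  bases <- c("A", "C", "G", "T")
  reasons <- dplyr::case_when(
    is.na(df$beta) | is.na(df$se) | is.na(df$p) | is.na(df$eaf) |
      is.na(df$pos) | is.na(df$n) ~ "unparseable numeric",
    df$se <= 0 ~ "nonpositive standard error",
    df$eaf <= 0 | df$eaf >= 1 ~ "eaf outside (0,1)",
    df$p <= 0 | df$p > 1 ~ "p outside (0,1]",
    !(df$ea %in% bases) | !(df$oa %in% bases) ~ "non-SNP allele",
    df$ea == df$oa ~ "identical alleles",
    !is.na(df$info) & (df$info < 0 | df$info > 1) ~ "info outside [0,1]",
    TRUE ~ NA_character_
  )
  rejected <- tibble::tibble(reason = reasons[!is.na(reasons)]) |>
    dplyr::count(.data$reason, name = "n_rows")
  list(records = df[is.na(reasons), , drop = FALSE], rejected = rejected)
}

#' Harmonize effect-allele orientation against a reference
#'
#' Aligns every record to a reference effect/other allele pair so effects can
#' be pooled across cohorts. Records already oriented pass through; swapped
#' records get `beta -> -beta`, `eaf -> 1 - eaf`; strand flips are resolved by
#' complementing both alleles and then applying the swap rule. Palindromic
#' (A/T or C/G) SNPs are flagged and, by default, retained; `strict = TRUE`
#' drops them. Records whose alleles cannot be reconciled are rejected with
#' reason `"allele mismatch"`.
#'
#' @param df Tibble of summary-statistic records (columns `snp`, `ea`, `oa`,
#'   `eaf`, `beta`, `p`, ...).
#' @param reference Tibble with columns `snp`, `ea`, `oa` giving the target
#'   orientation per SNP.
#' @param strict Drop palindromic SNPs instead of passing them through.
#' @return The harmonized tibble with a logical `palindromic` column; rejected
#'   rows are attached as the `"rejected"` attribute with their reason.
#' @export
harmonize_alleles <- function(df, reference, strict = FALSE) {
  ref <- reference[match(df$snp, reference$snp), ]
  same <- df$ea == ref$ea & df$oa == ref$oa
  swapped <- df$ea == ref$oa & df$oa == ref$ea
  flip_same <- complement_allele(df$ea) == ref$ea & complement_allele(df$oa) == ref$oa
  flip_swap <- complement_allele(df$ea) == ref$oa & complement_allele(df$oa) == ref$ea
  pal <- is_palindromic(df$ea, df$oa)
  # For palindromic SNPs strand status is unknowable from alleles alone:
  # same/swap already covers them, the strand branches add nothing new.
  action <- dplyr::case_when(
    is.na(ref$ea) ~ "mismatch",
    same ~ "keep",
    swapped ~ "swap",
    !pal & flip_same ~ "strand",
    !pal & flip_swap ~ "strand_swap",
    TRUE ~ "mismatch"
  )
  out <- df
  do_swap <- action %in% c("swap", "strand_swap")
  do_flip <- action %in% c("strand", "strand_swap")
  out$ea[do_flip] <- complement_allele(df$ea[do_flip])
  out$oa[do_flip] <- complement_allele(df$oa[do_flip])
  tmp_ea <- out$ea[do_swap]
  out$ea[do_swap] <- out$oa[do_swap]
  out$oa[do_swap] <- tmp_ea
  out$beta[do_swap] <- -out$beta[do_swap]
  out$eaf[do_swap] <- 1 - out$eaf[do_swap]
  out$palindromic <- pal
  keep <- action != "mismatch" & !(strict & pal)
  rejected <- df[action == "mismatch", , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- "allele mismatch"
  res <- out[keep, , drop = FALSE]
  attr(res, "rejected") <- rejected
  res
}

#' Genomic-control inflation factor
#'
#' Computes lambda_GC = median(z^2) / 0.4549 (the median of a chi-square with
#' one degree of freedom), the classical measure of residual test-statistic
#' inflation from population stratification.
#'
#' @param z Vector of association z-scores (beta/se).
#' @param min_snps Minimum number of values required (default 100); fewer is
#'   an error, since the median of a handful of statistics says nothing about
#'   inflation.
#' @return A one-row tibble with `lambda_gc` and `n_snps_used`.
#' @export
gc_lambda <- function(z, min_snps = 100) {
  z <- z[!is.na(z)]
  if (length(z) < min_snps) {
    abort_glyco(paste0("insufficient SNPs for lambda: ", length(z), " < ", min_snps),
                "insufficient_snps")
  }
  tibble::tibble(
    lambda_gc = stats::median(z^2) / CHISQ1_MEDIAN,
    n_snps_used = length(z)
  )
}

#' Apply genomic-control correction to summary statistics
#'
#' Inflates standard errors by `sqrt(lambda)` (deflating z and recomputing p)
#' when `lambda > 1`; a lambda at or below 1 leaves the records untouched.
#' Either way the lambda used is recorded in the `"gc"` attribute, so a run
#' with a deflation-free cohort is still auditable.
#'
#' @param df Tibble with `beta` and `se` columns.
#' @param lambda_gc Positive inflation factor (from [gc_lambda()]).
#' @return `df` with corrected `se`/`p` (and `z` if present) and attribute
#'   `"gc"`, a list with `lambda_gc` and `applied`.
#' @export
gc_correct <- function(df, lambda_gc) {
  stopifnot(is.numeric(lambda_gc), length(lambda_gc) == 1, lambda_gc > 0)
  applied <- lambda_gc > 1
  if (applied) {
    df$se <- df$se * sqrt(lambda_gc)
    if ("z" %in% names(df)) df$z <- df$beta / df$se
    df$p <- p_from_z(df$beta / df$se)
  }
  attr(df, "gc") <- list(lambda_gc = lambda_gc, applied = applied)
  df
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-cohort effect estimates for each SNP-trait pair with weights
#' `1/se^2`: `beta_meta = sum(w * beta) / sum(w)`, `se_meta = 1/sqrt(sum(w))`,
#' `z = beta_meta/se_meta`, and a two-sided normal p-value. The per-cohort
#' effect signs are concatenated into a METAL-style direction string.
#'
#' All records for one SNP must already share an allele orientation (see
#' [harmonize_alleles()]); mixed orientation is an error, not a warning.
#'
#' @param df Tibble of harmonized records with columns `snp`, `trait_id`,
#'   `beta`, `se`, `n`, and (for the orientation check) `ea`, `oa`. A
#'   `cohort_id` column, if present, orders the direction string.
#' @return One tibble row per SNP-trait pair: `snp`, `trait_id`, `ea`, `oa`,
#'   `eaf` (sample-size weighted), `beta`, `se`, `z`, `p`, `n`, `n_cohorts`,
#'   `direction`.
#' @export
ivw_meta <- function(df) {
  stopifnot(nrow(df) >= 1)
  if (!"trait_id" %in% names(df)) df$trait_id <- "trait"
  orient <- df |>
    dplyr::distinct(.data$snp, .data$ea, .data$oa) |>
    dplyr::count(.data$snp)
  if (any(orient$n > 1)) {
    abort_glyco("mixed allele orientation within a SNP: harmonize first",
                "orientation_mismatch")
  }
  if ("cohort_id" %in% names(df)) {
    df <- dplyr::arrange(df, .data$snp, .data$trait_id, .data$cohort_id)
  }
  df |>
    dplyr::group_by(.data$snp, .data$trait_id) |>
    dplyr::summarise(
      ea = .data$ea[1],
      oa = .data$oa[1],
      eaf = if (all(is.na(.data$eaf))) NA_real_ else
        stats::weighted.mean(.data$eaf, .data$n, na.rm = TRUE),
      direction = paste(ifelse(.data$beta > 0, "+",
                               ifelse(.data$beta < 0, "-", "0")),
                        collapse = ""),
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = 1 / sqrt(sum(1 / .data$se^2)),
      n = sum(.data$n),
      n_cohorts = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(z = .data$beta / .data$se, p = p_from_z(.data$z)) |>
    dplyr::relocate("z", "p", .after = "se")
}
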