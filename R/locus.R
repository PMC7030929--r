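# Significance scheme, locus definition and merging, lead-SNP selection,
# replication calls.

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0,1).
#' @param m Number of independent tests (>= 1).
#' @return `alpha / m`. Reporting elsewhere rounds to 2 significant figures;
#'   the returned value is exact.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) abort_glyco("m must be >= 1", "bad_m")
  alpha / m
}

# Genome-wide significance for 21 independent glycan traits, and the
# suggestive bound one order of magnitude looser.
GENOME_WIDE_P <- 5e-8 / 21
SUGGESTIVE_P <- 5e-7 / 21

#' Classify associations into significance tiers
#'
#' Three-tier call: `significant` when `p <= genome_wide`, `suggestive` when
#' `genome_wide < p <= suggestive`, otherwise `none`. A p-value exactly on a
#' threshold falls in the stricter tier.
#'
#' @param df Tibble with a `p` column (one row per SNP-trait test).
#' @param genome_wide,suggestive Tier thresholds; the defaults are 5e-8 and
#'   5e-7 Bonferroni-corrected for 21 independent glycan traits (2.4e-9 and
#'   2.4e-8).
#' @return `df` with a `tier` factor column.
#' @export
classify_association <- function(df, genome_wide = GENOME_WIDE_P,
                                 suggestive = SUGGESTIVE_P) {
  stopifnot(all(df$p > 0 & df$p <= 1), genome_wide < suggestive)
  df$tier <- factor(
    dplyr::case_when(
      df$p <= genome_wide ~ "significant",
      df$p <= suggestive ~ "suggestive",
      TRUE ~ "none"
    ),
    levels = c("significant", "suggestive", "none")
  )
  df
}

#' Define loci around associated SNPs by LD claiming
#'
#' Greedy clumping on the called SNPs: in ascending p-value order, each
#' still-unclaimed SNP seeds a locus and claims every unclaimed called SNP
#' with `r2 >= r2_min` within `max_span` base pairs on the same chromosome.
#' Locus bounds are the min/max positions of the members (1-based inclusive).
#' SNPs absent from the LD table are treated as singletons with a warning.
#'
#' @param calls Tibble of called SNPs: `snp`, `chr`, `pos`, `p` (minimum p
#'   across traits per SNP).
#' @param ld Tibble of pairwise LD: columns `snp_a`, `snp_b`, `r2`
#'   (unordered pairs; both orders accepted).
#' @param r2_min LD threshold for claiming (default 0.5).
#' @param max_span Maximum distance from the lead (default 1 Mb).
#' @return Tibble of loci: `locus_id`, `chr`, `start`, `end`, `lead_snp`,
#'   `lead_p`, `n_snps`, and a list-column `members` of member SNP ids.
#' @export
define_loci <- function(calls, ld, r2_min = 0.5, max_span = 1e6) {
  stopifnot(nrow(calls) >= 1)
  calls <- dplyr::arrange(calls, .data$p, .data$snp)
  ld2 <- dplyr::bind_rows(
    dplyr::select(ld, snp_a = "snp_a", snp_b = "snp_b", r2 = "r2"),
    dplyr::select(ld, snp_a = "snp_b", snp_b = "snp_a", r2 = "r2")
  ) |>
    dplyr::filter(.data$r2 >= r2_min)
  known <- unique(c(ld2$snp_a, ld2$snp_b))
  orphans <- setdiff(calls$snp, known)
  if (length(orphans) > 0) {
    rlang::warn(paste0(length(orphans),
                       " SNP(s) absent from the LD source; treated as singleton loci"))
  }
  claimed <- rep(FALSE, nrow(calls))
  names(claimed) <- calls$snp
  loci <- list()
  for (i in seq_len(nrow(calls))) {
    lead <- calls$snp[i]
    if (claimed[[lead]]) next
    partners <- ld2$snp_b[ld2$snp_a == lead]
    cand <- calls$snp %in% partners & !claimed &
      calls$chr == calls$chr[i] & abs(calls$pos - calls$pos[i]) <= max_span
    members <- c(lead, calls$snp[cand])
    claimed[members] <- TRUE
    pos <- calls$pos[match(members, calls$snp)]
    loci[[length(loci) + 1]] <- tibble::tibble(
      chr = calls$chr[i], start = min(pos), end = max(pos),
      lead_snp = lead, lead_p = calls$p[i], n_snps = length(members),
      members = list(members)
    )
  }
  out <- dplyr::bind_rows(loci) |>
    dplyr::arrange(.data$chr, .data$start)
  out$locus_id <- paste0("L", seq_len(nrow(out)))
  dplyr::relocate(out, "locus_id")
}

#' Merge overlapping loci
#'
#' Transitive interval merging per chromosome on 1-based inclusive bounds;
#' two loci sharing even one base are merged, and the lead of the merged
#' locus is the member lead with the smallest p-value.
#'
#' @param loci Tibble from [define_loci()].
#' @return Tibble in the same layout with pairwise-disjoint loci.
#' @export
merge_overlapping <- function(loci) {
  if (nrow(loci) <= 1) return(loci)
  loci <- dplyr::arrange(loci, .data$chr, .data$start, .data$end)
  group <- integer(nrow(loci))
  g <- 0L
  cur_end <- -Inf
  cur_chr <- ""
  for (i in seq_len(nrow(loci))) {
    if (loci$chr[i] != cur_chr || loci$start[i] > cur_end) {
      g <- g + 1L
      cur_chr <- loci$chr[i]
      cur_end <- loci$end[i]
    } else {
      cur_end <- max(cur_end, loci$end[i])
    }
    group[i] <- g
  }
  loci$`..group` <- group
  out <- loci |>
    dplyr::group_by(.data$`..group`) |>
    dplyr::summarise(
      chr = .data$chr[1],
      start = min(.data$start),
      end = max(.data$end),
      lead_snp = .data$lead_snp[which.min(.data$lead_p)],
      lead_p = min(.data$lead_p),
      members = list(sort(unique(unlist(.data$members)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_snps = lengths(.data$members)) |>
    dplyr::select(-"..group") |>
    dplyr::arrange(.data$chr, .data$start)
  out$locus_id <- paste0("L", seq_len(nrow(out)))
  dplyr::relocate(out, "locus_id", "chr", "start", "end", "lead_snp", "lead_p",
                  "n_snps", "members")
}

#' Select the lead SNP of a locus across all traits
#'
#' The lead (top) SNP is the member with the globally smallest p-value over
#' all member SNP x trait pairs; exact ties break lexicographically by
#' `(p, snp, trait_id)` so the choice is deterministic.
#'
#' @param members Character vector of member SNP ids (non-empty).
#' @param meta Tibble of meta-analysis results (`snp`, `trait_id`, `p`).
#' @return One-row tibble: `snp`, `trait_id`, `p`.
#' @export
select_lead_snp <- function(members, meta) {
  stopifnot(length(members) >= 1)
  hits <- meta |>
    dplyr::filter(.data$snp %in% members) |>
    dplyr::arrange(.data$p, .data$snp, .data$trait_id)
  if (nrow(hits) == 0) abort_glyco("no meta results for locus members", "no_results")
  dplyr::select(hits[1, ], "snp", "trait_id", "p")
}

#' Count other glycan traits associated with a locus
#'
#' Number of distinct traits with at least one suggestive-or-better call among
#' the member SNPs. The lead trait itself is excluded by default (the count is
#' of "other glycans"); set `include_lead_trait = TRUE` to count it.
#'
#' @param members Character vector of member SNP ids.
#' @param calls Tibble with `snp`, `trait_id`, `tier` (from
#'   [classify_association()]).
#' @param lead_trait Trait id of the lead association (excluded by default).
#' @param include_lead_trait Count the lead trait too.
#' @return Integer count.
#' @export
count_locus_glycans <- function(members, calls, lead_trait,
                                include_lead_trait = FALSE) {
  traits <- calls |>
    dplyr::filter(.data$snp %in% members,
                  .data$tier %in% c("significant", "suggestive")) |>
    dplyr::pull(.data$trait_id) |>
    unique()
  if (!include_lead_trait) traits <- setdiff(traits, lead_trait)
  length(traits)
}

#' Evaluate replication of discovery lead associations
#'
#' A discovery association replicates when its replication p-value passes the
#' Bonferroni bound `0.05 / n_loci` AND the effect direction agrees between
#' discovery and replication; the direction flag is also reported on its own.
#' Discovery and replication records must share an allele orientation.
#'
#' @param discovery,replication Tibbles with `snp`, `trait_id`, `ea`, `oa`,
#'   `beta`, `p`; rows are matched on `(snp, trait_id)`.
#' @param n_loci Number of genome-wide significant loci tested (Bonferroni
#'   denominator).
#' @return Tibble with `snp`, `trait_id`, `beta_disc`, `beta_repl`, `p_repl`,
#'   `direction_consistent`, `replicated`, and attribute `"p_threshold"`.
#' @export
evaluate_replication <- function(discovery, replication, n_loci) {
  stopifnot(n_loci >= 1)
  thr <- 0.05 / n_loci
  j <- dplyr::inner_join(
    dplyr::select(discovery, "snp", "trait_id", disc_ea = "ea", disc_oa = "oa",
                  beta_disc = "beta"),
    dplyr::select(replication, "snp", "trait_id", repl_ea = "ea", repl_oa = "oa",
                  beta_repl = "beta", p_repl = "p"),
    by = c("snp", "trait_id")
  )
  if (any(j$disc_ea != j$repl_ea | j$disc_oa != j$repl_oa)) {
    abort_glyco("discovery/replication allele orientation mismatch: harmonize first",
                "orientation_mismatch")
  }
  out <- j |>
    dplyr::mutate(
      direction_consistent = sign(.data$beta_disc) == sign(.data$beta_repl),
      replicated = .data$p_repl <= thr & .data$direction_consistent
    ) |>
    dplyr::select("snp", "trait_id", "beta_disc", "beta_repl", "p_repl",
                  "direction_consistent", "replicated")
  attr(out, "p_threshold") <- thr
  out
}

#' Export loci as BED intervals
#'
#' Converts the internal 1-based inclusive bounds to BED's 0-based half-open
#' convention and writes a tab-separated file with `chrom`, `chromStart`,
#' `chromEnd`, `name` (lead SNP).
#'
#' @param loci Tibble from [define_loci()]/[merge_overlapping()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- tibble::tibble(
    chrom = loci$chr,
    chromStart = loci$start - 1L,
    chromEnd = loci$end,
    name = loci$lead_snp
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

# "chromosome: locus start-locus end" rendering used in locus reports.
locus_string <- function(chr, start, end) {
  paste0(chr, ":", start, "-", end)
}
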