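# Glycome-wide effect vectors, the pairwise Spearman network, permutation
# validation, and hierarchical clustering of loci.

#' Build glycome-wide effect vectors for lead SNPs
#'
#' For each lead SNP, collects the association z-score (`beta/se`) on every
#' retained glycan trait into one ordered vector. Traits listed in
#' `exclude_traits` (typically the derived re-normalizations of directly
#' measured glycans) are dropped before the vectors are formed. A missing
#' SNP-trait combination is an error naming both — no silent imputation.
#'
#' @param meta Tibble of meta-analysis results with `snp`, `trait_id`, and
#'   either `z` or both `beta` and `se`.
#' @param lead_snps Character vector of lead SNP ids.
#' @param exclude_traits Character vector of trait ids to drop (default none).
#' @return A numeric matrix, one row per lead SNP, one column per retained
#'   trait (columns in sorted trait order, identical across rows).
#' @export
build_effect_vectors <- function(meta, lead_snps, exclude_traits = character()) {
  if (!"z" %in% names(meta)) meta$z <- meta$beta / meta$se
  sub <- meta |>
    dplyr::filter(.data$snp %in% lead_snps,
                  !.data$trait_id %in% exclude_traits)
  traits <- sort(unique(sub$trait_id))
  mat <- matrix(NA_real_, nrow = length(lead_snps), ncol = length(traits),
                dimnames = list(lead_snps, traits))
  mat[cbind(match(sub$snp, lead_snps), match(sub$trait_id, traits))] <- sub$z
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort_glyco(paste0("missing meta result for SNP ", lead_snps[miss[1]],
                       ", trait ", traits[miss[2]]), "missing_result")
  }
  mat
}

# Spearman rho with average ranks for ties, and the t-approximation p-value
# with n - 2 degrees of freedom.
spearman_rho_p <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_glyco("degenerate vector: all values equal", "degenerate_vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p)
}

#' Spearman correlation edge between two effect vectors
#'
#' @param v1,v2 Numeric vectors of equal length (>= 4), not all-constant.
#' @param snp_a,snp_b Optional node labels.
#' @return One-row tibble: `snp_a`, `snp_b`, `rho`, `abs_rho`, `p_edge`.
#' @export
spearman_edge <- function(v1, v2, snp_a = "a", snp_b = "b") {
  s <- spearman_rho_p(v1, v2)
  tibble::tibble(snp_a = snp_a, snp_b = snp_b,
                 rho = unname(s["rho"]), abs_rho = abs(unname(s["rho"])),
                 p_edge = unname(s["p"]))
}

#' All pairwise Spearman edges between effect vectors
#'
#' Computes the Spearman correlation and its p-value for every unordered pair
#' of rows, giving exactly `n(n-1)/2` edges.
#'
#' @param vectors Matrix from [build_effect_vectors()] (rows = lead SNPs).
#' @return Tibble of edges (`snp_a`, `snp_b`, `rho`, `abs_rho`, `p_edge`)
#'   with class `glyco_network`.
#' @export
build_network <- function(vectors) {
  n <- nrow(vectors)
  stopifnot(n >= 2)
  ids <- rownames(vectors) %||% paste0("snp", seq_len(n))
  pairs <- utils::combn(n, 2)
  edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    spearman_edge(vectors[i, ], vectors[j, ], ids[i], ids[j])
  })
  class(edges) <- c("glyco_network", class(edges))
  edges
}

#' Prune a correlation network to Bonferroni-significant edges
#'
#' Keeps edges with `p_edge <= alpha / n_edges`, the Bonferroni bound over all
#' pairwise tests in the build (e.g. 0.05/351 ~ 1.4e-4 for 27 nodes).
#'
#' @param edges Tibble from [build_network()].
#' @param alpha Family-wise error rate (default 0.05).
#' @return The significant edges with a `significant` column (all `TRUE`) and
#'   attribute `"p_threshold"`.
#' @export
prune_network <- function(edges, alpha = 0.05) {
  thr <- alpha / nrow(edges)
  out <- edges |>
    dplyr::filter(.data$p_edge <= thr) |>
    dplyr::mutate(significant = TRUE)
  attr(out, "p_threshold") <- thr
  attr(out, "n_tests") <- nrow(edges)
  out
}

#' Construct the null SNP pool for permutation analysis
#'
#' Starting from all genotyped/imputed SNPs, removes (i) every SNP inside any
#' associated locus and (ii) every SNP whose minimum association p-value
#' across traits is at or below `p_filter` — so the pool carries no residual
#' glycosylation signal. Counts at each stage are recorded.
#'
#' @param snps Tibble with `snp` and `min_p` (minimum p across all traits).
#' @param locus_members Character vector of SNP ids inside associated loci.
#' @param p_filter Exclusion threshold on `min_p` (default 5e-5).
#' @return List with `pool` (character vector of retained SNP ids) and
#'   `provenance`, a tibble of `(stage, n_snps)` for the stages `initial`,
#'   `after_locus_removal`, `final`.
#' @export
build_permutation_pool <- function(snps, locus_members, p_filter = 5e-5) {
  n0 <- nrow(snps)
  s1 <- snps[!snps$snp %in% locus_members, , drop = FALSE]
  s2 <- s1[s1$min_p > p_filter, , drop = FALSE]
  if (nrow(s2) == 0) abort_glyco("permutation pool is empty", "empty_pool")
  list(
    pool = s2$snp,
    provenance = tibble::tibble(
      stage = c("initial", "after_locus_removal", "final"),
      n_snps = c(n0, nrow(s1), nrow(s2))
    )
  )
}

#' Permutation null distributions of effect-vector correlations
#'
#' Samples `k` SNPs from the null pool once, without replacement, and reuses
#' the same sample for every top SNP (per-top-SNP resampling available via
#' `resample_per_top`). For each top SNP the absolute Spearman correlations of
#' its glycome-wide effects with those of the sampled null SNPs form the
#' reference distribution for edge validation.
#'
#' @param top_vectors Matrix of top-SNP effect vectors (rows = top SNPs).
#' @param pool_vectors Matrix of effect vectors for pool SNPs (rows named by
#'   SNP id).
#' @param pool Character vector of eligible pool SNP ids (from
#'   [build_permutation_pool()]).
#' @param k Number of null SNPs to sample (default 1e5, capped at pool size
#'   with an error if exceeded).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param resample_per_top Draw an independent sample per top SNP.
#' @return Object of class `glyco_null`: list with `null` (matrix of sorted
#'   `abs_rho`, one row per top SNP), `k`, `sampled_snps`, `seed`.
#' @export
permutation_null <- function(top_vectors, pool_vectors, pool, k = 1e5, seed,
                             resample_per_top = FALSE) {
  stopifnot(!missing(seed))
  pool <- intersect(pool, rownames(pool_vectors))
  if (k > length(pool)) {
    abort_glyco(paste0("k = ", k, " exceeds pool size ", length(pool)), "k_too_large")
  }
  top_ranks <- t(apply(top_vectors, 1, rank))
  set.seed(seed)
  if (resample_per_top) {
    # Independent draw per top SNP; abs Spearman = |Pearson on ranks|.
    rows <- lapply(seq_len(nrow(top_vectors)), function(i) {
      chosen_i <- sample(pool, k, replace = FALSE)
      null_ranks <- t(apply(pool_vectors[chosen_i, , drop = FALSE], 1, rank))
      abs(stats::cor(top_ranks[i, ], t(null_ranks)))[1, ]
    })
    null <- do.call(rbind, rows)
    chosen <- NULL
  } else {
    chosen <- sample(pool, k, replace = FALSE)
    null_ranks <- t(apply(pool_vectors[chosen, , drop = FALSE], 1, rank))
    # One matrix product gives all top x null rank correlations.
    null <- abs(stats::cor(t(top_ranks), t(null_ranks)))
  }
  null <- t(apply(null, 1, sort))
  rownames(null) <- rownames(top_vectors)
  structure(list(null = null, k = k, sampled_snps = chosen, seed = seed),
            class = "glyco_null")
}

#' Upper-tail quantile of an observed correlation in its null distribution
#'
#' Fraction of null absolute correlations at least as large as the observed
#' one; 0 means no null value reached the observed correlation. (Whether the
#' null is expressed in |rho| or rho^2 is immaterial: the map is monotone, so
#' the quantile is identical.)
#'
#' @param observed Observed absolute correlation.
#' @param null Numeric vector of null absolute correlations (non-empty), or a
#'   `glyco_null` object plus `top_snp`.
#' @param top_snp Row to use when `null` is a `glyco_null`.
#' @return Quantile in \[0,1\].
#' @export
null_quantile <- function(observed, null, top_snp = NULL) {
  if (inherits(null, "glyco_null")) {
    stopifnot(!is.null(top_snp))
    null <- null$null[top_snp, ]
  }
  stopifnot(length(null) > 0)
  mean(null >= observed)
}

#' Hierarchically cluster loci on their correlation profiles
#'
#' Rows of the (symmetric, unit-diagonal) absolute-correlation matrix are the
#' feature vectors; loci are clustered with Euclidean row distance and
#' complete linkage. A signed matrix may be supplied for sensitivity analysis.
#'
#' @param mat Square symmetric correlation matrix with unit diagonal.
#' @param k Number of clusters at which to cut the dendrogram (default 3).
#' @return Object of class `glyco_clusters`: list with `hclust` (the
#'   dendrogram), `labels` (named integer cluster labels at the cut), `k`.
#' @export
cluster_loci <- function(mat, k = 3) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (nrow(mat) > 1 && !isTRUE(all.equal(mat, t(mat), tolerance = 1e-8))) {
    abort_glyco("correlation matrix is not symmetric", "asymmetric_matrix")
  }
  if (nrow(mat) == 1) {
    return(structure(list(hclust = NULL,
                          labels = stats::setNames(1L, rownames(mat)), k = 1L),
                     class = "glyco_clusters"))
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = "complete")
  k <- min(k, nrow(mat))
  structure(list(hclust = hc, labels = stats::cutree(hc, k = k), k = k),
            class = "glyco_clusters")
}

#' Export a pruned network as GraphML and an edge-list TSV
#'
#' Nodes carry locus/gene annotations; edges carry `rho`, `rho2` (the squared
#' Spearman correlation used as edge weight in visualization) and the
#' significance flag. Both files round-trip: reading the GraphML back yields
#' the same nodes and edge weights.
#'
#' @param edges Pruned edge tibble (from [prune_network()]); may be empty.
#' @param nodes Tibble with `snp` and optional annotation columns (e.g.
#'   `gene`); `snp` must be unique.
#' @param graphml_path,tsv_path Output paths.
#' @return The igraph object, invisibly.
#' @export
export_network <- function(edges, nodes, graphml_path, tsv_path) {
  if (anyDuplicated(nodes$snp)) abort_glyco("duplicate node ids", "duplicate_nodes")
  el <- edges |>
    dplyr::mutate(rho2 = .data$rho^2) |>
    dplyr::select("snp_a", "snp_b", "rho", "rho2",
                  dplyr::any_of(c("p_edge", "significant")))
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = as.data.frame(nodes))
  igraph::write_graph(g, graphml_path, format = "graphml")
  readr::write_tsv(el, tsv_path)
  invisible(g)
}

#' Write permutation null distributions as a two-column TSV
#'
#' @param null_dist A `glyco_null` object.
#' @param path Output path; columns `top_snp`, `abs_rho`.
#' @return `path`, invisibly.
#' @export
write_null_tsv <- function(null_dist, path) {
  df <- tibble::tibble(
    top_snp = rep(rownames(null_dist$null), each = ncol(null_dist$null)),
    abs_rho = as.vector(t(null_dist$null))
  )
  readr::write_tsv(df, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
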