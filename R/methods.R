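# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.glyco_network <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.glyco_network <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x),
                 n_nodes = length(unique(c(x$snp_a, x$snp_b))),
                 mean_abs_rho = mean(x$abs_rho),
                 max_abs_rho = max(x$abs_rho))
}

#' @export
tidy.glyco_clusters <- function(x, ...) {
  tibble::tibble(locus = names(x$labels), cluster = unname(x$labels))
}

#' @export
glance.glyco_clusters <- function(x, ...) {
  tibble::tibble(k = x$k,
                 n_loci = length(x$labels),
                 max_merge_height = if (is.null(x$hclust)) NA_real_ else
                   max(x$hclust$height))
}

#' @export
tidy.glyco_null <- function(x, ...) {
  tibble::tibble(top_snp = rep(rownames(x$null), each = ncol(x$null)),
                 abs_rho = as.vector(t(x$null)))
}

#' @export
glance.glyco_null <- function(x, ...) {
  tibble::tibble(n_top_snps = nrow(x$null), k = x$k, seed = x$seed)
}

#' @export
tidy.glyco_run <- function(x, ...) {
  x$reports$locus_report
}

#' @export
glance.glyco_run <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$loci$loci),
                 n_edges_pruned = nrow(x$network$pruned),
                 n_pool = length(x$network$pool$pool),
                 k_perm = x$network$nulls$k,
                 k_clusters = x$clusters$result$k,
                 seed = x$manifest$seed)
}

#' Heatmap of the pairwise effect-vector correlation network
#'
#' @param object A `glyco_network` edge tibble from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glyco_network <- function(object, ...) {
  nodes <- sort(unique(c(object$snp_a, object$snp_b)))
  full <- dplyr::bind_rows(
    dplyr::select(object, a = "snp_a", b = "snp_b", "abs_rho"),
    dplyr::select(object, a = "snp_b", b = "snp_a", "abs_rho"),
    tibble::tibble(a = nodes, b = nodes, abs_rho = 1)
  )
  ggplot2::ggplot(full, ggplot2::aes(.data$a, .data$b, fill = .data$abs_rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "|rho|") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Glycome-wide effect correlation network") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

# Segment coordinates of an hclust dendrogram (leaves at height 0).
hclust_segments <- function(hc) {
  n <- length(hc$order)
  x_of <- function(node, xs) if (node < 0) which(hc$order == -node) else xs[node]
  xs <- numeric(nrow(hc$merge))
  segs <- vector("list", nrow(hc$merge))
  hts <- c(0)
  h_of <- function(node) if (node < 0) 0 else hc$height[node]
  for (i in seq_len(nrow(hc$merge))) {
    l <- hc$merge[i, 1]; r <- hc$merge[i, 2]
    xl <- x_of(l, xs); xr <- x_of(r, xs)
    segs[[i]] <- tibble::tibble(
      x = c(xl, xr, xl), xend = c(xl, xr, xr),
      y = c(h_of(l), h_of(r), hc$height[i]),
      yend = c(hc$height[i], hc$height[i], hc$height[i])
    )
    xs[i] <- (xl + xr) / 2
  }
  dplyr::bind_rows(segs)
}

#' Dendrogram of the locus clustering
#'
#' @param object A `glyco_clusters` from [cluster_loci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glyco_clusters <- function(object, ...) {
  if (is.null(object$hclust)) {
    return(ggplot2::ggplot() + ggplot2::ggtitle("single locus: trivial tree"))
  }
  hc <- object$hclust
  leaves <- tibble::tibble(
    x = seq_along(hc$order),
    label = hc$labels[hc$order],
    cluster = factor(object$labels[hc$labels[hc$order]])
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = hclust_segments(hc),
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = leaves,
      ggplot2::aes(x = .data$x, y = -0.02 * max(hc$height),
                   label = .data$label, colour = .data$cluster),
      angle = 90, hjust = 1, size = 2.8
    ) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "complete-linkage height",
                  title = "Hierarchical clustering of loci") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Null distribution of permutation correlations with observed edges
#'
#' @param object A `glyco_null` from [permutation_null()].
#' @param observed Optional tibble of observed edges (`snp_a`, `abs_rho`)
#'   drawn as vertical lines over the matching top SNP's null.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glyco_null <- function(object, observed = NULL, ...) {
  df <- tidy.glyco_null(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$abs_rho)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60") +
    ggplot2::facet_wrap(~top_snp) +
    ggplot2::labs(x = "|rho| against random null SNPs", y = "count",
                  title = "Permutation null of effect-vector correlations") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    obs <- dplyr::rename(observed, top_snp = "snp_a")
    p <- p + ggplot2::geom_vline(data = obs,
                                 ggplot2::aes(xintercept = .data$abs_rho),
                                 colour = "red", linetype = 2)
  }
  p
}

#' @export
print.glyco_run <- function(x, ...) {
  cat("<glyco_run>\n")
  cat("  loci:          ", nrow(x$loci$loci), "\n")
  cat("  pruned edges:  ", nrow(x$network$pruned), "of",
      nrow(x$network$edges), "\n")
  cat("  permutation k: ", x$network$nulls$k, "\n")
  cat("  clusters (k):  ", x$clusters$result$k, "\n")
  cat("  seed:          ", x$manifest$seed, "\n")
  invisible(x)
}

#' @export
print.glyco_pwm <- function(x, ...) {
  cat("<glyco_pwm>", x$tf, "length", x$length, "\n")
  invisible(x)
}
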