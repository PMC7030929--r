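# Internal helpers shared across modules.

# Two-sided normal tail for z; safe for |z| large (log-scale lower tail).
p_from_z <- function(z) {
  2 * stats::pnorm(-abs(z))
}

# Median of chi-square with 1 df; the null expectation behind lambda_GC.
CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) {
  unname(DNA_COMPLEMENT[x])
}

is_palindromic <- function(ea, oa) {
  ea == complement_allele(oa)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 means
#' the partitions are identical up to label permutation, 0 is the expectation
#' for unrelated partitions.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Abort with a classed condition so tests can assert on error class.
abort_glyco <- function(msg, class) {
  rlang::abort(msg, class = paste0("glyconet_", class))
}
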