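# Shared fixture builders. All randomness is seeded per call site.

small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_loci = 6, n_clusters = 3, snps_per_locus = 3,
         background_pool_size = 300, n_traits_direct = 20, n_derived = 5,
         seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

# A well-formed summary-statistics tibble for IO tests.
toy_sumstats <- function() {
  tibble::tibble(
    snp = c("rs1", "rs2", "rs3"),
    chr = c("1", "1", "2"),
    pos = c(100L, 200L, 300L),
    ea = c("A", "G", "T"),
    oa = c("G", "A", "C"),
    eaf = c(0.3, 0.5, 0.1),
    beta = c(0.2, -0.1, 0.05),
    se = c(0.05, 0.04, 0.06),
    p = c(1e-4, 0.01, 0.4),
    n = c(1000, 1000, 1000),
    info = c(0.99, 1, 0.95)
  )
}

write_toy_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

# A tiny JASPAR-format PWM file with one 4-long motif, and the identical
# counts in MEME minimal format.
toy_pwm_counts <- function() {
  matrix(c(8, 0, 1, 1,
           0, 9, 0, 1,
           1, 0, 8, 1,
           1, 1, 1, 7), nrow = 4, byrow = TRUE,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

write_toy_jaspar <- function(counts = toy_pwm_counts(),
                             path = tempfile(fileext = ".jaspar")) {
  fmt <- function(b) paste0(b, "  [ ", paste(counts[b, ], collapse = " "), " ]")
  writeLines(c(">MA0001.1 TOYTF", vapply(c("A", "C", "G", "T"), fmt, "")), path)
  path
}

write_toy_meme <- function(counts = toy_pwm_counts(),
                           path = tempfile(fileext = ".meme")) {
  nsites <- colSums(counts)[1]
  probs <- sweep(counts, 2, colSums(counts), "/")
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    "MOTIF TOYTF",
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            ncol(counts), nsites),
    apply(probs, 2, function(cl) paste(sprintf("%.10f", cl), collapse = " "))
  )
  writeLines(lines, path)
  path
}
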