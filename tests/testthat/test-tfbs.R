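test_that("JASPAR and MEME encodings of the same counts agree", {
  ja <- read_pwm(write_toy_jaspar(), "jaspar")
  me <- read_pwm(write_toy_meme(), "meme")
  expect_equal(names(ja), names(me))
  expect_equal(ja[[1]]$log_odds, me[[1]]$log_odds, tolerance = 1e-9)
  expect_equal(ja[[1]]$length, 4)

  expect_error(read_pwm(write_toy_jaspar(), "jaspar", pseudocount = 0),
               class = "glyconet_zero_cell")
  no_zero <- toy_pwm_counts() + 1
  expect_silent(read_pwm(write_toy_jaspar(no_zero), "jaspar", pseudocount = 0))
})

test_that("score_allele attains the column-max on consensus and is strand-symmetric", {
  pwm <- read_pwm(write_toy_jaspar(), "jaspar")[[1]]
  consensus <- paste(c("A", "C", "G", "T")[apply(pwm$counts, 2, which.max)],
                     collapse = "")
  flank <- paste0("TTTT", consensus, "TTTT")
  s <- score_allele(pwm, flank, substr(consensus, 1, 1), 5)
  expect_equal(s, sum(apply(pwm$log_odds, 2, max)), tolerance = 1e-12)

  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(flank, "")[[1]]), collapse = ""))
  s_rc <- score_allele(pwm, rc, chartr("ACGT", "TGCA", substr(consensus, 1, 1)),
                       nchar(flank) - 5 + 1)
  expect_equal(s_rc, s, tolerance = 1e-12)

  expect_error(score_allele(pwm, "ACG", "A", 1), class = "glyconet_short_flank")
})

test_that("window scores match an exhaustive recomputation oracle", {
  set.seed(47)
  counts <- matrix(sample(1:20, 16, replace = TRUE), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- read_pwm(write_toy_jaspar(counts), "jaspar")[[1]]
  flank <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                 collapse = "")
  offset <- 8
  allele <- "G"
  got <- score_allele(pwm, flank, allele, offset)
  seq_sub <- flank
  substr(seq_sub, offset, offset) <- allele
  chars <- strsplit(seq_sub, "")[[1]]
  rc_chars <- rev(chartr("ACGT", "TGCA", chars))
  brute <- -Inf
  for (start in 1:(15 - 4 + 1)) {
    if (start > offset || start + 3 < offset) next
    win <- chars[start:(start + 3)]
    rc_start <- 15 - (start + 3) + 1
    rcw <- rc_chars[rc_start:(rc_start + 3)]
    for (w in list(win, rcw)) {
      sc <- sum(vapply(1:4, function(j) {
        pwm$log_odds[match(w[j], c("A", "C", "G", "T")), j]
      }, numeric(1)))
      brute <- max(brute, sc)
    }
  }
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("score p-values match exhaustive enumeration for short motifs", {
  set.seed(53)
  pwm <- read_pwm(write_toy_jaspar(), "jaspar")[[1]]
  all_kmers <- expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                           stringsAsFactors = FALSE)
  all_scores <- apply(all_kmers, 1, function(w) {
    sum(vapply(1:4, function(j) {
      pwm$log_odds[match(w[j], c("A", "C", "G", "T")), j]
    }, numeric(1)))
  })
  for (q in quantile(all_scores, c(0, 0.25, 0.5, 0.9, 1))) {
    expect_equal(score_pvalue(pwm, q), mean(all_scores >= q - 1e-9),
                 tolerance = 1e-12)
  }
  # boundaries
  expect_equal(score_pvalue(pwm, max(all_scores) + 10),
               mean(all_scores >= max(all_scores) - 1e-9))
  expect_equal(score_pvalue(pwm, min(all_scores) - 10), 1)
})

test_that("score p-values are monotone and the long-motif DP matches enumeration", {
  long <- planted_motif(length = 10, seed = 59)
  scores <- seq(min(long$log_odds) * 10, sum(apply(long$log_odds, 2, max)),
                length.out = 25)
  pv <- vapply(scores, function(s) score_pvalue(long, s), numeric(1))
  expect_true(all(diff(pv) <= 1e-15))

  # brute-force enumeration over all 4^10 sequences via column convolution in
  # a different order (right to left) as an independent check
  probs <- rep(0.25, 4)
  vals <- long$log_odds[, 10]
  ps <- probs
  for (j in 9:1) {
    vals <- as.vector(outer(long$log_odds[, j], vals, "+"))
    ps <- as.vector(outer(probs, ps, "*"))
  }
  for (s in quantile(vals, c(0.1, 0.5, 0.99))) {
    expect_equal(score_pvalue(long, s), sum(ps[vals >= s - 1e-9]),
                 tolerance = 1e-9)
  }
})

test_that("allele-effect classification follows the significance contrast", {
  expect_equal(classify_allele_effect(1e-10, 0.3, 20, 5, alpha = 1.8e-8), "disrupts")
  expect_equal(classify_allele_effect(0.3, 1e-10, 5, 20, alpha = 1.8e-8), "introduces")
  expect_equal(classify_allele_effect(1e-10, 1e-10, 20, 20.5, alpha = 1.8e-8),
               "no_effect")                       # similar-score filter
  expect_equal(classify_allele_effect(1e-10, 1e-10, 20, 15, alpha = 1.8e-8),
               "ambiguous")
  expect_equal(classify_allele_effect(0.5, 0.5, 3, 9), "no_effect")
  # symmetry: swapping ref/alt swaps disrupts <-> introduces
  set.seed(61)
  for (i in 1:20) {
    rp <- 10^-runif(1, 0, 12); ap <- 10^-runif(1, 0, 12)
    rs <- runif(1, 0, 25); as <- runif(1, 0, 25)
    fwd <- classify_allele_effect(rp, ap, rs, as)
    rev <- classify_allele_effect(ap, rp, as, rs)
    expected <- c(disrupts = "introduces", introduces = "disrupts",
                  ambiguous = "ambiguous", no_effect = "no_effect")[fwd]
    expect_equal(rev, unname(expected))
  }
})

test_that("enrichment_ratio compares class fractions with the two-fold flag", {
  eq <- enrichment_ratio(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(eq$ratio, 1)
  expect_false(eq$flag)

  e4 <- enrichment_ratio(c(rep(TRUE, 4), rep(FALSE, 6)),
                         c(TRUE, rep(FALSE, 9)))
  expect_equal(e4$ratio, 4)
  expect_true(e4$flag)

  inf <- enrichment_ratio(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_equal(inf$ratio, Inf)
  expect_equal(inf$n_nonassoc, 2)
  expect_error(enrichment_ratio(logical(0), TRUE), class = "glyconet_empty_class")
})

test_that("planted disruptions are called and the fold recovered", {
  td <- simulate_tfbs_dataset(n_assoc = 80, n_nonassoc = 80, planted_fold = 4,
                              base_rate = 0.12, seed = 67)
  calls <- call_binding_effects(td$flanks, list(td$pwm))
  per_snp <- attr(calls, "per_snp")
  joined <- dplyr::inner_join(per_snp, td$flanks, by = "snp")
  # every planted disruption is detected, and only those
  expect_equal(joined$affects_binding, joined$planted)
  er <- enrichment_ratio(joined$affects_binding[joined$class == "assoc"],
                         joined$affects_binding[joined$class == "nonassoc"])
  expect_gt(er$ratio, 1.5)
})
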