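# Allele-level transcription-factor binding-site scoring: PWM parsing,
# log-odds scanning over SNP-covering windows on both strands, exact score
# p-values, disruption/introduction calls, and associated-vs-nonassociated
# enrichment.

BASES <- c("A", "C", "G", "T")

new_pwm <- function(tf, counts, background, pseudocount) {
  stopifnot(nrow(counts) == 4, all(counts >= 0))
  rownames(counts) <- BASES
  if (pseudocount == 0 && any(counts == 0)) {
    abort_glyco("zero cell requires pseudocount", "zero_cell")
  }
  n_seq <- colSums(counts)
  probs <- sweep(counts + pseudocount * background,
                 2, n_seq + pseudocount, "/")
  log_odds <- log2(sweep(probs, 1, background, "/"))
  pwm <- structure(
    list(tf = tf, counts = counts, log_odds = log_odds,
         length = ncol(counts), background = background,
         pseudocount = pseudocount),
    class = "glyco_pwm"
  )
  pwm$dist <- score_distribution(pwm)
  pwm
}

#' Read position weight matrices from JASPAR or MEME text files
#'
#' Parses all motifs in the file, converts counts to log2-odds against the
#' background base distribution with a pseudocount, and precomputes each
#' motif's exact background score distribution (used by [score_pvalue()]).
#' MEME letter-probability matrices are converted back to counts via their
#' `nsites` so that identically derived JASPAR and MEME files yield identical
#' log-odds.
#'
#' @param path Path to a JASPAR (`>id name` header plus four `A/C/G/T [..]`
#'   rows) or MEME minimal-format text file.
#' @param format `"jaspar"` or `"meme"`.
#' @param pseudocount Added (scaled by background) to every count; 0 with a
#'   zero count is an error.
#' @param background Length-4 base distribution (A, C, G, T), summing to 1;
#'   defaults to the file's background (MEME) or uniform.
#' @return Named list of `glyco_pwm` objects.
#' @export
read_pwm <- function(path, format = c("jaspar", "meme"), pseudocount = 1,
                     background = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "jaspar") parse_jaspar(lines, pseudocount, background %||% rep(0.25, 4))
  else parse_meme(lines, pseudocount, background)
}

parse_jaspar <- function(lines, pseudocount, background) {
  headers <- grep("^>", lines)
  if (length(headers) == 0) abort_glyco("no JASPAR motif headers found", "parse_error")
  out <- list()
  for (h in seq_along(headers)) {
    start <- headers[h]
    end <- if (h < length(headers)) headers[h + 1] - 1 else length(lines)
    tf <- trimws(sub("^>\\S*\\s*", "", lines[start]))
    if (tf == "") tf <- sub("^>", "", lines[start])
    block <- lines[(start + 1):end]
    rows <- lapply(BASES, function(b) {
      ln <- grep(paste0("^\\s*", b, "\\b"), block, value = TRUE)
      if (length(ln) != 1) {
        abort_glyco(paste0("malformed JASPAR matrix for ", tf, ": row ", b),
                    "parse_error")
      }
      nums <- regmatches(ln, gregexpr("[0-9.eE+-]+", ln))[[1]]
      as.numeric(nums)
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1) {
      abort_glyco(paste0("malformed JASPAR matrix for ", tf,
                         ": unequal row lengths at position ", min(lens) + 1),
                  "parse_error")
    }
    counts <- do.call(rbind, rows)
    out[[tf]] <- new_pwm(tf, counts, background, pseudocount)
  }
  out
}

parse_meme <- function(lines, pseudocount, background) {
  if (is.null(background)) {
    bg_i <- grep("^Background letter frequencies", lines)
    background <- rep(0.25, 4)
    if (length(bg_i) == 1 && bg_i < length(lines)) {
      nums <- as.numeric(regmatches(lines[bg_i + 1],
                                    gregexpr("[0-9.eE+-]+", lines[bg_i + 1]))[[1]])
      if (length(nums) >= 8) background <- nums[c(2, 4, 6, 8)]
    }
  }
  motif_i <- grep("^MOTIF\\b", lines)
  if (length(motif_i) == 0) abort_glyco("no MEME MOTIF blocks found", "parse_error")
  out <- list()
  for (m in seq_along(motif_i)) {
    tf <- strsplit(trimws(lines[motif_i[m]]), "\\s+")[[1]][2]
    lp_rel <- grep("^letter-probability matrix",
                   lines[motif_i[m]:length(lines)])[1]
    if (is.na(lp_rel)) {
      abort_glyco(paste0("malformed MEME motif ", tf, ": no matrix header"),
                  "parse_error")
    }
    lp <- motif_i[m] + lp_rel - 1
    hdr <- lines[lp]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
    if (is.na(nsites)) nsites <- 20
    mat <- t(vapply(lines[(lp + 1):(lp + w)], function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    counts <- t(mat) * nsites
    out[[tf]] <- new_pwm(tf, counts, background, pseudocount)
  }
  out
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

score_window <- function(pwm, window) {
  idx <- match(strsplit(window, "")[[1]], BASES)
  sum(pwm$log_odds[cbind(idx, seq_len(pwm$length))])
}

#' Best PWM score of an allele's flanking sequence
#'
#' Substitutes the allele at the SNP position, then scores every window of
#' motif length that covers the SNP, on both strands, and returns the maximum
#' log2-odds. Windows not covering the SNP are irrelevant to the allele
#' contrast and are skipped.
#'
#' @param pwm A `glyco_pwm`.
#' @param flank Flanking sequence (character, A/C/G/T).
#' @param allele Single base substituted at `snp_offset`.
#' @param snp_offset 1-based position of the SNP within `flank`.
#' @return Maximum log2-odds score over qualifying windows and strands.
#' @export
score_allele <- function(pwm, flank, allele, snp_offset) {
  flank <- toupper(flank)
  L <- pwm$length
  n <- nchar(flank)
  if (n < L) abort_glyco("flank shorter than motif", "short_flank")
  stopifnot(snp_offset >= 1, snp_offset <= n, allele %in% BASES)
  substr(flank, snp_offset, snp_offset) <- allele
  starts <- max(1, snp_offset - L + 1):min(n - L + 1, snp_offset)
  best <- -Inf
  for (s in starts) {
    win <- substr(flank, s, s + L - 1)
    best <- max(best, score_window(pwm, win), score_window(pwm, revcomp(win)))
  }
  best
}

# Background distribution of the score of one motif-length window. Exact
# enumeration (sequential outer addition over positions) for length <= 8;
# for longer motifs the same convolution is run as a dynamic program that
# aggregates identical partial sums, falling back to a fine discretization of
# the column scores when the value set would not collapse.
score_distribution <- function(pwm, max_values = 1e5, grid = 1e-4) {
  convolve_cols <- function(lo) {
    vals <- lo[, 1]
    probs <- pwm$background
    for (j in seq_len(ncol(lo))[-1]) {
      vals <- as.vector(outer(vals, lo[, j], "+"))
      probs <- as.vector(outer(probs, pwm$background, "*"))
      if (length(vals) > max_values) {
        agg <- rowsum(probs, group = vals)
        vals <- as.numeric(rownames(agg))
        probs <- agg[, 1]
      }
    }
    agg <- rowsum(probs, group = vals)
    tibble::tibble(score = as.numeric(rownames(agg)), prob = agg[, 1])
  }
  d <- if (pwm$length <= 8) {
    convolve_cols(pwm$log_odds)
  } else {
    # try exact aggregation; discretize only if the value set explodes
    res <- tryCatch({
      lo <- pwm$log_odds
      vals <- lo[, 1]; probs <- pwm$background
      for (j in 2:ncol(lo)) {
        vals <- as.vector(outer(vals, lo[, j], "+"))
        probs <- as.vector(outer(probs, pwm$background, "*"))
        agg <- rowsum(probs, group = vals)
        vals <- as.numeric(rownames(agg))
        probs <- agg[, 1]
        if (length(vals) > max_values) stop("explode")
      }
      tibble::tibble(score = vals, prob = probs)
    }, error = function(e) NULL)
    if (is.null(res)) {
      lo_g <- round(pwm$log_odds / grid) * grid
      pw2 <- pwm
      pw2$log_odds <- lo_g
      vals <- lo_g[, 1]; probs <- pwm$background
      for (j in 2:ncol(lo_g)) {
        vals <- as.vector(outer(vals, lo_g[, j], "+"))
        probs <- as.vector(outer(probs, pwm$background, "*"))
        agg <- rowsum(probs, group = round(vals / grid))
        vals <- as.numeric(rownames(agg)) * grid
        probs <- agg[, 1]
      }
      res <- tibble::tibble(score = vals, prob = probs)
    }
    res
  }
  d <- d[order(d$score), ]
  d$tail <- rev(cumsum(rev(d$prob)))
  d
}

#' Background p-value of a PWM score
#'
#' Probability, under the background base distribution, that a random
#' sequence of motif length scores at least `score`. Computed from the
#' motif's exact score distribution (enumeration for motifs of length <= 8, a
#' convolution dynamic program otherwise). A score above the maximum
#' attainable returns the smallest mass point (the consensus probability); a
#' score below the minimum returns 1.
#'
#' @param pwm A `glyco_pwm`.
#' @param score Log2-odds score (finite).
#' @return P-value in (0, 1].
#' @export
score_pvalue <- function(pwm, score) {
  stopifnot(is.finite(score))
  d <- pwm$dist
  idx <- which(d$score >= score - 1e-9)
  if (length(idx) == 0) return(unname(d$tail[nrow(d)]))  # above max: consensus mass
  unname(d$tail[idx[1]])
}

#' Classify the allele-level effect on TF binding
#'
#' A SNP disrupts a binding site when the reference allele's best score is
#' significant at `alpha` and the alternate allele's is not; it introduces
#' one in the mirror case. Alleles with near-equal scores (within
#' `score_tol` log2-odds units) are filtered to `no_effect` regardless of
#' significance — a conservative guard against calling a site changed when
#' both alleles bind comparably. Both alleles significant with genuinely
#' different scores is `ambiguous`.
#'
#' @param ref_p,alt_p Score p-values for reference and alternate allele.
#' @param ref_score,alt_score Best log2-odds scores.
#' @param alpha Significance threshold; the default 1.8e-8 is 0.05 Bonferroni
#'   corrected for 2,764,712 allele-level tests.
#' @param score_tol Similar-score tolerance in log2-odds (default 1 bit).
#' @return One of `"disrupts"`, `"introduces"`, `"ambiguous"`, `"no_effect"`.
#' @export
classify_allele_effect <- function(ref_p, alt_p, ref_score, alt_score,
                                   alpha = 0.05 / 2764712, score_tol = 1) {
  ref_sig <- ref_p <= alpha
  alt_sig <- alt_p <= alpha
  dplyr::case_when(
    abs(ref_score - alt_score) < score_tol ~ "no_effect",
    ref_sig & !alt_sig ~ "disrupts",
    alt_sig & !ref_sig ~ "introduces",
    ref_sig & alt_sig ~ "ambiguous",
    TRUE ~ "no_effect"
  )
}

#' Score and classify every SNP against every PWM
#'
#' Convenience wrapper: for each SNP flank and each motif, scores both
#' alleles, computes score p-values, and classifies the allele effect. A
#' SNP's overall `affects_binding` flag is `TRUE` when any motif yields a
#' disrupts/introduces call.
#'
#' @param flanks Tibble with `snp`, `seq`, `snp_offset`, `ref`, `alt`.
#' @param pwms List of `glyco_pwm` objects (from [read_pwm()]).
#' @param alpha,score_tol Passed to [classify_allele_effect()].
#' @return Tibble of calls: one row per SNP x motif with scores, p-values and
#'   `call`, plus the per-SNP summary attribute `"per_snp"`.
#' @export
call_binding_effects <- function(flanks, pwms, alpha = 0.05 / 2764712,
                                 score_tol = 1) {
  calls <- purrr::map_dfr(pwms, function(pwm) {
    ref_s <- purrr::map2_dbl(flanks$seq, seq_len(nrow(flanks)), function(sq, i) {
      score_allele(pwm, sq, flanks$ref[i], flanks$snp_offset[i])
    })
    alt_s <- purrr::map2_dbl(flanks$seq, seq_len(nrow(flanks)), function(sq, i) {
      score_allele(pwm, sq, flanks$alt[i], flanks$snp_offset[i])
    })
    tibble::tibble(
      snp = flanks$snp, tf = pwm$tf,
      ref_score = ref_s, alt_score = alt_s,
      ref_p = vapply(ref_s, function(s) score_pvalue(pwm, s), numeric(1)),
      alt_p = vapply(alt_s, function(s) score_pvalue(pwm, s), numeric(1))
    )
  })
  calls$call <- classify_allele_effect(calls$ref_p, calls$alt_p,
                                       calls$ref_score, calls$alt_score,
                                       alpha = alpha, score_tol = score_tol)
  per_snp <- calls |>
    dplyr::group_by(.data$snp) |>
    dplyr::summarise(affects_binding = any(.data$call %in% c("disrupts", "introduces")),
                     .groups = "drop")
  attr(calls, "per_snp") <- per_snp
  calls
}

#' Write/read SNP flanking sequences as FASTA plus a sidecar allele TSV
#'
#' The FASTA carries one record per SNP (id = SNP id); the sidecar TSV holds
#' the SNP offset, reference/alternate alleles and class labels that FASTA
#' cannot carry.
#'
#' @param flanks Tibble with `snp`, `seq` and metadata columns.
#' @param fasta_path,tsv_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_flanks_fasta <- function(flanks, fasta_path, tsv_path) {
  seqs <- Biostrings::DNAStringSet(flanks$seq)
  names(seqs) <- flanks$snp
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(dplyr::select(flanks, -"seq"), tsv_path)
  invisible(fasta_path)
}

#' @rdname write_flanks_fasta
#' @export
read_flanks_fasta <- function(fasta_path, tsv_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  tibble::tibble(snp = names(seqs), seq = unname(as.character(seqs))) |>
    dplyr::inner_join(meta, by = "snp")
}

#' Enrichment of binding-site alterations among associated SNPs
#'
#' Ratio of the fraction of associated SNPs with a disrupts/introduces call
#' to the same fraction among nonassociated SNPs. The flag is raised when the
#' ratio reaches `fold` (default 2, the "at least two times more likely"
#' criterion). A zero nonassociated fraction with a nonzero associated
#' fraction is reported as `Inf`, with the counts retained for context.
#'
#' @param associated,nonassociated Logical vectors (or tibbles with an
#'   `affects_binding` column): does each SNP alter any binding site?
#' @param fold Flag threshold (default 2).
#' @return One-row tibble: `n_assoc`, `n_nonassoc`, `frac_assoc`,
#'   `frac_nonassoc`, `ratio`, `flag`.
#' @export
enrichment_ratio <- function(associated, nonassociated, fold = 2) {
  as_flag <- function(x, nm) {
    if (is.data.frame(x)) x <- x$affects_binding
    if (length(x) == 0) abort_glyco(paste0("empty class: ", nm), "empty_class")
    x
  }
  a <- as_flag(associated, "associated")
  b <- as_flag(nonassociated, "nonassociated")
  fa <- mean(a)
  fb <- mean(b)
  ratio <- if (fb == 0) {
    if (fa == 0) NA_real_ else Inf
  } else fa / fb
  tibble::tibble(n_assoc = length(a), n_nonassoc = length(b),
                 frac_assoc = fa, frac_nonassoc = fb,
                 ratio = ratio, flag = !is.na(ratio) && ratio >= fold)
}
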