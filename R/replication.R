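# Replication-stage analytics: allelic 2x2 odds-ratio / chi-square tests,
# per-group allele frequency summaries, LD-based tag-SNP selection from
# family frequency matrices, and temporal allele-frequency tracking.

#' Allelic 2x2 association test from counts
#'
#' Association between a binary resistance phenotype and allele counts
#' (2 per homozygote, 1 per heterozygote): Pearson chi-square on the
#' observed 2x2 table (no continuity correction by default) and the odds
#' ratio with a Wald confidence interval on the log scale. If any cell is
#' zero, the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied to the odds ratio and its interval (flagged); the chi-square is
#' always computed on the uncorrected table.
#'
#' @param a resistant-allele count in the resistant class.
#' @param b susceptible-allele count in the resistant class.
#' @param c resistant-allele count in the susceptible class.
#' @param d susceptible-allele count in the susceptible class.
#' @param continuity apply the Yates continuity correction to the
#'   chi-square (default FALSE).
#' @param conf_level confidence level of the Wald interval.
#' @return a list of class `test_result_2x2`: `table`, `or`, `log_or_ci`,
#'   `chisq`, `df`, `p`, `zero_cell_corrected`, `continuity`.
#' @examples
#' allelic_test_counts(30, 18, 18, 30)  # OR 2.78, chi-square 6, P 0.014
#' @export
allelic_test_counts <- function(a, b, c, d, continuity = FALSE,
                                conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    fail_field("counts", "cell counts must be non-negative integers")
  tab <- matrix(counts, 2L, 2L, byrow = TRUE,
                dimnames = list(class = c("resistant", "susceptible"),
                                allele = c("resistant", "susceptible")))
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (n == 0L || any(rs == 0) || any(cs == 0)) {
    chisq <- NA_real_; p <- NA_real_
  } else {
    expected <- outer(rs, cs) / n
    dev <- abs(tab - expected)
    if (continuity) dev <- pmax(dev - 0.5, 0)
    chisq <- sum(dev^2 / expected)
    p <- stats::pchisq(chisq, 1L, lower.tail = FALSE)
  }
  zero_cell <- any(counts == 0)
  ct <- if (zero_cell) counts + 0.5 else counts
  or <- (ct["a"] * ct["d"]) / (ct["b"] * ct["c"])
  se <- sqrt(sum(1 / ct))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    table = tab, or = unname(or),
    log_or_ci = unname(log(or) + c(-1, 1) * zq * se),
    chisq = unname(chisq), df = 1L, p = unname(p),
    zero_cell_corrected = zero_cell, continuity = continuity
  ), class = "test_result_2x2")
}

#' @export
print.test_result_2x2 <- function(x, ...) {
  cat(sprintf("allelic 2x2 test: OR = %.3f%s, chi-square = %.3f, P = %.4g\n",
              x$or, if (x$zero_cell_corrected) " (zero-cell corrected)" else "",
              x$chisq, x$p))
  invisible(x)
}

#' Allelic association test for one SNP
#'
#' Counts resistant (X) alleles by phenotype class from genotype dosages
#' and runs [allelic_test_counts()].
#'
#' @param genotypes individuals-by-SNP dosage matrix (dosage of the
#'   resistant/X allele).
#' @param phenotype factor or character per individual with values `res`
#'   and `sus`.
#' @param snp SNP column name or index.
#' @param ... passed to [allelic_test_counts()].
#' @return a `test_result_2x2`, or a list with `reason =
#'   "monomorphic"` and `or = NA` when the SNP carries no variation.
#' @export
allelic_test <- function(genotypes, phenotype, snp, ...) {
  genotypes <- as.matrix(genotypes)
  ph <- as.character(phenotype)
  if (!all(ph %in% c("res", "sus")))
    fail_field("phenotype", "values must be 'res' or 'sus'")
  if (!any(ph == "res") || !any(ph == "sus"))
    stop("both phenotype classes must be non-empty", call. = FALSE)
  g <- genotypes[, snp]
  ok <- !is.na(g)
  g <- g[ok]; ph <- ph[ok]
  if (length(unique(g)) < 2L)
    return(structure(list(or = NA_real_, chisq = NA_real_, p = NA_real_,
                          reason = "monomorphic"),
                     class = "test_result_2x2"))
  a <- sum(g[ph == "res"]); b <- 2 * sum(ph == "res") - a
  cc <- sum(g[ph == "sus"]); d <- 2 * sum(ph == "sus") - cc
  allelic_test_counts(a, b, cc, d, ...)
}

#' Per-group allele counts and frequencies for a SNP
#'
#' @param genotypes individuals-by-SNP dosage matrix (resistant-allele
#'   dosage).
#' @param snp SNP column name or index.
#' @param grouping group label per individual (e.g. population).
#' @param conf_level level of the exact binomial confidence interval.
#' @return a list: `per_group` data.frame (`group`, `n_alleles`,
#'   `count`, `freq`, `ci_lo`, `ci_hi`), and `mean_freq`, `sd_freq`
#'   across non-empty groups.
#' @export
genotype_frequency_table <- function(genotypes, snp, grouping,
                                     conf_level = 0.95) {
  genotypes <- as.matrix(genotypes)
  stopifnot(length(grouping) == nrow(genotypes))
  g <- genotypes[, snp]
  grp <- as.character(grouping)
  labs <- unique(grp)
  rows <- lapply(labs, function(l) {
    gi <- g[grp == l & !is.na(g)]
    n_all <- 2L * length(gi)
    cnt <- sum(gi)
    if (n_all == 0L)
      return(data.frame(group = l, n_alleles = 0L, count = 0L,
                        freq = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        stringsAsFactors = FALSE))
    ci <- stats::binom.test(cnt, n_all, conf.level = conf_level)$conf.int
    data.frame(group = l, n_alleles = n_all, count = cnt,
               freq = cnt / n_all, ci_lo = ci[1L], ci_hi = ci[2L],
               stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, rows)
  fr <- per_group$freq[per_group$n_alleles > 0]
  list(per_group = per_group,
       mean_freq = mean(fr),
       sd_freq = if (length(fr) > 1L) stats::sd(fr) else NA_real_)
}

#' Select a tag SNP by family-wise frequency correlation
#'
#' Approximates LD from a family allele-frequency matrix: the Pearson
#' correlation across families between the target SNP's frequencies and
#' every other SNP's, filtered to candidates whose minor allele frequency
#' is within `maf_window` of the target's. The tag is the candidate with
#' the highest |correlation|; ties are broken by smaller MAF difference,
#' then by genomic proximity when annotation is supplied.
#'
#' @param freqs families-by-SNP frequency matrix (>= 8 families).
#' @param target target SNP column name.
#' @param maf_window maximum |MAF difference| (default 0.10).
#' @param annot optional annotation (`snp_id`, `chrom`, `pos`) for the
#'   proximity tie-break.
#' @return a list of class `tag_snp_report`: `target`, `tag` (NA with a
#'   `reason` if no candidate passes), `correlation`, `candidates`
#'   data.frame (`snp_id`, `correlation`, `maf`, `delta_maf`, `eligible`),
#'   `maf_window`.
#' @export
tag_snp_select <- function(freqs, target, maf_window = 0.10, annot = NULL) {
  stopifnot(is.matrix(freqs))
  if (nrow(freqs) < 8L) stop("need at least 8 families", call. = FALSE)
  if (!target %in% colnames(freqs))
    stop("target SNP not present in the frequency matrix", call. = FALSE)
  others <- setdiff(colnames(freqs), target)
  tv <- freqs[, target]
  mean_freq <- colMeans(freqs, na.rm = TRUE)
  maf <- pmin(mean_freq, 1 - mean_freq)
  corr <- vapply(others, function(s)
    suppressWarnings(stats::cor(tv, freqs[, s],
                                use = "pairwise.complete.obs")),
    numeric(1L))
  delta <- abs(maf[others] - maf[target])
  eligible <- !is.na(corr) & delta <= maf_window
  cand <- data.frame(snp_id = others, correlation = unname(corr),
                     maf = unname(maf[others]), delta_maf = unname(delta),
                     eligible = unname(eligible),
                     row.names = NULL, stringsAsFactors = FALSE)
  cand <- cand[order(-abs(cand$correlation), cand$delta_maf), ]
  if (!any(eligible))
    return(structure(list(target = target, tag = NA_character_,
                          correlation = NA_real_, candidates = cand,
                          maf_window = maf_window,
                          reason = "no candidate within the MAF window"),
                     class = "tag_snp_report"))
  el <- cand[cand$eligible, ]
  best_abs <- abs(el$correlation[1L])
  top <- el[abs(el$correlation) >= best_abs - 1e-12, ]
  if (nrow(top) > 1L) {
    top <- top[top$delta_maf <= min(top$delta_maf) + 1e-12, , drop = FALSE]
    if (nrow(top) > 1L && !is.null(annot)) {
      ti <- match(target, annot$snp_id)
      pos <- annot$pos[match(top$snp_id, annot$snp_id)]
      same <- annot$chrom[match(top$snp_id, annot$snp_id)] ==
        annot$chrom[ti]
      dist <- ifelse(same, abs(pos - annot$pos[ti]), Inf)
      top <- top[order(dist), , drop = FALSE]
    }
  }
  structure(list(target = target, tag = top$snp_id[1L],
                 correlation = top$correlation[1L], candidates = cand,
                 maf_window = maf_window),
            class = "tag_snp_report")
}

#' @export
print.tag_snp_report <- function(x, ...) {
  if (is.na(x$tag))
    cat(sprintf("tag SNP for %s: none (%s)\n", x$target, x$reason))
  else
    cat(sprintf("tag SNP for %s: %s (family-wise r = %.3f)\n",
                x$target, x$tag, x$correlation))
  invisible(x)
}

#' Temporal allele-frequency trend and heterogeneity
#'
#' Per-time-window allele frequencies with exact binomial confidence
#' intervals and a k-by-2 chi-square test of frequency homogeneity across
#' windows ("relative stability" corresponds to failing to reject).
#'
#' @param counts matrix or data.frame with one row per time window and two
#'   columns: counts of the tracked allele and of the alternative allele.
#'   Row names label the windows.
#' @param conf_level binomial confidence level.
#' @return a list of class `temporal_table`: `per_window` data.frame
#'   (`window`, `n_alleles`, `count`, `freq`, `ci_lo`, `ci_hi`),
#'   `chisq`, `df`, `p`, `n_windows_used`.
#' @export
temporal_trend <- function(counts, conf_level = 0.95) {
  m <- as.matrix(counts)
  if (ncol(m) != 2L) fail_field("counts", "need exactly two allele columns")
  if (any(m < 0) || any(m != round(m)))
    fail_field("counts", "allele counts must be non-negative integers")
  if (nrow(m) < 2L) stop("need at least 2 time windows", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("window", seq_len(nrow(m)))
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sprintf("excluding %d window(s) with zero total alleles",
                    sum(tot == 0)))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (nrow(m) < 2L) stop("fewer than 2 usable windows", call. = FALSE)
  per <- lapply(seq_len(nrow(m)), function(i) {
    ci <- stats::binom.test(m[i, 1L], tot[i], conf.level = conf_level)$conf.int
    data.frame(window = rownames(m)[i], n_alleles = tot[i],
               count = m[i, 1L], freq = m[i, 1L] / tot[i],
               ci_lo = ci[1L], ci_hi = ci[2L],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  cs <- colSums(m)
  if (any(cs == 0)) {
    chisq <- 0; p <- 1  # tracked allele absent/fixed everywhere
  } else {
    expected <- outer(tot, cs) / sum(m)
    chisq <- sum((m - expected)^2 / expected)
    p <- stats::pchisq(chisq, nrow(m) - 1L, lower.tail = FALSE)
  }
  structure(list(per_window = do.call(rbind, per), chisq = chisq,
                 df = nrow(m) - 1L, p = p, n_windows_used = nrow(m)),
            class = "temporal_table")
}

#' @export
print.temporal_table <- function(x, ...) {
  cat(sprintf(
    "temporal trend over %d windows: heterogeneity chi-square = %.3f (df %d), P = %.4g\n",
    x$n_windows_used, x$chisq, x$df, x$p))
  print(x$per_window, row.names = FALSE)
  invisible(x)
}
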