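# Dye-bias calibration and pooled allele-frequency estimation.
#
# Two-colour genotyping channels are rarely balanced: in a heterozygote,
# whose true allelic ratio is 1:1, the mean cy3:cy5 signal ratio defines
# the per-SNP dye-bias factor k. Pool allele frequencies are then
# estimated as p(X) = X / (X + k Y), p(Y) = 1 - p(X).

QC_REASONS <- c("ok", "too_few_hets", "k_extreme", "sd_extreme",
                "monomorphic", "unscorable")

#' Estimate per-SNP dye bias from individual heterozygotes
#'
#' For every SNP with at least two individually genotyped heterozygotes,
#' computes `k` as the arithmetic mean of the per-heterozygote X/Y (cy3/cy5)
#' signal ratios, and `sd_k` as their sample standard deviation. A twofold
#' cy5 excess (mean ratio 0.5) therefore gives `k = 0.5`. Heterozygote
#' cells with Y = 0 have an infinite ratio; they are dropped from the mean
#' and counted in `n_dropped`.
#'
#' @param signals a [signal_matrix()] of kind `"individual"`.
#' @param genotypes samples-by-SNP dosage matrix (0/1/2, `NA` allowed);
#'   heterozygotes are cells equal to 1. Row and column names are matched
#'   with `signals`.
#' @return a `data.frame` of class `dye_bias_table`: `snp_id`, `k`,
#'   `sd_k`, `n_het` (heterozygote ratios used), `n_dropped`, `qc_pass`,
#'   `qc_reason`. Before percentile filtering (see [qc_filter_snps()]),
#'   `qc_reason` is one of `ok`, `too_few_hets`, `monomorphic`,
#'   `unscorable`.
#' @examples
#' g <- matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "snp1"))
#' sm <- signal_matrix(matrix(c(50, 50, 50), 3, dimnames = dimnames(g)),
#'                     matrix(c(100, 100, 100), 3, dimnames = dimnames(g)))
#' estimate_dye_bias(sm, g)$k  # twofold cy5 bias -> 0.5
#' @export
estimate_dye_bias <- function(signals, genotypes) {
  stopifnot(inherits(signals, "signal_matrix"))
  genotypes <- as.matrix(genotypes)
  samples <- intersect(rownames(signals$x), rownames(genotypes))
  snps <- intersect(colnames(signals$x), colnames(genotypes))
  if (length(samples) == 0L)
    stop("signals and genotypes share no sample identifiers", call. = FALSE)
  if (length(snps) == 0L)
    stop("signals and genotypes share no SNP identifiers", call. = FALSE)
  X <- signals$x[samples, snps, drop = FALSE]
  Y <- signals$y[samples, snps, drop = FALSE]
  G <- genotypes[samples, snps, drop = FALSE]

  het <- !is.na(G) & G == 1 & !is.na(X)
  finite <- het & Y > 0
  ratio <- X / Y
  ratio[!finite] <- NA_real_
  n_het <- colSums(finite)
  n_dropped <- colSums(het & Y == 0)
  k <- colMeans(ratio, na.rm = TRUE)
  k[n_het == 0L] <- NA_real_
  sd_k <- col_sds(ratio)

  reason <- rep("ok", length(snps))
  poly <- apply(G, 2L, function(g) length(unique(g[!is.na(g)])) > 1L)
  has_het <- colSums(!is.na(G) & G == 1) > 0L
  reason[n_het < 2L] <- "too_few_hets"
  reason[!poly & !has_het] <- "monomorphic"
  reason[colSums(!is.na(X)) == 0L] <- "unscorable"

  structure(data.frame(
    snp_id = snps, k = k, sd_k = sd_k,
    n_het = as.integer(n_het), n_dropped = as.integer(n_dropped),
    qc_pass = reason == "ok", qc_reason = reason,
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("dye_bias_table", "data.frame"))
}

#' Apply percentile-based dye-bias QC exclusion criteria
#'
#' Flags SNPs whose dye-bias estimate is extreme or poorly estimated:
#' (1) `k` above the empirical upper percentile (default 95th) of the `k`
#' distribution across SNPs; (2) `sd_k` above the same percentile of the
#' `sd_k` distribution. Percentiles are computed over SNPs that passed the
#' two-heterozygote minimum (the linear-interpolation empirical percentile,
#' [stats::quantile()] type 7). SNPs exceeding both criteria are recorded
#' in the `exceeds_k`/`exceeds_sd` columns; `qc_reason` reports
#' `k_extreme` with priority over `sd_extreme`.
#'
#' @param bias a `dye_bias_table` from [estimate_dye_bias()].
#' @param k_percentile,sd_percentile percentile cutoffs (default 95).
#' @param quiet suppress the count summary message.
#' @return the table with `qc_pass`, `qc_reason`, `exceeds_k`,
#'   `exceeds_sd` updated; the cutoff values are attached as attributes
#'   `k_cutoff` and `sd_cutoff`.
#' @export
qc_filter_snps <- function(bias, k_percentile = 95, sd_percentile = 95,
                           quiet = FALSE) {
  stopifnot(inherits(bias, "dye_bias_table"))
  if (nrow(bias) == 0L) stop("empty dye-bias table", call. = FALSE)
  if (k_percentile <= 0 || k_percentile > 100 ||
      sd_percentile <= 0 || sd_percentile > 100)
    fail_field("percentile", "cutoff percentiles must be in (0, 100]")
  eligible <- bias$qc_reason %in% c("ok", "k_extreme", "sd_extreme")
  if (!any(eligible))
    stop("no SNP passes the heterozygote minimum; cannot compute percentiles",
         call. = FALSE)
  k_cut <- stats::quantile(bias$k[eligible], k_percentile / 100,
                           na.rm = TRUE, names = FALSE)
  sd_cut <- stats::quantile(bias$sd_k[eligible], sd_percentile / 100,
                            na.rm = TRUE, names = FALSE)
  bias$exceeds_k <- eligible & !is.na(bias$k) & bias$k > k_cut
  bias$exceeds_sd <- eligible & !is.na(bias$sd_k) & bias$sd_k > sd_cut
  reason <- ifelse(!eligible, bias$qc_reason,
                   ifelse(bias$exceeds_k, "k_extreme",
                          ifelse(bias$exceeds_sd, "sd_extreme", "ok")))
  bias$qc_reason <- reason
  bias$qc_pass <- reason == "ok"
  attr(bias, "k_cutoff") <- k_cut
  attr(bias, "sd_cutoff") <- sd_cut
  if (!quiet) {
    tab <- table(factor(reason, levels = QC_REASONS))
    message(sprintf(
      "dye-bias QC: %d/%d SNPs pass (k cutoff %.4g, sd cutoff %.4g); %s",
      sum(bias$qc_pass), nrow(bias), k_cut, sd_cut,
      paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
            collapse = ", ")))
  }
  bias
}

#' Estimate pool allele frequencies from two-channel signals
#'
#' Applies the dye-bias-corrected estimator
#' `p(X) = X / (X + k Y)` and `p(Y) = 1 - p(X)` to every pool-by-SNP cell,
#' using only SNPs that pass dye-bias QC. Cells with X = Y = 0 (and cells
#' missing in the signals) are set to `NA`.
#'
#' @param signals a [signal_matrix()] of kind `"pool"` (rows = family
#'   pools).
#' @param bias a QC-filtered `dye_bias_table` ([qc_filter_snps()]); every
#'   SNP in `signals` must be present in it.
#' @return a pools-by-SNP numeric matrix of `p(X)` estimates in \[0, 1\]
#'   restricted to QC-passing SNPs, with the `k` used attached as
#'   attribute `k`.
#' @examples
#' b <- structure(data.frame(snp_id = "s1", k = 0.5, sd_k = 0, n_het = 5L,
#'                           n_dropped = 0L, qc_pass = TRUE, qc_reason = "ok"),
#'                class = c("dye_bias_table", "data.frame"))
#' sm <- signal_matrix(matrix(100, 1, 1, dimnames = list("pool1", "s1")),
#'                     matrix(100, 1, 1, dimnames = list("pool1", "s1")),
#'                     kind = "pool")
#' pooled_allele_frequency(sm, b)  # 100 / (100 + 0.5 * 100) = 2/3
#' @export
pooled_allele_frequency <- function(signals, bias) {
  stopifnot(inherits(signals, "signal_matrix"),
            inherits(bias, "dye_bias_table"))
  missing_snps <- setdiff(colnames(signals$x), bias$snp_id)
  if (length(missing_snps))
    stop("SNP(s) absent from the dye-bias table: ",
         paste(utils::head(missing_snps, 10L), collapse = ", "),
         if (length(missing_snps) > 10L) ", ...", call. = FALSE)
  keep <- intersect(colnames(signals$x), bias$snp_id[bias$qc_pass])
  if (length(keep) == 0L)
    stop("no QC-passing SNPs in the signal matrix", call. = FALSE)
  X <- signals$x[, keep, drop = FALSE]
  Y <- signals$y[, keep, drop = FALSE]
  k <- bias$k[match(keep, bias$snp_id)]
  denom <- X + sweep(Y, 2L, k, `*`)
  p <- X / denom
  p[!is.na(denom) & denom == 0] <- NA_real_
  attr(p, "k") <- stats::setNames(k, keep)
  p
}

#' Concordance of pooled frequency estimates with individual genotypes
#'
#' Compares pool allele-frequency estimates with frequencies computed from
#' individual genotypes of the same groups (mean dosage / 2 over matching
#' individuals), across all matched (SNP, group) pairs.
#'
#' @param pooled groups-by-SNP matrix of estimated `p(X)` (rows named by
#'   group/family id).
#' @param genotypes individuals-by-SNP dosage matrix.
#' @param groups group (family) label for each row of `genotypes`.
#' @return a list of class `concordance_report`: `r_squared` (squared
#'   Pearson correlation over matched pairs), `slope` and `intercept` of
#'   the least-squares line of pooled on genotype frequencies, `n` pairs,
#'   and `per_snp` mean residuals. A negative slope raises an
#'   allele-orientation warning.
#' @export
frequency_concordance <- function(pooled, genotypes, groups) {
  genotypes <- as.matrix(genotypes)
  stopifnot(length(groups) == nrow(genotypes))
  groups <- as.character(groups)
  cnt <- rowsum((!is.na(genotypes)) * 1, groups)
  gfreq <- rowsum(ifelse(is.na(genotypes), 0, genotypes), groups) / (2 * cnt)
  gfreq[cnt == 0] <- NA_real_
  common_g <- intersect(rownames(pooled), rownames(gfreq))
  common_s <- intersect(colnames(pooled), colnames(gfreq))
  if (length(common_g) == 0L || length(common_s) == 0L)
    stop("no matching groups/SNPs between pooled and genotype frequencies",
         call. = FALSE)
  pv <- pooled[common_g, common_s, drop = FALSE]
  gv <- gfreq[common_g, common_s, drop = FALSE]
  ok <- !is.na(pv) & !is.na(gv)
  if (sum(ok) < 3L)
    stop("fewer than 3 matched frequency pairs", call. = FALSE)
  x <- gv[ok]; y <- pv[ok]
  r <- stats::cor(x, y)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  if (!is.na(slope) && slope < 0)
    warning("negative slope: pooled frequencies appear orientation-flipped ",
            "relative to genotype frequencies")
  resid <- pv - gv
  per_snp <- data.frame(snp_id = common_s,
                        mean_residual = colMeans(resid, na.rm = TRUE),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(r_squared = r^2, slope = slope,
                 intercept = unname(fit$coefficients[1L]),
                 n = sum(ok), per_snp = per_snp),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "pool/genotype frequency concordance: R^2 = %.4f (slope %.3f, n = %d pairs)\n",
    x$r_squared, x$slope, x$n))
  invisible(x)
}
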