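# Within-population structure: stratification PCA on control SNPs,
# localization of PC-correlated SNPs to a genomic region (the inversion),
# per-SNP Hudson F_ST between clusters, composite LD r2, and an exact
# Hardy-Weinberg test.

#' PCA of family pool frequencies at control SNPs
#'
#' Principal components of the family-by-control-SNP allele-frequency
#' matrix, used to detect within-sample stratification. Columns are
#' standardized (mean 0, variance 1); missing cells are mean-imputed for
#' the decomposition only (their count is reported). Component signs are
#' fixed by convention: the largest-|loading| SNP of each component loads
#' positive.
#'
#' @param freqs families-by-SNP frequency matrix (e.g. from
#'   [pooled_allele_frequency()]).
#' @param annot SNP annotation `data.frame` with columns `snp_id`,
#'   `chrom`, `pos`, `class` (`"candidate"`/`"control"`).
#' @param n_components number of components to return.
#' @return a list of class `pool_pca`: `scores` (families x components),
#'   `loadings` (SNPs x components), `var_frac` (variance-explained
#'   fractions of the returned components), `snps_used`, `n_imputed`.
#' @export
pca_control <- function(freqs, annot, n_components = 5L) {
  stopifnot(is.matrix(freqs), is.data.frame(annot))
  ctrl <- annot$snp_id[annot$class == "control"]
  use <- intersect(colnames(freqs), ctrl)
  if (nrow(freqs) < 3L) stop("need at least 3 families", call. = FALSE)
  if (length(use) < 2L)
    stop("need at least 2 control SNPs with data", call. = FALSE)
  m <- freqs[, use, drop = FALSE]
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2L]]
  }
  sds <- col_sds(m)
  keep <- !is.na(sds) & sds > 0
  if (!any(keep)) stop("no variance in control-SNP frequencies", call. = FALSE)
  m <- scale(m[, keep, drop = FALSE])
  pr <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  nc <- min(n_components, ncol(pr$rotation))
  scores <- pr$x[, seq_len(nc), drop = FALSE]
  loadings <- pr$rotation[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {      # sign convention
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_frac <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(nc)]
  structure(list(scores = scores, loadings = loadings, var_frac = var_frac,
                 snps_used = colnames(m), n_imputed = n_imputed),
            class = "pool_pca")
}

#' @export
print.pool_pca <- function(x, ...) {
  cat(sprintf("pool PCA: %d families x %d control SNPs (%d cells imputed)\n",
              nrow(x$scores), length(x$snps_used), x$n_imputed))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$var_frac), collapse = " "), "\n")
  invisible(x)
}

#' Test localization of PC-correlated SNPs to a genomic region
#'
#' For each control SNP, computes |Pearson r| between its family
#' frequencies and a principal component's scores, then compares |r| of
#' SNPs inside a region (the inversion) against those outside with a
#' two-sided Mann-Whitney rank-sum test. The normal approximation with tie
#' correction provides the Z statistic; when both groups have at most 8
#' SNPs the exact distribution is used for the P-value.
#'
#' @param freqs families-by-SNP frequency matrix.
#' @param annot SNP annotation with `snp_id`, `chrom`, `pos`, `class`.
#' @param pca a `pool_pca` from [pca_control()].
#' @param component which component to use (default 1).
#' @param region region string `"CHROM:START-END"` or parsed list.
#' @param r_threshold |r| threshold for listing strongly correlated SNPs
#'   (default 0.5).
#' @return a list of class `localization_report`: `per_snp` (snp, |r|,
#'   inside flag), `mean_r_inside`, `n_inside`, `mean_r_outside`,
#'   `n_outside`, `z`, `p`, `high_r_snps`.
#' @export
pc_localization_test <- function(freqs, annot, pca, component = 1L,
                                 region, r_threshold = 0.5) {
  stopifnot(inherits(pca, "pool_pca"))
  if (component > ncol(pca$scores))
    stop("component not present in the PCA result", call. = FALSE)
  reg <- parse_region(region)
  use <- intersect(pca$snps_used, colnames(freqs))
  a <- annot[match(use, annot$snp_id), ]
  inside <- a$chrom == reg$chrom & a$pos >= reg$start & a$pos <= reg$end
  if (!any(inside))
    stop("region contains no control SNPs", call. = FALSE)
  sc <- pca$scores[, component]
  r_abs <- abs(vapply(use, function(s)
    suppressWarnings(stats::cor(freqs[, s], sc, use = "pairwise.complete.obs")),
    numeric(1L)))
  ok <- !is.na(r_abs)
  rs <- rank_sum_test(r_abs[ok & inside], r_abs[ok & !inside])
  structure(list(
    per_snp = data.frame(snp_id = use, r_abs = unname(r_abs),
                         inside = inside, row.names = NULL,
                         stringsAsFactors = FALSE),
    mean_r_inside = mean(r_abs[ok & inside]),
    n_inside = sum(ok & inside),
    mean_r_outside = mean(r_abs[ok & !inside]),
    n_outside = sum(ok & !inside),
    z = rs$z, p = rs$p,
    high_r_snps = use[ok & r_abs >= r_threshold]
  ), class = "localization_report")
}

#' @export
print.localization_report <- function(x, ...) {
  cat(sprintf(
    "PC localization: mean |r| inside = %.3f (N = %d), outside = %.3f (N = %d)\n",
    x$mean_r_inside, x$n_inside, x$mean_r_outside, x$n_outside))
  cat(sprintf("  Mann-Whitney Z = %.2f, two-sided P = %.3g; %d SNP(s) above threshold\n",
              x$z, x$p, length(x$high_r_snps)))
  invisible(x)
}

# Two-sided Mann-Whitney rank-sum test. Normal approximation with tie
# correction for Z; exact P (via wilcox.test enumeration) when both
# groups are small and untied.
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) return(list(z = NA_real_, p = NA_real_))
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sig2 > 0) (u - mu) / sqrt(sig2) else 0
  if (n1 <= 8L && n2 <= 8L && !any(duplicated(all_v))) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    p <- if (sig2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  list(z = z, p = min(p, 1))
}

#' Per-SNP Hudson F_ST between clusters
#'
#' Hudson-type two-population F_ST per SNP for every pair of clusters,
#' with finite-sample correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`, with `n` the allele counts.
#' Negative estimates are retained (flagged), not truncated; SNPs
#' monomorphic across both clusters of a pair are reported `NA`.
#'
#' @param genotypes individuals-by-SNP dosage matrix.
#' @param clusters cluster label per row of `genotypes`.
#' @return a `data.frame`: `snp_id`, `cluster_a`, `cluster_b`, `fst`,
#'   `negative` flag, allele frequencies `p_a`, `p_b` and allele counts
#'   `n_a`, `n_b`.
#' @export
per_snp_fst <- function(genotypes, clusters) {
  genotypes <- as.matrix(genotypes)
  stopifnot(length(clusters) == nrow(genotypes))
  cl <- as.character(clusters)
  labs <- sort(unique(cl))
  if (length(labs) < 2L) stop("need at least 2 clusters", call. = FALSE)
  sizes <- table(cl)
  if (any(sizes < 2L))
    stop("every cluster needs at least 2 individuals", call. = FALSE)
  stats_for <- function(lab) {
    g <- genotypes[cl == lab, , drop = FALSE]
    n <- 2 * colSums(!is.na(g))
    p <- colSums(g, na.rm = TRUE) / n
    list(p = p, n = n)
  }
  st <- lapply(stats::setNames(labs, labs), stats_for)
  out <- list()
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in seq((i + 1), length(labs))) {
      a <- st[[i]]; b <- st[[j]]
      num <- (a$p - b$p)^2 -
        a$p * (1 - a$p) / pmax(a$n - 1, 1) -
        b$p * (1 - b$p) / pmax(b$n - 1, 1)
      den <- a$p * (1 - b$p) + b$p * (1 - a$p)
      fst <- ifelse(den > 0, num / den, NA_real_)
      fst[a$n == 0 | b$n == 0] <- NA_real_
      out[[length(out) + 1L]] <- data.frame(
        snp_id = colnames(genotypes), cluster_a = labs[i], cluster_b = labs[j],
        fst = unname(fst), negative = !is.na(fst) & fst < 0,
        p_a = unname(a$p), p_b = unname(b$p),
        n_a = unname(a$n), n_b = unname(b$n),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Composite linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of genotype dosages (composite LD, no
#' phasing), over pairwise-complete individuals. Undefined (`NA`) if
#' either SNP is monomorphic among the shared non-missing individuals.
#'
#' @param genotypes individuals-by-SNP dosage matrix.
#' @param snp_a,snp_b SNP column names or indices.
#' @return r-squared in \[0, 1\], or `NA`.
#' @examples
#' g <- cbind(a = c(0, 0, 2, 2), b = c(2, 2, 0, 0))
#' ld_r2(g, "a", "b")  # perfect (negative) correlation -> 1
#' @export
ld_r2 <- function(genotypes, snp_a, snp_b) {
  genotypes <- as.matrix(genotypes)
  x <- genotypes[, snp_a]; y <- genotypes[, snp_b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the P-value
#' is the sum of probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#'
#' @param n_hom1 count of one homozygote class.
#' @param n_het heterozygote count.
#' @param n_hom2 count of the other homozygote class.
#' @return exact two-sided P-value in (0, 1].
#' @examples
#' hwe_exact(3, 0, 1)   # 1/7
#' hwe_exact(25, 50, 25)  # observed configuration is modal -> 1
#' @export
hwe_exact <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts)))
    fail_field("counts", "genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1L) fail_field("counts", "total count must be at least 1")
  n_a <- 2 * counts[1L] + counts[2L]       # allele-1 count
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0L) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
      h * log(2)
  }, numeric(1L))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(counts[2L], hets)]
  if (is.na(p_obs))
    fail_field("counts", "heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' Seeded k-means clustering of individuals from genotype PCs
#'
#' Stand-in clustering for model-based population assignment: k-means on
#' the leading principal components of the standardized genotype matrix,
#' deterministic given the seed. Labels are opaque integers.
#'
#' @param genotypes individuals-by-SNP dosage matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_pcs number of genotype PCs to cluster on (default 10, capped
#'   by the matrix rank).
#' @return integer vector of cluster labels, one per individual.
#' @export
cluster_families <- function(genotypes, k, seed = 1L, n_pcs = 10L) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (k > n) stop("k cannot exceed the number of individuals", call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k == 1L) return(rep(1L, n))
  m <- genotypes
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2L]]
  }
  sds <- col_sds(m)
  m <- scale(m[, !is.na(sds) & sds > 0, drop = FALSE])
  pr <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  npc <- min(n_pcs, ncol(pr$x))
  with_stage_seed(seed, {
    km <- stats::kmeans(pr$x[, seq_len(npc), drop = FALSE], centers = k,
                        nstart = 10L, iter.max = 50L)
    as.integer(km$cluster)
  })
}
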