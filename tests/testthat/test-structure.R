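# Stratification PCA, inversion localization, Hudson F_ST, composite LD,
# HWE exact test, and the k-means clustering stand-in.

ctrl_annot <- function(snps, chrom = "2L", pos = NULL) {
  data.frame(snp_id = snps, chrom = chrom,
             pos = if (is.null(pos)) seq_along(snps) * 1e6 else pos,
             class = "control", stringsAsFactors = FALSE)
}

test_that("PCA concentrates on the variance-carrying SNPs", {
  fams <- sprintf("f%02d", 1:10)
  m <- matrix(0.5, 10, 3, dimnames = list(fams, c("a", "b", "c")))
  m[, "a"] <- seq(0.1, 0.9, length.out = 10)
  pca <- pca_control(m, ctrl_annot(c("a", "b", "c")))
  expect_equal(abs(pca$loadings["a", 1]), 1)
  expect_equal(pca$var_frac[1], 1)

  # two perfectly correlated columns share the loading equally
  m[, "b"] <- 0.2 + 0.5 * m[, "a"]
  pca <- pca_control(m, ctrl_annot(c("a", "b", "c")))
  expect_equal(pca$var_frac[1], 1)
  expect_equal(abs(pca$loadings["a", 1]), abs(pca$loadings["b", 1]))
  expect_equal(abs(pca$loadings["a", 1]), 1 / sqrt(2))

  expect_error(pca_control(matrix(0.5, 5, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))),
                           ctrl_annot(c("a", "b", "c"))),
               "no variance")
})

test_that("PCA variance fractions are invariant to SNP column order", {
  set.seed(5)
  m <- matrix(runif(80), 8, 10,
              dimnames = list(sprintf("f%d", 1:8), sprintf("s%02d", 1:10)))
  an <- ctrl_annot(colnames(m))
  p1 <- pca_control(m, an)
  p2 <- pca_control(m[, sample(ncol(m))], an)
  expect_equal(p1$var_frac, p2$var_frac)
})

test_that("PC1 of the default simulation tracks the inversion karyotype", {
  study <- default_study(seed = 1)
  pca <- pca_control(study$pooled, study$annotation)
  kary <- tapply(study$population$offspring$karyotype,
                 study$population$offspring$family, mean)
  r <- cor(pca$scores[, 1], kary[rownames(pca$scores)])
  expect_gt(abs(r), 0.5)
})

test_that("localization test separates inside from outside correlations", {
  # construct frequencies whose correlation with a score vector is known
  fams <- sprintf("f%02d", 1:12)
  score <- seq(-1, 1, length.out = 12)
  make_col <- function(r, noise_seed) {
    set.seed(noise_seed)
    r * score + sqrt(1 - r^2) * scale(residuals(lm(rnorm(12) ~ score)))
  }
  snps <- sprintf("s%02d", 1:8)
  m <- sapply(1:8, function(i) make_col(c(rep(0.8, 4), rep(0.1, 4))[i], i))
  m <- matrix(as.numeric(m), 12, 8, dimnames = list(fams, snps))
  an <- ctrl_annot(snps, pos = c(25e6, 30e6, 35e6, 40e6,
                                 5e6, 10e6, 15e6, 45e6))
  pca <- list(scores = matrix(score, 12, 1, dimnames = list(fams, NULL)),
              snps_used = snps)
  class(pca) <- "pool_pca"
  rep <- pc_localization_test(m, an, pca, 1, "2L:22000000-42000000")
  expect_equal(rep$n_inside + rep$n_outside, 8L)
  expect_gt(rep$mean_r_inside, rep$mean_r_outside)
  expect_gt(rep$z, 2)
  expect_lt(rep$p, 0.05)

  # indistinguishable groups: P near 1
  m2 <- m[, c(1:4, 1:4)]
  colnames(m2) <- snps
  rep2 <- pc_localization_test(m2, an, pca, 1, "2L:22000000-42000000")
  expect_gt(rep2$p, 0.9)

  expect_error(pc_localization_test(m, an, pca, 1, "3R:1-1000"),
               "no control SNPs")
})

test_that("default-simulation PC1 correlations localize to the inversion", {
  for (seed in 1:3) {
    study <- default_study(seed = seed)
    pca <- pca_control(study$pooled, study$annotation)
    rep <- pc_localization_test(study$pooled, study$annotation, pca, 1,
                                "2L:22000000-42000000")
    expect_gt(rep$mean_r_inside, rep$mean_r_outside)
  }
})

test_that("Hudson F_ST matches its boundary and asymptotic values", {
  big <- function(p, n = 500) c(rep(2L, round(p * n)), rep(0L, n - round(p * n)))
  cl <- rep(c("a", "b"), each = 500)

  fixed <- per_snp_fst(cbind(s = c(big(1), big(0))), cl)
  expect_equal(fixed$fst, 1)

  same <- per_snp_fst(cbind(s = c(big(0.4), big(0.4))), cl)
  expect_lt(abs(same$fst), 0.01)

  asym <- per_snp_fst(cbind(s = c(big(0.9), big(0.1))), cl)
  expect_equal(asym$fst, 0.64 / 0.82, tolerance = 0.01)

  mono <- per_snp_fst(cbind(s = c(big(0), big(0))), cl)
  expect_true(is.na(mono$fst))

  # sampling noise can push the corrected estimator negative: retained
  set.seed(2)
  g <- cbind(s = rbinom(40, 2, 0.5))
  res <- per_snp_fst(g, rep(c("a", "b"), 20))
  expect_true(is.finite(res$fst))
  expect_identical(res$negative, res$fst < 0)

  expect_error(per_snp_fst(cbind(s = c(0L, 1L)), c("a", "b")),
               "at least 2 individuals")
})

test_that("composite LD r2 behaves like a squared correlation", {
  g <- cbind(a = c(0, 1, 2, 1), b = c(0, 2, 0, 2),
             c = c(0, 0, 2, 2), d = c(2, 2, 0, 0), e = c(1, 1, 1, 1))
  expect_equal(ld_r2(g, "a", "a"), 1)
  expect_equal(ld_r2(g, "c", "d"), 1)       # perfect negative correlation
  expect_equal(ld_r2(g, "a", "b"), 0)       # hand-checked zero covariance
  expect_true(is.na(ld_r2(g, "a", "e")))    # monomorphic partner

  # symmetry and orientation-flip invariance over random dosage pairs
  set.seed(8)
  for (i in 1:20) {
    x <- sample(0:2, 15, replace = TRUE)
    y <- sample(0:2, 15, replace = TRUE)
    m <- cbind(x = x, y = y, yf = 2L - y)
    expect_equal(ld_r2(m, "x", "y"), ld_r2(m, "y", "x"))
    expect_equal(ld_r2(m, "x", "y"), ld_r2(m, "x", "yf"))
  }
})

# independent enumeration oracle: direct factorial formula over all
# heterozygote configurations compatible with the allele counts
hwe_oracle <- function(n1, nh, n2) {
  n <- n1 + nh + n2
  na <- 2 * n1 + nh
  configs <- list()
  for (h in 0:n) {
    r1 <- (na - h) / 2
    if (r1 < 0 || r1 != round(r1)) next
    r2 <- n - h - r1
    if (r2 < 0) next
    configs[[length(configs) + 1L]] <-
      c(h = h, pr = factorial(n) / (factorial(r1) * factorial(h) *
                                      factorial(r2)) * 2^h)
  }
  tab <- do.call(rbind, configs)
  pr <- tab[, "pr"] / sum(tab[, "pr"])
  p_obs <- pr[tab[, "h"] == nh]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

test_that("HWE exact test equals enumeration for the worked cases", {
  expect_equal(hwe_exact(10, 0, 0), 1)
  expect_equal(hwe_exact(3, 0, 1), 1 / 7)
  expect_equal(hwe_exact(25, 50, 25), 1)
  expect_error(hwe_exact(-1, 2, 3), "non-negative")
})

test_that("HWE exact test matches the enumeration oracle on small tables", {
  for (n1 in 0:6) for (nh in 0:6) for (n2 in 0:6) {
    if (n1 + nh + n2 == 0 || n1 + nh + n2 > 12) next
    expect_equal(hwe_exact(n1, nh, n2), hwe_oracle(n1, nh, n2),
                 tolerance = 1e-10,
                 label = sprintf("hwe(%d,%d,%d)", n1, nh, n2))
  }
})

test_that("k-means clustering separates clearly differentiated groups", {
  set.seed(4)
  g1 <- matrix(rbinom(20 * 10, 2, 0.05), 20, 10)
  g2 <- matrix(rbinom(20 * 10, 2, 0.95), 20, 10)
  g <- rbind(g1, g2)
  colnames(g) <- sprintf("s%02d", 1:10)
  truth <- rep(1:2, each = 20)
  cl <- cluster_families(g, k = 2, seed = 3)
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_equal(agree, 1)
  expect_identical(cl, cluster_families(g, k = 2, seed = 3))
  expect_identical(cluster_families(g, k = 1, seed = 3), rep(1L, 40))
  expect_error(cluster_families(g[1:3, ], k = 5, seed = 1), "exceed")
})

test_that("simulated inversion region shows elevated between-karyotype F_ST", {
  study <- default_study(seed = 1)
  pop <- study$population
  g <- pop$offspring$genotypes[1:300, ]
  kary <- pop$offspring$karyotype[1:300]
  keep <- kary != 1
  fst <- per_snp_fst(g[keep, ], ifelse(kary[keep] == 2, "inv", "std"))
  inv <- pop$snps$inversion[match(fst$snp_id, pop$snps$snp_id)] &
    pop$snps$differentiated[match(fst$snp_id, pop$snps$snp_id)]
  expect_gt(mean(fst$fst[inv], na.rm = TRUE),
            mean(fst$fst[!inv], na.rm = TRUE))
})
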