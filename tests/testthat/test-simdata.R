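# Forward simulator: founder frequencies, Mendelian segregation,
# inversion linkage, bioassay liability model, signal generation, colony.

test_that("realized founder frequency of the target-site SNP matches its input", {
  cfg <- sim_config(seed = 1)
  pop <- simulate_population(cfg)
  founders <- rbind(pop$mothers$genotypes, pop$fathers$genotypes)
  n_alleles <- 2 * nrow(founders)  # 2 x (2 x 98) founder alleles
  realized <- sum(founders[, "Vgsc_kdr"]) / n_alleles
  interval <- qbinom(c(0.005, 0.995), n_alleles, 0.94) / n_alleles
  expect_gte(realized, interval[1])
  expect_lte(realized, interval[2])
})

test_that("degenerate karyotype frequency gives zero karyotype variance", {
  cfg <- small_config(seed = 2, inversion_karyotype_freq = 1.0)
  pop <- simulate_population(cfg)
  expect_true(all(pop$offspring$karyotype == 2L))
  expect_true(all(pop$mothers$karyotype == 2L))
})

test_that("population simulation is deterministic given the seed", {
  cfg <- small_config(seed = 7)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$offspring$genotypes, p2$offspring$genotypes)
  expect_identical(p1$snps, p2$snps)
  expect_identical(simulate_bioassay(p1, cfg), simulate_bioassay(p2, cfg))
})

test_that("offspring dosages respect Mendelian bounds from parental genotypes", {
  cfg <- small_config(seed = 3)
  pop <- simulate_population(cfg)
  fam_idx <- match(pop$offspring$family, pop$families$family_id)
  m <- pop$mothers$genotypes[fam_idx, , drop = FALSE]
  f <- pop$fathers$genotypes[fam_idx, , drop = FALSE]
  g <- pop$offspring$genotypes
  lower <- (m == 2) + (f == 2)
  upper <- (m >= 1) + (f >= 1)
  expect_true(all(g >= lower))
  expect_true(all(g <= upper))
})

test_that("karyotype correlates with inversion SNPs more than with others", {
  for (seed in 1:3) {
    pop <- simulate_population(small_config(seed = seed))
    kary <- pop$offspring$karyotype
    r <- suppressWarnings(
      abs(cor(kary, pop$offspring$genotypes))[1, ])
    inv <- pop$snps$inversion & pop$snps$differentiated
    expect_gt(mean(r[inv], na.rm = TRUE), mean(r[!inv], na.rm = TRUE))
  }
})

test_that("null liability model gives symmetric mortality around one half", {
  cfg <- sim_config(seed = 5, baseline_logit = 0, family_sd = 0,
                    humidity_beta = 0, karyotype_beta = 0,
                    target_site_beta = 0,
                    causal_effects = data.frame(snp_id = character(0),
                                                freq = numeric(0),
                                                beta = numeric(0)))
  pop <- simulate_population(cfg)
  phen <- simulate_bioassay(pop, cfg)
  overall <- sum(phen$n_dead) / sum(phen$n_exposed)
  expect_lt(abs(overall - 0.5), 0.05)
})

test_that("negative humidity effect induces a negative mortality-humidity correlation", {
  cfg <- sim_config(seed = 11, karyotype_beta = 0, target_site_beta = 0,
                    causal_effects = data.frame(snp_id = character(0),
                                                freq = numeric(0),
                                                beta = numeric(0)))
  phen <- simulate_bioassay(simulate_population(cfg), cfg)
  ct <- cor.test(phen$mortality, phen$humidity)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("a protective allele lowers mortality of families carrying it", {
  study <- default_study(seed = 1)
  fam_dose <- study$family_freq[study$phenotype$family_id, "Cyp4j5"]
  rho <- cor(fam_dose, study$phenotype$mortality, method = "spearman")
  expect_lt(rho, 0)
})

test_that("noiseless signals reproduce the dye-bias mechanism exactly", {
  cfg <- small_config(seed = 4, signal_cv = 0,
                      dyebias_distribution = list(dist = "loguniform",
                                                  min = 0.5, max = 0.5))
  g <- matrix(c(1L, 2L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  sm <- simulate_signals(g, cfg, kind = "individual")
  expect_equal(sm$x["a", 1] / sm$y["a", 1], 0.5)     # heterozygote X:Y = k
  expect_equal(sm$y["b", 1], 0)                       # X-homozygote: no Y
  bias <- make_bias_table("s1", k = 0.77)
  p <- pooled_allele_frequency(
    signal_matrix(sm$x["b", , drop = FALSE], sm$y["b", , drop = FALSE],
                  kind = "pool"), bias)
  expect_equal(unname(p[1, 1]), 1)                    # p(X)=1 for any k
})

test_that("pool frequencies round-trip through noiseless signals (Eq. 1)", {
  cfg <- small_config(seed = 4, signal_cv = 0,
                      dyebias_distribution = list(dist = "loguniform",
                                                  min = 2, max = 2))
  pool <- matrix(9 / 30, 1, 1, dimnames = list("fam1", "s1"))  # 9 of 30 alleles
  sm <- simulate_signals(pool, cfg, kind = "pool")
  p <- pooled_allele_frequency(sm, make_bias_table("s1", k = 2))
  expect_equal(unname(p[1, 1]), 9 / 30, tolerance = 1e-12)
})

test_that("negative signal noise is rejected", {
  expect_error(small_config(signal_cv = -0.1), "signal_cv")
})

test_that("colony simulation yields the configured class sizes deterministically", {
  cfg <- small_config(seed = 6)
  col1 <- simulate_colony(cfg)
  expect_equal(nrow(col1$genotypes), 56L)  # 20 susceptible + 36 resistant
  expect_equal(as.vector(table(col1$phenotype)), c(20L, 36L))
  col2 <- simulate_colony(cfg)
  expect_identical(col1$genotypes, col2$genotypes)
  expect_error(simulate_colony(small_config(colony_n_susceptible = 0)),
               "colony_n_susceptible")
})

test_that("allelic tests on null colony SNPs reject at about the nominal rate", {
  rejections <- 0L; tests <- 0L
  for (seed in 1:25) {
    cfg <- sim_config(n_families = 4L, n_snps = 12L, n_control_snps = 4L,
                      n_control_inside = 2L, n_extra_females = 0L,
                      karyotype_beta = 0, target_site_beta = 0,
                      causal_effects = data.frame(snp_id = character(0),
                                                  freq = numeric(0),
                                                  beta = numeric(0)),
                      seed = seed)
    col <- simulate_colony(cfg)
    for (s in c("ctrl_0001", "cand_0001")) {
      res <- allelic_test(col$genotypes, col$phenotype, s)
      if (!is.na(res$p)) {
        tests <- tests + 1L
        rejections <- rejections + (res$p < 0.05)
      }
    }
  }
  # 99% binomial envelope around the nominal 5% level
  expect_gte(tests, 40L)
  expect_lte(rejections, qbinom(0.995, tests, 0.05))
})

test_that("simulated tables round-trip losslessly through the TSV dialect", {
  study <- simulate_study(small_config(seed = 8))
  tmp <- withr::local_tempfile(fileext = ".tsv")

  write_table(study$phenotype[, c("family_id", "n_exposed", "n_dead",
                                  "mortality", "humidity", "temperature",
                                  "sex")], tmp, schema = "phenotype")
  expect_equal(read_table(tmp, "phenotype")$mortality,
               study$phenotype$mortality)

  sig_tab <- signals_to_table(study$pool_signals)
  write_table(sig_tab, tmp, schema = "signals")
  back <- table_to_signals(read_table(tmp, "signals"), kind = "pool")
  expect_equal(back$x, study$pool_signals$x)
  expect_equal(back$y, study$pool_signals$y)

  gt <- genotypes_to_table(study$ind_genotypes)
  write_table(gt, tmp, schema = "genotypes")
  expect_identical(table_to_genotypes(read_table(tmp, "genotypes")),
                   study$ind_genotypes)
})
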