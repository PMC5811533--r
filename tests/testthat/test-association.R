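# Rank transform, partial correlation, the association scan, stepwise
# selection, and the power machinery.

test_that("rank transform uses average ranks and preserves missingness", {
  expect_equal(rank_transform(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rank_transform(c(5, 5, 1)), c(2.5, 2.5, 1))
  expect_equal(rank_transform(c(2, NA, 1)), c(2, NA, 1))
  # invariance to strictly monotone transforms
  x <- c(0.2, 1.5, 0.9, 7, 3)
  expect_equal(rank_transform(exp(x)), rank_transform(x))
  expect_equal(rank_transform(-1 / (1 + x)), rank_transform(x))
  expect_error(rank_transform(c(NA, NA)), "all values missing")
})

test_that("partial correlation residualizes on covariates correctly", {
  expect_equal(partial_correlation(1:5, 1:5, rep(7, 5))$r, 1)
  pc <- partial_correlation(c(1, 3, 2, 4), c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(pc$r, 1)

  # with no covariates it is the plain Pearson correlation
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  pc0 <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc0$r, unname(ct$estimate))
  expect_equal(pc0$p, ct$p.value)

  # affine transformation of covariates changes nothing
  z <- rnorm(30)
  a <- partial_correlation(x, y, z)
  b <- partial_correlation(x, y, 100 - 7 * z)
  expect_equal(a$r, b$r)
  expect_equal(a$p, b$p)

  # zero residual variance is reported, not an error
  res <- partial_correlation(rep(1, 10), rnorm(10))
  expect_true(is.na(res$r))
  expect_equal(res$reason, "zero residual variance")
})

test_that("partial correlation is calibrated under conditional independence", {
  set.seed(12)
  reps <- 400
  p <- replicate(reps, {
    z <- rnorm(40)
    x <- 0.8 * z + rnorm(40)
    y <- -0.8 * z + rnorm(40)
    partial_correlation(x, y, z)$p
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.11)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("covariate-free scan equals a rank correlation scan", {
  study <- default_study(seed = 1)
  pooled <- study$pooled[, 1:40]
  phen <- study$phenotype
  scan <- association_scan(pooled, phen, models = list(none = character(0)),
                           annot = study$annotation)
  for (s in colnames(pooled)[c(1, 7, 20, 33)]) {
    x <- pooled[phen$family_id, s]
    rho <- cor(x, phen$mortality, method = "spearman")
    row <- scan[scan$snp_id == s, ]
    expect_equal(row$r, rho, tolerance = 1e-12)
    # oracle P via the t test on pre-ranked data
    ct <- cor.test(rank(x), rank(phen$mortality))
    expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  }
  expect_true(all(scan$neglog10p >= 0, na.rm = TRUE))
  expect_true(all(abs(scan$r) <= 1, na.rm = TRUE))
})

test_that("scan input validation catches small and incomplete designs", {
  study <- default_study(seed = 1)
  pooled <- study$pooled[1:6, 1:10]
  expect_error(association_scan(pooled, study$phenotype), "at least 8")
  phen <- study$phenotype
  phen$humidity[1:40] <- NA
  expect_error(association_scan(study$pooled[, 1:5], phen,
                                models = list(h = "humidity")),
               "humidity")
  expect_error(association_scan(study$pooled[, 1:5], study$phenotype,
                                models = list(h = "nosuch")),
               "nosuch")
})

test_that("stepwise selection follows entry order and cumulative r-squared", {
  set.seed(9)
  n <- 24
  x1 <- drop(scale(poly(1:n, 2)[, 1]))
  x2 <- drop(scale(poly(1:n, 2)[, 2]))
  e <- drop(scale(residuals(lm(rnorm(n) ~ x1 + x2))))
  y <- sqrt(0.3) * x1 + sqrt(0.2) * x2 + sqrt(0.5) * e
  d <- data.frame(y = y, x1 = x1, x2 = x2)

  sw <- stepwise_regression(d, "y", c("x1", "x2"))
  expect_identical(sw$steps$predictor, c("x1", "x2"))
  expect_equal(sw$steps$r_squared, c(0.3, 0.5), tolerance = 1e-9)

  # single predictor: model r2 equals the squared correlation
  sw1 <- stepwise_regression(d, "y", "x1")
  expect_equal(sw1$steps$r_squared, cor(y, x1)^2)

  # a duplicated predictor never enters
  d$x1copy <- d$x1
  expect_warning(sw2 <- stepwise_regression(d, "y", c("x1", "x1copy", "x2")),
                 "collinear")
  expect_false("x1copy" %in% sw2$final)

  expect_error(stepwise_regression(d, "y", "x1", entry = 0.2, removal = 0.1),
               "entry")
})

test_that("stepwise cumulative r-squared matches the full refit at each step", {
  set.seed(21)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 2] <- X[, 1] * 0.5 + rnorm(n, sd = 0.8)
  y <- X %*% c(0.8, 0.4, 0.3, 0, 0) + rnorm(n)
  d <- data.frame(y = y, X)
  sw <- stepwise_regression(d, "y", paste0("X", 1:5))
  entered <- character(0)
  for (i in seq_len(nrow(sw$steps))) {
    pred <- sw$steps$predictor[i]
    if (startsWith(pred, "-")) {
      entered <- setdiff(entered, sub("^-", "", pred))
    } else entered <- c(entered, pred)
    fit <- summary(lm(reformulate(entered, "y"), data = d))
    expect_equal(sw$steps$r_squared[i], fit$r.squared, tolerance = 1e-9)
  }
})

test_that("stepwise decomposition of the simulated study ranks humidity first", {
  study <- default_study(seed = 1)
  phen <- study$phenotype
  cand <- c("Cyp4j5", "Vgsc_kdr", "Coeae1d", "Cyp4j10")
  d <- data.frame(mortality = rank_transform(phen$mortality),
                  humidity = rank_transform(phen$humidity))
  for (s in cand) d[[s]] <- rank_transform(study$pooled[phen$family_id, s])
  sw <- stepwise_regression(d, "mortality", cand, forced = "humidity")
  expect_equal(sw$steps$predictor[1], "humidity")
  expect_gt(length(sw$final), 1)                 # some SNP enters
  expect_true(all(diff(sw$steps$r_squared[!startsWith(sw$steps$predictor, "-")]) > -1e-12))
})

test_that("the Fisher-z minimal detectable correlation matches the study's power analysis", {
  expect_equal(detectable_effect(98, n_tests = 894), 0.46, tolerance = 0.01)
  expect_equal(detectable_effect(50, n_tests = 1), 0.387, tolerance = 0.005)
  expect_lt(detectable_effect(1e6), 0.005)
  # monotone: decreasing in n, increasing in the test burden
  n_grid <- c(20, 50, 100, 400)
  expect_true(all(diff(vapply(n_grid, detectable_effect, numeric(1),
                              n_tests = 100)) < 0))
  t_grid <- c(1, 10, 100, 1000)
  expect_true(all(diff(vapply(t_grid, function(m)
    detectable_effect(98, n_tests = m), numeric(1))) > 0))
  expect_error(detectable_effect(3), "exceed 3")
})

test_that("empirical power agrees with the analytic calculation", {
  # type-I error at the null
  ep0 <- empirical_power(0, n = 98, n_tests = 1, reps = 2000, seed = 5)
  expect_lt(abs(ep0$power - 0.05), 0.02)
  # self-consistency at the minimal detectable effect
  eff <- detectable_effect(50, n_tests = 1)
  ep <- empirical_power(eff, n = 50, n_tests = 1, reps = 4000, seed = 6)
  expect_lt(abs(ep$power - 0.80), 0.03)
  # saturation
  ep9 <- empirical_power(0.9, n = 98, n_tests = 1, reps = 500, seed = 7)
  expect_gt(ep9$power, 0.99)
  expect_error(empirical_power(1, n = 98), "effect")
})
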