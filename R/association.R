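# Discovery-stage association: rank-transformed (partial) correlations of
# family pool allele frequency with proportionate bioassay mortality,
# stepwise variance decomposition, and the study power calculation.

#' Rank-transform a numeric vector
#'
#' Average ranks for ties; missing values stay missing; ranks lie in
#' `[1, n_nonmissing]`.
#'
#' @param values numeric vector.
#' @return numeric vector of ranks with `NA` preserved.
#' @examples
#' rank_transform(c(5, 5, 1))  # 2.5 2.5 1
#' @export
rank_transform <- function(values) {
  if (all(is.na(values))) stop("all values missing", call. = FALSE)
  rank(values, na.last = "keep", ties.method = "average")
}

#' Partial correlation with t test
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on an intercept and the covariates. With no covariates this
#' is the plain Pearson correlation. The t statistic is
#' `r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of freedom
#' (`k` = number of covariates); P is two-sided.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return a list `r`, `t`, `p`, `n`, `df`; `r` is `NA` with a `reason`
#'   element when a residual variance is zero.
#' @examples
#' partial_correlation(c(1, 3, 2, 4), c(1, 2, 3, 4), c(0, 1, 0, 1))$r  # 1
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    cv <- matrix(numeric(0), length(x), 0)
  } else {
    cv <- as.matrix(covariates)
  }
  ok <- !is.na(x) & !is.na(y) & (ncol(cv) == 0 | !rowSums(is.na(cv)))
  n <- sum(ok)
  k <- ncol(cv)
  if (n < k + 3L)   # at least 1 residual degree of freedom
    stop(sprintf("need at least %d complete cases, got %d", k + 3L, n),
         call. = FALSE)
  xr <- x[ok]; yr <- y[ok]
  if (k > 0L) {
    design <- cbind(1, cv[ok, , drop = FALSE])
    qx <- qr(design)
    xr <- qr.resid(qx, xr)
    yr <- qr.resid(qx, yr)
    k <- qx$rank - 1L   # collinear covariates consume no extra df
  }
  if (stats::var(xr) == 0 || stats::var(yr) == 0)
    return(list(r = NA_real_, t = NA_real_, p = NA_real_, n = n,
                df = n - 2L - k, reason = "zero residual variance"))
  r <- stats::cor(xr, yr)
  df <- n - 2L - k
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(r = r, t = t, p = p, n = n, df = df)
}

#' Family-pool association scan
#'
#' For each SNP, rank-transforms the family allele frequencies, the
#' proportionate bioassay mortality, and the covariates, then computes
#' their partial correlation ([partial_correlation()]) over
#' pairwise-complete families. Several covariate models can be scanned in
#' one call (e.g. humidity only, and humidity plus PC1).
#'
#' @param freqs families-by-SNP matrix of pool allele frequencies
#'   (QC-passing SNPs).
#' @param phenotype family phenotype `data.frame` with columns `family_id`
#'   and `mortality`, plus any covariate columns (e.g. `humidity`,
#'   `temperature`). Rows are matched to `freqs` by `family_id`.
#' @param models named list of character vectors of covariate labels; the
#'   empty vector means plain correlation. Labels resolve to columns of
#'   `phenotype` or to PCA components `"PC1"`, `"PC2"`, ... of `pca`.
#' @param pca optional `pool_pca` from [pca_control()] supplying PC
#'   covariates (scores matched to `freqs` rows).
#' @param annot optional SNP annotation to carry `chrom`/`pos` into the
#'   result.
#' @param rank_covariates rank-transform covariates as well (default
#'   TRUE).
#' @param max_missing_covariate maximum tolerated fraction of families
#'   with a missing covariate (default 0.2).
#' @return a `data.frame` of class `association_result`: `snp_id`,
#'   `chrom`, `pos`, `model`, `n`, `r`, `t`, `p`, `neglog10p`.
#' @export
association_scan <- function(freqs, phenotype,
                             models = list(humidity = "humidity"),
                             pca = NULL, annot = NULL,
                             rank_covariates = TRUE,
                             max_missing_covariate = 0.2) {
  stopifnot(is.matrix(freqs), is.data.frame(phenotype),
            all(c("family_id", "mortality") %in% names(phenotype)))
  if (is.null(names(models)) || any(names(models) == ""))
    stop("`models` must be a named list", call. = FALSE)
  fams <- intersect(rownames(freqs), phenotype$family_id)
  if (length(fams) < 8L) stop("need at least 8 families", call. = FALSE)
  ph <- phenotype[match(fams, phenotype$family_id), ]
  fr <- freqs[fams, , drop = FALSE]

  cov_pool <- ph[setdiff(names(ph), c("family_id", "sex"))]
  if (!is.null(pca)) {
    sc <- pca$scores
    if (!all(fams %in% rownames(sc)))
      stop("PCA scores missing for some families", call. = FALSE)
    sc <- sc[fams, , drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
    cov_pool <- cbind(cov_pool, as.data.frame(sc))
  }

  y <- rank_transform(ph$mortality)
  out <- vector("list", length(models))
  for (mi in seq_along(models)) {
    labels <- models[[mi]]
    if (length(labels)) {
      missing_lab <- setdiff(labels, names(cov_pool))
      if (length(missing_lab))
        stop("covariate(s) not available: ",
             paste(missing_lab, collapse = ", "), call. = FALSE)
      cv <- as.matrix(cov_pool[labels])
      frac_na <- colMeans(is.na(cv))
      if (any(frac_na > max_missing_covariate))
        stop("covariate missing for too many families: ",
             paste(labels[frac_na > max_missing_covariate], collapse = ", "),
             call. = FALSE)
      if (rank_covariates) cv <- apply(cv, 2L, rank_transform)
    } else cv <- NULL
    res <- lapply(colnames(fr), function(s) {
      xv <- fr[, s]
      ok <- !is.na(xv)
      if (sum(ok) < (if (is.null(cv)) 0 else ncol(cv)) + 4L)
        return(list(r = NA_real_, t = NA_real_, p = NA_real_, n = sum(ok)))
      # ranks recomputed within the complete-case set of this SNP
      xs <- rank_transform(ifelse(ok, xv, NA))
      ys <- if (all(ok)) y else rank_transform(ifelse(ok, ph$mortality, NA))
      cvs <- if (!is.null(cv) && !all(ok)) {
        tmp <- cv; tmp[!ok, ] <- NA
        if (rank_covariates) apply(tmp, 2L, rank_transform) else tmp
      } else cv
      if (stats::var(xs[ok]) == 0)
        return(list(r = NA_real_, t = NA_real_, p = NA_real_, n = sum(ok)))
      partial_correlation(xs, ys, cvs)
    })
    df <- data.frame(
      snp_id = colnames(fr),
      model = names(models)[mi],
      n = vapply(res, function(z) as.integer(z$n), integer(1L)),
      r = vapply(res, function(z) z$r, numeric(1L)),
      t = vapply(res, function(z) z$t, numeric(1L)),
      p = vapply(res, function(z) z$p, numeric(1L)),
      row.names = NULL, stringsAsFactors = FALSE)
    out[[mi]] <- df
  }
  res <- do.call(rbind, out)
  res$neglog10p <- -log10(res$p)
  if (!is.null(annot)) {
    idx <- match(res$snp_id, annot$snp_id)
    res$chrom <- annot$chrom[idx]
    res$pos <- annot$pos[idx]
  } else {
    res$chrom <- NA_character_; res$pos <- NA_real_
  }
  res <- res[, c("snp_id", "chrom", "pos", "model", "n", "r", "t", "p",
                 "neglog10p")]
  class(res) <- c("association_result", "data.frame")
  res
}

#' Forward stepwise regression with backward removal
#'
#' Classic stepwise selection for the variance decomposition of the
#' resistance phenotype: forced covariates (e.g. humidity) enter first;
#' then, at each step, the candidate predictor with the smallest
#' nested-model F-test P-value below the entry threshold is added, after
#' which any non-forced included predictor whose removal P-value exceeds
#' the removal threshold is dropped. Candidates nearly collinear with the
#' included set (R-squared > 0.999) are skipped with a warning.
#'
#' @param data data.frame holding the response and predictors
#'   (complete-case rows are used).
#' @param response name of the response column.
#' @param candidates character vector of candidate predictor columns.
#' @param forced character vector of columns forced into the model first.
#' @param entry,removal P-value thresholds (defaults 0.05 and 0.10).
#' @return a list of class `stepwise_model`: `steps` (data.frame with
#'   `step`, `predictor`, `p_enter`, `r_squared` cumulative), `final`
#'   (character vector of selected predictors incl. forced), `forced`,
#'   `thresholds`.
#' @export
stepwise_regression <- function(data, response, candidates,
                                forced = character(0),
                                entry = 0.05, removal = 0.10) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(candidates %in% names(data)), all(forced %in% names(data)))
  if (entry <= 0 || entry >= 1 || removal <= 0 || removal >= 1 ||
      entry > removal)
    fail_field("thresholds", "need 0 < entry <= removal < 1")
  used <- stats::complete.cases(data[c(response, candidates, forced)])
  d <- data[used, , drop = FALSE]
  y <- d[[response]]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  rss_of <- function(vars) {
    if (length(vars) == 0L) return(tss)
    X <- cbind(1, as.matrix(d[vars]))
    sum(qr.resid(qr(X), y)^2)
  }
  f_test <- function(rss0, rss1, df_extra, df_resid) {
    if (rss1 <= 0) return(0)
    f <- ((rss0 - rss1) / df_extra) / (rss1 / df_resid)
    stats::pf(f, df_extra, df_resid, lower.tail = FALSE)
  }
  included <- forced
  pool <- setdiff(candidates, forced)
  steps <- list()
  rss_cur <- rss_of(included)
  step_no <- 0L
  for (v in forced) {
    step_no <- step_no + 1L
    steps[[step_no]] <- data.frame(
      step = step_no, predictor = v, p_enter = NA_real_,
      r_squared = 1 - rss_of(forced[seq_len(match(v, forced))]) / tss,
      stringsAsFactors = FALSE)
  }
  repeat {
    # forward
    best_v <- NULL; best_p <- Inf; best_rss <- NA_real_
    for (v in pool) {
      vars1 <- c(included, v)
      X <- cbind(1, as.matrix(d[vars1]))
      if (length(included)) {  # collinearity guard
        xres <- qr.resid(qr(cbind(1, as.matrix(d[included]))), d[[v]])
        if (sum(xres^2) / max(sum((d[[v]] - mean(d[[v]]))^2),
                              .Machine$double.eps) < 0.001) {
          warning(sprintf("skipping collinear predictor '%s'", v))
          pool <- setdiff(pool, v)
          next
        }
      } else if (stats::var(d[[v]]) == 0) {
        warning(sprintf("skipping constant predictor '%s'", v))
        pool <- setdiff(pool, v)
        next
      }
      rss1 <- rss_of(vars1)
      p <- f_test(rss_cur, rss1, 1L, n - length(vars1) - 1L)
      if (!is.na(p) && p < best_p) {
        best_p <- p; best_v <- v; best_rss <- rss1
      }
    }
    if (is.null(best_v) || best_p >= entry) break
    included <- c(included, best_v)
    pool <- setdiff(pool, best_v)
    rss_cur <- best_rss
    step_no <- step_no + 1L
    steps[[step_no]] <- data.frame(
      step = step_no, predictor = best_v, p_enter = best_p,
      r_squared = 1 - rss_cur / tss, stringsAsFactors = FALSE)
    # backward
    repeat {
      removable <- setdiff(included, forced)
      if (length(removable) == 0L) break
      p_rem <- vapply(removable, function(v) {
        rss0 <- rss_of(setdiff(included, v))
        f_test(rss0, rss_cur, 1L, n - length(included) - 1L)
      }, numeric(1L))
      worst <- which.max(p_rem)
      if (p_rem[worst] <= removal) break
      v <- removable[worst]
      included <- setdiff(included, v)
      pool <- union(pool, v)
      rss_cur <- rss_of(included)
      step_no <- step_no + 1L
      steps[[step_no]] <- data.frame(
        step = step_no, predictor = paste0("-", v), p_enter = p_rem[worst],
        r_squared = 1 - rss_cur / tss, stringsAsFactors = FALSE)
    }
  }
  structure(list(steps = do.call(rbind, steps), final = included,
                 forced = forced,
                 thresholds = c(entry = entry, removal = removal),
                 n = n),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("stepwise model (n = %d, entry %.2f / removal %.2f)\n",
              x$n, x$thresholds["entry"], x$thresholds["removal"]))
  if (is.null(x$steps)) cat("  no predictor entered\n") else
    print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Minimal detectable correlation (Fisher z power calculation)
#'
#' The smallest true correlation between family allele frequency and
#' mortality that is rejectable with the target power at a
#' Bonferroni-corrected alpha, by the Fisher z approximation:
#' `r = tanh((z_{1-alpha/2} + z_{power}) / sqrt(n - 3))` with
#' `alpha = alpha_family / n_tests`.
#'
#' @param n number of families.
#' @param n_tests number of tests for the Bonferroni correction.
#' @param alpha_family overall alpha (default 0.05).
#' @param power target power (default 0.80).
#' @param sides 1 or 2 (default two-sided).
#' @return the minimal detectable correlation.
#' @examples
#' detectable_effect(98, n_tests = 894)  # ~0.46
#' @export
detectable_effect <- function(n, n_tests = 1L, alpha_family = 0.05,
                              power = 0.80, sides = 2L) {
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  check_count(n_tests, "n_tests")
  check_prob(alpha_family, "alpha_family")
  if (power <= 0 || power >= 1) fail_field("power", "must be in (0, 1)")
  if (!sides %in% c(1L, 2L)) fail_field("sides", "must be 1 or 2")
  alpha <- alpha_family / n_tests
  z_alpha <- stats::qnorm(1 - alpha / sides)
  tanh((z_alpha + stats::qnorm(power)) / sqrt(n - 3))
}

#' Monte Carlo power of the correlation test
#'
#' Simulates bivariate-normal samples of size `n` with the given true
#' correlation and reports the fraction rejected at the Bonferroni alpha,
#' with an exact binomial confidence interval.
#'
#' @param effect true correlation (|effect| < 1).
#' @param n sample size (families).
#' @param n_tests,alpha_family Bonferroni specification.
#' @param reps number of replicates (>= 100).
#' @param seed integer seed.
#' @param sides 1 or 2.
#' @return a list `power` (rejection proportion), `ci` (95% binomial
#'   interval), `reps`, `alpha`.
#' @export
empirical_power <- function(effect, n, n_tests = 1L, alpha_family = 0.05,
                            reps = 5000L, seed = 1L, sides = 2L) {
  if (abs(effect) >= 1) fail_field("effect", "must satisfy |effect| < 1")
  if (reps < 100L) fail_field("reps", "need at least 100 replicates")
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  alpha <- alpha_family / n_tests
  with_stage_seed(seed, {
    z1 <- matrix(stats::rnorm(n * reps), n, reps)
    z2 <- matrix(stats::rnorm(n * reps), n, reps)
    x <- z1
    y <- effect * z1 + sqrt(1 - effect^2) * z2
    xc <- sweep(x, 2L, colMeans(x)); yc <- sweep(y, 2L, colMeans(y))
    r <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- if (sides == 2L) 2 * stats::pt(-abs(t), n - 2) else
      stats::pt(t, n - 2, lower.tail = FALSE)
    rej <- sum(p < alpha)
    ci <- stats::binom.test(rej, reps)$conf.int
    list(power = rej / reps, ci = as.numeric(ci), reps = reps, alpha = alpha)
  })
}
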