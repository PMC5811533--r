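# Forward simulator of the isofemale family-pool study design.
#
# The population carries a biallelic "karyotype locus" for a large
# polymorphic inversion: each founder haplotype is either inverted or
# standard, and SNPs inside the inversion span are transmitted together
# with the arrangement (suppressed recombination) and may have
# arrangement-specific allele frequencies. SNPs outside the span segregate
# independently.

# approximate chromosome-arm lengths (bp) used to lay out the panel
ARM_LENGTHS <- c("2R" = 61545105, "2L" = 49364325, "3R" = 53200684,
                 "3L" = 41963435, "X" = 24393108)

# published 2L coordinates of the default causal markers
CAUSAL_POSITIONS <- list(
  Vgsc_kdr = list(chrom = "2L", pos = 2422652),
  Cyp4j5   = list(chrom = "2L", pos = 25635973),
  Cyp4j10  = list(chrom = "2L", pos = 25636722),
  Coeae1d  = list(chrom = "2L", pos = 20288132)
)

#' Simulate the study population of isofemale families
#'
#' Generates the SNP panel (candidate and control SNPs laid out across five
#' chromosome arms), founder mothers, fathers and extra genotyped females
#' drawn from the configured allele frequencies, and each family's
#' offspring by Mendelian segregation from one mother and one father
#' (single insemination). Haplotypes inside the inversion span are
#' transmitted as a block together with the arrangement; arrangement-
#' specific allele frequencies for non-causal inversion SNPs follow a
#' Balding-Nichols model with parameter `inversion_fst`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `pool_population`: a list with elements
#'   `snps` (per-SNP annotation and truth: `snp_id`, `chrom`, `pos`,
#'   `class`, `gene`, `inversion`, `p_std`, `p_inv`, `true_freq`, `beta`),
#'   `offspring` (`family`, `karyotype`, `genotypes` dosage matrix),
#'   `mothers`, `fathers`, `extra_females` (each `genotypes` + `karyotype`),
#'   `families` (ids and offspring counts) and `config`.
#' @examples
#' cfg <- sim_config(n_families = 6, n_snps = 30, n_control_snps = 8,
#'                   n_control_inside = 3, n_extra_females = 4, seed = 2)
#' pop <- simulate_population(cfg)
#' dim(pop$offspring$genotypes)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(derive_seed(config$seed, "population"), {
    snps <- build_panel(config)
    S <- nrow(snps)
    nf <- config$n_families
    f_inv <- config$inversion_karyotype_freq

    draw_founders <- function(m, prefix) {
      arr <- matrix(stats::runif(m * 2) < f_inv, m, 2)  # TRUE = inverted
      hap <- function(a_col) {
        p <- matrix(snps$p_std, m, S, byrow = TRUE)
        dcol <- which(snps$differentiated)
        if (length(dcol) && any(a_col))
          p[a_col, dcol] <- matrix(snps$p_inv[dcol], sum(a_col),
                                   length(dcol), byrow = TRUE)
        matrix(as.integer(stats::runif(m * S) < p), m, S,
               dimnames = list(sprintf("%s%03d", prefix, seq_len(m)),
                               snps$snp_id))
      }
      list(h1 = hap(arr[, 1L]), h2 = hap(arr[, 2L]), arr = arr)
    }

    mothers <- draw_founders(nf, "mo")
    fathers <- draw_founders(nf, "fa")
    extra <- if (config$n_extra_females > 0)
      draw_founders(config$n_extra_females, "ext") else NULL

    n_off <- sample(seq(config$offspring_range[1L], config$offspring_range[2L]),
                    nf, replace = TRUE)
    fam_ids <- sprintf("F%03d", seq_len(nf))
    fam_idx <- rep(seq_len(nf), n_off)
    N <- length(fam_idx)
    block <- which(snps$inversion)

    transmit <- function(par) {
      pick2 <- matrix(stats::runif(N * S) < 0.5, N, S)
      hap <- par$h1[fam_idx, , drop = FALSE]
      h2 <- par$h2[fam_idx, , drop = FALSE]
      hap[pick2] <- h2[pick2]
      b2 <- stats::runif(N) < 0.5  # one haplotype choice for the whole block
      if (length(block)) {
        hb <- par$h1[fam_idx, block, drop = FALSE]
        hb[b2, ] <- par$h2[fam_idx, block, drop = FALSE][b2, ]
        hap[, block] <- hb
      }
      arr <- ifelse(b2, par$arr[fam_idx, 2L], par$arr[fam_idx, 1L])
      list(hap = hap, arr = arr)
    }
    tm <- transmit(mothers)
    tf <- transmit(fathers)
    geno <- tm$hap + tf$hap
    rownames(geno) <- sprintf("%s_o%02d", fam_ids[fam_idx],
                              sequence(n_off))

    founder_geno <- function(fo) {
      g <- fo$h1 + fo$h2
      list(genotypes = g, karyotype = as.integer(rowSums(fo$arr)))
    }

    structure(list(
      snps = snps,
      families = data.frame(family_id = fam_ids, n_offspring = n_off,
                            stringsAsFactors = FALSE),
      offspring = list(family = fam_ids[fam_idx],
                       karyotype = as.integer(tm$arr) + as.integer(tf$arr),
                       genotypes = geno),
      mothers = founder_geno(mothers),
      fathers = founder_geno(fathers),
      extra_females = if (is.null(extra)) NULL else founder_geno(extra),
      config = config
    ), class = "pool_population")
  })
}

# Lay out the SNP panel and draw per-SNP truth (frequencies, effects).
# Called inside the population RNG stream.
build_panel <- function(config) {
  S <- config$n_snps
  span <- config$inversion_span
  ichrom <- config$inversion_chrom

  causal <- data.frame(snp_id = "Vgsc_kdr", freq = config$target_site_freq,
                       beta = config$target_site_beta,
                       stringsAsFactors = FALSE)
  if (nrow(config$causal_effects))
    causal <- rbind(causal, config$causal_effects[, c("snp_id", "freq", "beta")])
  nc <- nrow(causal)
  n_ctrl <- config$n_control_snps
  n_cand <- S - n_ctrl - nc
  if (n_cand < 0)
    fail_field("n_snps", "too small for the causal and control SNP counts")

  causal_pos <- t(vapply(causal$snp_id, function(id) {
    kp <- CAUSAL_POSITIONS[[id]]
    if (is.null(kp))  # unknown custom causal SNP: place on 2R
      c(chrom = "2R", pos = as.character(ceiling(stats::runif(1) * ARM_LENGTHS["2R"])))
    else c(chrom = kp$chrom, pos = as.character(kp$pos))
  }, character(2L)))

  rand_pos <- function(n, exclude_span = FALSE, only_span = FALSE) {
    if (only_span) {
      chrom <- rep(ichrom, n)
      pos <- ceiling(stats::runif(n, span[1L] - 1, span[2L]))
      return(data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE))
    }
    chrom <- sample(names(ARM_LENGTHS), n, replace = TRUE,
                    prob = ARM_LENGTHS / sum(ARM_LENGTHS))
    pos <- ceiling(stats::runif(n) * ARM_LENGTHS[chrom])
    if (exclude_span) {
      bad <- chrom == ichrom & pos >= span[1L] & pos <= span[2L]
      while (any(bad)) {
        chrom[bad] <- sample(names(ARM_LENGTHS), sum(bad), replace = TRUE,
                             prob = ARM_LENGTHS / sum(ARM_LENGTHS))
        pos[bad] <- ceiling(stats::runif(sum(bad)) * ARM_LENGTHS[chrom[bad]])
        bad <- chrom == ichrom & pos >= span[1L] & pos <= span[2L]
      }
    }
    data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  }

  ctrl_in <- rand_pos(config$n_control_inside, only_span = TRUE)
  ctrl_out <- rand_pos(n_ctrl - config$n_control_inside, exclude_span = TRUE)
  cand <- rand_pos(n_cand)

  snps <- data.frame(
    snp_id = c(causal$snp_id,
               sprintf("ctrl_%04d", seq_len(n_ctrl)),
               sprintf("cand_%04d", seq_len(n_cand))),
    chrom = c(causal_pos[, 1L], ctrl_in$chrom, ctrl_out$chrom, cand$chrom),
    pos = as.numeric(c(causal_pos[, 2L], ctrl_in$pos, ctrl_out$pos, cand$pos)),
    class = c(rep("candidate", nc), rep("control", n_ctrl),
              rep("candidate", n_cand)),
    gene = c(causal$snp_id, rep(".", n_ctrl + n_cand)),
    beta = c(causal$beta, rep(0, n_ctrl + n_cand)),
    stringsAsFactors = FALSE
  )
  snps$inversion <- snps$chrom == ichrom &
    snps$pos >= span[1L] & snps$pos <= span[2L]

  # allele-X frequencies: configured for causal SNPs, random orientation
  # of a uniform MAF for neutral ones
  fm <- config$founder_maf_distribution
  maf <- stats::runif(nrow(snps), fm$min, fm$max)
  flip <- stats::runif(nrow(snps)) < 0.5
  p <- ifelse(flip, 1 - maf, maf)
  p[seq_len(nc)] <- causal$freq
  snps$p_std <- p
  snps$p_inv <- p

  # arrangement differentiation for non-causal SNPs inside the span
  snps$differentiated <- snps$inversion & snps$beta == 0 &
    config$inversion_fst > 0
  if (any(snps$differentiated)) {
    F <- config$inversion_fst
    d <- which(snps$differentiated)
    a <- p[d] * (1 - F) / F
    b <- (1 - p[d]) * (1 - F) / F
    snps$p_inv[d] <- stats::rbeta(length(d), a, b)
    snps$p_std[d] <- stats::rbeta(length(d), a, b)
  }
  f <- config$inversion_karyotype_freq
  snps$true_freq <- f * snps$p_inv + (1 - f) * snps$p_std
  snps
}

#' Simulate family bioassays under a logit-binomial liability model
#'
#' Families are assigned round-robin to assay days; each day gets a
#' humidity and temperature drawn uniformly from the configured ranges.
#' Each exposed offspring dies independently with probability
#' `plogis(baseline_logit + humidity_beta * (H - mid) +
#' sum(beta_g (dosage_g - 2 p_g)) + karyotype_beta (karyotype - 2 f_inv) +
#' family_effect)`; covariates and dosages are centred so the intercept is
#' the population-mean logit of death.
#'
#' @param truth a `pool_population` from [simulate_population()].
#' @param config the same [sim_config()] used to generate `truth`.
#' @return a `data.frame` with one row per family: `family_id`,
#'   `n_exposed`, `n_dead`, `mortality`, `humidity`, `temperature`,
#'   `assay_day`, `sex`.
#' @export
simulate_bioassay <- function(truth, config) {
  stopifnot(inherits(truth, "pool_population"), inherits(config, "sim_config"))
  if (!identical(truth$snps$snp_id, colnames(truth$offspring$genotypes)))
    stop("truth object is inconsistent with its SNP panel", call. = FALSE)
  with_stage_seed(derive_seed(config$seed, "bioassay"), {
    fams <- truth$families
    keep <- fams$n_offspring > 0
    if (!all(keep)) {
      warning(sprintf("excluding %d family(ies) with zero offspring",
                      sum(!keep)))
      fams <- fams[keep, , drop = FALSE]
    }
    nf <- nrow(fams)
    day <- rep_len(seq_len(config$n_assay_days), nf)
    hum_day <- stats::runif(config$n_assay_days, config$humidity_range[1L],
                            config$humidity_range[2L])
    tmp_day <- stats::runif(config$n_assay_days, config$temperature_range[1L],
                            config$temperature_range[2L])
    fam_eff <- stats::rnorm(nf, 0, config$family_sd)

    off <- truth$offspring
    in_keep <- off$family %in% fams$family_id
    fam_of <- match(off$family[in_keep], fams$family_id)
    G <- off$genotypes[in_keep, , drop = FALSE]
    causal <- which(truth$snps$beta != 0)
    eta <- config$baseline_logit +
      config$humidity_beta * (hum_day[day[fam_of]] - mean(config$humidity_range)) +
      fam_eff[fam_of] +
      config$karyotype_beta *
        (off$karyotype[in_keep] - 2 * config$inversion_karyotype_freq)
    if (length(causal)) {
      Gc <- sweep(G[, causal, drop = FALSE], 2L,
                  2 * truth$snps$true_freq[causal], `-`)
      eta <- eta + drop(Gc %*% truth$snps$beta[causal])
    }
    dead <- stats::rbinom(length(eta), 1L, stats::plogis(eta))
    n_dead <- as.integer(rowsum(dead, fam_of)[, 1L])
    data.frame(
      family_id = fams$family_id,
      n_exposed = fams$n_offspring,
      n_dead = n_dead,
      mortality = n_dead / fams$n_offspring,
      humidity = hum_day[day],
      temperature = tmp_day[day],
      assay_day = day,
      sex = "F",
      stringsAsFactors = FALSE
    )
  })
}

#' True per-SNP dye-bias factors of a simulation config
#'
#' The per-SNP cy3:cy5 bias factors `k` are drawn once per config (their
#' own seeded stream), so individual and pool signals simulated from the
#' same config share the same bias.
#'
#' @param config a [sim_config()] object.
#' @param snp_ids SNP identifiers to name the result with (defaults to the
#'   panel order; `k` depends only on the panel size).
#' @return named numeric vector of length `n_snps`.
#' @export
true_dye_bias <- function(config, snp_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  db <- config$dyebias_distribution
  k <- with_stage_seed(derive_seed(config$seed, "dyebias"),
                       exp(stats::runif(config$n_snps, log(db$min), log(db$max))))
  if (!is.null(snp_ids)) names(k) <- snp_ids
  k
}

#' Simulate two-channel array signals for individuals or pools
#'
#' The expected X (cy3) signal is proportional to the fraction of X
#' alleles, and the expected Y (cy5) signal to the complementary fraction
#' divided by the SNP's dye-bias factor `k`, so a heterozygote's mean X:Y
#' ratio equals `k`. Multiplicative lognormal noise with coefficient of
#' variation `signal_cv` is applied independently to each channel;
#' signals are always non-negative.
#'
#' @param x a samples-by-SNP matrix of genotype dosages in \{0, 1, 2\}
#'   (`kind = "individual"`) or of pool allele frequencies in \[0, 1\]
#'   (`kind = "pool"`). Column names must be SNP ids.
#' @param config a [sim_config()] object (supplies `k`, noise and scale).
#' @param kind `"individual"` or `"pool"`.
#' @return a [signal_matrix()] object.
#' @export
simulate_signals <- function(x, config, kind = c("individual", "pool")) {
  stopifnot(inherits(config, "sim_config"), is.matrix(x))
  kind <- match.arg(kind)
  if (config$signal_cv < 0) fail_field("signal_cv", "must be >= 0")
  if (ncol(x) > config$n_snps)
    stop("more SNP columns than the configured panel size", call. = FALSE)
  if (kind == "individual") {
    if (!all(x[!is.na(x)] %in% c(0, 1, 2)))
      stop("individual dosages must be 0, 1 or 2", call. = FALSE)
    fx <- x / 2
  } else {
    if (any(x[!is.na(x)] < 0 | x[!is.na(x)] > 1))
      stop("pool allele frequencies must be in [0, 1]", call. = FALSE)
    fx <- x
  }
  k <- true_dye_bias(config)[seq_len(ncol(x))]
  names(k) <- colnames(x)
  ex <- config$signal_scale * fx
  ey <- sweep(config$signal_scale * (1 - fx), 2L, k, `/`)
  if (config$signal_cv > 0) {
    s <- sqrt(log(1 + config$signal_cv^2))
    noise <- function(e, tag) with_stage_seed(
      derive_seed(config$seed, paste0("signals_", kind, "_", tag)), {
        n <- matrix(stats::rlnorm(length(e), -s^2 / 2, s), nrow(e), ncol(e))
        e * n
      })
    ex <- noise(ex, "x")
    ey <- noise(ey, "y")
  }
  dimnames(ex) <- dimnames(ey) <- dimnames(x)
  signal_matrix(ex, ey, kind = kind)
}

#' Simulate the colony individual-association experiment
#'
#' Draws unrelated individuals from the configured population model,
#' assigns survival at a discriminating insecticide dose from the same
#' liability model as the family bioassays (without family effects or
#' humidity variation), and returns phenotype-classified susceptible
#' (died) and resistant (survived) groups of the configured sizes.
#'
#' @param config a [sim_config()] object.
#' @return a list with `genotypes` (dosage matrix, one row per individual),
#'   `phenotype` (factor with levels `sus`, `res`), `karyotype`, and
#'   `snps` (the panel annotation).
#' @export
simulate_colony <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$colony_n_susceptible <= 0 || config$colony_n_resistant <= 0)
    fail_field("colony_n_susceptible", "group sizes must be positive")
  with_stage_seed(derive_seed(config$seed, "colony"), {
    snps <- build_panel(config)
    S <- nrow(snps)
    need_s <- config$colony_n_susceptible
    need_r <- config$colony_n_resistant
    f_inv <- config$inversion_karyotype_freq
    causal <- which(snps$beta != 0)
    got_s <- got_r <- NULL
    kar_s <- kar_r <- integer(0)
    tries <- 0L
    while ((is.null(got_s) || nrow(got_s) < need_s ||
            nrow(got_r) < need_r) && tries < 200L) {
      tries <- tries + 1L
      m <- 128L
      arr <- matrix(stats::runif(m * 2) < f_inv, m, 2)
      hap <- function(a_col) {
        p <- matrix(snps$p_std, m, S, byrow = TRUE)
        dcol <- which(snps$differentiated)
        if (length(dcol) && any(a_col))
          p[a_col, dcol] <- matrix(snps$p_inv[dcol], sum(a_col),
                                   length(dcol), byrow = TRUE)
        matrix(as.integer(stats::runif(m * S) < p), m, S)
      }
      g <- hap(arr[, 1L]) + hap(arr[, 2L])
      colnames(g) <- snps$snp_id
      kar <- as.integer(rowSums(arr))
      eta <- config$baseline_logit +
        config$karyotype_beta * (kar - 2 * f_inv)
      if (length(causal))
        eta <- eta + drop(sweep(g[, causal, drop = FALSE], 2L,
                                2 * snps$true_freq[causal], `-`) %*%
                            snps$beta[causal])
      dead <- stats::rbinom(m, 1L, stats::plogis(eta)) == 1L
      got_s <- rbind(got_s, g[dead, , drop = FALSE])
      got_r <- rbind(got_r, g[!dead, , drop = FALSE])
      kar_s <- c(kar_s, kar[dead])
      kar_r <- c(kar_r, kar[!dead])
    }
    if (nrow(got_s) < need_s || nrow(got_r) < need_r)
      stop("could not fill colony phenotype groups; check the mortality model",
           call. = FALSE)
    g <- rbind(got_s[seq_len(need_s), , drop = FALSE],
               got_r[seq_len(need_r), , drop = FALSE])
    rownames(g) <- sprintf("col%03d", seq_len(nrow(g)))
    list(genotypes = g,
         phenotype = factor(rep(c("sus", "res"), c(need_s, need_r)),
                            levels = c("sus", "res")),
         karyotype = c(kar_s[seq_len(need_s)], kar_r[seq_len(need_r)]),
         snps = snps)
  })
}

#' Simulate a complete family-pool study
#'
#' Convenience wrapper running [simulate_population()],
#' [simulate_bioassay()] and [simulate_signals()] and assembling every
#' table the analysis pipeline consumes: individual calibration signals
#' and genotypes (mothers plus extra females), family-pool signals, the
#' family phenotype table, and SNP annotation.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `config`, `population`, `phenotype`,
#'   `annotation`, `family_freq` (true family allele-frequency matrix),
#'   `pool_signals`, `ind_genotypes`, `ind_signals`.
#' @examples
#' cfg <- sim_config(n_families = 10, n_snps = 60, n_control_snps = 15,
#'                   n_control_inside = 5, n_extra_females = 10, seed = 3)
#' study <- simulate_study(cfg)
#' names(study)
#' @export
simulate_study <- function(config) {
  pop <- simulate_population(config)
  phen <- simulate_bioassay(pop, config)
  fam <- factor(pop$offspring$family, levels = pop$families$family_id)
  famfreq <- rowsum(pop$offspring$genotypes, fam) /
    (2 * pop$families$n_offspring)
  rownames(famfreq) <- pop$families$family_id
  ind_geno <- rbind(pop$mothers$genotypes,
                    if (!is.null(pop$extra_females))
                      pop$extra_females$genotypes)
  list(
    config = config,
    population = pop,
    phenotype = phen,
    annotation = pop$snps[, c("snp_id", "chrom", "pos", "class", "gene",
                              "inversion")],
    family_freq = famfreq,
    pool_signals = simulate_signals(famfreq, config, kind = "pool"),
    ind_genotypes = ind_geno,
    ind_signals = simulate_signals(ind_geno, config, kind = "individual")
  )
}
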