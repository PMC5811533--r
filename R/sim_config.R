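#' Simulation configuration for the isofemale family-pool study design
#'
#' Builds and validates the parameter set that drives the forward simulator.
#' Defaults emulate the discovery-stage design of a candidate-gene
#' insecticide-resistance study in *Anopheles gambiae*: 98 isofemale
#' families of 10--20 female offspring (median 15) assayed for permethrin
#' mortality, a 1536-SNP candidate-enriched panel with 195 control SNPs (32
#' inside and 163 outside a large polymorphic inversion on chromosome 2L
#' with breakpoints near 22 and 42 Mb), a target-site resistance allele near
#' fixation (0.94), metabolic-gene SNPs at intermediate frequency with
#' liability-scale effects on bioassay death, an inverse humidity effect on
#' mortality, and per-SNP dye bias in the two-channel array signals.
#'
#' Mortality follows a logit-binomial liability model: each exposed
#' offspring dies with probability
#' `plogis(baseline_logit + humidity_beta * (H - mid(humidity_range)) +
#' sum(beta_g * (dosage_g - 2 p_g)) + karyotype_beta * (karyotype - 2 f_inv)
#' + family_effect)` where the family effect is Gaussian with standard
#' deviation `family_sd`. Humidity and dosages are centred so that
#' `baseline_logit` is the population-average logit of death.
#'
#' @param n_families number of isofemale families (pools).
#' @param offspring_range integer interval `c(low, high)` of female
#'   offspring per family; counts are drawn uniformly.
#' @param n_extra_females additional individually genotyped wild females
#'   (not founding a family) available for dye-bias calibration.
#' @param n_snps total SNPs on the panel.
#' @param n_control_snps number of control (non-candidate) SNPs.
#' @param n_control_inside number of control SNPs placed inside the
#'   inversion span.
#' @param inversion_chrom chromosome arm carrying the inversion.
#' @param inversion_span 1-based inclusive bp interval of the inversion.
#' @param inversion_karyotype_freq population frequency of the inverted
#'   arrangement.
#' @param inversion_fst Balding-Nichols differentiation parameter between
#'   the inverted and standard arrangements for non-causal SNPs inside the
#'   span (0 = no arrangement structure).
#' @param karyotype_beta effect of one copy of the inverted arrangement on
#'   the log-odds of death.
#' @param founder_maf_distribution list describing the neutral founder
#'   minor-allele-frequency distribution; currently
#'   `list(dist = "uniform", min, max)`.
#' @param target_site_freq resistance-allele frequency of the near-fixed
#'   target-site SNP.
#' @param target_site_beta its effect on the log-odds of death (negative =
#'   protective resistance allele).
#' @param causal_effects data.frame with columns `snp_id`, `freq`, `beta`
#'   for additional (metabolic-gene) causal SNPs; `beta` is on the log-odds
#'   of death per allele copy.
#' @param humidity_beta effect of relative humidity (percent, centred at the
#'   midpoint of `humidity_range`) on the log-odds of death.
#' @param humidity_range percent relative-humidity interval across assay days.
#' @param temperature_range degrees-Celsius interval across assay days
#'   (covariate only; no effect on mortality by default).
#' @param n_assay_days number of bioassay days; families are assigned to
#'   days round-robin and share that day's humidity and temperature.
#' @param baseline_logit intercept of the death-probability model.
#' @param family_sd standard deviation of the Gaussian family random effect
#'   on the logit scale.
#' @param dyebias_distribution list describing the per-SNP dye-bias factor k
#'   distribution; currently `list(dist = "loguniform", min, max)`.
#' @param signal_cv coefficient of variation of the multiplicative
#'   two-channel signal noise.
#' @param signal_scale expected total signal of a fully X-allele cell
#'   (arbitrary fluorescence units).
#' @param colony_n_susceptible,colony_n_resistant group sizes for the
#'   colony-based individual association experiment.
#' @param seed integer root seed; all stages derive their own streams from
#'   it (see [derive_seed()]).
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_population()], [simulate_study()]
#' @examples
#' cfg <- sim_config(n_families = 12, n_snps = 40, n_control_snps = 10,
#'                   n_control_inside = 4, seed = 7)
#' cfg$n_families
#' @export
sim_config <- function(n_families = 98L,
                       offspring_range = c(10L, 20L),
                       n_extra_females = 118L,
                       n_snps = 1536L,
                       n_control_snps = 195L,
                       n_control_inside = 32L,
                       inversion_chrom = "2L",
                       inversion_span = c(22000000, 42000000),
                       inversion_karyotype_freq = 0.5,
                       inversion_fst = 0.3,
                       karyotype_beta = 0.5,
                       founder_maf_distribution = list(dist = "uniform",
                                                       min = 0.05, max = 0.5),
                       target_site_freq = 0.94,
                       target_site_beta = -1.2,
                       causal_effects = default_causal_effects(),
                       humidity_beta = -0.05,
                       humidity_range = c(55, 90),
                       temperature_range = c(24, 28),
                       n_assay_days = 14L,
                       baseline_logit = 0.7,
                       family_sd = 0.8,
                       dyebias_distribution = list(dist = "loguniform",
                                                   min = 1 / 3, max = 3),
                       signal_cv = 0.01,
                       signal_scale = 1000,
                       colony_n_susceptible = 20L,
                       colony_n_resistant = 36L,
                       seed = 1L) {
  cfg <- list(
    n_families = check_count(n_families, "n_families"),
    offspring_range = offspring_range,
    n_extra_females = check_count(n_extra_females, "n_extra_females", min = 0L),
    n_snps = check_count(n_snps, "n_snps"),
    n_control_snps = check_count(n_control_snps, "n_control_snps"),
    n_control_inside = check_count(n_control_inside, "n_control_inside", min = 0L),
    inversion_chrom = inversion_chrom,
    inversion_span = as.numeric(inversion_span),
    inversion_karyotype_freq = check_prob(inversion_karyotype_freq,
                                          "inversion_karyotype_freq"),
    inversion_fst = check_prob(inversion_fst, "inversion_fst"),
    karyotype_beta = karyotype_beta,
    founder_maf_distribution = founder_maf_distribution,
    target_site_freq = check_prob(target_site_freq, "target_site_freq"),
    target_site_beta = target_site_beta,
    causal_effects = causal_effects,
    humidity_beta = humidity_beta,
    humidity_range = as.numeric(humidity_range),
    temperature_range = as.numeric(temperature_range),
    n_assay_days = check_count(n_assay_days, "n_assay_days"),
    baseline_logit = baseline_logit,
    family_sd = family_sd,
    dyebias_distribution = dyebias_distribution,
    signal_cv = signal_cv,
    signal_scale = signal_scale,
    colony_n_susceptible = check_count(colony_n_susceptible, "colony_n_susceptible"),
    colony_n_resistant = check_count(colony_n_resistant, "colony_n_resistant"),
    seed = check_count(seed, "seed", min = 0L)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

#' Default causal (metabolic-gene) SNP effects
#'
#' Three detoxification-gene markers at intermediate minor-allele frequency
#' with protective (negative) liability-scale effects, placed at their
#' published 2L coordinates. The strongest effect corresponds roughly to a
#' family-level frequency-mortality correlation at the study's analytic
#' detection limit.
#'
#' @return data.frame with columns `snp_id`, `freq`, `beta`.
#' @export
default_causal_effects <- function() {
  data.frame(
    snp_id = c("Cyp4j5", "Cyp4j10", "Coeae1d"),
    freq = c(0.37, 0.45, 0.49),
    beta = c(-1.2, -0.6, -0.8),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  orng <- cfg$offspring_range
  if (length(orng) != 2L || any(orng < 1) || orng[1L] > orng[2L])
    fail_field("offspring_range", "must be c(low, high) with 1 <= low <= high")
  cfg$offspring_range <- as.integer(orng)
  if (cfg$n_control_snps > cfg$n_snps)
    fail_field("n_control_snps", "cannot exceed n_snps")
  if (cfg$n_control_inside > cfg$n_control_snps)
    fail_field("n_control_inside", "cannot exceed n_control_snps")
  sp <- cfg$inversion_span
  if (length(sp) != 2L || sp[1L] >= sp[2L] || any(sp <= 0))
    fail_field("inversion_span", "must be c(low, high) with 0 < low < high")
  fm <- cfg$founder_maf_distribution
  if (!identical(fm$dist, "uniform") || fm$min <= 0 || fm$max > 0.5 ||
      fm$min > fm$max)
    fail_field("founder_maf_distribution",
               "must be list(dist = 'uniform', min, max) with 0 < min <= max <= 0.5")
  db <- cfg$dyebias_distribution
  if (!identical(db$dist, "loguniform") || db$min <= 0 || db$min > db$max)
    fail_field("dyebias_distribution",
               "must be list(dist = 'loguniform', min, max) with 0 < min <= max")
  if (!is.numeric(cfg$signal_cv) || cfg$signal_cv < 0)
    fail_field("signal_cv", "must be >= 0")
  if (cfg$humidity_range[1L] > cfg$humidity_range[2L])
    fail_field("humidity_range", "low must be <= high")
  ce <- cfg$causal_effects
  if (!is.data.frame(ce) || !all(c("snp_id", "freq", "beta") %in% names(ce)))
    fail_field("causal_effects",
               "must be a data.frame with columns snp_id, freq, beta")
  if (nrow(ce) && (any(ce$freq < 0) || any(ce$freq > 1)))
    fail_field("causal_effects", "freq values must be in [0, 1]")
  if (anyDuplicated(ce$snp_id)) fail_field("causal_effects", "duplicated snp_id")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Family-pool study simulation config\n")
  cat(sprintf("  families: %d (offspring %d-%d), extra females: %d\n",
              x$n_families, x$offspring_range[1L], x$offspring_range[2L],
              x$n_extra_females))
  cat(sprintf("  panel: %d SNPs (%d control, %d control inside inversion)\n",
              x$n_snps, x$n_control_snps, x$n_control_inside))
  cat(sprintf("  inversion: %s:%s-%s, karyotype freq %.2f, Fst %.2f, beta %.2f\n",
              x$inversion_chrom, format(x$inversion_span[1L], scientific = FALSE),
              format(x$inversion_span[2L], scientific = FALSE),
              x$inversion_karyotype_freq, x$inversion_fst, x$karyotype_beta))
  cat(sprintf("  causal SNPs: target site (p=%.2f, beta=%.2f) + %d metabolic\n",
              x$target_site_freq, x$target_site_beta, nrow(x$causal_effects)))
  cat(sprintf("  humidity beta %.3f over %.0f-%.0f%%RH; family sd %.2f\n",
              x$humidity_beta, x$humidity_range[1L], x$humidity_range[2L],
              x$family_sd))
  cat(sprintf("  signals: cv %.3f, dye bias %s[%.3g, %.3g]; seed %d\n",
              x$signal_cv, x$dyebias_distribution$dist,
              x$dyebias_distribution$min, x$dyebias_distribution$max, x$seed))
  invisible(x)
}

#' Read a simulation config from a YAML file
#'
#' Flat key-value YAML; keys are the arguments of [sim_config()]. Unknown
#' keys are an error. `causal_effects` may be given as a list of
#' `{snp_id, freq, beta}` mappings.
#'
#' @param path path to a YAML file.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(vals$causal_effects) && !is.data.frame(vals$causal_effects))
    vals$causal_effects <- do.call(rbind, lapply(vals$causal_effects,
                                                 as.data.frame))
  do.call(sim_config, vals)
}
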