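# Shared fixtures: a small study config for fast unit tests, a cached
# default-scale study for the heavier scenario checks, and a hand
# constructor for dye-bias tables.

small_config <- function(seed = 1, ...) {
  defaults <- list(n_families = 12L, offspring_range = c(8L, 12L),
                   n_extra_females = 10L, n_snps = 60L,
                   n_control_snps = 15L, n_control_inside = 5L,
                   n_assay_days = 4L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# default-scale study, simulated once per test run and reused
.study_cache <- new.env(parent = emptyenv())

default_study <- function(seed = 1, ...) {
  key <- paste(seed, ..., sep = "|")
  if (is.null(.study_cache[[key]])) {
    cfg <- sim_config(seed = seed, ...)
    study <- simulate_study(cfg)
    bias <- qc_filter_snps(
      estimate_dye_bias(study$ind_signals, study$ind_genotypes),
      quiet = TRUE)
    study$bias <- bias
    study$pooled <- pooled_allele_frequency(study$pool_signals, bias)
    .study_cache[[key]] <- study
  }
  .study_cache[[key]]
}

make_bias_table <- function(snp_id, k, sd_k = 0, n_het = 10L,
                            qc_reason = "ok") {
  structure(data.frame(
    snp_id = snp_id,
    k = rep_len(k, length(snp_id)),
    sd_k = rep_len(sd_k, length(snp_id)),
    n_het = as.integer(rep_len(n_het, length(snp_id))),
    n_dropped = rep(0L, length(snp_id)),
    qc_pass = rep_len(qc_reason, length(snp_id)) == "ok",
    qc_reason = rep_len(qc_reason, length(snp_id)),
    stringsAsFactors = FALSE
  ), class = c("dye_bias_table", "data.frame"))
}

# named 2-channel matrices for a single SNP from per-sample (x, y) pairs
single_snp_signals <- function(x, y, snp = "snp1") {
  ids <- sprintf("s%02d", seq_along(x))
  signal_matrix(matrix(x, ncol = 1, dimnames = list(ids, snp)),
                matrix(y, ncol = 1, dimnames = list(ids, snp)))
}
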