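# Internal helpers: seeding, validation, genomic regions.

#' Derive a stage-specific seed from a root seed
#'
#' Each stochastic stage of the simulator draws from its own stream so that
#' stages are independently reproducible: the stage seed is a deterministic
#' hash of the root seed and the stage name, kept below 2^31.
#'
#' @param seed integer root seed.
#' @param stage character stage label (e.g. `"population"`, `"signals_pool"`).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) %% 599479) * 3571 + h)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_stage_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stop() with a field name, used by config/input validators
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    fail_field(field, "must be a single value in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    fail_field(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

#' Parse a genomic region string
#'
#' Regions are written `CHROM:START-END` with 1-based inclusive coordinates
#' (e.g. `"2L:22000000-42000000"`).
#'
#' @param region region string, or a list already of the parsed form.
#' @return a list with elements `chrom`, `start`, `end`.
#' @examples
#' parse_region("2L:22000000-42000000")
#' @export
parse_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    region$start <- as.numeric(region$start)
    region$end <- as.numeric(region$end)
    return(region[c("chrom", "start", "end")])
  }
  if (!is.character(region) || length(region) != 1L ||
      !grepl("^[^:]+:[0-9]+-[0-9]+$", region))
    fail_field("region", "must be of the form CHROM:START-END")
  chrom <- sub(":.*$", "", region)
  nums <- strsplit(sub("^[^:]+:", "", region), "-", fixed = TRUE)[[1L]]
  start <- as.numeric(nums[1L]); end <- as.numeric(nums[2L])
  if (start > end) fail_field("region", "START must be <= END")
  list(chrom = chrom, start = start, end = end)
}

# column standard deviation ignoring NA, n-1 denominator
col_sds <- function(m) {
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  ss <- colSums(sweep(m, 2L, mu, `-`)^2, na.rm = TRUE)
  out <- sqrt(ss / pmax(n - 1L, 1L))
  out[n < 2L] <- NA_real_
  out
}
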