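# Readers and writers for the pipeline's tab-separated table formats.
#
# Dialect: UTF-8, tab-delimited, header row, '.' for missing values,
# floats written with 15 significant digits so tables round-trip through
# read_table(write_table(x)) without loss.

#' Table schemas used by the pipeline
#'
#' Named column-type specifications for every TSV the pipeline reads or
#' writes. Types: `character`, `double`, `prob` (double in \[0,1\]),
#' `integer`, `count` (integer >= 0), `dosage` (0/1/2), `flag`
#' (TRUE/FALSE).
#'
#' @format a named list; each element is a list of `columns` (named
#'   character vector of types) and `key` (columns whose combination must
#'   be unique).
#' @export
table_schemas <- function() list(
  signals = list(columns = c(sample_id = "character", snp_id = "character",
                             x_raw = "double", y_raw = "double"),
                 key = c("sample_id", "snp_id")),
  dye_bias = list(columns = c(snp_id = "character", k = "double",
                              sd_k = "double", n_het = "count",
                              qc_pass = "flag", qc_reason = "character"),
                  key = "snp_id"),
  frequencies = list(columns = c(family_id = "character",
                                 snp_id = "character", p_x = "prob"),
                     key = c("family_id", "snp_id")),
  annotation = list(columns = c(snp_id = "character", chrom = "character",
                                pos = "count", class = "character",
                                gene = "character"),
                    key = "snp_id"),
  phenotype = list(columns = c(family_id = "character", n_exposed = "count",
                               n_dead = "count", mortality = "prob",
                               humidity = "double", temperature = "double",
                               sex = "character"),
                   key = "family_id"),
  genotypes = list(columns = c(sample_id = "character", snp_id = "character",
                               dosage = "dosage"),
                   key = c("sample_id", "snp_id")),
  replication = list(columns = c(sample_id = "character",
                                 population = "character",
                                 phenotype = "character",
                                 snp_id = "character", genotype = "dosage"),
                     key = c("sample_id", "snp_id")),
  association = list(columns = c(snp_id = "character", chrom = "character",
                                 pos = "count", model = "character",
                                 n = "count", r = "double", t = "double",
                                 p = "double", neglog10p = "double"),
                     key = c("snp_id", "model"))
)

resolve_schema <- function(schema) {
  if (is.character(schema)) {
    reg <- table_schemas()
    if (!schema %in% names(reg))
      stop("unknown schema '", schema, "'; known: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    reg[[schema]]
  } else {
    stopifnot(is.list(schema), !is.null(schema$columns))
    schema
  }
}

parse_column <- function(vals, type, col, path) {
  miss <- vals == "."
  bad_at <- function(rows, what) {
    stop(sprintf("%s: column '%s', line %d: %s", path, col,
                 rows[1L] + 1L, what), call. = FALSE)  # +1 for header
  }
  out <- switch(type,
    character = ifelse(miss, NA_character_, vals),
    flag = {
      v <- toupper(vals)
      bad <- !miss & !v %in% c("TRUE", "FALSE")
      if (any(bad)) bad_at(which(bad), "expected TRUE or FALSE")
      ifelse(miss, NA, v == "TRUE")
    },
    {
      suppressWarnings(num <- as.numeric(vals))
      bad <- !miss & is.na(num)
      if (any(bad)) bad_at(which(bad), sprintf("unparseable value '%s'",
                                               vals[which(bad)[1L]]))
      num[miss] <- NA
      if (type %in% c("integer", "count", "dosage")) {
        bad <- !is.na(num) & num != round(num)
        if (any(bad)) bad_at(which(bad), "expected an integer")
        if (type == "count" && any(!is.na(num) & num < 0))
          bad_at(which(!is.na(num) & num < 0), "expected a count >= 0")
        if (type == "dosage" && any(!is.na(num) & !num %in% c(0, 1, 2)))
          bad_at(which(!is.na(num) & !num %in% c(0, 1, 2)),
                 "dosage must be one of {0, 1, 2}")
        num <- as.integer(num)
      }
      if (type == "prob" && any(!is.na(num) & (num < 0 | num > 1)))
        bad_at(which(!is.na(num) & (num < 0 | num > 1)),
               "expected a value in [0, 1]")
      num
    })
  out
}

#' Read a typed, validated TSV table
#'
#' Header columns may appear in any order but must include every schema
#' column; cells are validated against the column type and the first
#' violation is reported with its line and column. `'.'` denotes missing.
#'
#' @param path file path.
#' @param schema a schema name (see [table_schemas()]) or a schema list.
#' @return a `data.frame` with columns in schema order.
#' @export
read_table <- function(path, schema) {
  sch <- resolve_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           quote = "", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(sch$columns), names(raw))
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in names(sch$columns))
    out[[col]] <- parse_column(raw[[col]], sch$columns[[col]], col, path)
  if (!is.null(sch$key) && nrow(out)) {
    keyv <- do.call(paste, c(out[sch$key], sep = "\r"))
    if (anyDuplicated(keyv))
      stop(sprintf("%s: duplicate key (%s) at line %d", path,
                   paste(sch$key, collapse = ", "),
                   which(duplicated(keyv))[1L] + 1L), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

format_cell <- function(x) {
  if (is.double(x)) {
    out <- vapply(x, function(v)
      if (is.na(v)) "." else sprintf("%.15g", v), character(1L))
  } else if (is.logical(x)) {
    out <- ifelse(is.na(x), ".", ifelse(x, "TRUE", "FALSE"))
  } else {
    out <- as.character(x)
    out[is.na(out)] <- "."
  }
  out
}

#' Write a table in the pipeline's TSV dialect
#'
#' Deterministic column order (schema order when a schema is given),
#' floats with 15 significant digits, missing values as `'.'` (never
#' `NA`/`NaN`). `read_table(write_table(x))` reproduces the values.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param schema optional schema name or list fixing the column order.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, schema = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(schema)) {
    sch <- resolve_schema(schema)
    missing_cols <- setdiff(names(sch$columns), names(table))
    if (length(missing_cols))
      stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    table <- table[names(sch$columns)]
  }
  cells <- vapply(table, format_cell, character(nrow(table)))
  if (nrow(table) == 1L) cells <- matrix(cells, nrow = 1L)
  if (nrow(table) == 0L)
    cells <- matrix(character(0), 0L, ncol(table))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(table), collapse = "\t"), con)
  if (nrow(table))
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Convert a signal matrix to/from the long signal table
#'
#' @param signals a [signal_matrix()].
#' @return `signals_to_table()`: a data.frame in the `signals` schema.
#' @export
signals_to_table <- function(signals) {
  stopifnot(inherits(signals, "signal_matrix"))
  data.frame(
    sample_id = rep(rownames(signals$x), times = ncol(signals$x)),
    snp_id = rep(colnames(signals$x), each = nrow(signals$x)),
    x_raw = as.vector(signals$x),
    y_raw = as.vector(signals$y),
    stringsAsFactors = FALSE
  )
}

#' @rdname signals_to_table
#' @param table a data.frame in the `signals` schema.
#' @param kind `"individual"` or `"pool"`.
#' @return `table_to_signals()`: a [signal_matrix()].
#' @export
table_to_signals <- function(table, kind = c("individual", "pool")) {
  kind <- match.arg(kind)
  samples <- unique(table$sample_id)
  snps <- unique(table$snp_id)
  x <- y <- matrix(NA_real_, length(samples), length(snps),
                   dimnames = list(samples, snps))
  i <- cbind(match(table$sample_id, samples), match(table$snp_id, snps))
  x[i] <- table$x_raw
  y[i] <- table$y_raw
  signal_matrix(x, y, kind = kind)
}

#' Convert a frequency matrix to/from the long frequency table
#'
#' @param freqs families-by-SNP matrix.
#' @return `freqs_to_table()`: a data.frame in the `frequencies` schema.
#' @export
freqs_to_table <- function(freqs) {
  data.frame(
    family_id = rep(rownames(freqs), times = ncol(freqs)),
    snp_id = rep(colnames(freqs), each = nrow(freqs)),
    p_x = as.vector(freqs),
    stringsAsFactors = FALSE
  )
}

#' @rdname freqs_to_table
#' @param table a data.frame in the `frequencies` schema.
#' @return `table_to_freqs()`: a families-by-SNP matrix.
#' @export
table_to_freqs <- function(table) {
  fams <- unique(table$family_id)
  snps <- unique(table$snp_id)
  m <- matrix(NA_real_, length(fams), length(snps),
              dimnames = list(fams, snps))
  m[cbind(match(table$family_id, fams), match(table$snp_id, snps))] <-
    table$p_x
  m
}

#' Convert a genotype matrix to/from the long genotype table
#'
#' @param genotypes samples-by-SNP dosage matrix.
#' @return `genotypes_to_table()`: a data.frame in the `genotypes` schema.
#' @export
genotypes_to_table <- function(genotypes) {
  data.frame(
    sample_id = rep(rownames(genotypes), times = ncol(genotypes)),
    snp_id = rep(colnames(genotypes), each = nrow(genotypes)),
    dosage = as.integer(genotypes),
    stringsAsFactors = FALSE
  )
}

#' @rdname genotypes_to_table
#' @param table a data.frame in the `genotypes` schema.
#' @return `table_to_genotypes()`: a samples-by-SNP integer matrix.
#' @export
table_to_genotypes <- function(table) {
  samples <- unique(table$sample_id)
  snps <- unique(table$snp_id)
  m <- matrix(NA_integer_, length(samples), length(snps),
              dimnames = list(samples, snps))
  m[cbind(match(table$sample_id, samples), match(table$snp_id, snps))] <-
    table$dosage
  m
}

#' Read ALT-allele dosages from a VCF
#'
#' Biallelic records only: the GT field is converted to the dosage of the
#' ALT allele. Multi-allelic records and half-calls are skipped/set
#' missing, with counts reported in attributes `n_multiallelic` and
#' `n_halfcalls`.
#'
#' @param path path to a VCF file.
#' @return samples-by-SNP integer dosage matrix; SNPs named by the VCF ID
#'   (or `CHROM_POS` when ID is `.`).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCFs requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = "_"),
                fix[, "ID"])
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(clean), ncol(clean))
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  half <- !is.na(clean) & grepl("\\.", clean) & clean != "./."
  n_half <- sum(half)
  out <- t(dosage)
  dimnames(out) <- list(colnames(gt), ids)
  attr(out, "n_multiallelic") <- n_multi
  attr(out, "n_halfcalls") <- n_half
  out
}
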