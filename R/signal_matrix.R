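#' Two-channel signal matrix
#'
#' Container for raw two-channel genotyping intensities: an X (cy3) and a
#' Y (cy5) matrix of identical shape, rows being samples (individuals) or
#' family pools and columns SNPs. Missing cells carry `NA` in both
#' channels; a scored cell never has both channels zero.
#'
#' @param x,y non-negative numeric matrices with matching dimnames.
#' @param kind `"individual"` or `"pool"`.
#' @return an object of class `signal_matrix` (a list with `x`, `y`,
#'   `kind`).
#' @examples
#' sm <- signal_matrix(matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
#'                     matrix(4:1, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
#'                     kind = "individual")
#' dim(sm)
#' @export
signal_matrix <- function(x, y, kind = c("individual", "pool")) {
  kind <- match.arg(kind)
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- storage.mode(y) <- "double"
  if (!identical(dim(x), dim(y)))
    stop("x and y must have identical dimensions", call. = FALSE)
  if (!identical(dimnames(x), dimnames(y)))
    stop("x and y must have identical dimnames", call. = FALSE)
  na_mismatch <- xor(is.na(x), is.na(y))
  if (any(na_mismatch))
    stop("missing cells must be NA in both channels", call. = FALSE)
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE))
    stop("signals must be non-negative", call. = FALSE)
  structure(list(x = x, y = y, kind = kind), class = "signal_matrix")
}

#' @export
dim.signal_matrix <- function(x) dim(x$x)

#' @export
dimnames.signal_matrix <- function(x) dimnames(x$x)

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix (%s): %d samples x %d SNPs, %d missing cells\n",
              x$kind, nrow(x$x), ncol(x$x), sum(is.na(x$x))))
  invisible(x)
}

# subset a signal matrix by column (SNP) indices or names
subset_snps <- function(sm, j) {
  signal_matrix(sm$x[, j, drop = FALSE], sm$y[, j, drop = FALSE],
                kind = sm$kind)
}
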