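#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero, as printed tables do
#'
#' `base::round()` rounds half to even; published tables round half up.
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' QTL interval size in megabases
#'
#' Size of a 1-based inclusive interval as printed in QTL summary tables:
#' `(end - start) / 1e6`, rounded to 3 decimals.
#' @param start,end interval bounds in bp (1-based, inclusive)
#' @return numeric vector of sizes in Mb
#' @export
qtl_size_mb <- function(start, end) {
  if (any(end < start)) stopf("end < start in qtl_size_mb")
  round_half_up((end - start) / 1e6, 3)
}

#' Alternate-allele percentage from carrier counts
#'
#' `100 * n_alt / (n_common + n_alt)` rounded to 2 decimals, the
#' "% panel having alternate allele" column of QTL summary tables.
#' @param n_common,n_alt accession counts carrying each homozygous allele
#' @return numeric vector of percentages
#' @export
pct_alt <- function(n_common, n_alt) {
  tot <- n_common + n_alt
  if (any(tot <= 0)) stopf("no scored accessions in pct_alt")
  round_half_up(100 * n_alt / tot, 2)
}

# Derive a stream seed below 2^31 from a base seed and a stream index.
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 2017 + 13 * as.numeric(k)) %% 2147480000L
}
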