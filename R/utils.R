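# Shared small helpers: DNA string ops and rounding conventions.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Operates on plain character strings over the alphabet `{A,C,G,T,N}`.
#' Vectorised over `x`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")  # "NACGT"
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Complement DNA bases
#'
#' @param x character vector of single bases (or strings; every base is
#'   complemented in place, without reversal).
#' @return complemented character vector.
#' @export
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Round half-up
#'
#' Base R's `round()` rounds half to even; the summary tables in this
#' package use commercial half-up rounding at a fixed number of decimals
#' (e.g. 175202/180950 -> 96.82).  A tiny epsilon guards against
#' representation error at exact halves.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage with half-up rounding
#'
#' @param count numerator(s).
#' @param total denominator.
#' @param digits decimal places (default 2).
#' @return numeric percentages; `NA` when `total` is 0.
#' @export
pct_of <- function(count, total, digits = 2) {
  if (length(total) == 1 && (is.na(total) || total == 0)) {
    return(rep(NA_real_, length(count)))
  }
  round_half_up(100 * count / total, digits)
}

# split one string into a character vector of single bases
str_bases <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# deterministic per-stage seed derived from a root seed; keeps values
# well inside 32-bit integer range
stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 1000003L) * 1009L + as.integer(stage)
}
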