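# Minor-allele-frequency statistics: per-marker MAF, spectrum binning
# into the eight array-summary bins, and cross-collection rare-allele
# comparison.

MAF_BIN_LABELS <- c("Monomorphic", "<0.01", "0.01~0.05", "0.05~0.10",
                    "0.10~0.20", "0.20~0.30", "0.30~0.40", "0.40>")

#' The MAF bin definition table
#'
#' `Monomorphic` holds MAF exactly 0; `<0.01` is the open interval
#' (0, 0.01); the middle bins are half-open `[lower, upper)`; the
#' `0.30~0.40` bin includes its upper bound, so the final `0.40>` bin is
#' `(0.40, 0.50]`.
#'
#' @return data.frame with columns `label`, `lower`, `upper`.
#' @export
maf_bins <- function() {
  data.frame(
    label = MAF_BIN_LABELS,
    lower = c(0, 0, 0.01, 0.05, 0.10, 0.20, 0.30, 0.40),
    upper = c(0, 0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50),
    stringsAsFactors = FALSE)
}

#' Per-marker minor allele frequency
#'
#' Heterozygotes contribute one alternate allele; missing calls are
#' excluded from the denominator.  `MAF = min(f, 1 - f)` with
#' `f = alt alleles / (2 x called samples)`.
#'
#' @param calls integer vector of one marker's codes (`0/1/2/-1`), or a
#'   `GenotypeMatrix` / matrix for the vectorised form (one MAF per
#'   row).
#' @return numeric MAF(s) in `[0, 0.5]`; `NA` for an all-missing row.
#' @export
compute_maf <- function(calls) {
  if (inherits(calls, "GenotypeMatrix")) calls <- calls$calls
  if (is.matrix(calls)) {
    called <- calls >= 0L
    alt <- rowSums(calls * called)
    tot <- 2 * rowSums(called)
    f <- ifelse(tot > 0, alt / tot, NA_real_)
    return(unname(pmin(f, 1 - f)))
  }
  called <- calls >= 0L
  tot <- 2 * sum(called)
  if (tot == 0) return(NA_real_)
  f <- sum(calls[called]) / tot
  min(f, 1 - f)
}

#' Assign MAF values to spectrum bins
#'
#' @param maf numeric vector in `[0, 0.5]` (`NA` allowed).
#' @return factor with levels in spectrum order (see [maf_bins()]).
#' @export
bin_maf <- function(maf) {
  lab <- rep(NA_character_, length(maf))
  ok <- !is.na(maf)
  if (any(maf[ok] < 0 | maf[ok] > 0.5)) stop("MAF must lie in [0, 0.5]")
  m <- maf
  lab[ok & m == 0] <- "Monomorphic"
  lab[ok & m > 0 & m < 0.01] <- "<0.01"
  lab[ok & m >= 0.01 & m < 0.05] <- "0.01~0.05"
  lab[ok & m >= 0.05 & m < 0.10] <- "0.05~0.10"
  lab[ok & m >= 0.10 & m < 0.20] <- "0.10~0.20"
  lab[ok & m >= 0.20 & m < 0.30] <- "0.20~0.30"
  lab[ok & m >= 0.30 & m <= 0.40] <- "0.30~0.40"
  lab[ok & m > 0.40] <- "0.40>"
  factor(lab, levels = MAF_BIN_LABELS)
}

#' MAF spectrum table over lifted markers
#'
#' Counts markers per MAF bin, restricted to `lifted_ids`, with
#' percentages of the lifted total (half-up, 2 decimals).
#'
#' @param gm a `GenotypeMatrix`.
#' @param lifted_ids marker ids to include (must be a subset of the
#'   matrix's markers).
#' @return data.frame with columns `bin`, `count`, `pct` plus a `Total`
#'   row; `pct` is `NA` (printed as a dash) when the lifted set is
#'   empty.
#' @export
maf_table <- function(gm, lifted_ids = gm$marker_ids) {
  if (!all(lifted_ids %in% gm$marker_ids)) {
    stop("lifted_ids must be a subset of the genotype matrix markers")
  }
  idx <- match(lifted_ids, gm$marker_ids)
  maf <- compute_maf(gm$calls[idx, , drop = FALSE])
  bins <- bin_maf(maf)
  counts <- as.integer(table(bins))
  total <- length(lifted_ids)
  pct <- pct_of(counts, total)
  rbind(
    data.frame(bin = MAF_BIN_LABELS, count = counts, pct = pct,
               stringsAsFactors = FALSE),
    data.frame(bin = "Total", count = total, pct = if (total > 0) 100 else NA_real_))
}

#' Percentage arithmetic of a printed spectrum table
#'
#' Recomputes per-bin percentages from externally supplied counts with
#' the same rounding convention as [maf_table()] — used to reproduce
#' published tables from their printed counts.
#'
#' @param counts named integer vector of per-bin counts.
#' @param total denominator (defaults to `sum(counts)`).
#' @return data.frame with `bin`, `count`, `pct`.
#' @export
maf_table_from_counts <- function(counts, total = sum(counts)) {
  data.frame(bin = names(counts), count = as.integer(counts),
             pct = pct_of(as.integer(counts), total),
             stringsAsFactors = FALSE)
}

#' Cross-collection fate of rare alleles
#'
#' Takes the markers that are rare (0 < MAF < 0.01) in collection A and
#' tabulates their MAF bins in collection B.  Markers with no called
#' genotypes in B are reported in a `Missing` row so the counts always
#' sum to A's rare total.
#'
#' @param gm_a,gm_b `GenotypeMatrix` objects over a shared marker
#'   universe.
#' @param lifted_ids marker ids to consider.
#' @return data.frame with columns `bin`, `count`, `pct` (percent of
#'   A's rare markers).
#' @export
cross_collection_rare <- function(gm_a, gm_b,
                                  lifted_ids = gm_a$marker_ids) {
  common <- intersect(lifted_ids, intersect(gm_a$marker_ids,
                                            gm_b$marker_ids))
  maf_a <- compute_maf(gm_a$calls[match(common, gm_a$marker_ids), ,
                                  drop = FALSE])
  rare <- !is.na(maf_a) & maf_a > 0 & maf_a < 0.01
  rare_ids <- common[rare]
  maf_b <- compute_maf(gm_b$calls[match(rare_ids, gm_b$marker_ids), ,
                                  drop = FALSE])
  bins <- bin_maf(maf_b)
  counts <- as.integer(table(bins))
  missing <- sum(is.na(maf_b))
  labels <- MAF_BIN_LABELS
  if (missing > 0) {
    counts <- c(counts, missing)
    labels <- c(labels, "Missing")
  }
  data.frame(bin = labels, count = counts,
             pct = pct_of(counts, length(rare_ids)),
             stringsAsFactors = FALSE)
}
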