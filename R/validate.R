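# Post-liftover validation: allele-divergence screening, strand-aware
# base-by-base flank identity against the source assembly, and
# cross-version consistency counts.  Filters only ever downgrade a
# LIFTED result; they never resurrect a failed one.

#' Validation parameters
#'
#' @param flank window half-width in bp around the SNP (default 50).
#' @param identity_threshold_pct retention threshold; markers below it
#'   become `LOW_IDENTITY` (default 100).
#' @param exclude_snp_base exclude the SNP base itself from the identity
#'   computation (default `TRUE`): the polymorphic site legitimately
#'   differs when the target assembly carries the alternate allele.
#' @return a list of class `ValidationParams`.
#' @export
validation_params <- function(flank = 50, identity_threshold_pct = 100,
                              exclude_snp_base = TRUE) {
  stopifnot(flank > 0,
            identity_threshold_pct >= 0, identity_threshold_pct <= 100)
  structure(list(flank = as.integer(flank),
                 identity_threshold_pct = identity_threshold_pct,
                 exclude_snp_base = isTRUE(exclude_snp_base)),
            class = "ValidationParams")
}

#' Allele-divergence check on a lifted marker
#'
#' The target base at the lifted position (complemented on the `-`
#' strand) must be one of the marker's two array alleles; otherwise the
#' result is downgraded to `ALLELE_DIVERGENT`.  `N` matches nothing.
#'
#' @param result one row of a liftover result `data.frame`
#'   (status `LIFTED`).
#' @param marker the matching marker row.
#' @param target the target `GenomeAssembly`.
#' @return the result row, possibly downgraded; columns `target_base`
#'   (forward-strand base) and `observed_allele` (marker-orientation
#'   base) are filled in.
#' @export
check_allele <- function(result, marker, target) {
  if (result$status != "LIFTED") return(result)
  b <- genome_base(target, result$tname, result$tpos0)
  obs <- if (result$strand == "-") comp_base(b) else b
  result$target_base <- b
  if (obs %in% c(marker$ref, marker$alt) && obs != "N") {
    result$observed_allele <- obs
  } else {
    result$status <- "ALLELE_DIVERGENT"
    result$observed_allele <- NA_character_
  }
  result
}

# oriented flank windows around a target position: returns list(up, down)
# as marker-orientation strings (up = bases 5' of the SNP in the
# marker's source orientation)
oriented_target_flanks <- function(target, tname, tpos0, strand, flank) {
  L <- target$lengths[[tname]]
  left <- genome_subseq(target, tname, tpos0 - min(flank, tpos0), tpos0)
  right <- genome_subseq(target, tname, tpos0 + 1L,
                         tpos0 + 1L + min(flank, L - tpos0 - 1L))
  if (strand == "+") {
    list(up = left, down = right)
  } else {
    list(up = revcomp(right), down = revcomp(left))
  }
}

#' Base-by-base flank identity validation
#'
#' Extracts up to `p$flank` bases on each side of the marker in the
#' source assembly and of the lifted position in the target assembly
#' (oriented by the lifted strand), compares them base by base over the
#' overlap of the realised flank lengths, and downgrades the result to
#' `LOW_IDENTITY` when the identity falls below
#' `p$identity_threshold_pct`.  The SNP base is excluded when
#' `p$exclude_snp_base`; `N` matches nothing; truncation at sequence
#' ends is not penalised.
#'
#' @inheritParams check_allele
#' @param source the source `GenomeAssembly`.
#' @param p a [validation_params()] object.
#' @return the result row with `identity_pct` filled in.
#' @export
validate_flank_identity <- function(result, marker, source, target,
                                    p = validation_params()) {
  if (result$status != "LIFTED") return(result)
  f <- p$flank
  su <- genome_subseq(source, marker$chrom,
                      marker$pos0 - min(f, marker$pos0), marker$pos0)
  sd <- genome_subseq(source, marker$chrom, marker$pos0 + 1L,
                      marker$pos0 + 1L +
                        min(f, source$lengths[[marker$chrom]] -
                              marker$pos0 - 1L))
  tf <- oriented_target_flanks(target, result$tname, result$tpos0,
                               result$strand, f)
  # align at the SNP: compare the tail of the up-flanks and the head of
  # the down-flanks over the realised overlap
  nu <- min(nchar(su), nchar(tf$up))
  nd <- min(nchar(sd), nchar(tf$down))
  a <- character(0)
  b <- character(0)
  if (nu > 0) {
    a <- c(a, str_bases(substr(su, nchar(su) - nu + 1L, nchar(su))))
    b <- c(b, str_bases(substr(tf$up, nchar(tf$up) - nu + 1L,
                               nchar(tf$up))))
  }
  if (nd > 0) {
    a <- c(a, str_bases(substr(sd, 1L, nd)))
    b <- c(b, str_bases(substr(tf$down, 1L, nd)))
  }
  if (!p$exclude_snp_base) {
    sb <- genome_base(source, marker$chrom, marker$pos0)
    tb0 <- genome_base(target, result$tname, result$tpos0)
    tb <- if (result$strand == "-") comp_base(tb0) else tb0
    a <- c(a, sb)
    b <- c(b, tb)
  }
  compared <- length(a)
  if (compared == 0) {
    result$identity_pct <- 0
    result$status <- "LOW_IDENTITY"
    return(result)
  }
  matches <- sum(a == b & a != "N" & b != "N")
  identity <- 100 * matches / compared
  result$identity_pct <- identity
  if (identity < p$identity_threshold_pct) {
    result$status <- "LOW_IDENTITY"
  }
  result
}

#' Cross-version liftover comparison (Venn counts)
#'
#' A marker counts as lifted in a version iff its final status is
#' `LIFTED`.  For two result sets the four counts
#' `both/only_a/only_b/neither` partition the shared marker universe;
#' see [venn_counts()] for three or more versions.
#'
#' @param results_a,results_b result `data.frame`s over the same
#'   marker universe.
#' @param label_a,label_b version labels (used in names only).
#' @return named integer vector `both, only_a, only_b, neither` with an
#'   attribute `labels`.
#' @export
compare_versions <- function(results_a, results_b,
                             label_a = "a", label_b = "b") {
  ids <- results_a$marker_id
  if (!setequal(ids, results_b$marker_id)) {
    stop("result sets cover different marker universes")
  }
  la <- results_a$status == "LIFTED"
  lb <- results_b$status[match(ids, results_b$marker_id)] == "LIFTED"
  out <- c(both = sum(la & lb), only_a = sum(la & !lb),
           only_b = sum(!la & lb), neither = sum(!la & !lb))
  attr(out, "labels") <- c(label_a, label_b)
  out
}

#' Membership counts over every region of an n-set Venn diagram
#'
#' @param results_list named list of result `data.frame`s over the same
#'   marker universe.
#' @return data.frame with one row per membership pattern (columns for
#'   each version, logical, plus `count`); counts sum to the universe
#'   size.
#' @export
venn_counts <- function(results_list) {
  stopifnot(length(results_list) >= 1)
  ids <- results_list[[1]]$marker_id
  lifted <- vapply(results_list, function(r) {
    r$status[match(ids, r$marker_id)] == "LIFTED"
  }, logical(length(ids)))
  if (is.null(dim(lifted))) lifted <- matrix(lifted, nrow = length(ids))
  pat <- apply(lifted, 1, function(z) paste(as.integer(z), collapse = ""))
  n <- length(results_list)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  names(grid) <- names(results_list)
  key <- apply(grid, 1, function(z) paste(as.integer(z), collapse = ""))
  grid$count <- as.integer(table(factor(pat, levels = key)))
  grid
}
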