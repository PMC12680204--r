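# Summary tables: liftover totals per chromosome, failure taxonomy,
# region distribution, failure causes, filter-cascade accounting.
# All percentages use half-up rounding at 2 decimals.

FAILURE_CATEGORIES <- c("multi_mapped", "unmapped", "allele_divergent",
                        "low_identity", "gap_at_site")

#' Filter-cascade accounting
#'
#' Reproduces the pipeline's headline bookkeeping: markers that never
#' produced an acceptable unique alignment (`prefilter_failures`,
#' e.g. multi-mapped and unmapped counts) plus markers removed by the
#' post-liftover screens (`filters`, e.g. allele-divergent and
#' low-identity counts) leave `retained = initial_lifted - sum(filters)`
#' markers.
#'
#' @param initial_lifted markers lifted before the validation screens.
#' @param filters named counts removed by each post-liftover screen.
#' @param prefilter_failures named counts that failed before lifting.
#' @return list with `retained`, `failed_total` and the `breakdown`
#'   (named vector over all failure categories).
#' @export
cascade_accounting <- function(initial_lifted, filters,
                               prefilter_failures) {
  retained <- initial_lifted - sum(filters)
  breakdown <- c(prefilter_failures, filters)
  list(retained = as.integer(retained),
       failed_total = as.integer(sum(breakdown)),
       breakdown = breakdown)
}

#' Liftover summary in the per-chromosome table shape
#'
#' Counts total/lifted/failed markers per source chromosome (scaffolds
#' pooled into one `Scaffolds` row) plus a `Total` row; percentages are
#' of the grand marker total.  Also returns the failure breakdown by
#' category and the forward/reverse strand breakdown of lifted markers.
#'
#' @param results final liftover results.
#' @param markers matching marker `data.frame`.
#' @param source source `GenomeAssembly` (for scaffold flags).
#' @param version_label label stored in the summary.
#' @return list of class `LiftoverSummary` with `table`, `failures`,
#'   `strands`, `version`.
#' @export
summarize_liftover <- function(results, markers, source,
                               version_label = "target") {
  stopifnot(nrow(results) == nrow(markers),
            all(results$marker_id == markers$id))
  grp <- ifelse(source$is_scaffold[markers$chrom], "Scaffolds",
                markers$chrom)
  lifted <- results$status == "LIFTED"
  rows <- sort(unique(grp))
  rows <- c(setdiff(rows, "Scaffolds"),
            if ("Scaffolds" %in% rows) "Scaffolds")
  total_all <- nrow(markers)
  tab <- do.call(rbind, lapply(rows, function(g) {
    sel <- grp == g
    data.frame(chromosome = g, total = sum(sel),
               lifted = sum(sel & lifted), failed = sum(sel & !lifted))
  }))
  tab <- rbind(tab, data.frame(chromosome = "Total", total = total_all,
                               lifted = sum(lifted),
                               failed = sum(!lifted)))
  tab$lifted_pct <- pct_of(tab$lifted, total_all)
  tab$failed_pct <- pct_of(tab$failed, total_all)
  failures <- c(
    multi_mapped = sum(results$status == "MULTI_MAPPED"),
    unmapped = sum(results$status == "UNMAPPED"),
    allele_divergent = sum(results$status == "ALLELE_DIVERGENT"),
    low_identity = sum(results$status == "LOW_IDENTITY"),
    gap_at_site = sum(results$status == "GAP_AT_SITE"))
  strands <- c(forward = sum(lifted & results$strand == "+"),
               reverse = sum(lifted & results$strand == "-"))
  structure(list(version = version_label, table = tab,
                 failures = failures, strands = strands),
            class = "LiftoverSummary")
}

#' @export
print.LiftoverSummary <- function(x, ...) {
  cat("Liftover summary (", x$version, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("failures:", paste(names(x$failures), x$failures, sep = "=",
                         collapse = " "), "\n")
  cat("strands: forward=", x$strands[["forward"]],
      " reverse=", x$strands[["reverse"]], "\n", sep = "")
  invisible(x)
}

#' Region distribution tables for lifted and failed markers
#'
#' The lifted table uses `{genic, intergenic, near_genic}` labels; the
#' failed table resolves near-genic into `{upstream, downstream}`.
#' Percentage denominators: the full array total for `"array_total"`
#' (per-version table shape), or each category's own total for
#' `"category_total"` (failure-comparison shape).
#'
#' @param labels region labels, one per marker (from
#'   [classify_region()]).
#' @param denominator see above.
#' @param total_markers the array total (required for
#'   `"array_total"`).
#' @return data.frame `region`, `count`, `pct`.
#' @export
summarize_regions <- function(labels,
                              denominator = c("array_total",
                                              "category_total"),
                              total_markers = length(labels)) {
  denominator <- match.arg(denominator)
  lv <- intersect(c("genic", "intergenic", "near_genic", "upstream",
                    "downstream"), unique(labels))
  counts <- table(factor(labels, levels = lv))
  den <- if (denominator == "array_total") total_markers
         else sum(counts)
  data.frame(region = names(counts), count = as.integer(counts),
             pct = pct_of(as.integer(counts), den),
             stringsAsFactors = FALSE)
}

#' Failure-cause table
#'
#' @param causes data.frame from [classify_failure()] (columns
#'   `marker_id`, `cause`), or a named count vector.
#' @return data.frame `cause`, `count`, `pct` (percent of the failed
#'   group's total).
#' @export
summarize_failure_causes <- function(causes) {
  counts <- if (is.data.frame(causes)) {
    table(factor(causes$cause,
                 levels = union(c("te_class_I", "te_class_II",
                                  "low_identity", "other"),
                                unique(causes$cause))))
  } else {
    as.table(causes)
  }
  data.frame(cause = names(counts), count = as.integer(counts),
             pct = pct_of(as.integer(counts), sum(counts)),
             stringsAsFactors = FALSE)
}

#' Re-derive a summary from per-marker results and assert consistency
#'
#' Checks the partition invariants: lifted + failed = total in every
#' row, failure categories sum to the failed total, strand counts sum
#' to the lifted total.
#'
#' @param summary a `LiftoverSummary`.
#' @param results,markers,source the inputs it was built from.
#' @return `TRUE` (invisibly) or an error.
#' @export
check_summary_consistency <- function(summary, results, markers, source) {
  fresh <- summarize_liftover(results, markers, source, summary$version)
  if (!identical(fresh$table, summary$table) ||
      !identical(fresh$failures, summary$failures) ||
      !identical(fresh$strands, summary$strands)) {
    stop("summary is not re-derivable from the per-marker results")
  }
  tab <- summary$table
  if (any(tab$lifted + tab$failed != tab$total)) {
    stop("lifted + failed != total in summary table")
  }
  tot <- tab[tab$chromosome == "Total", ]
  if (sum(summary$failures) != tot$failed) {
    stop("failure categories do not sum to the failed total")
  }
  if (sum(summary$strands) != tot$lifted) {
    stop("strand counts do not sum to the lifted total")
  }
  invisible(TRUE)
}
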