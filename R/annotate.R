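# Positional classification of markers against gene annotations, and
# failure-cause classification by transposable-element overlap and
# cross-assembly low-identity windows.

#' Classify positions as genic / near-genic / intergenic
#'
#' A position inside a gene is `genic` (distance 0); otherwise, if the
#' nearest gene boundary is within `near_window` bp (inclusive) the
#' position is `near_genic`, refined to `upstream`/`downstream` relative
#' to the nearest gene's strand when `directional = TRUE`; everything
#' else is `intergenic`.  The nearest gene is chosen by minimal
#' distance, ties broken by smaller start coordinate, remaining
#' direction ties resolved as `upstream`.
#'
#' @param chrom,pos0 vectors of positions (0-based).
#' @param genes interval `data.frame` of gene features.
#' @param near_window near-genic window in bp (default 5000).
#' @param directional split `near_genic` into `upstream`/`downstream`.
#' @return data.frame with columns `label`, `nearest_gene`, `distance`.
#' @export
classify_region <- function(chrom, pos0, genes, near_window = 5000,
                            directional = FALSE) {
  n <- length(chrom)
  label <- rep("intergenic", n)
  nearest <- rep(NA_character_, n)
  distance <- rep(Inf, n)
  g <- genes[genes$kind == "gene" | genes$kind == "other", , drop = FALSE]
  if (nrow(g) > 0) {
    for (i in seq_len(n)) {
      gi <- g[g$chrom == chrom[i], , drop = FALSE]
      if (nrow(gi) == 0) next
      p <- pos0[i]
      inside <- gi$start0 <= p & p < gi$end0
      if (any(inside)) {
        w <- which(inside)
        w <- w[order(gi$start0[w])][1]
        label[i] <- "genic"
        nearest[i] <- gi$name[w]
        distance[i] <- 0
        next
      }
      d <- ifelse(p < gi$start0, gi$start0 - p, p - gi$end0 + 1L)
      dmin <- min(d)
      distance[i] <- dmin
      w <- which(d == dmin)
      w <- w[order(gi$start0[w])][1]
      nearest[i] <- gi$name[w]
      if (dmin <= near_window) {
        if (directional) {
          gstrand <- if (gi$strand[w] == "-") "-" else "+"
          before <- p < gi$start0[w]
          label[i] <- if (xor(before, gstrand == "-")) "upstream"
                      else "downstream"
        } else {
          label[i] <- "near_genic"
        }
      }
    }
  }
  data.frame(label = label, nearest_gene = nearest, distance = distance,
             stringsAsFactors = FALSE)
}

#' Failure-cause classification for unlifted markers
#'
#' The first class in `priority` whose interval set contains the
#' marker's source position wins; markers in no annotated interval are
#' `other`.  By default retrotransposons (class I) outrank DNA
#' transposons (class II), which outrank low-identity windows.
#'
#' @param markers marker `data.frame` (only failed markers should be
#'   passed, but no check is enforced beyond the per-row `results`).
#' @param results matching liftover results (status must not be
#'   `LIFTED`).
#' @param tes transposable-element intervals (kinds `te_class_I`,
#'   `te_class_II`).
#' @param low_identity_regions intervals of kind `low_identity` from
#'   [scan_low_identity()].
#' @param priority evaluation order of the cause classes.
#' @param flank_window when positive, a marker overlaps an interval if
#'   any base of its `±flank_window` bp window does (default 0: point
#'   overlap).
#' @return data.frame with columns `marker_id`, `cause`, `te_name`.
#' @export
classify_failure <- function(markers, results, tes,
                             low_identity_regions = NULL,
                             priority = c("te_class_I", "te_class_II",
                                          "low_identity", "other"),
                             flank_window = 0) {
  if (any(results$status == "LIFTED")) {
    stop("classify_failure applies to failed markers only")
  }
  n <- nrow(markers)
  cause <- rep("other", n)
  te_name <- rep(NA_character_, n)
  sets <- list(
    te_class_I = tes[tes$kind == "te_class_I", , drop = FALSE],
    te_class_II = tes[tes$kind == "te_class_II", , drop = FALSE],
    low_identity = if (is.null(low_identity_regions)) {
      interval_table(character(0), integer(0), integer(0))[0, ]
    } else low_identity_regions)
  pos_lo <- markers$pos0 - flank_window
  pos_hi <- markers$pos0 + flank_window
  unassigned <- rep(TRUE, n)
  for (cls in setdiff(priority, "other")) {
    iv <- sets[[cls]]
    if (is.null(iv) || nrow(iv) == 0) next
    hit <- overlaps_window(markers$chrom, pos_lo, pos_hi, iv)
    take <- unassigned & hit$any
    cause[take] <- cls
    te_name[take] <- hit$name[take]
    unassigned[take] <- FALSE
  }
  data.frame(marker_id = markers$id, cause = cause, te_name = te_name,
             stringsAsFactors = FALSE)
}

# window-vs-interval overlap; returns list(any = logical, name = chr)
overlaps_window <- function(chrom, lo0, hi0, intervals) {
  n <- length(chrom)
  if (nrow(intervals) == 0) {
    return(list(any = rep(FALSE, n), name = rep(NA_character_, n)))
  }
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(pmax(lo0, 0L) + 1L, hi0 + 1L))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start0 + 1L,
                                               intervals$end0))
  ov <- GenomicRanges::findOverlaps(q, s, select = "first")
  list(any = !is.na(ov),
       name = ifelse(is.na(ov), NA_character_, intervals$name[ov]))
}

#' Scan for low-identity windows between two assemblies
#'
#' Tiles the source genome into non-overlapping windows, lifts each
#' window's midpoint through the chains, extracts the corresponding
#' target window in the mapped orientation and computes base identity.
#' Windows with identity strictly below `threshold_pct` — or whose
#' midpoint cannot be lifted — are emitted; adjacent qualifying windows
#' are merged.
#'
#' @param source,target `GenomeAssembly` objects.
#' @param chains chains from [build_chains()] (or a simulator truth
#'   chain).
#' @param window tile width in bp (default 1000).
#' @param threshold_pct identity threshold; 95 for failure-cause tables,
#'   90 for coarser divergence tracks.
#' @return interval `data.frame` of kind `low_identity`.
#' @export
scan_low_identity <- function(source, target, chains, window = 1000,
                              threshold_pct = 95) {
  out <- list()
  for (chrom in names(source$sequences)) {
    L <- source$lengths[[chrom]]
    starts <- seq(0L, L - 1L, by = window)
    bad <- logical(length(starts))
    for (i in seq_along(starts)) {
      w0 <- starts[i]
      w1 <- min(L, w0 + window)
      mid <- w0 + (w1 - w0) %/% 2L
      hit <- lift_by_chain(chrom, mid, chains)
      if (!is.list(hit)) { bad[i] <- TRUE; next }
      src <- genome_subseq(source, chrom, w0, w1)
      tlen <- target$lengths[[hit$tname]]
      if (hit$strand == "+") {
        t0 <- hit$tpos0 - (mid - w0)
        tgt <- genome_subseq(target, hit$tname, max(0L, t0),
                             min(tlen, t0 + (w1 - w0)))
        if (t0 < 0) src <- substr(src, 1L - t0, nchar(src))
      } else {
        t1 <- hit$tpos0 + (mid - w0) + 1L
        t0 <- t1 - (w1 - w0)
        tgt <- revcomp(genome_subseq(target, hit$tname, max(0L, t0),
                                     min(tlen, t1)))
        if (t1 > tlen) src <- substr(src, 1L + (t1 - tlen), nchar(src))
      }
      m <- min(nchar(src), nchar(tgt))
      if (m == 0) { bad[i] <- TRUE; next }
      a <- str_bases(substr(src, 1L, m))
      b <- str_bases(substr(tgt, 1L, m))
      identity <- 100 * sum(a == b & a != "N" & b != "N") / m
      bad[i] <- identity < threshold_pct
    }
    if (any(bad)) {
      r <- rle(bad)
      ends <- cumsum(r$lengths)
      begins <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        out[[length(out) + 1L]] <- interval_table(
          chrom, starts[begins[j]],
          min(L, starts[ends[j]] + window),
          name = sprintf("lowid_%s_%d", chrom, starts[begins[j]]),
          kind = "low_identity")
      }
    }
  }
  if (length(out) == 0) {
    return(interval_table(character(0), integer(0), integer(0))[0, ])
  }
  do.call(rbind, out)
}

#' Scaffold-vs-chromosome placement accounting
#'
#' Counts marker fates by origin (scaffold or chromosome in the source
#' assembly) and destination class in the target assembly.
#'
#' @param markers marker `data.frame`.
#' @param results matching liftover results.
#' @param source,target `GenomeAssembly` objects with `is_scaffold`
#'   flags.
#' @return data.frame with columns `origin`, `placement`
#'   (`chromosome`/`scaffold`/`failed`) and `count`; counts partition
#'   the marker set.
#' @export
scaffold_placement_report <- function(markers, results, source, target) {
  origin <- ifelse(source$is_scaffold[markers$chrom],
                   "scaffold", "chromosome")
  lifted <- results$status == "LIFTED"
  placement <- rep("failed", nrow(markers))
  placement[lifted] <- ifelse(target$is_scaffold[results$tname[lifted]],
                              "scaffold", "chromosome")
  agg <- as.data.frame(table(origin = origin, placement = placement),
                       stringsAsFactors = FALSE)
  names(agg)[3] <- "count"
  agg$count <- as.integer(agg$count)
  agg
}
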