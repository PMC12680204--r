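# Flank extraction and the k-mer seeded, banded local aligner that
# stands in for BLAT in the liftover pipeline.
#
# Scoring is PSL-like and fixed across the package:
#   score    = matches - mismatches - gap_openings
#   identity = 100 * matches / (matches + mismatches + gap_bases)
# Gap extensions beyond the opening are free but their bases count
# against identity.  'N' never matches anything.  With the default
# min_score = 100 a full 101 bp flank query must align essentially
# perfectly, which is what makes the downstream allele and identity
# screens meaningful.

#' Alignment parameters
#'
#' @param k seed length (tile size), default 12.
#' @param min_score minimum accepted alignment score, default 100.
#' @param min_identity_pct minimum accepted percent identity, default 98.
#' @param max_seed_diag_gap diagonal slack when clustering seeds.
#' @param band half-width of the banded extension.
#' @param mask_snp_base score the query's SNP column as neutral (neither
#'   match nor mismatch, weight 0).  This mirrors the validation module's
#'   `exclude_snp_base`: the polymorphic site legitimately differs when
#'   the target assembly carries the other allele (or a diverged base),
#'   and penalising it would make such markers unalignable at
#'   `min_score = 100`.  Set to `FALSE` for plain sequence alignment.
#' @return a list of class `AlignParams`.
#' @export
align_params <- function(k = 12, min_score = 100, min_identity_pct = 98,
                         max_seed_diag_gap = 5, band = 10,
                         mask_snp_base = TRUE) {
  stopifnot(k >= 1, k <= 31,
            min_identity_pct >= 0, min_identity_pct <= 100,
            max_seed_diag_gap >= 0, band >= 0)
  structure(list(k = as.integer(k), min_score = min_score,
                 min_identity_pct = min_identity_pct,
                 max_seed_diag_gap = as.integer(max_seed_diag_gap),
                 band = as.integer(band),
                 mask_snp_base = isTRUE(mask_snp_base)),
            class = "AlignParams")
}

#' Extract the flank query around a marker
#'
#' Takes up to `flank` bases upstream and downstream of the SNP (the SNP
#' base included), truncating at sequence ends.
#'
#' @param marker one row of a marker `data.frame`.
#' @param genome the source `GenomeAssembly`.
#' @param flank flank half-width in bp (default 50).
#' @return a list of class `FlankQuery` with fields `marker_id`, `seq`,
#'   `snp_offset`, `up_len`, `down_len`, plus the source coordinates
#'   `chrom` and `start0` of the query's first base.
#' @export
extract_flank <- function(marker, genome, flank = 50) {
  chrom <- marker$chrom
  if (!chrom %in% names(genome$sequences)) {
    stop("marker chromosome absent from genome: ", chrom)
  }
  L <- genome$lengths[[chrom]]
  pos0 <- marker$pos0
  stopifnot(pos0 >= 0, pos0 < L)
  up <- min(flank, pos0)
  down <- min(flank, L - pos0 - 1L)
  seq <- genome_subseq(genome, chrom, pos0 - up, pos0 + down + 1L)
  structure(list(marker_id = marker$id, seq = seq,
                 snp_offset = as.integer(up),
                 up_len = as.integer(up), down_len = as.integer(down),
                 chrom = chrom, start0 = as.integer(pos0 - up)),
            class = "FlankQuery")
}

#' Build a k-mer index over the forward strand of an assembly
#'
#' Every overlapping k-mer (step 1) of every sequence is recorded;
#' k-mers containing `N` are skipped.  Reverse-strand hits are found at
#' query time by searching the reverse-complemented query.
#'
#' @param genome target `GenomeAssembly`.
#' @param k seed length.
#' @return an object of class `KmerIndex`.
#' @export
build_index <- function(genome, k = 12) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  all_kmer <- character(0)
  all_pos <- integer(0)
  all_tid <- integer(0)
  tnames <- names(genome$sequences)
  for (ti in seq_along(tnames)) {
    s <- genome$sequences[[ti]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    all_kmer <- c(all_kmer, kmers[ok])
    all_pos <- c(all_pos, starts[ok] - 1L)
    all_tid <- c(all_tid, rep(ti, sum(ok)))
  }
  f <- factor(all_kmer)
  env_p <- list2env(split(all_pos, f), hash = TRUE)
  env_t <- list2env(split(all_tid, f), hash = TRUE)
  structure(list(k = k, env_p = env_p, env_t = env_t, tnames = tnames),
            class = "KmerIndex")
}

# look up seed hits of a query string on one effective strand;
# returns data.frame(qpos0, tid, tpos0)
seed_hits <- function(qseq, index) {
  k <- index$k
  qlen <- nchar(qseq)
  if (qlen < k) return(NULL)
  starts <- seq_len(qlen - k + 1L)
  kmers <- substring(qseq, starts, starts + k - 1L)
  pl <- mget(kmers, envir = index$env_p, ifnotfound = list(NULL))
  tl <- mget(kmers, envir = index$env_t, ifnotfound = list(NULL))
  n <- lengths(pl)
  if (sum(n) == 0) return(NULL)
  data.frame(qpos0 = rep(starts - 1L, n),
             tid = unlist(tl, use.names = FALSE),
             tpos0 = unlist(pl, use.names = FALSE))
}

# assemble an Alignment object from the DP column map (window coords)
make_alignment <- function(marker_id, qseq_eff, qlen, strand, tname, tseq,
                           wstart, dp, mask_eff) {
  qcol <- dp$q
  tcol <- dp$t
  tabs <- tcol + wstart           # absolute forward target coords
  if (strand == "-") {
    q_orig <- ifelse(is.na(qcol), NA_integer_, qlen - 1L - qcol)
    ord <- rev(seq_along(qcol))
    q_use <- q_orig[ord]
    t_use <- tabs[ord]
    # per-column characters still follow the DP (reverse-complement) view
    qch <- str_bases(qseq_eff)[qcol[ord] + 1L]
    tch <- str_bases(substr(tseq, wstart + 1L,
                            wstart + max(tcol, na.rm = TRUE) + 1L))[tcol[ord] + 1L]
    mask_col <- !is.na(qcol[ord]) & qcol[ord] == mask_eff
  } else {
    q_use <- qcol
    t_use <- tabs
    qch <- str_bases(qseq_eff)[qcol + 1L]
    tch <- str_bases(substr(tseq, wstart + 1L,
                            wstart + max(tcol, na.rm = TRUE) + 1L))[tcol + 1L]
    mask_col <- !is.na(qcol) & qcol == mask_eff
  }
  aligned <- !is.na(q_use) & !is.na(t_use)
  scored <- aligned & !mask_col
  is_match <- scored & qch == tch & qch != "N" & tch != "N"
  matches <- sum(is_match, na.rm = TRUE)
  mismatches <- sum(scored, na.rm = TRUE) - matches
  q_gap_bases <- sum(is.na(q_use))
  t_gap_bases <- sum(is.na(t_use))
  gap_openings <- n_runs(is.na(q_use)) + n_runs(is.na(t_use))
  score <- as.numeric(matches - mismatches - gap_openings)
  denom <- matches + mismatches + q_gap_bases + t_gap_bases
  identity <- if (denom > 0) 100 * matches / denom else NA_real_
  tq <- t_use[!is.na(t_use)]
  qq <- q_use[!is.na(q_use)]
  structure(list(
    marker_id = marker_id, tname = tname,
    tstart0 = min(tq), tend0 = max(tq) + 1L,
    strand = strand,
    qstart0 = min(qq), qend0 = max(qq) + 1L,
    matches = matches, mismatches = mismatches,
    q_gap_bases = q_gap_bases, t_gap_bases = t_gap_bases,
    gap_openings = gap_openings,
    score = score, identity_pct = identity,
    colmap = cbind(q = q_use, t = t_use)),
    class = "Alignment")
}

# number of TRUE runs in a logical vector
n_runs <- function(x) {
  if (length(x) == 0 || !any(x)) return(0L)
  r <- rle(x)
  sum(r$values)
}

#' Align a flank query against an indexed target assembly
#'
#' Seed-and-extend: (1) exact k-mer seeds are collected for the query
#' and its reverse complement; (2) seeds sharing target sequence, strand
#' and diagonal (within `max_seed_diag_gap`) are clustered; (3) each
#' cluster is extended by a banded local alignment over the implied
#' target window; (4) alignments passing `min_score` and
#' `min_identity_pct` are kept; (5) hits whose target spans overlap
#' reciprocally by at least 50% are deduplicated, keeping the higher
#' score.
#'
#' @param q a `FlankQuery` (or any list with `seq` and `snp_offset`).
#' @param index a `KmerIndex` built from the target with `p$k`.
#' @param genome the target `GenomeAssembly`.
#' @param p an [align_params()] object.
#' @return list of `Alignment` objects sorted by decreasing score (ties
#'   by target name and start); may be empty.
#' @export
align_flank <- function(q, index, genome, p = align_params()) {
  stopifnot(index$k == p$k)
  qseq <- q$seq
  qlen <- nchar(qseq)
  res <- list()
  for (strand in c("+", "-")) {
    qeff <- if (strand == "+") qseq else revcomp(qseq)
    mask_eff <- if (!p$mask_snp_base || is.null(q$snp_offset)) -1L
                else if (strand == "+") q$snp_offset
                else qlen - 1L - q$snp_offset
    hits <- seed_hits(qeff, index)
    if (is.null(hits)) next
    hits$diag <- hits$tpos0 - hits$qpos0
    for (ti in unique(hits$tid)) {
      h <- hits[hits$tid == ti, ]
      tname <- index$tnames[ti]
      tseq <- genome$sequences[[tname]]
      L <- nchar(tseq)
      dg <- sort(unique(h$diag))
      brk <- c(0L, which(diff(dg) > p$max_seed_diag_gap), length(dg))
      for (ci in seq_len(length(brk) - 1L)) {
        dmin <- dg[brk[ci] + 1L]
        dmax <- dg[brk[ci + 1L]]
        wstart <- max(0L, dmin - p$band)
        wend <- min(L, dmax + qlen + p$band)
        if (wend - wstart < index$k) next
        win <- substr(tseq, wstart + 1L, wend)
        dp <- .banded_local_align(qeff, win, mask_eff,
                                  dmin - wstart - p$band,
                                  dmax - wstart + p$band)
        if (is.null(dp$q) || dp$score <= 0) next
        aln <- make_alignment(q$marker_id, qeff, qlen, strand, tname,
                              tseq, wstart, dp, mask_eff)
        res[[length(res) + 1L]] <- aln
      }
    }
  }
  if (length(res) == 0) return(res)
  res <- res[order(-vapply(res, `[[`, numeric(1), "score"))]
  res <- dedup_alignments(res)
  keep <- vapply(res, function(a) {
    a$score >= p$min_score && !is.na(a$identity_pct) &&
      a$identity_pct >= p$min_identity_pct
  }, logical(1))
  res <- res[keep]
  ord <- order(-vapply(res, `[[`, numeric(1), "score"),
               vapply(res, `[[`, character(1), "tname"),
               vapply(res, function(a) as.numeric(a$tstart0), numeric(1)))
  res[ord]
}

# drop alignments whose target span reciprocally overlaps (>= 50%) a
# higher-scoring retained alignment; input sorted by decreasing score
dedup_alignments <- function(alns) {
  kept <- list()
  for (a in alns) {
    dup <- FALSE
    for (b in kept) {
      if (a$tname != b$tname) next
      ov <- min(a$tend0, b$tend0) - max(a$tstart0, b$tstart0)
      if (ov <= 0) next
      if (ov >= 0.5 * (a$tend0 - a$tstart0) &&
          ov >= 0.5 * (b$tend0 - b$tstart0)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- a
  }
  kept
}

#' Percent identity of an alignment
#'
#' `100 * matches / (matches + mismatches + gap bases)`.
#'
#' @param a an `Alignment`.
#' @return identity in `[0, 100]`.
#' @export
compute_identity <- function(a) {
  denom <- a$matches + a$mismatches + a$q_gap_bases + a$t_gap_bases
  if (denom == 0) stop("alignment has no columns")
  100 * a$matches / denom
}

#' Dump alignments as a PSL-like TSV
#'
#' One row per alignment, for debugging; columns mirror the `Alignment`
#' fields (without the column map).
#'
#' @param alignments list of `Alignment` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  cols <- c("marker_id", "tname", "tstart0", "tend0", "strand",
            "qstart0", "qend0", "matches", "mismatches",
            "q_gap_bases", "t_gap_bases", "score", "identity_pct")
  rows <- lapply(alignments, function(a) {
    as.data.frame(a[cols], stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment %s -> %s:%d-%d (%s) score=%g identity=%.2f\n",
              x$marker_id, x$tname, x$tstart0, x$tend0, x$strand,
              x$score, x$identity_pct))
  invisible(x)
}
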