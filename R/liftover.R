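# Liftover engine: turn per-marker alignments into lifted coordinates
# and alleles, build collinear chains from the accepted alignments, and
# lift residual positions through chain blocks (UCSC-liftOver style, no
# interpolation inside inter-block gaps).

LIFT_STATUSES <- c("LIFTED", "UNMAPPED", "MULTI_MAPPED",
                   "ALLELE_DIVERGENT", "LOW_IDENTITY", "GAP_AT_SITE")

#' Classify a marker's threshold-passing alignments
#'
#' Zero hits is `UNMAPPED`; two or more hits tied at the best score
#' (margin 0, distinct loci after deduplication) is `MULTI_MAPPED`;
#' otherwise the single best hit is unique.
#'
#' @param alignments list of `Alignment` objects from [align_flank()].
#' @param p an [align_params()] (reserved for a configurable margin).
#' @return list with `status` in `{"UNIQUE","MULTI_MAPPED","UNMAPPED"}`
#'   and, when unique, the winning `alignment`.
#' @export
classify_hits <- function(alignments, p = align_params()) {
  if (length(alignments) == 0) {
    return(list(status = "UNMAPPED", alignment = NULL))
  }
  scores <- vapply(alignments, `[[`, numeric(1), "score")
  best <- max(scores)
  if (sum(scores == best) >= 2) {
    return(list(status = "MULTI_MAPPED", alignment = NULL))
  }
  list(status = "UNIQUE", alignment = alignments[[which.max(scores)]])
}

#' Project the SNP position through an alignment's column map
#'
#' @param a the unique accepted `Alignment` for a marker.
#' @param q the marker's `FlankQuery`.
#' @return list `(tname, tpos0, strand)`, or the string
#'   `"GAP_AT_SITE"` when the SNP column is aligned to a target gap or
#'   lies outside the aligned query span.  `tpos0` is always reported in
#'   target-forward coordinates, also on the `-` strand.
#' @export
map_snp_position <- function(a, q) {
  cm <- a$colmap
  row <- which(!is.na(cm[, "q"]) & cm[, "q"] == q$snp_offset)
  if (length(row) == 0) return("GAP_AT_SITE")
  t <- cm[row[1], "t"]
  if (is.na(t)) return("GAP_AT_SITE")
  list(tname = a$tname, tpos0 = as.integer(t), strand = a$strand)
}

#' Orient an allele pair for the lifted strand
#'
#' Identity on `+`; complement of both alleles on `-`.
#'
#' @param ref,alt single bases.
#' @param strand `"+"` or `"-"`.
#' @return list `(lifted_ref, lifted_alt)`.
#' @export
lift_alleles <- function(ref, alt, strand) {
  if (strand == "-") {
    list(lifted_ref = comp_base(ref), lifted_alt = comp_base(alt))
  } else {
    list(lifted_ref = ref, lifted_alt = alt)
  }
}

# decompose one accepted alignment into ungapped blocks in *source*
# coordinates (via the FlankQuery's source anchoring)
alignment_blocks <- function(a, q) {
  cm <- a$colmap
  ok <- !is.na(cm[, "q"]) & !is.na(cm[, "t"])
  if (!any(ok)) return(NULL)
  qv <- cm[ok, "q"]
  tv <- cm[ok, "t"]
  step_t <- if (a$strand == "+") 1L else -1L
  newblk <- c(TRUE, diff(qv) != 1L | diff(tv) != step_t)
  bid <- cumsum(newblk)
  nb <- max(bid)
  out <- vector("list", nb)
  for (b in seq_len(nb)) {
    qs <- qv[bid == b]
    ts <- tv[bid == b]
    src0 <- q$start0 + qs[1]
    src1 <- q$start0 + qs[length(qs)] + 1L
    t0 <- min(ts[1], ts[length(ts)])
    t1 <- max(ts[1], ts[length(ts)]) + 1L
    out[[b]] <- data.frame(
      tname_src = q$chrom, src_start0 = src0, src_end0 = src1,
      tname_tgt = a$tname, tgt_start0 = t0, tgt_end0 = t1,
      strand = a$strand,
      score = a$score / nb,  # alignment score shared across its blocks
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build collinear chains from accepted flank alignments
#'
#' Ungapped sub-blocks of the accepted alignments are sorted by source
#' coordinate and greedily linked while they stay on the same
#' (source sequence, target sequence, strand), remain collinear, and
#' leave gaps of at most `max_gap` on both sides.  Overlapping blocks
#' with an identical source-to-target offset (from overlapping flank
#' queries) are merged; a block that overlaps the running chain with a
#' conflicting offset is dropped.
#'
#' @param accepted list of `list(alignment =, query =)` pairs from
#'   unique classifications.
#' @param max_gap maximum source/target gap bridged within a chain (bp).
#' @return list of `Chain` objects: `list(id, blocks, score)` where
#'   `blocks` is a data.frame of collinear ungapped blocks.
#' @export
build_chains <- function(accepted, max_gap = 10000) {
  if (length(accepted) == 0) return(list())
  blocks <- do.call(rbind, lapply(accepted, function(x) {
    alignment_blocks(x$alignment, x$query)
  }))
  if (is.null(blocks) || nrow(blocks) == 0) return(list())
  blocks <- blocks[order(blocks$tname_src, blocks$src_start0,
                         blocks$src_end0), ]
  chains <- list()
  cur <- NULL  # running chain: list of merged block rows
  flush <- function(chains, cur) {
    if (is.null(cur)) return(chains)
    df <- do.call(rbind, cur)
    chains[[length(chains) + 1L]] <- list(
      id = length(chains) + 1L, blocks = df, score = sum(df$score))
    chains
  }
  # offset invariant under merging: '+' blocks share t0 - s0;
  # '-' blocks share t1 + s0 (equivalently t0 + s1)
  blk_offset <- function(b) {
    if (b$strand == "+") b$tgt_start0 - b$src_start0
    else b$tgt_end0 + b$src_start0
  }
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (is.null(cur)) { cur <- list(b); next }
    last <- cur[[length(cur)]]
    same <- b$tname_src == last$tname_src &&
      b$tname_tgt == last$tname_tgt && b$strand == last$strand
    if (same && b$src_start0 <= last$src_end0) {
      # overlapping or adjacent in source
      if (blk_offset(b) == blk_offset(last) &&
          b$src_end0 >= last$src_start0) {
        merged <- last
        merged$src_end0 <- max(last$src_end0, b$src_end0)
        merged$src_start0 <- min(last$src_start0, b$src_start0)
        if (b$strand == "+") {
          merged$tgt_start0 <- min(last$tgt_start0, b$tgt_start0)
          merged$tgt_end0 <- max(last$tgt_end0, b$tgt_end0)
        } else {
          merged$tgt_start0 <- min(last$tgt_start0, b$tgt_start0)
          merged$tgt_end0 <- max(last$tgt_end0, b$tgt_end0)
        }
        merged$score <- last$score + b$score
        cur[[length(cur)]] <- merged
      }
      # conflicting overlap: drop the incoming block
      next
    }
    src_gap <- b$src_start0 - last$src_end0
    tgt_gap <- if (b$strand == "+") b$tgt_start0 - last$tgt_end0
               else last$tgt_start0 - b$tgt_end0
    if (same && src_gap >= 0 && src_gap <= max_gap &&
        tgt_gap >= 0 && tgt_gap <= max_gap) {
      cur[[length(cur) + 1L]] <- b
    } else {
      chains <- flush(chains, cur)
      cur <- list(b)
    }
  }
  chains <- flush(chains, cur)
  chains
}

#' Lift a source position through chain blocks
#'
#' A position inside a block is projected by offset (strand-aware); a
#' position falling between the blocks of a chain is `UNMAPPED` — gaps
#' are never interpolated.  When several chains' blocks contain the
#' position, the highest-scoring chain wins.
#'
#' @param chrom,pos0 source coordinate (0-based).
#' @param chains list of chains from [build_chains()].
#' @return list `(tname, tpos0, strand)` or the string `"UNMAPPED"`.
#' @export
lift_by_chain <- function(chrom, pos0, chains) {
  best <- NULL
  best_score <- -Inf
  for (ch in chains) {
    bl <- ch$blocks
    hit <- which(bl$tname_src == chrom & bl$src_start0 <= pos0 &
                   pos0 < bl$src_end0)
    if (length(hit) == 0) next
    if (ch$score > best_score) {
      b <- bl[hit[1], ]
      tpos0 <- if (b$strand == "+") {
        b$tgt_start0 + (pos0 - b$src_start0)
      } else {
        b$tgt_start0 + (b$src_end0 - 1L - pos0)
      }
      best <- list(tname = b$tname_tgt, tpos0 = as.integer(tpos0),
                   strand = b$strand)
      best_score <- ch$score
    }
  }
  if (is.null(best)) "UNMAPPED" else best
}

#' Write chains in UCSC chain format
#'
#' Header lines follow
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand
#' qStart qEnd id`; block lines are `size dt dq` with a bare `size` on
#' the last block.  The source assembly takes the `t` side (strand
#' always `+`), the target assembly the `q` side, with `-`-strand
#' coordinates expressed on the reverse strand as the format requires.
#'
#' @param chains list of chains.
#' @param source,target the two `GenomeAssembly` objects (for sizes).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain_file <- function(chains, source, target, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    bl <- ch$blocks
    tName <- bl$tname_src[1]
    qName <- bl$tname_tgt[1]
    strand <- bl$strand[1]
    tSize <- source$lengths[[tName]]
    qSize <- target$lengths[[qName]]
    tStart <- min(bl$src_start0)
    tEnd <- max(bl$src_end0)
    if (strand == "+") {
      qStart <- min(bl$tgt_start0)
      qEnd <- max(bl$tgt_end0)
    } else {
      qStart <- qSize - max(bl$tgt_end0)
      qEnd <- qSize - min(bl$tgt_start0)
    }
    writeLines(sprintf("chain %d %s %d + %d %d %s %d %s %d %d %d",
                       as.integer(round(ch$score)), tName, tSize,
                       tStart, tEnd, qName, qSize, strand,
                       qStart, qEnd, ch$id), con)
    n <- nrow(bl)
    for (i in seq_len(n)) {
      size <- bl$src_end0[i] - bl$src_start0[i]
      if (i < n) {
        dt <- bl$src_start0[i + 1L] - bl$src_end0[i]
        dq <- if (strand == "+") {
          bl$tgt_start0[i + 1L] - bl$tgt_end0[i]
        } else {
          bl$tgt_start0[i] - bl$tgt_end0[i + 1L]
        }
        writeLines(sprintf("%d\t%d\t%d", size, dt, dq), con)
      } else {
        writeLines(sprintf("%d", size), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}
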