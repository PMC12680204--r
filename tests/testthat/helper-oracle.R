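# Independent brute-force local-alignment oracle, pure R.
# Scoring must mirror the package's scheme (match +1, mismatch -1, gap
# opening -1, free extension, N never matches) but the implementation
# is a full unseeded dynamic program, kept deliberately separate from
# the package's seeded/banded code path.
#
# With free gap extension the recurrences collapse: a gap state equals
# the running maximum of M over the gapped dimension minus the single
# opening cost, which allows a row-vectorised DP.
oracle_local_score <- function(query, target) {
  qb <- strsplit(query, "")[[1]]
  tb <- strsplit(target, "")[[1]]
  m <- length(qb)
  n <- length(tb)
  best <- 0
  Mprev <- rep(-Inf, n)          # M[i-1, ]
  bestAbovePrev <- rep(-Inf, n)  # max over rows <= i-2 of M[, j]
  for (i in seq_len(m)) {
    s <- ifelse(tb == qb[i] & qb[i] != "N" & tb != "N", 1, -1)
    cmPrev <- if (i == 1) rep(-Inf, n) else cummax(Mprev)
    opts_diag <- c(0, pmax(0,
      pmax(Mprev[-n], pmax(bestAbovePrev[-n] - 1,
                           c(-Inf, cmPrev[-c(n - 1, n)]) - 1))))
    if (n == 1) opts_diag <- 0
    Mrow <- s + pmax(0, opts_diag)
    best <- max(best, Mrow)
    bestAbovePrev <- pmax(bestAbovePrev, Mprev)
    Mprev <- Mrow
  }
  best
}

# plain cubic reference used once to validate the oracle itself
oracle_local_score_naive <- function(query, target) {
  qb <- strsplit(query, "")[[1]]
  tb <- strsplit(target, "")[[1]]
  m <- length(qb)
  n <- length(tb)
  M <- matrix(-Inf, m + 1, n + 1)
  QG <- matrix(-Inf, m + 1, n + 1)
  TG <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (qb[i - 1] == tb[j - 1] && qb[i - 1] != "N" &&
               tb[j - 1] != "N") 1 else -1
      M[i, j] <- s + max(0, M[i - 1, j - 1], QG[i - 1, j - 1],
                         TG[i - 1, j - 1])
      QG[i, j] <- max(M[i - 1, j] - 1, QG[i - 1, j])
      TG[i, j] <- max(M[i, j - 1] - 1, TG[i, j - 1])
      best <- max(best, M[i, j])
    }
  }
  best
}
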