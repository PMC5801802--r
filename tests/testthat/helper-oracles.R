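# Independent oracles used to check the implementation.

# Brute-force inverted-repeat search on a *linear* sequence: walks every
# anti-diagonal p + q = D and every mismatch-bounded window on it, so it
# visits every qualifying interval pair. Mismatch budget: a pair of
# intervals of length len qualifies when its mismatch count is at most
# frac * len. Ties resolved as the implementation documents: longest,
# then smallest first start, then smallest second start.
oracle_find_ir <- function(seq, min_len, frac) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- unname(c(A = "T", C = "G", G = "C", T = "A", N = "?")[s])
  n <- length(s)
  best <- NULL # c(a, b, len, mism)
  consider <- function(a, b, len, mism) {
    if (is.null(best)) {
      best <<- c(a, b, len, mism)
      return()
    }
    if (len > best[3] ||
      (len == best[3] && a < best[1]) ||
      (len == best[3] && a == best[1] && b < best[2])) {
      best <<- c(a, b, len, mism)
    }
  }
  for (D in 0:(2 * n - 2)) {
    p_lo <- max(0L, D - n + 1L)
    p_hi <- (D - 1L) %/% 2L
    width <- p_hi - p_lo + 1L
    if (width < min_len) next
    p <- p_lo:p_hi
    mm <- s[p + 1L] != comp[D - p + 1L]
    mp <- which(mm)
    ext <- c(0L, mp, width + 1L)
    cmax <- min(floor(frac * width), length(mp))
    for (cc in 0:cmax) {
      for (i in seq_len(length(mp) - cc + 1L)) {
        len <- ext[i + cc + 1L] - ext[i] - 1L
        if (len < min_len || cc > frac * len) next
        a <- p_lo + ext[i] # 0-based start of first interval
        b <- D - (a + len - 1L) # 0-based start of second interval
        consider(a, b, len, cc)
      }
    }
  }
  if (is.null(best)) {
    return(list(found = FALSE))
  }
  list(
    found = TRUE,
    first = c(start = best[1], len = best[3]),
    second = c(start = best[2], len = best[3]),
    mismatch_count = best[4]
  )
}

# Leftmost string-equivalent position (0-based) of deleting `dl` bases at
# 0-based offset `off` from `s`: slides left while the removal yields the
# same string.
leftmost_del_off <- function(s, off, dl) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  while (off > 0 && ch[off] == ch[off + dl]) off <- off - 1L
  off
}

# Score-only affine-gap global alignment by direct dynamic programming
# over the three Gotoh matrices; no traceback, no tie logic.
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -8, gap_ext = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(
        M[i - 1, j] + gap_open + gap_ext,
        X[i - 1, j] + gap_ext,
        Y[i - 1, j] + gap_open + gap_ext
      )
      Y[i, j] <- max(
        M[i, j - 1] + gap_open + gap_ext,
        X[i, j - 1] + gap_open + gap_ext,
        Y[i, j - 1] + gap_ext
      )
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}
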