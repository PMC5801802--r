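## arcs on the circle are c(start = 0-based, len = bp); they may wrap

arc <- function(start, len) {
  c(start = as.integer(start), len = as.integer(len))
}

arc_positions <- function(a, genome_length) {
  if (a[["len"]] == 0L) {
    return(integer())
  }
  (a[["start"]] + seq_len(a[["len"]]) - 1L) %% genome_length
}

arcs_disjoint <- function(a, b, genome_length) {
  if (a[["len"]] == 0L || b[["len"]] == 0L) {
    return(TRUE)
  }
  d1 <- (b[["start"]] - a[["start"]]) %% genome_length
  d2 <- (a[["start"]] - b[["start"]]) %% genome_length
  d1 >= a[["len"]] && d2 >= b[["len"]]
}

arc_contains <- function(a, pos, genome_length) {
  a[["len"]] > 0L && ((pos - a[["start"]]) %% genome_length) < a[["len"]]
}

new_quadripartite <- function(lsc, ssc, ir_a, ir_b, mismatch_count,
                              genome_length) {
  x <- structure(
    list(
      lsc = lsc, ssc = ssc, ir_a = ir_a, ir_b = ir_b,
      mismatch_count = as.integer(mismatch_count),
      genome_length = as.integer(genome_length)
    ),
    class = "quadripartite"
  )
  total <- lsc[["len"]] + ssc[["len"]] + 2L * ir_a[["len"]]
  if (total != genome_length) {
    stop(
      "quadripartite regions do not compose to the genome length (",
      total, " != ", genome_length, ")",
      call. = FALSE
    )
  }
  if (ir_a[["len"]] != ir_b[["len"]]) {
    stop("inverted repeat arms differ in length", call. = FALSE)
  }
  if (lsc[["len"]] < ssc[["len"]]) {
    stop("LSC shorter than SSC", call. = FALSE)
  }
  x
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<quadripartite> %s bp: LSC %s bp @%d | IRa %s bp @%d | ",
      "SSC %s bp @%d | IRb %s bp @%d | arm mismatches %d\n"
    ),
    format(x$genome_length, big.mark = ","),
    format(x$lsc[["len"]], big.mark = ","), x$lsc[["start"]],
    format(x$ir_a[["len"]], big.mark = ","), x$ir_a[["start"]],
    format(x$ssc[["len"]], big.mark = ","), x$ssc[["start"]],
    format(x$ir_b[["len"]], big.mark = ","), x$ir_b[["start"]],
    x$mismatch_count
  ))
  invisible(x)
}

#' Tidy a quadripartite structure into a region table
#'
#' @param x A `quadripartite` object.
#' @param ... Unused.
#' @return A tibble with one row per region (`LSC`, `IRa`, `SSC`, `IRb`)
#'   and 1-based inclusive `start`/`end` output coordinates alongside the
#'   0-based internal `start0`.
#' @export
tidy.quadripartite <- function(x, ...) {
  regions <- list(LSC = x$lsc, IRa = x$ir_a, SSC = x$ssc, IRb = x$ir_b)
  tibble(
    region = names(regions),
    start0 = vapply(regions, `[[`, 0L, "start"),
    length = vapply(regions, `[[`, 0L, "len"),
    start = vapply(regions, `[[`, 0L, "start") + 1L,
    end = vapply(regions, function(a) {
      ((a[["start"]] + a[["len"]] - 1L) %% x$genome_length) + 1L
    }, 0L)
  )
}

#' One-row summary of a quadripartite structure
#'
#' @param x A `quadripartite` object.
#' @param ... Unused.
#' @return A one-row tibble with region lengths, the composition total and
#'   arm mismatch count.
#' @export
glance.quadripartite <- function(x, ...) {
  tibble(
    genome_length = x$genome_length,
    lsc_len = x$lsc[["len"]],
    ssc_len = x$ssc[["len"]],
    ir_len = x$ir_a[["len"]],
    composed_length = x$lsc[["len"]] + x$ssc[["len"]] + 2L * x$ir_a[["len"]],
    arm_mismatches = x$mismatch_count
  )
}

## maximal windows with a proportional mismatch budget along one
## anti-diagonal. mism: logical vector over p = p_lo..p_hi. Returns a data
## frame of candidate windows (local 0-based offset a within p_lo..p_hi,
## len, mismatches).
budget_windows <- function(mism, min_len, max_mismatch_frac, max_len) {
  n <- length(mism)
  if (n < min_len) {
    return(NULL)
  }
  mpos <- which(mism) # 1-based within the diagonal slice
  cmax <- floor(max_mismatch_frac * min(n, max_len))
  cmax <- min(cmax, length(mpos))
  ext <- c(0L, mpos, n + 1L)
  out <- vector("list", cmax + 1L)
  for (c in 0:cmax) {
    k <- length(mpos)
    i <- seq_len(k - c + 1L) # left sentinel index into ext
    lens <- ext[i + c + 1L] - ext[i] - 1L
    starts <- ext[i] + 1L
    keep <- lens >= min_len & c <= max_mismatch_frac * pmin(lens, max_len)
    if (!any(keep)) next
    lens <- pmin(lens[keep], max_len)
    out[[c + 1L]] <- data.frame(a = starts[keep], len = lens, mismatches = c)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(NULL)
  }
  do.call(rbind, out)
}

#' Find the inverted-repeat pair of a circular genome
#'
#' Searches the genome against its own reverse complement for the
#' maximal-length pair of disjoint arcs `(IRa, IRb)` such that the first
#' arc equals the reverse complement of the second with at most
#' `max_mismatch_frac * length` mismatches. The search anchors exact
#' 21-mers between the doubled sequence and its reverse complement, then
#' scans every anchored anti-diagonal for the longest window satisfying
#' the mismatch budget, so arcs may wrap the origin. Ties on length are
#' broken toward the pair whose first arc starts at the smallest
#' coordinate.
#'
#' @param x A [plastome].
#' @param min_len Minimum arm length in bp (>= 50).
#' @param max_mismatch_frac Maximum mismatch fraction between the two arms
#'   (0 to 0.02). Plastome arms are kept virtually identical by gene
#'   conversion, so the default is 0.5%.
#' @return An object of class `ir_pair`: list with `found` (logical),
#'   `first` and `second` arcs (`start`, `len`), and `mismatch_count`.
#'   When no qualifying pair exists, `found` is `FALSE` (a valid outcome
#'   for plastomes that have lost one repeat copy).
#' @export
find_inverted_repeat <- function(x, min_len = 1000L, max_mismatch_frac = 0.005) {
  stopifnot(inherits(x, "plastome"))
  if (min_len < 50L) {
    stop("min_len must be >= 50", call. = FALSE)
  }
  if (max_mismatch_frac < 0 || max_mismatch_frac > 0.02) {
    stop("max_mismatch_frac must be in [0, 0.02]", call. = FALSE)
  }
  L <- x$length
  no_ir <- structure(
    list(found = FALSE, first = NULL, second = NULL, mismatch_count = NA_integer_),
    class = "ir_pair"
  )
  if (L < 2L * min_len) {
    return(no_ir)
  }
  k <- 21L
  s2str <- paste0(x$sequence, x$sequence)
  r2str <- revcomp(s2str)
  n2 <- 2L * L
  starts <- seq_len(n2 - k + 1L)
  fw <- substring(s2str, starts, starts + k - 1L)
  rc <- substring(r2str, starts, starts + k - 1L)
  ## drop hyper-repetitive k-mers to bound the join
  fw_tab <- table(fw)
  busy <- names(fw_tab)[fw_tab > 16L]
  rc_idx <- split(seq_along(rc), rc)
  rc_idx <- rc_idx[!names(rc_idx) %in% busy]
  hit <- fw %in% names(rc_idx)
  if (!any(hit)) {
    return(no_ir)
  }
  i0 <- which(hit) - 1L # 0-based forward positions
  matches <- rc_idx[fw[hit]]
  reps <- lengths(matches)
  diags <- unique(rep(i0, reps) + n2 - (unlist(matches, use.names = FALSE) - 1L) - 1L)
  s2 <- seq_to_int(s2str)
  c2 <- comp_int(s2)
  max_len <- L %/% 2L
  cand <- vector("list", length(diags))
  for (di in seq_along(diags)) {
    D <- diags[[di]]
    p_lo <- max(0L, D - (n2 - 1L))
    p_hi <- (D - 1L) %/% 2L
    if (p_hi - p_lo + 1L < min_len) next
    p <- p_lo:p_hi
    mism <- s2[p + 1L] != c2[D - p + 1L] | s2[p + 1L] == 0L
    win <- budget_windows(mism, min_len, max_mismatch_frac, max_len)
    if (is.null(win)) next
    win$start1 <- p_lo + win$a - 1L # 0-based start of first interval in s2
    win$D <- D
    cand[[di]] <- win
  }
  cand <- cand[!vapply(cand, is.null, TRUE)]
  if (length(cand) == 0L) {
    return(no_ir)
  }
  cand <- do.call(rbind, cand)
  ## map to circular arcs; first arc = smaller canonical start
  a1 <- cand$start1 %% L
  a2 <- (cand$D - (cand$start1 + cand$len - 1L)) %% L
  first <- pmin(a1, a2)
  second <- pmax(a1, a2)
  key <- paste(first, second, cand$len)
  keep <- !duplicated(key)
  cand <- cand[keep, , drop = FALSE]
  first <- first[keep]
  second <- second[keep]
  ord <- order(-cand$len, first, second)
  for (idx in ord) {
    A <- arc(first[idx], cand$len[idx])
    B <- arc(second[idx], cand$len[idx])
    if (arcs_disjoint(A, B, L)) {
      mm <- count_arm_mismatches(x, A, B)
      return(structure(
        list(found = TRUE, first = A, second = B, mismatch_count = mm),
        class = "ir_pair"
      ))
    }
  }
  no_ir
}

count_arm_mismatches <- function(x, a, b) {
  sa <- seq_to_int(arc_seq(x, a[["start"]], a[["len"]]))
  sb <- seq_to_int(arc_seq(x, b[["start"]], b[["len"]]))
  sb_rc <- rev(comp_int(sb))
  sum(sa != sb_rc | sa == 0L)
}

#' @export
print.ir_pair <- function(x, ...) {
  if (!x$found) {
    cat("<ir_pair> no IR found\n")
  } else {
    cat(sprintf(
      "<ir_pair> arms %s bp at %d and %d (%d mismatches)\n",
      format(x$first[["len"]], big.mark = ","),
      x$first[["start"]], x$second[["start"]], x$mismatch_count
    ))
  }
  invisible(x)
}

#' Derive the quadripartite partition from an inverted-repeat pair
#'
#' The two arcs between the repeat arms become the single-copy regions:
#' the longer is the LSC, the shorter the SSC. If the two arcs tie in
#' length the arc containing coordinate 0 is taken as the LSC, with a
#' warning. `IRa` is the arm that follows the LSC on the circle.
#'
#' @param x A [plastome].
#' @param ir_pair An `ir_pair` from [find_inverted_repeat()], or a list
#'   with `first`/`second` arcs.
#' @return A `quadripartite` object.
#' @export
partition_quadripartite <- function(x, ir_pair) {
  stopifnot(inherits(x, "plastome"))
  if (inherits(ir_pair, "ir_pair") && !isTRUE(ir_pair$found)) {
    stop("no inverted repeat to partition on", call. = FALSE)
  }
  A <- ir_pair$first
  B <- ir_pair$second
  L <- x$length
  if (A[["len"]] != B[["len"]]) {
    stop("inverted repeat arms must have equal length", call. = FALSE)
  }
  if (!arcs_disjoint(A, B, L)) {
    stop("inverted repeat arms overlap", call. = FALSE)
  }
  gap1 <- arc((A[["start"]] + A[["len"]]) %% L,
    (B[["start"]] - A[["start"]] - A[["len"]]) %% L
  )
  gap2 <- arc((B[["start"]] + B[["len"]]) %% L,
    (A[["start"]] - B[["start"]] - B[["len"]]) %% L
  )
  if (gap1[["len"]] > gap2[["len"]]) {
    lsc <- gap1
    ssc <- gap2
  } else if (gap2[["len"]] > gap1[["len"]]) {
    lsc <- gap2
    ssc <- gap1
  } else {
    warning("single-copy arcs tie in length; LSC set to the arc containing coordinate 0")
    if (arc_contains(gap1, 0L, L)) {
      lsc <- gap1
      ssc <- gap2
    } else {
      lsc <- gap2
      ssc <- gap1
    }
  }
  ## IRa is the arm that follows the LSC
  after_lsc <- (lsc[["start"]] + lsc[["len"]]) %% L
  if (A[["start"]] == after_lsc) {
    ir_a <- A
    ir_b <- B
  } else {
    ir_a <- B
    ir_b <- A
  }
  mm <- if (inherits(ir_pair, "ir_pair") && !is.na(ir_pair$mismatch_count)) {
    ir_pair$mismatch_count
  } else {
    count_arm_mismatches(x, A, B)
  }
  new_quadripartite(lsc, ssc, ir_a, ir_b, mm, L)
}

#' Detect the quadripartite structure of a plastome
#'
#' Convenience wrapper running [find_inverted_repeat()] and
#' [partition_quadripartite()].
#'
#' @inheritParams find_inverted_repeat
#' @return A `quadripartite` object, or `NULL` when no repeat is found.
#' @export
detect_structure <- function(x, min_len = 1000L, max_mismatch_frac = 0.005) {
  pair <- find_inverted_repeat(x, min_len, max_mismatch_frac)
  if (!pair$found) {
    return(NULL)
  }
  partition_quadripartite(x, pair)
}
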