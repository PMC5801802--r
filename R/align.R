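#' Globally align a target coding sequence to its functional reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties (Gotoh
#' three-state dynamic programming, compiled). A gap of length L costs
#' `gap_open + L * gap_ext`. Tie-breaking is deterministic: a mismatch is
#' preferred over a gap, a gap in the target over a gap in the reference,
#' and equal-scoring gaps are placed leftmost.
#'
#' @param target_nt Target coding sequence (5' to 3' spliced nucleotides).
#'   An empty target is an absence signal: the function returns `NULL`.
#' @param reference_nt Reference coding sequence from the functional
#'   outgroup copy; must be a whole number of codons, start with `ATG` and
#'   end with a stop codon.
#' @param gene,species Labels carried into the result.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters
#'   (defaults +2, -3, -8, -2).
#' @return A `cds_alignment` object: list with `gene`, `species`,
#'   `ref_aln`/`tgt_aln` (gapped strings), `score`, `ref_length_nt` and
#'   `coverage_frac` (fraction of reference positions with aligned target
#'   bases). `NULL` when `target_nt` is empty.
#' @export
align_cds <- function(target_nt, reference_nt, gene = NA_character_,
                      species = NA_character_, match = 2L, mismatch = -3L,
                      gap_open = -8L, gap_ext = -2L) {
  reference_nt <- toupper(reference_nt)
  if (nchar(reference_nt) %% 3L != 0L) {
    stop("reference CDS length is not a multiple of 3", call. = FALSE)
  }
  if (substr(reference_nt, 1L, 3L) != "ATG") {
    stop("reference CDS does not start with ATG", call. = FALSE)
  }
  last <- substr(reference_nt, nchar(reference_nt) - 2L, nchar(reference_nt))
  if (!last %in% STOP_CODONS) {
    stop("reference CDS does not end with a stop codon", call. = FALSE)
  }
  if (is.null(target_nt) || is.na(target_nt) || nchar(target_nt) == 0L) {
    return(NULL)
  }
  target_nt <- toupper(target_nt)
  res <- .align_affine_cpp(
    reference_nt, target_nt,
    as.integer(match), as.integer(mismatch),
    as.integer(gap_open), as.integer(gap_ext)
  )
  rchars <- strsplit(res$ref_aln, "", fixed = TRUE)[[1]]
  tchars <- strsplit(res$tgt_aln, "", fixed = TRUE)[[1]]
  cov <- sum(rchars != "-" & tchars != "-") / nchar(reference_nt)
  structure(
    list(
      gene = gene,
      species = species,
      ref_aln = res$ref_aln,
      tgt_aln = res$tgt_aln,
      score = res$score,
      ref_length_nt = nchar(reference_nt),
      coverage_frac = cov
    ),
    class = "cds_alignment"
  )
}

#' @export
print.cds_alignment <- function(x, ...) {
  cat(sprintf(
    "<cds_alignment> %s / %s: score %g, reference %d nt, coverage %.2f\n",
    x$gene, x$species, x$score, x$ref_length_nt, x$coverage_frac
  ))
  invisible(x)
}

#' Tidy an alignment into one row per column
#'
#' @param x A `cds_alignment`.
#' @param ... Unused.
#' @return A tibble with column index, aligned bases and running 1-based
#'   reference/target positions (`NA` at gaps).
#' @export
tidy.cds_alignment <- function(x, ...) {
  r <- strsplit(x$ref_aln, "", fixed = TRUE)[[1]]
  t <- strsplit(x$tgt_aln, "", fixed = TRUE)[[1]]
  tibble(
    column = seq_along(r),
    ref_base = r,
    tgt_base = t,
    ref_pos = ifelse(r == "-", NA_integer_, cumsum(r != "-")),
    tgt_pos = ifelse(t == "-", NA_integer_, cumsum(t != "-"))
  )
}

#' One-row alignment summary
#'
#' @param x A `cds_alignment`.
#' @param ... Unused.
#' @return A one-row tibble with score, lengths and coverage.
#' @export
glance.cds_alignment <- function(x, ...) {
  tibble(
    gene = x$gene,
    species = x$species,
    score = x$score,
    ref_length_nt = x$ref_length_nt,
    target_length_nt = nchar(gsub("-", "", x$tgt_aln, fixed = TRUE)),
    coverage_frac = x$coverage_frac
  )
}
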