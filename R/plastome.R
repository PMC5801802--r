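#' @useDynLib plastomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a circular plastome object
#'
#' A plastome is a circular nucleotide sequence with an identifier. The
#' sequence is stored uppercase over the alphabet `A`, `C`, `G`, `T`, `N`;
#' `U` is mapped to `T` on construction so RNA-alphabet inputs are
#' tolerated.
#'
#' @param sequence Single character string, the genome sequence.
#' @param id Text label for the genome.
#' @return An object of class `plastome`: a list with elements `id`,
#'   `sequence` and `length`.
#' @examples
#' p <- plastome("atgcatgcat", id = "toy")
#' p$length
#' @export
plastome <- function(sequence, id = "plastome") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- chartr("u", "t", sequence)
  seq <- toupper(chartr("U", "T", seq))
  if (nchar(seq) == 0L) {
    stop("plastome sequence is empty", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(
      "illegal characters in sequence: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(id = id, sequence = seq, length = nchar(seq)),
    class = "plastome"
  )
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf(
    "<plastome> %s: %s bp circular\n", x$id, format(x$length, big.mark = ",")
  ))
  invisible(x)
}

#' Read a single-record FASTA file as a plastome
#'
#' @param fasta_path Path to a FASTA file holding exactly one record.
#' @return A [plastome] object named after the FASTA header.
#' @export
load_plastome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("file not found: ", fasta_path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) != 1L) {
    stop(
      sprintf("expected 1 record, found %d in %s", length(set), fasta_path),
      call. = FALSE
    )
  }
  plastome(as.character(set[[1]]), id = names(set)[1])
}

#' Write a plastome to FASTA
#'
#' @param x A [plastome].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plastome <- function(x, path) {
  stopifnot(inherits(x, "plastome"))
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character string over A/C/G/T/N.
#' @return The reverse complement, same case.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## integer encoding used by the repeat finder: A=1 C=2 G=3 T=4 N=0
seq_to_int <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  m[is.na(m)] <- 0L
  as.integer(m)
}

## complement in integer code; N (0) complements to 0 and never matches
comp_int <- function(x) {
  out <- integer(length(x))
  out[x == 1L] <- 4L
  out[x == 2L] <- 3L
  out[x == 3L] <- 2L
  out[x == 4L] <- 1L
  out
}

#' Rotate a circular plastome
#'
#' Rotates the sequence so that the base at 0-based position `offset`
#' becomes position 0. Rotating by `offset` and then by `-offset` restores
#' the original sequence; length and base composition are preserved.
#'
#' @param x A [plastome].
#' @param offset Integer rotation, interpreted modulo genome length.
#' @return A rotated [plastome].
#' @export
rotate_plastome <- function(x, offset) {
  stopifnot(inherits(x, "plastome"))
  off <- ((as.integer(offset)) %% x$length + x$length) %% x$length
  if (off == 0L) {
    return(x)
  }
  seq <- paste0(
    substr(x$sequence, off + 1L, x$length),
    substr(x$sequence, 1L, off)
  )
  plastome(seq, id = x$id)
}

#' Extract an arc of a circular sequence
#'
#' @param x A [plastome] or character sequence.
#' @param start 0-based start position of the arc.
#' @param len Arc length in bp; the arc may wrap the origin.
#' @return Character string of length `len`.
#' @export
arc_seq <- function(x, start, len) {
  seq <- if (inherits(x, "plastome")) x$sequence else x
  n <- nchar(seq)
  stopifnot(len >= 0L, len <= n)
  if (len == 0L) {
    return("")
  }
  start <- ((as.integer(start)) %% n + n) %% n
  end <- start + len
  if (end <= n) {
    substr(seq, start + 1L, end)
  } else {
    paste0(substr(seq, start + 1L, n), substr(seq, 1L, end - n))
  }
}

#' Canonicalize a plastome presentation
#'
#' Rotates the genome so that the LSC starts at position 0 and is followed
#' by the first inverted-repeat arm (IRa), then the SSC, then IRb — the
#' standard presentation for plastome coordinates. The returned `offset` is
#' the 0-based position in the input genome that becomes position 0; shift
#' feature coordinates with [shift_features()] using the same offset.
#'
#' @param x A [plastome].
#' @param structure A `quadripartite` structure for `x` (see
#'   [partition_quadripartite()]).
#' @return List with elements `plastome` (rotated), `structure`
#'   (recomputed for the rotated genome) and `offset`.
#' @export
canonicalize <- function(x, structure) {
  stopifnot(inherits(x, "plastome"), inherits(structure, "quadripartite"))
  if (structure$genome_length != x$length) {
    stop("structure does not match plastome length", call. = FALSE)
  }
  off <- structure$lsc[["start"]]
  rot <- rotate_plastome(x, off)
  shift_arc <- function(a) {
    c(
      start = ((a[["start"]] - off) %% x$length + x$length) %% x$length,
      len = a[["len"]]
    )
  }
  new_structure <- new_quadripartite(
    lsc = shift_arc(structure$lsc),
    ssc = shift_arc(structure$ssc),
    ir_a = shift_arc(structure$ir_a),
    ir_b = shift_arc(structure$ir_b),
    mismatch_count = structure$mismatch_count,
    genome_length = x$length
  )
  list(plastome = rot, structure = new_structure, offset = as.integer(off))
}

#' Shift feature coordinates after a rotation
#'
#' @param features Feature table (see [load_features()]).
#' @param offset The rotation offset returned by [canonicalize()].
#' @param genome_length Genome length in bp.
#' @return The feature table with `start`/`end` shifted modulo the genome.
#' @export
shift_features <- function(features, offset, genome_length) {
  n <- genome_length
  off <- ((as.integer(offset)) %% n + n) %% n
  dplyr::mutate(
    features,
    start = (.data$start - off) %% n,
    end = (.data$end - off - 1L) %% n + 1L
  )
}
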