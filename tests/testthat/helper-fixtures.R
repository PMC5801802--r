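# Fixture builders shared across test files.

BASES <- c("A", "C", "G", "T")

rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

comp1 <- function(x) chartr("ACGT", "TGCA", x)

# A genome with one planted inverted repeat:
#   flank_a | R | spacer | revcomp(R) | flank_c
# The four bases adjacent to the planted arms are chosen non-complementary
# to their partners so the repeat cannot extend by chance and the planted
# coordinates are exactly maximal.
planted_ir_genome <- function(flank_a = 100, arm = 80, spacer = 60,
                              flank_c = 80) {
  repeat {
    A <- rand_bases(flank_a)
    R <- rand_bases(arm)
    B <- rand_bases(spacer)
    C <- rand_bases(flank_c)
    seq <- paste0(A, R, B, revcomp(R), C)
    # outer guard: base before R vs base after revcomp(R)
    left_out <- substr(A, flank_a, flank_a)
    right_out <- substr(C, 1, 1)
    # inner guard: base after R vs base before revcomp(R)
    left_in <- substr(B, 1, 1)
    right_in <- substr(B, spacer, spacer)
    if (left_out != comp1(right_out) && left_in != comp1(right_in)) {
      return(list(
        seq = seq,
        first = c(start = flank_a, len = arm),
        second = c(start = flank_a + arm + spacer, len = arm)
      ))
    }
  }
}

# Random protein CDS: ATG + non-stop codons + TAA, total length nt.
random_cds <- function(len_nt) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 9)
  mid <- character(len_nt / 3 - 2)
  for (i in seq_along(mid)) {
    repeat {
      cd <- rand_bases(3)
      if (!cd %in% c("TAA", "TAG", "TGA")) break
    }
    mid[i] <- cd
  }
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}

# Remove `len` bases starting at codon `k` (1-based) from a CDS.
delete_at_codon <- function(cds, k, len) {
  off <- 3 * (k - 1)
  paste0(substr(cds, 1, off), substr(cds, off + len + 1, nchar(cds)))
}

# Insert `bases` immediately before codon `k`.
insert_at_codon <- function(cds, k, bases) {
  off <- 3 * (k - 1)
  paste0(substr(cds, 1, off), bases, substr(cds, off + 1, nchar(cds)))
}

# Replace codon `k` with `codon`.
replace_codon <- function(cds, k, codon) {
  off <- 3 * (k - 1)
  paste0(substr(cds, 1, off), codon, substr(cds, off + 4, nchar(cds)))
}

# Small feature table on a toy genome.
toy_features <- function(genome_length = 400) {
  gene_features(
    gene = c("geneA", "geneB", "geneB2"),
    feature_class = c("protein", "tRNA", "tRNA"),
    strand = c("+", "-", "+"),
    exon = c(1L, 1L, 1L),
    start = c(10L, 200L, 300L),
    end = c(100L, 275L, 375L),
    feature_id = c(1L, 2L, 3L),
    genome_length = genome_length
  )
}

# Quick simulation used by several files; cached per session.
cached_sim <- local({
  sim <- NULL
  function(seed = 11) {
    if (is.null(sim)) {
      sim <<- simulate_plastomes(sim_config(seed = seed))
    }
    sim
  }
})
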