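test_that("FASTA loading normalizes case and maps U to T", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toy", "atgcaugcat"), f)
  p <- load_plastome(f)
  expect_s3_class(p, "plastome")
  expect_equal(p$length, 10L)
  expect_equal(p$sequence, "ATGCATGCAT")
})

test_that("FASTA preconditions are enforced with informative errors", {
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), f2)
  expect_error(load_plastome(f2), "expected 1 record, found 2")
  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGX"), f3)
  expect_error(load_plastome(f3), "X")
  expect_error(plastome(""), "empty")
})

test_that("plastome round-trips through FASTA", {
  set.seed(1)
  p <- plastome(rand_bases(257), id = "rt")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_plastome(p, f)
  q <- load_plastome(f)
  expect_equal(q$sequence, p$sequence)
  expect_equal(q$id, "rt")
})

test_that("feature TSV converts 1-based inclusive ranges to internal coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    c(
      "name\tclass\tstrand\texons",
      "ndhA\tprotein\t+\t100-639,1740-2292",
      "trnH\ttRNA\t-\t5-80"
    ),
    f
  )
  feats <- load_features(f, genome_length = 3000L)
  ndhA <- feats[feats$gene == "ndhA", ]
  expect_equal(ndhA$start, c(99L, 1739L))
  expect_equal(ndhA$end, c(639L, 2292L))
  trnH <- feats[feats$gene == "trnH", ]
  expect_equal(trnH$feature_class, "tRNA")
  expect_equal(trnH$strand, "-")
  expect_equal(c(trnH$start, trnH$end), c(4L, 80L))
})

test_that("feature validation rejects bad inputs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    c("name\tclass\tstrand\texons", "tiny\tprotein\t+\t10-11"),
    f
  )
  expect_error(load_features(f, 100L), "shorter than one codon")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    c("name\tclass\tstrand\texons", "geneZ\tweird\t+\t10-60"),
    f2
  )
  expect_error(load_features(f2, 100L), "unknown feature class")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    c("name\tclass\tstrand\texons", "geneZ\ttRNA\t+\t10-150"),
    f3
  )
  expect_error(load_features(f3, 100L), "wrap")
})

test_that("feature tables round-trip through the TSV dialect", {
  feats <- toy_features()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features(feats, f)
  back <- load_features(f, 400L)
  expect_equal(
    back[, c("gene", "feature_class", "strand", "exon", "start", "end")],
    feats[, c("gene", "feature_class", "strand", "exon", "start", "end")]
  )
})

test_that("rotation preserves length and composition and round-trips", {
  set.seed(2)
  p <- plastome(rand_bases(300))
  q <- rotate_plastome(p, 123L)
  expect_equal(q$length, p$length)
  expect_equal(
    sort(strsplit(q$sequence, "")[[1]]),
    sort(strsplit(p$sequence, "")[[1]])
  )
  back <- rotate_plastome(q, -123L)
  expect_equal(back$sequence, p$sequence)
})

test_that("canonicalize rotates the LSC to position 0 and shifts features consistently", {
  g <- planted_ir_genome(flank_a = 150, arm = 80, spacer = 60, flank_c = 110)
  p <- plastome(g$seq, id = "toy")
  str0 <- partition_quadripartite(
    p,
    list(first = g$first, second = g$second)
  )
  rot <- rotate_plastome(p, 37L)
  ir <- find_inverted_repeat(rot, min_len = 50, max_mismatch_frac = 0)
  str_rot <- partition_quadripartite(rot, ir)
  can <- canonicalize(rot, str_rot)
  expect_equal(can$structure$lsc[["start"]], 0L)
  expect_equal(can$plastome$length, p$length)
  # region lengths unchanged by rotation
  expect_equal(can$structure$lsc[["len"]], str0$lsc[["len"]])
  expect_equal(can$structure$ir_a[["len"]], str0$ir_a[["len"]])
  # a feature's sequence is invariant under rotation + coordinate shift
  feats <- gene_features(
    gene = "marker", feature_class = "tRNA", strand = "+",
    exon = 1L, start = 100L, end = 170L, genome_length = p$length
  )
  rot_feats <- shift_features(feats, 37L, p$length) # feature coords on `rot`
  shifted <- shift_features(rot_feats, can$offset, p$length)
  expect_equal(
    get_cds(can$plastome, shifted, 1L),
    get_cds(p, feats, 1L)
  )
})

test_that("canonicalizing an already canonical genome is the identity", {
  sim <- cached_sim()
  anc <- generate_ancestor(sim$config)
  can <- canonicalize(anc$plastome, anc$structure)
  expect_equal(can$offset, 0L)
  expect_equal(can$plastome$sequence, anc$plastome$sequence)
})
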