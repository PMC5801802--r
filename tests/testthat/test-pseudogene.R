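test_that("identical sequences align gap-free with full coverage", {
  set.seed(201)
  cds <- random_cds(300)
  aln <- align_cds(cds, cds, gene = "g", species = "s")
  expect_equal(aln$ref_aln, cds)
  expect_equal(aln$tgt_aln, cds)
  expect_equal(aln$coverage_frac, 1.0)
  expect_equal(aln$score, 2 * 300)
})

test_that("a single deleted base is placed as one leftmost gap in its homopolymer", {
  # reference contains an AAAA homopolymer at nt 7..10
  ref <- paste0("ATG", "CCG", "AAA", "ACC", "GGT", "TAA")
  tgt <- paste0("ATGCCG", "AAA", "CCGGTTAA") # one A removed
  aln <- align_cds(tgt, ref)
  gaps <- gregexpr("-", aln$tgt_aln, fixed = TRUE)[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(as.integer(gaps), 7L) # first position of the homopolymer
  expect_equal(gsub("-", "", aln$tgt_aln), tgt)
  expect_equal(aln$ref_aln, ref)
})

test_that("alignment score equals the exhaustive DP oracle on random pairs", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    m <- sample(10:60, 1)
    a <- rand_bases(n)
    b <- rand_bases(m)
    got <- plastomics:::.align_affine_cpp(a, b, 2L, -3L, -8L, -2L)$score
    expect_equal(got, oracle_align_score(a, b), info = paste("pair", i))
  }
})

test_that("alignment preconditions are enforced and empty target signals absence", {
  expect_error(align_cds("ATG", "ATGAA"), "multiple of 3")
  expect_error(align_cds("ATG", "CCCTAA"), "start with ATG")
  expect_error(align_cds("ATG", "ATGCCC"), "stop codon")
  expect_null(align_cds("", "ATGTAA"))
  expect_null(align_cds(NULL, "ATGTAA"))
})

test_that("a 1-bp deletion in codon 2 emits one frameshift at amino acid 2", {
  ref <- "ATGAAACCCGGGTGA"
  tgt <- delete_at_codon(ref, 2, 1)
  aln <- align_cds(tgt, ref)
  fs <- scan_frameshifts(aln)
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$kind, "FS")
  expect_equal(fs$aa_ref, 2L)
  expect_match(fs$change, "^del 1 nt @ ref nt [4-6]$")
})

test_that("in-frame indels emit no frameshift", {
  ref <- "ATGAAACCCGGGTGA"
  tgt <- delete_at_codon(ref, 3, 3)
  aln <- align_cds(tgt, ref)
  expect_equal(nrow(scan_frameshifts(aln)), 0L)
})

test_that("compensating indels emit two frameshifts and restore the frame", {
  set.seed(203)
  repeat { # pick a reference where the deletion site cannot left-shift
    ref <- random_cds(60) # 20 codons
    if (leftmost_del_off(ref, 24L, 1L) == 24L) break
  }
  ins_base <- setdiff(BASES, substr(ref, 12, 12))[1]
  tgt <- delete_at_codon(ref, 9, 1) # -1 at codon 9
  tgt <- insert_at_codon(tgt, 5, ins_base) # +1 at codon 5 (upstream)
  aln <- align_cds(tgt, ref)
  fs <- scan_frameshifts(aln)
  expect_equal(nrow(fs), 2L)
  expect_equal(sort(fs$aa_ref), c(5L, 9L))
  expect_equal(fs$frame_state[order(fs$aa_ref)], c(0L, 1L))
  # net indel sums to zero: frame restored after the second event
  expect_equal(sum(fs$indel_net), 0L)
})

test_that("an in-frame stop-gain substitution is reported and not frameshift-induced", {
  ref <- "ATGGAAGAATGA"
  tgt <- "ATGTAAGAATGA"
  aln <- align_cds(tgt, ref)
  sc <- scan_stops(aln, scan_frameshifts(aln))
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$aa_ref, 2L)
  expect_equal(sc$aa_target, 2L)
  expect_false(sc$frameshift_induced)
  expect_equal(sc$change, "SC @ ref nt 4 codon TAA")
})

test_that("an identical target yields no stop calls", {
  set.seed(204)
  cds <- random_cds(120)
  aln <- align_cds(cds, cds)
  expect_equal(nrow(scan_stops(aln, scan_frameshifts(aln))), 0L)
})

test_that("stops downstream of an uncompensated frameshift are flagged induced", {
  # deleting 1 nt in codon 2 shifts the frame so the target reads
  # ATG AAC TGA ...: an out-of-frame stop right after the frameshift
  ref <- paste0("ATG", "AAA", "CTG", "AGT", "TGG", "AGA", "TGA")
  tgt <- delete_at_codon(ref, 2, 1)
  aln <- align_cds(tgt, ref)
  fs <- scan_frameshifts(aln)
  sc <- scan_stops(aln, fs)
  expect_equal(nrow(fs), 1L)
  if (nrow(sc) > 0) {
    expect_true(all(sc$frameshift_induced))
  }
  # shifted frame of the target reads ...TGA... after the deletion
  expect_gte(nrow(sc), 1L)
})

test_that("the reference terminal stop and beyond are never premature", {
  set.seed(205)
  cds <- random_cds(60)
  # target identical: its terminal TAA aligns to the reference terminal codon
  aln <- align_cds(cds, cds)
  expect_equal(nrow(scan_stops(aln)), 0L)
  # target extended beyond the reference terminus with an extra stop codon
  tgt <- paste0(cds, "TAA")
  aln2 <- align_cds(tgt, cds)
  expect_equal(nrow(scan_stops(aln2)), 0L)
})

test_that("planted indels are detected iff their length is not a multiple of 3", {
  set.seed(206)
  cds <- random_cds(300) # 100 codons
  for (L in 1:6) {
    for (k in c(2L, 17L, 50L)) {
      tgt <- delete_at_codon(cds, k, L)
      aln <- align_cds(tgt, cds)
      fs <- scan_frameshifts(aln)
      if (L %% 3 == 0) {
        expect_equal(nrow(fs), 0L, info = paste("L", L, "k", k))
      } else {
        expect_equal(nrow(fs), 1L, info = paste("L", L, "k", k))
        # the gap lands at the leftmost string-equivalent position
        off_norm <- leftmost_del_off(cds, 3L * (k - 1L), L)
        expect_equal(fs$aa_ref, 1L + off_norm %/% 3L,
          info = paste("L", L, "k", k)
        )
        expect_equal(fs$ref_nt_pos, off_norm + 1L, info = paste("L", L, "k", k))
      }
    }
  }
})

test_that("gene status follows the absence/partial/pseudogene precedence", {
  set.seed(207)
  exon_map <- tibble::tibble(exon = c(1L, 2L), start = c(0L, 150L), end = c(150L, 300L))
  cds <- random_cds(300)
  # absent: no alignment at all
  st <- call_status("g", "s", NULL, exon_map = exon_map)
  expect_equal(st$status, "absent")
  # partial: exon 2 deleted
  tgt <- substr(cds, 1, 150)
  aln <- align_cds(tgt, cds, gene = "g", species = "s")
  fs <- scan_frameshifts(aln)
  sc <- scan_stops(aln, fs)
  st2 <- call_status("g", "s", aln, fs, sc, exon_map = exon_map)
  expect_equal(st2$status, "partial")
  expect_equal(st2$missing_exons[[1]], 2L)
  # pseudogene: one frameshift anywhere
  tgt3 <- delete_at_codon(cds, 10, 1)
  aln3 <- align_cds(tgt3, cds, gene = "g", species = "s")
  fs3 <- scan_frameshifts(aln3)
  st3 <- call_status("g", "s", aln3, fs3, scan_stops(aln3, fs3),
    exon_map = exon_map
  )
  expect_equal(st3$status, "potential_pseudogene")
  # intact otherwise
  aln4 <- align_cds(cds, cds, gene = "g", species = "s")
  st4 <- call_status("g", "s", aln4, exon_map = exon_map)
  expect_equal(st4$status, "intact")
})

test_that("gene content tabulation counts duplicated copies and types", {
  sim <- cached_sim()
  anc <- generate_ancestor(sim$config)
  feats <- assign_gene_regions(anc$structure, anc$features)
  statuses <- call_status("ndhA", "anc", NULL) # single absent row placeholder
  statuses$status <- "intact"
  tab <- tabulate_gene_content(
    statuses,
    tibble::tibble(species = "anc", features = list(feats))
  )
  roster <- default_gene_roster()
  n_prot_sc <- sum(roster$class == "protein" & roster$region != "IR")
  n_prot_ir <- sum(roster$class == "protein" & roster$region == "IR")
  expect_equal(tab$duplicated, 2L * n_prot_ir)
  expect_equal(tab$total_protein_genes, n_prot_sc + 2L * n_prot_ir)
  expect_equal(tab$display, sprintf("%d (%d)", tab$total_protein_genes, tab$duplicated))
  expect_equal(tab$trna_types, length(unique(roster$gene[roster$class == "tRNA"])))
  expect_equal(tab$rrna_types, length(unique(roster$gene[roster$class == "rRNA"])))
})
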