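test_that("region assignment labels genes by majority and flags straddlers", {
  set.seed(301)
  # genome: LSC [0,180) | IRa [180,260) | SSC [260,320) | IRb [320,400)
  A <- rand_bases(180)
  R <- rand_bases(80)
  B <- rand_bases(60)
  seq <- paste0(A, R, B, revcomp(R))
  p <- plastome(seq)
  st <- partition_quadripartite(
    p,
    list(first = c(start = 180L, len = 80L), second = c(start = 320L, len = 80L))
  )
  feats <- gene_features(
    gene = c("inIR", "inIR", "straddler", "sscGene"),
    feature_class = c("tRNA", "tRNA", "tRNA", "tRNA"),
    strand = "+",
    exon = 1L,
    start = c(190L, 330L, 160L, 270L), # twin copies in both arms
    end = c(250L, 390L, 190L, 310L), # straddler: 20 bp LSC + 10 bp IRa
    feature_id = 1:4,
    genome_length = 400L
  )
  ann <- assign_gene_regions(st, feats)
  a <- dplyr::distinct(ann, feature_id, gene, region, straddle, copy_number)
  expect_equal(a$region[a$gene == "inIR"], c("IR", "IR"))
  expect_equal(a$copy_number[a$gene == "inIR"], c(2L, 2L))
  expect_equal(a$region[a$gene == "straddler"], "LSC")
  expect_true(a$straddle[a$gene == "straddler"])
  expect_equal(a$region[a$gene == "sscGene"], "SSC")
  expect_equal(a$copy_number[a$gene == "sscGene"], 1L)
})

test_that("the simulator's planted IR genes are all labeled IR", {
  sim <- cached_sim()
  anc <- generate_ancestor(sim$config)
  ann <- assign_gene_regions(anc$structure, anc$features)
  ir_genes <- unique(ann$gene[ann$region == "IR"])
  roster_ir <- default_gene_roster()
  expect_setequal(ir_genes, roster_ir$gene[roster_ir$region == "IR"])
  # every IR gene has its twin: copy_number 2 on both instances
  expect_true(all(ann$copy_number[ann$region == "IR"] == 2L))
})

test_that("comparing a genome against itself yields the all-zero expansion report", {
  sim <- cached_sim()
  anc <- generate_ancestor(sim$config)
  bundle <- list(
    plastome = anc$plastome, features = anc$features, structure = anc$structure
  )
  rep <- map_ir_expansion(bundle, bundle, species = "self")
  expect_equal(rep$expansion_total, 0L)
  expect_equal(rep$from_lsc_bp, 0L)
  expect_equal(rep$from_ssc_bp, 0L)
  expect_equal(rep$genes_from_lsc, 0L)
  expect_equal(rep$genes_from_ssc, 0L)
  expect_equal(rep$ir_len_diff, 0L)
})

test_that("expansion reports enforce the component-sum identity", {
  expect_error(
    expansion_report("x", 100L, 60L, 30L, 1L, 1L, expansion_total = 80L),
    "!="
  )
  rep <- expansion_report("x", 100L, 60L, 30L, 1L, 1L)
  expect_equal(rep$expansion_total, 90L)
  expect_error(
    expansion_report("x", 100L, -5L, 30L, 0L, 1L),
    "non-negative"
  )
})

test_that("expansion mapping recovers planted boundary shifts within anchor resolution", {
  sim <- cached_sim()
  pp <- run_pipeline(sim, outgroup = "Lph")
  truth <- sim$ledger$leaf_expansion
  for (sp in setdiff(names(sim$leaves), "Lph")) {
    got <- pp$expansion[pp$expansion$species == sp, ]
    want <- truth[truth$species == sp, ]
    expect_setequal(
      got$recruited_genes[[1]]$gene[
        got$recruited_genes[[1]]$source_region == "LSC"
      ],
      want$genes_from_lsc[[1]]
    )
    expect_setequal(
      got$recruited_genes[[1]]$gene[
        got$recruited_genes[[1]]$source_region == "SSC"
      ],
      want$genes_from_ssc[[1]]
    )
    expect_lte(
      abs(got$from_lsc_bp - want$from_lsc_bp),
      max(want$resolution_lsc, 1L)
    )
    expect_lte(
      abs(got$from_ssc_bp - want$from_ssc_bp),
      max(want$resolution_ssc, 1L)
    )
  }
})

test_that("extending the planted boundary shift never decreases recruited bp", {
  cfg_small <- sim_config(
    seed = 31,
    events = list(
      list(branch = "bs", type = "ir_expand", source = "LSC", target_bp = 500L)
    )
  )
  cfg_large <- sim_config(
    seed = 31,
    events = list(
      list(branch = "bs", type = "ir_expand", source = "LSC", target_bp = 1500L)
    )
  )
  measure <- function(cfg) {
    sim <- evolve_along_tree(generate_ancestor(cfg), config = cfg)
    tgt <- sim$leaves[["Bam"]]
    og <- sim$leaves[["Lph"]]
    rep <- map_ir_expansion(
      list(plastome = tgt$plastome, features = tgt$features, structure = tgt$structure),
      list(plastome = og$plastome, features = og$features, structure = og$structure),
      species = "Bam"
    )
    rep$from_lsc_bp
  }
  expect_gte(measure(cfg_large), measure(cfg_small))
})

test_that("structure summaries recompose lengths and flag published mismatches", {
  empty <- summarize_structures(tibble::tibble(
    species = character(), plastome_length = integer(), lsc_len = integer(),
    ssc_len = integer(), ir_len = integer()
  ))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("composed_length", "length_mismatch") %in% names(empty)))
  comp <- tibble::tibble(
    species = c("ok", "off"),
    plastome_length = c(400L, 401L),
    lsc_len = c(180L, 180L),
    ssc_len = c(60L, 60L),
    ir_len = c(80L, 80L)
  )
  expect_warning(out <- summarize_structures(comp), "off")
  expect_equal(out$composed_length, c(400L, 400L))
  expect_equal(out$length_mismatch, c(FALSE, TRUE))
})
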