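test_that("the ancestor satisfies the quadripartite composition identity", {
  cfg <- sim_config(seed = 51)
  anc <- generate_ancestor(cfg)
  g <- glance(anc$structure)
  expect_equal(g$composed_length, g$genome_length)
  expect_equal(g$lsc_len, cfg$lsc_len)
  expect_equal(g$ssc_len, cfg$ssc_len)
  expect_equal(g$ir_len, cfg$ir_len)
  expect_equal(g$arm_mismatches, 0L)
})

test_that("generation is deterministic under the seed", {
  a1 <- generate_ancestor(sim_config(seed = 52))
  a2 <- generate_ancestor(sim_config(seed = 52))
  expect_identical(a1$plastome$sequence, a2$plastome$sequence)
  expect_identical(a1$features, a2$features)
  a3 <- generate_ancestor(sim_config(seed = 53))
  expect_false(identical(a1$plastome$sequence, a3$plastome$sequence))
  s1 <- simulate_plastomes(sim_config(seed = 52))
  s2 <- simulate_plastomes(sim_config(seed = 52))
  for (nm in names(s1$leaves)) {
    expect_identical(
      s1$leaves[[nm]]$plastome$sequence,
      s2$leaves[[nm]]$plastome$sequence
    )
    expect_identical(
      as.numeric(s1$coverage[[nm]]),
      as.numeric(s2$coverage[[nm]])
    )
  }
})

test_that("repeat detection recovers the planted ancestral arms exactly", {
  anc <- generate_ancestor(sim_config(seed = 54))
  ir <- find_inverted_repeat(anc$plastome, min_len = 1000L, max_mismatch_frac = 0)
  expect_true(ir$found)
  expect_equal(ir$first[["start"]], anc$structure$ir_a[["start"]])
  expect_equal(ir$first[["len"]], anc$structure$ir_a[["len"]])
  expect_equal(ir$second[["start"]], anc$structure$ir_b[["start"]])
  expect_equal(ir$mismatch_count, 0L)
})

test_that("zero substitution rate and no events reproduce the ancestor at every leaf", {
  cfg <- sim_config(seed = 55, subst_rate = 0, events = list())
  anc <- generate_ancestor(cfg)
  sim <- evolve_along_tree(anc, config = cfg)
  for (nm in names(sim$leaves)) {
    expect_identical(sim$leaves[[nm]]$plastome$sequence, anc$plastome$sequence)
  }
  expect_equal(nrow(sim$ledger$events), 0L)
})

test_that("engineered mutations are inherited by exactly the descendant leaves", {
  sim <- cached_sim()
  anc_cds <- nchar(plastomics:::comp_cds_seq(
    generate_ancestor(sim$config)$components$ir, "ndhB"
  ))
  for (nm in names(sim$leaves)) {
    lf <- sim$leaves[[nm]]
    inst <- lf$features[lf$features$gene == "ndhB", ]
    len <- sum(inst$end - inst$start) / 2 # two identical IR copies
    if (nm %in% c("She", "Sas")) {
      expect_equal(len, anc_cds - 1, info = nm) # inherited 1-bp deletion
    } else {
      expect_equal(len, anc_cds, info = nm)
    }
  }
  # the exon deletion is private to its terminal branch
  for (nm in names(sim$leaves)) {
    n_exons <- sum(sim$leaves[[nm]]$features$gene == "ndhA")
    expect_equal(n_exons, if (nm == "She") 1L else 2L, info = nm)
  }
})

test_that("every leaf keeps the structural identity after events", {
  sim <- cached_sim()
  for (nm in names(sim$leaves)) {
    g <- glance(sim$leaves[[nm]]$structure)
    expect_equal(g$composed_length, g$genome_length, info = nm)
    expect_equal(
      nchar(sim$leaves[[nm]]$plastome$sequence), g$genome_length,
      info = nm
    )
  }
})

test_that("simulated coverage doubles inside the repeat arms", {
  sim <- cached_sim()
  lf <- sim$leaves[["Lph"]]
  track <- simulate_coverage(lf$structure, base_depth = 40L, seed = 9)
  td <- tidy(lf$structure)
  ira <- td[td$region == "IRa", ]
  in_ir <- (ira$start0 + 1):(ira$start0 + ira$length)
  mean_ir <- mean(as.numeric(track)[in_ir])
  expect_lt(abs(mean_ir - 80), 3 * sqrt(80 / ira$length))
  lsc <- 1:td$length[td$region == "LSC"]
  expect_lt(abs(mean(as.numeric(track)[lsc]) - 40), 3 * sqrt(40 / length(lsc)))
  expect_error(simulate_coverage(lf$structure, base_depth = 5L), ">= 10")
})

test_that("infeasible gene packing raises an error", {
  cfg <- sim_config(seed = 56, lsc_len = 1000L)
  expect_error(generate_ancestor(cfg), "infeasible packing")
})

test_that("simulation bundles round-trip through the on-disk layout", {
  cfg <- sim_config(
    seed = 57,
    events = list(
      list(branch = "bs", type = "ir_expand", source = "LSC", target_bp = 600L)
    )
  )
  sim <- simulate_plastomes(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "tree.nwk")))
  expect_true(file.exists(file.path(dir, "truth_ledger.json")))
  back <- load_plastome(file.path(dir, "Bam.fasta"))
  expect_equal(back$sequence, sim$leaves[["Bam"]]$plastome$sequence)
  feats <- load_features(
    file.path(dir, "Bam.features.tsv"), back$length
  )
  expect_equal(
    sort(unique(feats$gene)),
    sort(unique(sim$leaves[["Bam"]]$features$gene))
  )
})
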