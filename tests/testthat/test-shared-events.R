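mut_row <- function(gene, species, kind, aa, pos, change, induced = FALSE) {
  tibble::tibble(
    gene = gene, species = species, kind = kind, aa_ref = aa, aa_target = aa,
    ref_nt_pos = pos, change = change, frame_state = 0L,
    frameshift_induced = if (kind == "FS") NA else induced,
    indel_net = if (kind == "FS") -1L else NA_integer_
  )
}

test_that("identical changes in two species form one identical-class event", {
  m <- dplyr::bind_rows(
    mut_row("ndhE", "X", "SC", 2L, 4L, "SC @ ref nt 4 codon TAA"),
    mut_row("ndhE", "Y", "SC", 2L, 4L, "SC @ ref nt 4 codon TAA")
  )
  ev <- collect_events(m)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "SC")
  expect_equal(ev$identity_class, "identical")
  expect_setequal(ev$species_set[[1]], c("X", "Y"))
})

test_that("different insertions at the same site are convergent, not identical", {
  m <- dplyr::bind_rows(
    mut_row("ndhE", "X", "FS", 34L, 100L, "ins 1 nt A @ ref nt 100"),
    mut_row("ndhE", "Y", "FS", 34L, 100L, "ins 1 nt T @ ref nt 100")
  )
  ev <- collect_events(m)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$identity_class, "convergent_same_site")
  expect_setequal(ev$species_set[[1]], c("X", "Y"))
})

test_that("singletons and frameshift-induced stops are excluded", {
  m <- dplyr::bind_rows(
    mut_row("ndhD", "X", "FS", 5L, 13L, "del 1 nt @ ref nt 13"),
    mut_row("ndhF", "X", "SC", 9L, 25L, "SC @ ref nt 25 codon TGA", induced = TRUE),
    mut_row("ndhF", "Y", "SC", 9L, 25L, "SC @ ref nt 25 codon TGA", induced = TRUE)
  )
  ev <- collect_events(m)
  expect_equal(nrow(ev), 0L)
})

test_that("the event set is invariant to species input order", {
  m <- dplyr::bind_rows(
    mut_row("ndhB", "She", "FS", 24L, 70L, "del 1 nt @ ref nt 70"),
    mut_row("ndhB", "Sas", "FS", 24L, 70L, "del 1 nt @ ref nt 70"),
    mut_row("ycf1", "Sfo", "SC", 10L, 28L, "SC @ ref nt 28 codon TAA"),
    mut_row("ycf1", "Bam", "SC", 10L, 28L, "SC @ ref nt 28 codon TAA")
  )
  ev1 <- collect_events(m)
  ev2 <- collect_events(m[sample(nrow(m)), ])
  expect_equal(
    ev1[, c("gene", "kind", "ref_nt_pos", "change", "identity_class")],
    ev2[, c("gene", "kind", "ref_nt_pos", "change", "identity_class")]
  )
  expect_equal(ev1$species_set, ev2$species_set)
})

test_that("every event member exists verbatim in the input mutation lists", {
  sim <- cached_sim()
  pp <- run_pipeline(sim, outgroup = "Lph")
  long <- write_shared_table(pp$events)
  if (nrow(long) > 0) {
    keys_in <- paste(pp$mutations$gene, pp$mutations$species,
      pp$mutations$kind, pp$mutations$ref_nt_pos)
    keys_ev <- paste(long$gene, long$species, long$kind, long$ref_nt_pos)
    expect_true(all(keys_ev %in% keys_in))
  }
})

test_that("an event planted on an internal branch is recovered with its descendant set", {
  cfg <- sim_config(
    seed = 41,
    events = list(
      list(branch = "striga", type = "fs", gene = "ndhD", codon = 20L, indel_len = -2L)
    )
  )
  sim <- simulate_plastomes(cfg)
  pp <- run_pipeline(sim, outgroup = "Lph")
  ev <- pp$events
  fs_ev <- ev[ev$gene == "ndhD" & ev$kind == "FS", ]
  expect_equal(nrow(fs_ev), 1L)
  expect_equal(fs_ev$identity_class, "identical")
  expect_setequal(fs_ev$species_set[[1]], c("She", "Sas", "Sfo"))
})

test_that("the long-format table mirrors grouped event boxes", {
  m <- dplyr::bind_rows(
    mut_row("ndhB", "She", "FS", 24L, 70L, "del 1 nt @ ref nt 70"),
    mut_row("ndhB", "Sas", "FS", 24L, 70L, "del 1 nt @ ref nt 70")
  )
  long <- write_shared_table(collect_events(m))
  expect_equal(nrow(long), 2L)
  expect_equal(long$event_id[1], long$event_id[2])
  expect_setequal(long$species, c("She", "Sas"))
  # empty input -> header-only file
  f <- withr::local_tempfile(fileext = ".tsv")
  write_shared_table(collect_events(empty <- plastomics:::empty_mutations()), f)
  expect_equal(length(readLines(f)), 1L)
})
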