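test_that("a planted exact inverted repeat is found at its exact coordinates", {
  set.seed(101)
  g <- planted_ir_genome(flank_a = 100, arm = 80, spacer = 60, flank_c = 80)
  p <- plastome(g$seq)
  ir <- find_inverted_repeat(p, min_len = 50, max_mismatch_frac = 0)
  expect_true(ir$found)
  expect_equal(ir$first, c(start = 100L, len = 80L))
  expect_equal(ir$second, c(start = 240L, len = 80L))
  expect_equal(ir$mismatch_count, 0L)
})

test_that("one substitution inside an arm is absorbed by the mismatch budget", {
  set.seed(102)
  g <- planted_ir_genome(flank_a = 100, arm = 80, spacer = 60, flank_c = 80)
  seq <- g$seq
  # substitute one base in the middle of the first arm
  pos <- 140L
  old <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- setdiff(BASES, old)[1]
  p <- plastome(seq)
  ir <- find_inverted_repeat(p, min_len = 50, max_mismatch_frac = 0.02)
  expect_true(ir$found)
  expect_equal(ir$first, c(start = 100L, len = 80L))
  expect_equal(ir$second, c(start = 240L, len = 80L))
  expect_equal(ir$mismatch_count, 1L)
})

test_that("a random sequence without a planted repeat yields the no-IR result", {
  set.seed(103)
  p <- plastome(rand_bases(500))
  ir <- find_inverted_repeat(p, min_len = 50, max_mismatch_frac = 0.02)
  expect_false(ir$found)
  orc <- oracle_find_ir(p$sequence, 50, 0.02)
  expect_false(orc$found)
})

test_that("the repeat finder agrees with the brute-force oracle on random genomes", {
  set.seed(104)
  for (i in 1:12) {
    plant <- i %% 2 == 0
    if (plant) {
      arm <- sample(60:160, 1)
      g <- planted_ir_genome(
        flank_a = sample(80:200, 1), arm = arm,
        spacer = sample(40:120, 1), flank_c = sample(80:200, 1)
      )
      seq <- g$seq
    } else {
      seq <- rand_bases(sample(300:900, 1))
    }
    frac <- sample(c(0, 0.01, 0.02), 1)
    got <- find_inverted_repeat(plastome(seq), 50, frac)
    orc <- oracle_find_ir(seq, 50, frac)
    expect_equal(got$found, orc$found, info = paste("case", i))
    if (orc$found) {
      expect_equal(got$first, orc$first, info = paste("case", i))
      expect_equal(got$second, orc$second, info = paste("case", i))
      expect_equal(got$mismatch_count, orc$mismatch_count,
        info = paste("case", i)
      )
    }
  }
})

test_that("detection is rotation invariant", {
  set.seed(105)
  g <- planted_ir_genome(flank_a = 150, arm = 90, spacer = 70, flank_c = 90)
  p <- plastome(g$seq)
  L <- p$length
  base <- find_inverted_repeat(p, 50, 0)
  for (off in c(17L, 200L, 399L)) {
    rot <- rotate_plastome(p, off)
    ir <- find_inverted_repeat(rot, 50, 0)
    expect_true(ir$found)
    starts <- sort(c(
      (ir$first[["start"]] + off) %% L,
      (ir$second[["start"]] + off) %% L
    ))
    expect_equal(
      starts,
      sort(c(base$first[["start"]], base$second[["start"]]))
    )
    expect_equal(ir$first[["len"]], base$first[["len"]])
  }
})

test_that("partitioning derives single-copy regions with the longer/shorter rule", {
  set.seed(106)
  g <- planted_ir_genome(flank_a = 100, arm = 80, spacer = 60, flank_c = 80)
  p <- plastome(g$seq) # 400 bp; IRs [100,180) and [240,320)
  st <- partition_quadripartite(p, list(first = g$first, second = g$second))
  expect_equal(st$ssc, c(start = 180L, len = 60L))
  expect_equal(st$lsc, c(start = 320L, len = 180L)) # wraps the origin
  expect_equal(
    st$lsc[["len"]] + st$ssc[["len"]] + 2L * st$ir_a[["len"]],
    p$length
  )
  # IRa follows the LSC
  expect_equal(st$ir_a[["start"]], 100L)
})

test_that("equal single-copy arcs tie-break to the arc containing coordinate 0", {
  set.seed(107)
  # 60 bp arcs on both sides
  A <- rand_bases(30)
  R <- rand_bases(80)
  B <- rand_bases(60)
  C <- rand_bases(30)
  p <- plastome(paste0(A, R, B, revcomp(R), C))
  expect_warning(
    st <- partition_quadripartite(
      p,
      list(
        first = c(start = 30L, len = 80L),
        second = c(start = 170L, len = 80L)
      )
    ),
    "tie"
  )
  expect_equal(st$lsc[["start"]], 250L) # the arc wrapping coordinate 0
})

test_that("overlapping repeat intervals are rejected", {
  p <- plastome(rand_bases(200))
  expect_error(
    partition_quadripartite(
      p,
      list(first = c(start = 10L, len = 60L), second = c(start = 50L, len = 60L))
    ),
    "overlap"
  )
})

test_that("coverage doubling segments are detected exactly on a clean track", {
  depth <- rep(30, 200)
  depth[51:100] <- 60
  calls <- detect_ir_from_coverage(coverage_track(depth), window = 5)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 50L)
  expect_equal(calls$end, 100L)
})

test_that("uniform coverage yields no repeat call and zero coverage errors", {
  expect_equal(
    nrow(detect_ir_from_coverage(coverage_track(rep(30, 200)), window = 5)),
    0L
  )
  expect_error(
    detect_ir_from_coverage(coverage_track(rep(0, 100))),
    "no coverage"
  )
})

test_that("Poisson coverage recovers planted arms within the smoothing window", {
  # an unexpanded genome: the single-copy regions dominate, so the
  # genome-wide median tracks the single-copy depth
  sim <- cached_sim()
  lf <- sim$leaves[["Lph"]]
  window <- 200L
  for (s in 1:3) {
    track <- simulate_coverage(lf$structure, base_depth = 40L, seed = 500 + s)
    calls <- detect_ir_from_coverage(track, window = window)
    td <- tidy(lf$structure)
    for (arm in c("IRa", "IRb")) {
      a <- td[td$region == arm, ]
      hit <- calls[abs(calls$start - a$start0) <= window &
        abs(calls$end - (a$start0 + a$length)) <= window, ]
      expect_equal(nrow(hit), 1L, info = paste("seed", s, arm))
    }
  }
})

test_that("sequence-based and coverage-based repeat calls agree on simulated data", {
  sim <- cached_sim()
  lf <- sim$leaves[["Avi"]]
  ir <- find_inverted_repeat(lf$plastome)
  track <- simulate_coverage(lf$structure, 40L, seed = 77)
  calls <- detect_ir_from_coverage(track, window = 200L)
  starts <- sort(c(ir$first[["start"]], ir$second[["start"]]))
  expect_equal(nrow(calls), 2L)
  expect_true(all(abs(sort(calls$start) - starts) <= 200L))
})
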