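#' Default gene roster for the synthetic ancestor
#'
#' A reduced plastome gene set at 1/10 scale: LSC genes with the
#' junction-flanking block (trnH..psbK) at the LSC end adjacent to IRa,
#' an SSC holding the ndh cluster and ycf1 (ycf1 at the IRa-facing end),
#' and an IR carrying ndhB, ycf2 and the rRNA operon placeholders.
#' Lengths are protein CDS lengths in nt (multiples of 3, including the
#' stop codon); `intron_len` > 0 splits the CDS into two exons of
#' `exon1_len` and the remainder.
#'
#' @return A tibble with one row per gene.
#' @export
default_gene_roster <- function() {
  tibble::tribble(
    ~region, ~gene, ~class, ~strand, ~length, ~exon1_len, ~intron_len,
    "LSC", "atpA", "protein", "+", 540L, NA, 0L,
    "LSC", "rpoA", "protein", "-", 360L, NA, 0L,
    "LSC", "rps11", "protein", "+", 240L, NA, 0L,
    "LSC", "rpl16", "protein", "+", 300L, NA, 0L,
    "LSC", "clpP", "protein", "+", 210L, NA, 0L,
    "LSC", "petA", "protein", "+", 330L, NA, 0L,
    "LSC", "psbB", "protein", "+", 510L, NA, 0L,
    "LSC", "ndhC", "protein", "+", 360L, NA, 0L,
    "LSC", "psbK", "protein", "+", 180L, NA, 0L,
    "LSC", "trnQ", "tRNA", "+", 72L, NA, 0L,
    "LSC", "rps16", "protein", "+", 270L, NA, 0L,
    "LSC", "trnK", "tRNA", "+", 72L, NA, 0L,
    "LSC", "matK", "protein", "+", 510L, NA, 0L,
    "LSC", "psbA", "protein", "-", 420L, NA, 0L,
    "LSC", "trnH", "tRNA", "+", 75L, NA, 0L,
    "IR", "ndhB", "protein", "+", 450L, NA, 0L,
    "IR", "ycf2", "protein", "+", 600L, NA, 0L,
    "IR", "rrn16", "rRNA", "+", 300L, NA, 0L,
    "IR", "rrn23", "rRNA", "+", 450L, NA, 0L,
    "IR", "trnI", "tRNA", "+", 72L, NA, 0L,
    "SSC", "ycf1", "protein", "+", 300L, NA, 0L,
    "SSC", "ndhF", "protein", "-", 240L, NA, 0L,
    "SSC", "ndhD", "protein", "+", 240L, NA, 0L,
    "SSC", "ndhA", "protein", "+", 300L, 150L, 90L,
    "SSC", "ndhH", "protein", "+", 210L, NA, 0L
  )
}

#' Default study tree
#'
#' Six leaves: an autotrophic outgroup (`Lph`), a near-autotrophic
#' facultative parasite (`Avi`), a facultative parasite (`Bam`) and three
#' obligate parasites (`Sfo`, and the sister pair `She`, `Sas`). Internal
#' branches are named by node labels so engineered events can reference
#' them.
#'
#' @return An ape `phylo` tree.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((She:0.02,Sas:0.02)shsa:0.02,Sfo:0.03)striga:0.03,",
    "Bam:0.05)bs:0.02,Avi:0.06)ingroup:0.02,Lph:0.08)root;"
  ))
}

#' Default engineered event set
#'
#' Five events emulating the study system: a shared LSC-side repeat
#' expansion in the parasite clade, an SSC-side expansion recruiting ycf1
#' in the obligate-parasite clade, a shared 1-bp frameshift in ndhB on
#' the sister-pair stem, a stop-gain in ndhD on one terminal branch, and
#' loss of the second ndhA exon on another.
#'
#' @return A list of event specifications.
#' @export
default_events <- function() {
  list(
    list(branch = "bs", type = "ir_expand", source = "LSC", target_bp = 800L),
    list(branch = "striga", type = "ir_expand", source = "SSC", target_bp = 450L),
    list(branch = "shsa", type = "fs", gene = "ndhB", codon = 24L, indel_len = -1L),
    list(branch = "Bam", type = "stop_gain", gene = "ndhD", codon = 36L),
    list(branch = "She", type = "delete_exon", gene = "ndhA", exon = 2L)
  )
}

#' Simulation configuration
#'
#' Defaults are 1/10-scale genomes (LSC 8,000 bp, SSC 1,800 bp, IR
#' 2,600 bp) with a Jukes-Cantor-type substitution probability of
#' 0.01/site per branch and the standard six-leaf tree and five-event
#' schedule.
#'
#' @param seed Integer seed; all outputs are pure functions of the
#'   configuration and seed.
#' @param lsc_len,ssc_len,ir_len Region lengths in bp.
#' @param subst_rate Per-site substitution probability per branch.
#' @param tree A `phylo` tree with named internal nodes.
#' @param events Event list (see [default_events()]); each event has a
#'   `branch` and a `type` in `ir_expand`, `fs`, `stop_gain`,
#'   `delete_gene`, `delete_exon`.
#' @param genes Gene roster tibble (see [default_gene_roster()]).
#' @param base_depth Mean single-copy read depth for simulated coverage.
#' @param min_gap Minimum intergenic gap in bp.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, lsc_len = 8000L, ssc_len = 1800L,
                       ir_len = 2600L, subst_rate = 0.01,
                       tree = default_species_tree(),
                       events = default_events(),
                       genes = default_gene_roster(),
                       base_depth = 40L, min_gap = 20L) {
  cfg <- list(
    seed = as.integer(seed), lsc_len = as.integer(lsc_len),
    ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
    subst_rate = subst_rate, tree = tree, events = events, genes = genes,
    base_depth = as.integer(base_depth), min_gap = as.integer(min_gap)
  )
  for (ev in events) {
    if (ev$type == "ir_expand") {
      src_len <- if (ev$source == "LSC") cfg$lsc_len else cfg$ssc_len
      if (ev$target_bp >= src_len) {
        stop("ir_expand target_bp must be smaller than the source region",
          call. = FALSE
        )
      }
    }
    if (ev$type %in% c("fs", "stop_gain")) {
      g <- genes[genes$gene == ev$gene, , drop = FALSE]
      if (nrow(g) == 0L) stop("event references unknown gene ", ev$gene, call. = FALSE)
      if (ev$codon > g$length[1] %/% 3L) {
        stop("event codon beyond gene length for ", ev$gene, call. = FALSE)
      }
    }
  }
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_mid <- len %/% 3L - 2L
  codons <- character(n_mid)
  for (i in seq_len(n_mid)) {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

## lay out one region: genes separated by random gaps >= min_gap
build_component <- function(roster, region_len, min_gap) {
  n <- nrow(roster)
  span <- integer(n)
  for (i in seq_len(n)) {
    span[i] <- roster$length[i] +
      ifelse(is.na(roster$intron_len[i]), 0L, roster$intron_len[i])
  }
  free <- region_len - sum(span) - (n + 1L) * min_gap
  if (free < 0L) {
    stop("infeasible packing: genes exceed region length", call. = FALSE)
  }
  extra <- if (free > 0L) {
    stats::rmultinom(1L, free, rep(1, n + 1L))[, 1L]
  } else {
    rep(0L, n + 1L)
  }
  gaps <- min_gap + extra
  seq_parts <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_len(n)) {
    seq_parts <- c(seq_parts, rand_seq(gaps[i]))
    pos <- pos + gaps[i]
    g <- roster[i, ]
    intron <- if (is.na(g$intron_len)) 0L else g$intron_len
    if (g$class == "protein") {
      cds <- rand_cds(g$length)
    } else {
      cds <- rand_seq(g$length)
    }
    if (intron > 0L) {
      e1 <- g$exon1_len
      body_fwd <- paste0(
        substr(cds, 1L, e1), rand_seq(intron),
        substr(cds, e1 + 1L, g$length)
      )
      body <- if (g$strand == "-") revcomp(body_fwd) else body_fwd
      if (g$strand == "+") {
        ex <- tibble(
          gene = g$gene, feature_class = g$class, strand = g$strand,
          exon = c(1L, 2L),
          start = c(pos, pos + e1 + intron),
          end = c(pos + e1, pos + g$length + intron)
        )
      } else {
        ## transcription runs right to left: exon 1 is the rightmost
        ex <- tibble(
          gene = g$gene, feature_class = g$class, strand = g$strand,
          exon = c(1L, 2L),
          start = c(pos + (g$length - e1) + intron, pos),
          end = c(pos + g$length + intron, pos + (g$length - e1))
        )
      }
    } else {
      body <- if (g$strand == "-") revcomp(cds) else cds
      ex <- tibble(
        gene = g$gene, feature_class = g$class, strand = g$strand,
        exon = 1L, start = pos, end = pos + g$length
      )
    }
    seq_parts <- c(seq_parts, body)
    feats[[i]] <- ex
    pos <- pos + nchar(body)
  }
  seq_parts <- c(seq_parts, rand_seq(region_len - pos))
  list(
    seq = paste(seq_parts, collapse = ""),
    features = dplyr::bind_rows(feats)
  )
}

#' Generate the synthetic ancestral plastome
#'
#' Builds a canonical quadripartite genome (LSC, IRa, SSC, IRb with IRb
#' the exact reverse complement of IRa), placing valid ORFs and RNA-gene
#' placeholders over the three region classes per the configured roster.
#' Deterministic under the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with `components` (lsc/ir/ssc
#'   sequences and local feature tables), `plastome`, `features` (global
#'   coordinates), and `structure`.
#' @export
generate_ancestor <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  comp <- list(
    lsc = build_component(
      config$genes[config$genes$region == "LSC", ],
      config$lsc_len, config$min_gap
    ),
    ir = build_component(
      config$genes[config$genes$region == "IR", ],
      config$ir_len, config$min_gap
    ),
    ssc = build_component(
      config$genes[config$genes$region == "SSC", ],
      config$ssc_len, config$min_gap
    )
  )
  comp <- guard_junctions(comp)
  out <- assemble_sim_genome(comp, id = "ancestor")
  out$config <- config
  out
}

## break chance reverse-complement matches at the four IR junctions so the
## planted arms are exactly maximal: the base pairs probed by a one-step
## arm extension are (LSC last, LSC first) and (SSC first, SSC last)
guard_junctions <- function(comp) {
  fix <- function(seq, get_pos, set_pos) {
    a <- substr(seq, get_pos, get_pos)
    b <- substr(seq, set_pos, set_pos)
    if (b == chartr("ACGT", "TGCA", a)) {
      repl <- setdiff(c("A", "C", "G", "T"), c(b, a))[1]
      substr(seq, set_pos, set_pos) <- repl
    }
    seq
  }
  l <- nchar(comp$lsc$seq)
  s <- nchar(comp$ssc$seq)
  comp$lsc$seq <- fix(comp$lsc$seq, 1L, l)
  comp$ssc$seq <- fix(comp$ssc$seq, s, 1L)
  comp
}

## component representation -> plastome + global features + structure
assemble_sim_genome <- function(comp, id) {
  l <- nchar(comp$lsc$seq)
  r <- nchar(comp$ir$seq)
  s <- nchar(comp$ssc$seq)
  genome <- paste0(comp$lsc$seq, comp$ir$seq, comp$ssc$seq, revcomp(comp$ir$seq))
  p <- plastome(genome, id = id)
  shift_tbl <- function(tb, off) {
    dplyr::mutate(tb, start = .data$start + off, end = .data$end + off)
  }
  ira_feats <- shift_tbl(comp$ir$features, l)
  irb_start <- l + r + s
  irb_feats <- comp$ir$features |>
    dplyr::mutate(
      new_start = irb_start + (r - .data$end),
      new_end = irb_start + (r - .data$start),
      strand = ifelse(.data$strand == "+", "-", "+")
    ) |>
    dplyr::mutate(start = .data$new_start, end = .data$new_end) |>
    dplyr::select(!c("new_start", "new_end"))
  feats <- dplyr::bind_rows(
    comp$lsc$features,
    ira_feats,
    shift_tbl(comp$ssc$features, l + r),
    irb_feats
  )
  ## instance id: lsc/ira/ssc features keep one instance per gene; the IRb
  ## copies are separate instances
  n_main <- nrow(comp$lsc$features) + nrow(ira_feats) + nrow(comp$ssc$features)
  block <- c(rep("main", n_main), rep("irb", nrow(irb_feats)))
  key <- paste(feats$gene, block)
  feats$feature_id <- match(key, unique(key))
  feats$segment <- 1L
  feats$wrap <- FALSE
  feats <- validate_features(feats, p$length)
  structure_ <- new_quadripartite(
    lsc = arc(0L, l),
    ir_a = arc(l, r),
    ssc = arc(l + r, s),
    ir_b = arc(l + r + s, r),
    mismatch_count = 0L,
    genome_length = p$length
  )
  structure(
    list(components = comp, plastome = p, features = feats,
      structure = structure_),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "<sim_genome> %s: LSC %d + IR %d + SSC %d (+IRb) = %d bp, %d features\n",
    x$plastome$id, nchar(x$components$lsc$seq), nchar(x$components$ir$seq),
    nchar(x$components$ssc$seq), x$plastome$length,
    length(unique(x$features$feature_id))
  ))
  invisible(x)
}
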