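## ---- component-level editing helpers (simulator internals) ----

## exon rows of one gene in transcription order with CDS offsets
comp_cds_map <- function(comp, gene) {
  tb <- comp$features[comp$features$gene == gene, , drop = FALSE]
  if (nrow(tb) == 0L) {
    return(NULL)
  }
  tb <- tb[order(tb$exon), , drop = FALSE]
  lens <- tb$end - tb$start
  tb$cds_start <- cumsum(c(0L, lens[-length(lens)]))
  tb$cds_len_total <- sum(lens)
  tb
}

comp_cds_seq <- function(comp, gene) {
  map <- comp_cds_map(comp, gene)
  if (is.null(map)) {
    return(NULL)
  }
  pieces <- substring(comp$seq, map$start + 1L, map$end)
  s <- paste(pieces, collapse = "")
  if (map$strand[1] == "-") revcomp(s) else s
}

## genomic interval [start,end) of CDS offsets [off, off+len); must fall in
## one exon
cds_to_genomic <- function(map, off, len = 1L) {
  row <- which(off >= map$cds_start & off < map$cds_start + (map$end - map$start))
  if (length(row) != 1L ||
    off + len > map$cds_start[row] + (map$end[row] - map$start[row])) {
    stop("CDS interval spans an exon boundary", call. = FALSE)
  }
  if (map$strand[1] == "+") {
    gs <- map$start[row] + (off - map$cds_start[row])
    c(start = gs, end = gs + len)
  } else {
    ge <- map$end[row] - (off - map$cds_start[row])
    c(start = ge - len, end = ge)
  }
}

genomic_to_cds <- function(map, pos) {
  row <- which(pos >= map$start & pos < map$end)
  if (length(row) != 1L) {
    return(NA_integer_)
  }
  if (map$strand[1] == "+") {
    map$cds_start[row] + (pos - map$start[row])
  } else {
    map$cds_start[row] + (map$end[row] - 1L - pos)
  }
}

## edit a component: delete del_len bases at 0-based pos, insert ins_str
## before pos. Shifts feature coordinates; an edit overlapping an exon
## boundary is a collision error.
comp_edit <- function(comp, pos, del_len = 0L, ins_str = "") {
  n <- nchar(comp$seq)
  stopifnot(pos >= 0L, pos + del_len <= n)
  comp$seq <- paste0(
    substr(comp$seq, 1L, pos), ins_str,
    substr(comp$seq, pos + del_len + 1L, n)
  )
  delta <- nchar(ins_str) - del_len
  f <- comp$features
  if (nrow(f) > 0L && delta != 0L) {
    after <- f$start >= pos + del_len
    inside <- f$start <= pos & f$end >= pos + del_len
    before <- f$end <= pos
    if (any(!(after | inside | before))) {
      stop("event collides with a feature boundary", call. = FALSE)
    }
    f$start[after] <- f$start[after] + delta
    f$end[after] <- f$end[after] + delta
    f$end[inside & !after] <- f$end[inside & !after] + delta
    comp$features <- f
  }
  comp
}

## slide an indel to its leftmost string-equivalent position
left_align_deletion <- function(cds, off, dl) {
  s <- strsplit(cds, "", fixed = TRUE)[[1]]
  while (off > 0L && s[off] == s[off + dl]) { # s is 1-based: s[off] == pos off-1
    off <- off - 1L
  }
  off
}

left_align_insertion <- function(cds, off, bases) {
  s <- strsplit(cds, "", fixed = TRUE)[[1]]
  b <- strsplit(bases, "", fixed = TRUE)[[1]]
  dl <- length(b)
  while (off > 0L && b[dl] == s[off]) {
    b <- c(s[off], b[-dl])
    off <- off - 1L
  }
  list(off = off, bases = paste(b, collapse = ""))
}

## protected CDS windows (per gene) around engineered mutation sites, so
## random substitutions cannot blur the planted signal in any lineage
build_protected <- function(config, pad = 6L) {
  prot <- list()
  for (ev in config$events) {
    if (!ev$type %in% c("fs", "stop_gain")) next
    off0 <- 3L * (ev$codon - 1L)
    width <- if (ev$type == "stop_gain") 3L else abs(ev$indel_len)
    win <- c(max(0L, off0 - pad), off0 + width + pad)
    prot[[ev$gene]] <- rbind(prot[[ev$gene]], win)
  }
  prot
}

is_protected <- function(protected, gene, off) {
  w <- protected[[gene]]
  if (is.null(w)) {
    return(FALSE)
  }
  any(off >= w[, 1] & off <= w[, 2])
}

## JC-type substitutions over one component; never creates or destroys a
## stop codon in any gene's reference frame, never touches a start codon,
## a terminal stop, or a protected window
substitute_component <- function(comp, rate, protected) {
  n <- nchar(comp$seq)
  n_sub <- stats::rbinom(1L, n, rate)
  if (n_sub == 0L) {
    return(comp)
  }
  positions <- sort(sample.int(n, n_sub) - 1L)
  prot_rows <- comp$features[comp$features$feature_class == "protein", , drop = FALSE]
  maps <- list()
  for (g in unique(prot_rows$gene)) maps[[g]] <- comp_cds_map(comp, g)
  seq_chars <- strsplit(comp$seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (pos in positions) {
    hit <- prot_rows[prot_rows$start <= pos & prot_rows$end > pos, , drop = FALSE]
    if (nrow(hit) == 0L) {
      cur <- seq_chars[pos + 1L]
      seq_chars[pos + 1L] <- sample(setdiff(bases, cur), 1L)
      next
    }
    gene <- hit$gene[1]
    map <- maps[[gene]]
    off <- genomic_to_cds(map, pos)
    cds_len <- map$cds_len_total[1]
    if (is.na(off) || off < 3L || off >= cds_len - 3L) next
    if (is_protected(protected, gene, off)) next
    strand <- map$strand[1]
    ## work in CDS orientation
    cod_idx <- off %/% 3L
    within <- off %% 3L
    cod_interval <- cds_to_genomic(map, cod_idx * 3L, 3L)
    cod_gen <- paste(seq_chars[(cod_interval[["start"]] + 1L):cod_interval[["end"]]],
      collapse = ""
    )
    codon <- if (strand == "-") revcomp(cod_gen) else cod_gen
    cur_cds_base <- substr(codon, within + 1L, within + 1L)
    alts <- sample(setdiff(bases, cur_cds_base))
    for (alt in alts) {
      new_codon <- codon
      substr(new_codon, within + 1L, within + 1L) <- alt
      if (!new_codon %in% STOP_CODONS) {
        new_gen <- if (strand == "-") revcomp(new_codon) else new_codon
        seq_chars[(cod_interval[["start"]] + 1L):cod_interval[["end"]]] <-
          strsplit(new_gen, "", fixed = TRUE)[[1]]
        break
      }
    }
  }
  comp$seq <- paste(seq_chars, collapse = "")
  comp
}

## intergenic gaps between gene spans of a component (includes region edges)
component_gaps <- function(comp, region_len) {
  f <- comp$features
  if (nrow(f) == 0L) {
    return(tibble(gap_start = 0L, gap_end = region_len))
  }
  spans <- f |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(s = min(.data$start), e = max(.data$end), .groups = "drop") |>
    dplyr::arrange(.data$s)
  tibble(
    gap_start = c(0L, spans$e),
    gap_end = c(spans$s, region_len)
  )
}

find_component <- function(comps, gene) {
  for (nm in c("lsc", "ir", "ssc")) {
    if (gene %in% comps[[nm]]$features$gene) {
      return(nm)
    }
  }
  stop("gene ", gene, " not present (already deleted?)", call. = FALSE)
}

## apply one engineered event; returns list(comps, record)
apply_sim_event <- function(comps, ev) {
  rec <- list(
    type = ev$type, gene = ev$gene %||% NA_character_,
    source = ev$source %||% NA_character_,
    codon = ev$codon %||% NA_integer_,
    kind = NA_character_, ref_nt_pos = NA_integer_, change = NA_character_,
    target_bp = ev$target_bp %||% NA_integer_, actual_bp = NA_integer_,
    anchor_resolution = NA_integer_, recruited = list(character())
  )
  if (ev$type == "ir_expand") {
    if (ev$source == "LSC") {
      lsc <- comps$lsc
      L <- nchar(lsc$seq)
      gaps <- component_gaps(lsc, L)
      gaps <- gaps[gaps$gap_end > gaps$gap_start, , drop = FALSE]
      mid <- (gaps$gap_start + gaps$gap_end) %/% 2L
      want <- L - ev$target_bp
      gi <- which.min(abs(mid - want))
      m <- mid[gi]
      moved_len <- L - m
      moved_feats <- lsc$features[lsc$features$start >= m, , drop = FALSE]
      keep_feats <- lsc$features[lsc$features$start < m, , drop = FALSE]
      ir <- comps$ir
      first_ir_start <- if (nrow(ir$features) > 0L) min(ir$features$start) else nchar(ir$seq)
      last_moved_end <- if (nrow(moved_feats) > 0L) max(moved_feats$end) else m
      inner_gap <- (L - last_moved_end) + first_ir_start
      outer_gap <- gaps$gap_end[gi] - gaps$gap_start[gi]
      moved_feats$start <- moved_feats$start - m
      moved_feats$end <- moved_feats$end - m
      ir$features$start <- ir$features$start + moved_len
      ir$features$end <- ir$features$end + moved_len
      ir$features <- dplyr::bind_rows(moved_feats, ir$features)
      ir$seq <- paste0(substr(lsc$seq, m + 1L, L), ir$seq)
      lsc$seq <- substr(lsc$seq, 1L, m)
      lsc$features <- keep_feats
      comps$lsc <- lsc
      comps$ir <- ir
      rec$actual_bp <- moved_len
      rec$anchor_resolution <- (outer_gap %/% 2L) + (inner_gap %/% 2L)
      rec$recruited <- list(unique(moved_feats$gene))
    } else if (ev$source == "SSC") {
      ssc <- comps$ssc
      S <- nchar(ssc$seq)
      gaps <- component_gaps(ssc, S)
      gaps <- gaps[gaps$gap_end > gaps$gap_start, , drop = FALSE]
      mid <- (gaps$gap_start + gaps$gap_end) %/% 2L
      gi <- which.min(abs(mid - ev$target_bp))
      m <- mid[gi]
      moved_feats <- ssc$features[ssc$features$end <= m, , drop = FALSE]
      keep_feats <- ssc$features[ssc$features$end > m, , drop = FALSE]
      ir <- comps$ir
      R <- nchar(ir$seq)
      last_ir_end <- if (nrow(ir$features) > 0L) max(ir$features$end) else 0L
      first_moved_start <- if (nrow(moved_feats) > 0L) min(moved_feats$start) else m
      inner_gap <- (R - last_ir_end) + first_moved_start
      outer_gap <- gaps$gap_end[gi] - gaps$gap_start[gi]
      moved_feats$start <- moved_feats$start + R
      moved_feats$end <- moved_feats$end + R
      ir$features <- dplyr::bind_rows(ir$features, moved_feats)
      ir$seq <- paste0(ir$seq, substr(ssc$seq, 1L, m))
      keep_feats$start <- keep_feats$start - m
      keep_feats$end <- keep_feats$end - m
      ssc$seq <- substr(ssc$seq, m + 1L, S)
      ssc$features <- keep_feats
      comps$ssc <- ssc
      comps$ir <- ir
      rec$actual_bp <- m
      rec$anchor_resolution <- (outer_gap %/% 2L) + (inner_gap %/% 2L)
      rec$recruited <- list(unique(moved_feats$gene))
    } else {
      stop("ir_expand source must be LSC or SSC", call. = FALSE)
    }
  } else if (ev$type == "fs") {
    nm <- find_component(comps, ev$gene)
    comp <- comps[[nm]]
    map <- comp_cds_map(comp, ev$gene)
    cds <- comp_cds_seq(comp, ev$gene)
    off0 <- 3L * (ev$codon - 1L)
    dl <- abs(ev$indel_len)
    if (ev$indel_len < 0L) {
      gint <- cds_to_genomic(map, off0, dl)
      comps[[nm]] <- comp_edit(comp, gint[["start"]], del_len = dl)
      off_norm <- left_align_deletion(cds, off0, dl)
      rec$kind <- "FS"
      rec$ref_nt_pos <- off_norm + 1L
      rec$change <- sprintf("del %d nt @ ref nt %d", dl, off_norm + 1L)
    } else {
      bases <- ev$bases %||% rand_seq(dl)
      gint <- cds_to_genomic(map, off0, 1L)
      gpos <- if (map$strand[1] == "+") gint[["start"]] else gint[["end"]]
      ins_genomic <- if (map$strand[1] == "-") revcomp(bases) else bases
      comps[[nm]] <- comp_edit(comp, gpos, del_len = 0L, ins_str = ins_genomic)
      norm <- left_align_insertion(cds, off0, bases)
      rec$kind <- "FS"
      rec$ref_nt_pos <- norm$off + 1L
      rec$change <- sprintf(
        "ins %d nt %s @ ref nt %d", dl, norm$bases, norm$off + 1L
      )
    }
  } else if (ev$type == "stop_gain") {
    nm <- find_component(comps, ev$gene)
    comp <- comps[[nm]]
    map <- comp_cds_map(comp, ev$gene)
    off0 <- 3L * (ev$codon - 1L)
    gint <- cds_to_genomic(map, off0, 3L)
    new_gen <- if (map$strand[1] == "-") revcomp("TAA") else "TAA"
    s <- comp$seq
    substr(s, gint[["start"]] + 1L, gint[["end"]]) <- new_gen
    comp$seq <- s
    comps[[nm]] <- comp
    rec$kind <- "SC"
    rec$ref_nt_pos <- off0 + 1L
    rec$change <- sprintf("SC @ ref nt %d codon TAA", off0 + 1L)
  } else if (ev$type == "delete_gene") {
    nm <- find_component(comps, ev$gene)
    comp <- comps[[nm]]
    rows <- comp$features$gene == ev$gene
    span_s <- min(comp$features$start[rows])
    span_e <- max(comp$features$end[rows])
    comp$features <- comp$features[!rows, , drop = FALSE]
    comps[[nm]] <- comp_edit(comp, span_s, del_len = span_e - span_s)
    rec$kind <- "gene_loss"
    rec$actual_bp <- span_e - span_s
  } else if (ev$type == "delete_exon") {
    nm <- find_component(comps, ev$gene)
    comp <- comps[[nm]]
    row <- which(comp$features$gene == ev$gene & comp$features$exon == ev$exon)
    if (length(row) != 1L) {
      stop("exon ", ev$exon, " of ", ev$gene, " not found", call. = FALSE)
    }
    s <- comp$features$start[row]
    e <- comp$features$end[row]
    comp$features <- comp$features[-row, , drop = FALSE]
    comps[[nm]] <- comp_edit(comp, s, del_len = e - s)
    rec$kind <- "exon_loss"
    rec$actual_bp <- e - s
    rec$codon <- ev$exon
  } else {
    stop("unknown event type: ", ev$type, call. = FALSE)
  }
  list(comps = comps, record = rec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evolve the ancestral plastome along a species tree
#'
#' Depth-first from the root: each branch first receives Jukes-Cantor-type
#' random substitutions (rejection-sampled so no unplanned stop codons,
#' start/stop losses or edits inside engineered-site windows arise — the
#' truth ledger is then the complete inventory of inactivating changes),
#' then its scheduled engineered events. The inverted repeat is evolved as
#' a single arm and re-duplicated at assembly, mimicking the concerted
#' evolution that keeps real arms virtually identical. Repeat expansions
#' snap to the midpoint of the nearest intergenic gap and record that
#' snapping resolution in the ledger.
#'
#' @param ancestor A `sim_genome` from [generate_ancestor()].
#' @param tree Optional `phylo`; defaults to the configuration tree.
#' @param config A [sim_config()]; defaults to the ancestor's.
#' @return A list of class `sim_result`: `leaves` (named list of
#'   `sim_genome`), `tree`, `ledger` (see Details) and `config`. The
#'   ledger holds `events` (one row per engineered event with branch,
#'   affected leaves, reference-anchored coordinates and anchor
#'   resolution), `leaf_structures`, `leaf_expansion` (expected recruited
#'   genes and bp per leaf vs. the outgroup) and `expected_mutations`.
#' @export
evolve_along_tree <- function(ancestor, tree = NULL, config = ancestor$config) {
  stopifnot(inherits(ancestor, "sim_genome"))
  if (is.null(tree)) tree <- config$tree
  tree <- validate_species_tree(tree)
  set.seed(config$seed + 1L)
  labels <- tree_branch_labels(tree)
  n_tip <- length(tree$tip.label)
  protected <- build_protected(config)
  events_by_branch <- split(
    config$events,
    vapply(config$events, `[[`, "", "branch")
  )
  unknown <- setdiff(names(events_by_branch), labels)
  if (length(unknown) > 0L) {
    stop("events reference unknown branches: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  env <- new.env()
  env$leaves <- list()
  env$records <- list()
  recurse <- function(node, comps) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    for (ch in children) {
      br <- labels[ch]
      st <- comps
      for (nm in c("lsc", "ir", "ssc")) {
        st[[nm]] <- substitute_component(st[[nm]], config$subst_rate, protected)
      }
      for (ev in events_by_branch[[br]] %||% list()) {
        res <- apply_sim_event(st, ev)
        st <- res$comps
        rec <- res$record
        rec$branch <- br
        rec$leaves <- list(sort(subtree_leaves(tree, ch)))
        env$records[[length(env$records) + 1L]] <- rec
      }
      if (ch <= n_tip) {
        env$leaves[[br]] <- st
      } else {
        recurse(ch, st)
      }
    }
  }
  recurse(n_tip + 1L, ancestor$components)
  leaves <- purrr::imap(env$leaves, function(st, nm) {
    assemble_sim_genome(st, id = nm)
  })
  leaves <- leaves[tree$tip.label]
  ledger <- build_truth_ledger(env$records, leaves, tree)
  structure(
    list(leaves = leaves, tree = tree, ledger = ledger, config = config),
    class = "sim_result"
  )
}

build_truth_ledger <- function(records, leaves, tree) {
  events <- if (length(records) == 0L) {
    tibble(
      event_id = integer(), branch = character(), type = character(),
      gene = character(), source = character(), codon = integer(),
      kind = character(), ref_nt_pos = integer(), change = character(),
      target_bp = integer(), actual_bp = integer(),
      anchor_resolution = integer(), recruited = list(), leaves = list()
    )
  } else {
    purrr::imap_dfr(records, function(r, i) {
      tibble(
        event_id = i, branch = r$branch, type = r$type, gene = r$gene,
        source = r$source, codon = r$codon, kind = r$kind,
        ref_nt_pos = r$ref_nt_pos, change = r$change,
        target_bp = r$target_bp, actual_bp = r$actual_bp,
        anchor_resolution = r$anchor_resolution,
        recruited = r$recruited, leaves = r$leaves
      )
    })
  }
  leaf_structures <- purrr::imap_dfr(leaves, function(lf, nm) {
    g <- glance.quadripartite(lf$structure)
    tibble(
      species = nm, genome_length = g$genome_length,
      lsc_len = g$lsc_len, ssc_len = g$ssc_len, ir_len = g$ir_len
    )
  })
  leaf_expansion <- purrr::map_dfr(names(leaves), function(sp) {
    on_path <- vapply(events$leaves, function(ls) sp %in% ls, TRUE)
    exp_ev <- events[on_path & events$type == "ir_expand", , drop = FALSE]
    lsc_ev <- exp_ev[exp_ev$source == "LSC", , drop = FALSE]
    ssc_ev <- exp_ev[exp_ev$source == "SSC", , drop = FALSE]
    tibble(
      species = sp,
      from_lsc_bp = sum(lsc_ev$actual_bp),
      from_ssc_bp = sum(ssc_ev$actual_bp),
      genes_from_lsc = list(as.character(sort(unique(unlist(lsc_ev$recruited))))),
      genes_from_ssc = list(as.character(sort(unique(unlist(ssc_ev$recruited))))),
      resolution_lsc = sum(lsc_ev$anchor_resolution),
      resolution_ssc = sum(ssc_ev$anchor_resolution)
    )
  })
  mut_ev <- events[events$type %in% c("fs", "stop_gain"), , drop = FALSE]
  expected_mutations <- if (nrow(mut_ev) == 0L) {
    tibble(
      species = character(), gene = character(), kind = character(),
      ref_nt_pos = integer(), change = character(), event_id = integer()
    )
  } else {
    purrr::pmap_dfr(
      list(mut_ev$event_id, mut_ev$gene, mut_ev$kind, mut_ev$ref_nt_pos,
        mut_ev$change, mut_ev$leaves),
      function(id, gene, kind, pos, change, ls) {
        tibble(
          species = ls, gene = gene, kind = kind,
          ref_nt_pos = pos, change = change, event_id = id
        )
      }
    )
  }
  status_ev <- events[events$type %in% c("fs", "stop_gain", "delete_gene",
    "delete_exon"), , drop = FALSE]
  expected_status <- if (nrow(status_ev) == 0L) {
    tibble(species = character(), gene = character(), status = character())
  } else {
    purrr::pmap_dfr(
      list(status_ev$type, status_ev$gene, status_ev$leaves),
      function(type, gene, ls) {
        st <- switch(type,
          fs = "potential_pseudogene",
          stop_gain = "potential_pseudogene",
          delete_gene = "absent",
          delete_exon = "partial"
        )
        tibble(species = ls, gene = gene, status = st)
      }
    ) |>
      dplyr::distinct()
  }
  list(
    events = events,
    leaf_structures = leaf_structures,
    leaf_expansion = leaf_expansion,
    expected_mutations = expected_mutations,
    expected_status = expected_status
  )
}

#' Simulate a read-coverage track for a quadripartite genome
#'
#' Per-base depths are drawn from Poisson(`base_depth`) in the
#' single-copy regions and Poisson(`2 * base_depth`) inside the repeat
#' arms — the coverage-doubling signature used to delimit the repeat.
#'
#' @param structure A `quadripartite` object.
#' @param base_depth Mean single-copy depth (>= 10).
#' @param seed Integer seed; same seed, same track.
#' @return A `coverage_track`.
#' @export
simulate_coverage <- function(structure, base_depth = 40L, seed = 1L) {
  stopifnot(inherits(structure, "quadripartite"))
  if (base_depth < 10L) {
    stop("base_depth must be >= 10", call. = FALSE)
  }
  set.seed(seed)
  L <- structure$genome_length
  lambda <- rep(base_depth, L)
  for (a in list(structure$ir_a, structure$ir_b)) {
    lambda[arc_positions(a, L) + 1L] <- 2L * base_depth
  }
  coverage_track(stats::rpois(L, lambda))
}

#' Run the full simulation: ancestor, evolution and coverage
#'
#' @param config A [sim_config()].
#' @return A `sim_result` (see [evolve_along_tree()]) with an added
#'   `coverage` element (one track per leaf) and the `ancestor`.
#' @export
simulate_plastomes <- function(config = sim_config()) {
  anc <- generate_ancestor(config)
  sim <- evolve_along_tree(anc, config = config)
  sim$ancestor <- anc
  sim$coverage <- purrr::imap(sim$leaves, function(lf, nm) {
    simulate_coverage(
      lf$structure, config$base_depth,
      seed = config$seed + 100L + match(nm, names(sim$leaves))
    )
  })
  sim
}

#' Write a simulation bundle to a directory
#'
#' Emits, per leaf, a FASTA genome, a feature TSV and a coverage TSV,
#' plus the tree in Newick and the truth ledger as JSON.
#'
#' @param sim A `sim_result` from [simulate_plastomes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$leaves)) {
    lf <- sim$leaves[[nm]]
    write_plastome(lf$plastome, file.path(dir, paste0(nm, ".fasta")))
    write_features(lf$features, file.path(dir, paste0(nm, ".features.tsv")))
    if (!is.null(sim$coverage[[nm]])) {
      write_coverage(sim$coverage[[nm]], file.path(dir, paste0(nm, ".coverage.tsv")))
    }
  }
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  ledger <- sim$ledger
  jsonlite::write_json(
    ledger,
    file.path(dir, "truth_ledger.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
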