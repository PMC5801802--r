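empty_mutations <- function() {
  tibble(
    gene = character(), species = character(), kind = character(),
    aa_ref = integer(), aa_target = integer(), ref_nt_pos = integer(),
    change = character(), frame_state = integer(),
    frameshift_induced = logical(), indel_net = integer()
  )
}

alignment_columns <- function(alignment) {
  r <- strsplit(alignment$ref_aln, "", fixed = TRUE)[[1]]
  t <- strsplit(alignment$tgt_aln, "", fixed = TRUE)[[1]]
  ref_count <- cumsum(r != "-") # ref bases consumed up to and incl. col
  tgt_count <- cumsum(t != "-")
  state <- ifelse(r == "-", "I", ifelse(t == "-", "D", "M"))
  list(r = r, t = t, ref_count = ref_count, tgt_count = tgt_count, state = state)
}

#' Scan an alignment for frameshift mutations
#'
#' Walks alignment columns left to right maintaining the cumulative net
#' indel length d (target insertions +1 per base, deletions -1). Each
#' maximal indel run whose length is not a multiple of 3 emits one
#' frameshift (FS) record anchored at the reference codon where the run
#' starts; in-frame (mod-3) indels emit nothing. The reading frame is
#' restored wherever d returns to 0 mod 3.
#'
#' @param alignment A `cds_alignment`.
#' @return A mutation tibble (kind `"FS"`) with reference-anchored
#'   (`aa_ref`, `ref_nt_pos`) and target-local (`aa_target`) coordinates,
#'   a canonical `change` descriptor, and the frame state just before the
#'   run (`frame_state`).
#' @export
scan_frameshifts <- function(alignment) {
  stopifnot(inherits(alignment, "cds_alignment"))
  cols <- alignment_columns(alignment)
  runs <- rle(cols$state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  d <- 0L
  for (i in seq_along(runs$values)) {
    st <- runs$values[i]
    if (st == "M") next
    len <- runs$lengths[i]
    col0 <- starts[i]
    signed <- if (st == "I") len else -len
    if (len %% 3L != 0L) {
      if (st == "D") {
        ref0 <- cols$ref_count[col0] - 1L # 0-based first deleted ref base
        change <- sprintf("del %d nt @ ref nt %d", len, ref0 + 1L)
      } else {
        ref0 <- cols$ref_count[col0] # 0-based next ref base
        bases <- paste(cols$t[col0:(col0 + len - 1L)], collapse = "")
        change <- sprintf("ins %d nt %s @ ref nt %d", len, bases, ref0 + 1L)
      }
      tgt0 <- if (st == "I") {
        cols$tgt_count[col0] - 1L
      } else {
        cols$tgt_count[col0]
      }
      out[[length(out) + 1L]] <- tibble(
        gene = alignment$gene,
        species = alignment$species,
        kind = "FS",
        aa_ref = 1L + ref0 %/% 3L,
        aa_target = 1L + tgt0 %/% 3L,
        ref_nt_pos = ref0 + 1L,
        change = change,
        frame_state = d %% 3L,
        frameshift_induced = NA,
        indel_net = signed
      )
    }
    d <- d + signed
  }
  if (length(out) == 0L) {
    return(empty_mutations())
  }
  dplyr::bind_rows(out)
}

#' Scan an alignment for premature stop codons
#'
#' Translates the target in its own running frame (frame shifts applied
#' cumulatively along the alignment) and reports every stop codon lying
#' strictly before the reference's terminal stop. Stops arising only
#' because the frame is shifted at the site (cumulative net indel not a
#' multiple of 3) are retained but flagged `frameshift_induced`; such
#' stops count toward pseudogene status but are excluded from
#' shared-event matching.
#'
#' @param alignment A `cds_alignment`.
#' @param fs_list Frameshift records from [scan_frameshifts()] on the same
#'   alignment (interface companion; the frame state is recomputed from
#'   the identical column walk).
#' @return A mutation tibble (kind `"SC"`).
#' @export
scan_stops <- function(alignment, fs_list = NULL) {
  stopifnot(inherits(alignment, "cds_alignment"))
  cols <- alignment_columns(alignment)
  tgt_cols <- which(cols$t != "-")
  n_codon <- length(tgt_cols) %/% 3L
  if (n_codon == 0L) {
    return(empty_mutations())
  }
  ins_before <- cumsum(cols$state == "I") - (cols$state == "I")
  del_before <- cumsum(cols$state == "D") - (cols$state == "D")
  ref_len <- alignment$ref_length_nt
  out <- list()
  for (ci in seq_len(n_codon)) {
    c3 <- tgt_cols[(3L * ci - 2L):(3L * ci)]
    codon <- paste(cols$t[c3], collapse = "")
    if (!codon %in% STOP_CODONS) next
    col0 <- c3[1]
    ref0 <- if (cols$r[col0] == "-") {
      cols$ref_count[col0]
    } else {
      cols$ref_count[col0] - 1L
    }
    if (ref0 >= ref_len - 3L) next # terminal or beyond: never premature
    d <- ins_before[col0] - del_before[col0]
    out[[length(out) + 1L]] <- tibble(
      gene = alignment$gene,
      species = alignment$species,
      kind = "SC",
      aa_ref = 1L + ref0 %/% 3L,
      aa_target = ci,
      ref_nt_pos = ref0 + 1L,
      change = sprintf("SC @ ref nt %d codon %s", ref0 + 1L, codon),
      frame_state = d %% 3L,
      frameshift_induced = d %% 3L != 0L,
      indel_net = NA_integer_
    )
  }
  if (length(out) == 0L) {
    return(empty_mutations())
  }
  dplyr::bind_rows(out)
}

#' Call the functional status of one gene in one species
#'
#' Status follows a fixed precedence: `absent` when reference coverage is
#' below `absence_threshold`; `partial` when at least one exon is
#' essentially missing (coverage below `partial_low`) while another is
#' essentially present (above `partial_high`); `potential_pseudogene`
#' when the alignment carries one or more frameshifts or premature stop
#' codons (any stop counts toward status; only non-frameshift-induced
#' stops are shareable across species); otherwise `intact`.
#'
#' @param gene,species Labels.
#' @param alignment A `cds_alignment`, or `NULL` when the gene is not
#'   annotated in the target (treated as zero coverage).
#' @param fs_list,sc_list Mutation tibbles from [scan_frameshifts()] and
#'   [scan_stops()].
#' @param exon_map Optional tibble (`exon`, `start`, `end`) giving
#'   reference exon boundaries in 0-based half-open CDS coordinates.
#' @param absence_threshold,partial_low,partial_high Coverage thresholds
#'   (defaults 0.20, 0.20, 0.80).
#' @return A one-row tibble of class `gene_status` with the status, the
#'   mutation counts, `missing_exons` and `mutations` list-columns.
#' @export
call_status <- function(gene, species, alignment, fs_list = NULL,
                        sc_list = NULL, exon_map = NULL,
                        absence_threshold = 0.20, partial_low = 0.20,
                        partial_high = 0.80) {
  if (is.null(fs_list)) fs_list <- empty_mutations()
  if (is.null(sc_list)) sc_list <- empty_mutations()
  cov <- if (is.null(alignment)) 0 else alignment$coverage_frac
  missing_exons <- integer()
  exon_cov <- NULL
  if (!is.null(alignment) && !is.null(exon_map) && nrow(exon_map) > 1L) {
    td <- tidy.cds_alignment(alignment)
    covered <- td$ref_pos[!is.na(td$ref_pos) & td$tgt_base != "-"]
    exon_cov <- vapply(seq_len(nrow(exon_map)), function(i) {
      lo <- exon_map$start[i] + 1L
      hi <- exon_map$end[i]
      sum(covered >= lo & covered <= hi) / (hi - lo + 1L)
    }, 0)
    missing_exons <- exon_map$exon[exon_cov < partial_low]
  }
  status <- if (cov < absence_threshold) {
    "absent"
  } else if (!is.null(exon_cov) &&
    any(exon_cov < partial_low) && any(exon_cov > partial_high)) {
    "partial"
  } else if (nrow(fs_list) + nrow(sc_list) >= 1L) {
    "potential_pseudogene"
  } else {
    "intact"
  }
  muts <- dplyr::bind_rows(fs_list, sc_list)
  out <- tibble(
    gene = gene,
    species = species,
    status = status,
    coverage_frac = cov,
    n_fs = nrow(fs_list),
    n_sc = nrow(sc_list),
    n_sc_shareable = sum(!sc_list$frameshift_induced %in% TRUE),
    missing_exons = list(as.integer(missing_exons)),
    mutations = list(muts)
  )
  class(out) <- c("gene_status", class(out))
  out
}

#' Align, scan and call one gene in one species
#'
#' Convenience wrapper chaining [align_cds()], [scan_frameshifts()],
#' [scan_stops()] and [call_status()].
#'
#' @inheritParams align_cds
#' @inheritParams call_status
#' @param ... Passed to [call_status()].
#' @return A one-row `gene_status` tibble.
#' @export
call_gene <- function(target_nt, reference_nt, gene, species,
                      exon_map = NULL, ...) {
  aln <- align_cds(target_nt, reference_nt, gene = gene, species = species)
  if (is.null(aln)) {
    return(call_status(gene, species, NULL, exon_map = exon_map, ...))
  }
  fs <- scan_frameshifts(aln)
  sc <- scan_stops(aln, fs)
  call_status(gene, species, aln, fs, sc, exon_map = exon_map, ...)
}

#' Tabulate per-species gene content
#'
#' Produces a gene-content summary shaped like published plastome
#' comparisons: total protein-coding genes (inverted-repeat duplicates
#' counted twice), the number of those copies that are duplicated (shown
#' in parentheses in the `display` column), potential pseudogene count,
#' and the number of distinct tRNA and rRNA types.
#'
#' @param statuses Bound `gene_status` rows, one per (gene, species).
#' @param region_assignments A tibble mapping `species` to
#'   region-annotated feature tables (list-column `features`), or a single
#'   feature table used for all species.
#' @return A tibble, one row per species.
#' @export
tabulate_gene_content <- function(statuses, region_assignments) {
  species <- unique(statuses$species)
  get_feats <- function(sp) {
    if (is.data.frame(region_assignments) &&
      "features" %in% names(region_assignments)) {
      region_assignments$features[[
        match(sp, region_assignments$species)
      ]]
    } else {
      region_assignments
    }
  }
  purrr::map_dfr(species, function(sp) {
    f <- get_feats(sp)
    inst <- feature_instances(f)
    ann <- dplyr::distinct(
      f[, c("feature_id", "copy_number")],
      .data$feature_id, .keep_all = TRUE
    )
    inst <- dplyr::left_join(inst, ann, by = "feature_id")
    prot <- inst[inst$feature_class == "protein", , drop = FALSE]
    dup <- sum(prot$copy_number == 2L)
    total <- nrow(prot)
    st <- statuses[statuses$species == sp, , drop = FALSE]
    tibble(
      species = sp,
      total_protein_genes = total,
      duplicated = dup,
      display = sprintf("%d (%d)", total, dup),
      potential_pseudogenes = length(unique(
        st$gene[st$status == "potential_pseudogene"]
      )),
      trna_types = length(unique(inst$gene[inst$feature_class == "tRNA"])),
      rrna_types = length(unique(inst$gene[inst$feature_class == "rRNA"]))
    )
  })
}
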