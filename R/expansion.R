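## bp of a linear interval [s, s+len) falling inside a circular arc
interval_arc_overlap <- function(s, len, region, genome_length) {
  if (len <= 0L || region[["len"]] == 0L) {
    return(0L)
  }
  q <- (s - region[["start"]]) %% genome_length
  ## interval occupies q .. q+len-1 (mod L) in arc-local coordinates;
  ## count how much lies in [0, region len)
  rl <- region[["len"]]
  hi <- q + len
  if (hi <= genome_length) {
    max(0L, min(hi, rl) - q)
  } else {
    max(0L, rl - q) + min(hi - genome_length, rl)
  }
}

#' Assign each gene to its quadripartite region
#'
#' Each annotation instance is labelled with the region (`LSC`, `SSC` or
#' `IR`) containing the majority of its exon bp; instances straddling a
#' junction are labelled by majority rule and flagged. Genes with two
#' instances both inside the repeat arms get `copy_number` 2.
#'
#' @param structure A `quadripartite` object.
#' @param features Feature tibble for the same (canonical) genome.
#' @return The feature tibble with `region`, `straddle` and `copy_number`
#'   columns added (constant within an instance).
#' @export
assign_gene_regions <- function(structure, features) {
  stopifnot(inherits(structure, "quadripartite"))
  features <- validate_features(features, structure$genome_length)
  L <- structure$genome_length
  regions <- list(
    LSC = structure$lsc, SSC = structure$ssc,
    IR = structure$ir_a, IRb = structure$ir_b
  )
  inst <- feature_instances(features)
  per_inst <- purrr::map(inst$feature_id, function(id) {
    ex <- features[features$feature_id == id, , drop = FALSE]
    ov <- vapply(regions, function(rg) {
      sum(vapply(seq_len(nrow(ex)), function(i) {
        interval_arc_overlap(ex$start[i], ex$end[i] - ex$start[i], rg, L)
      }, 0L))
    }, 0L)
    total <- sum(ex$end - ex$start)
    if (sum(ov) != total) {
      stop("feature ", ex$gene[1], " extends outside the genome", call. = FALSE)
    }
    ir_bp <- ov[["IR"]] + ov[["IRb"]]
    bp <- c(LSC = ov[["LSC"]], SSC = ov[["SSC"]], IR = ir_bp)
    lab <- names(bp)[which.max(bp)]
    tibble(
      feature_id = id,
      region = lab,
      straddle = max(bp) < total
    )
  })
  ann <- dplyr::bind_rows(per_inst)
  ann <- dplyr::left_join(
    ann,
    inst[, c("feature_id", "gene")],
    by = "feature_id"
  )
  ir_twins <- ann |>
    dplyr::filter(.data$region == "IR") |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n >= 2L)
  ann$copy_number <- ifelse(
    ann$region == "IR" & ann$gene %in% ir_twins$gene, 2L, 1L
  )
  dplyr::left_join(
    features,
    ann[, c("feature_id", "region", "straddle", "copy_number")],
    by = "feature_id"
  )
}

#' Construct an IR expansion report
#'
#' Validates the internal identity
#' `expansion_total == from_lsc_bp + from_ssc_bp`.
#'
#' @param species Species label.
#' @param ir_len Repeat arm length (bp).
#' @param from_lsc_bp,from_ssc_bp Repeat bp recruited from each
#'   single-copy region.
#' @param genes_from_lsc,genes_from_ssc Counts of formerly single-copy
#'   genes now inside the repeat.
#' @param expansion_total Total expansion bp; computed when `NULL`,
#'   validated against the component sum when supplied.
#' @param ir_len_diff Raw arm-length difference versus the outgroup.
#' @param recruited_genes Tibble of recruited genes
#'   (`gene`, `source_region`, `non_contiguous`).
#' @return A one-row tibble of class `expansion_report`.
#' @export
expansion_report <- function(species, ir_len, from_lsc_bp, from_ssc_bp,
                             genes_from_lsc, genes_from_ssc,
                             expansion_total = NULL,
                             ir_len_diff = NA_integer_,
                             recruited_genes = NULL) {
  if (any(c(from_lsc_bp, from_ssc_bp) < 0)) {
    stop("expansion bp fields must be non-negative", call. = FALSE)
  }
  if (is.null(expansion_total)) {
    expansion_total <- from_lsc_bp + from_ssc_bp
  } else if (expansion_total != from_lsc_bp + from_ssc_bp) {
    stop(
      "expansion_total (", expansion_total,
      ") != from_lsc_bp + from_ssc_bp (", from_lsc_bp + from_ssc_bp, ")",
      call. = FALSE
    )
  }
  if (is.null(recruited_genes)) {
    recruited_genes <- tibble(
      gene = character(), source_region = character(),
      non_contiguous = logical()
    )
  }
  if (nrow(recruited_genes) > 0) {
    n_lsc <- length(unique(recruited_genes$gene[
      recruited_genes$source_region == "LSC"
    ]))
    n_ssc <- length(unique(recruited_genes$gene[
      recruited_genes$source_region == "SSC"
    ]))
    if (n_lsc != genes_from_lsc || n_ssc != genes_from_ssc) {
      stop("recruited gene list does not match gene counts", call. = FALSE)
    }
  }
  out <- tibble(
    species = species,
    ir_len = as.integer(ir_len),
    expansion_total = as.integer(expansion_total),
    from_lsc_bp = as.integer(from_lsc_bp),
    from_ssc_bp = as.integer(from_ssc_bp),
    genes_from_lsc = as.integer(genes_from_lsc),
    genes_from_ssc = as.integer(genes_from_ssc),
    ir_len_diff = as.integer(ir_len_diff),
    recruited_genes = list(recruited_genes)
  )
  class(out) <- c("expansion_report", class(out))
  out
}

## signed arm-local coordinate of a genomic position relative to arm start;
## positions shortly before the arm come out negative
arm_coord <- function(pos, arm, genome_length) {
  d <- (pos - arm[["start"]]) %% genome_length
  ifelse(d > genome_length - genome_length %/% 2L, d - genome_length, d)
}

#' Quantify IR boundary expansion relative to an outgroup
#'
#' Every target gene inside the target repeat whose namesake lies in the
#' outgroup LSC (resp. SSC) counts as recruited from that region; genes
#' resident in the outgroup repeat contribute nothing. Recruited bp are
#' measured on one arm as maximal runs of recruited genes, each run
#' bounded by the midpoint of the intergenic gap between its outermost
#' recruited gene and the nearest non-recruited neighbour (clipped to the
#' arm), so junction bp between genes are attributed symmetrically.
#' Recruited runs not adjacent to the junction facing their source region
#' are flagged `non_contiguous` (internally relocated blocks).
#'
#' @param target,outgroup Lists with elements `plastome`, `features` and
#'   `structure` (canonical presentation). Feature tables may already
#'   carry region assignments; otherwise [assign_gene_regions()] is run.
#' @param species Label for the report (default: target plastome id).
#' @return A one-row `expansion_report` tibble.
#' @export
map_ir_expansion <- function(target, outgroup, species = NULL) {
  t_str <- target$structure
  o_str <- outgroup$structure
  stopifnot(inherits(t_str, "quadripartite"), inherits(o_str, "quadripartite"))
  t_feat <- target$features
  o_feat <- outgroup$features
  if (!"region" %in% names(t_feat)) {
    t_feat <- assign_gene_regions(t_str, t_feat)
  }
  if (!"region" %in% names(o_feat)) {
    o_feat <- assign_gene_regions(o_str, o_feat)
  }
  if (is.null(species)) species <- target$plastome$id
  shared <- intersect(unique(t_feat$gene), unique(o_feat$gene))
  if (length(shared) == 0L) {
    stop("cannot anchor homology: no shared gene names", call. = FALSE)
  }
  o_inst <- feature_instances(o_feat)
  o_region <- o_feat |>
    dplyr::distinct(.data$feature_id, .data$gene, .data$region) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      source_region = if (any(.data$region == "IR")) "IR" else .data$region[1],
      .groups = "drop"
    )
  L <- t_str$genome_length
  arm <- t_str$ir_a
  inst <- feature_instances(t_feat)
  inst <- dplyr::left_join(
    inst,
    dplyr::distinct(
      t_feat[, c("feature_id", "region")],
      .data$feature_id, .keep_all = TRUE
    ),
    by = "feature_id"
  )
  ## genes on arm A, ordered along the arm
  in_arm_a <- inst$region == "IR" &
    vapply(seq_len(nrow(inst)), function(i) {
      u <- arm_coord(inst$span_start[i], arm, L)
      u >= 0 && u < arm[["len"]]
    }, TRUE)
  arm_genes <- inst[in_arm_a, , drop = FALSE]
  arm_genes$u_start <- arm_coord(arm_genes$span_start, arm, L)
  arm_genes$u_end <- arm_genes$u_start + (arm_genes$span_end - arm_genes$span_start)
  arm_genes <- arm_genes[order(arm_genes$u_start), , drop = FALSE]
  arm_genes <- dplyr::left_join(arm_genes, o_region, by = "gene")
  arm_genes$source_region[is.na(arm_genes$source_region)] <- "absent"
  arm_genes$recruited <- arm_genes$source_region %in% c("LSC", "SSC")
  ## nearest single-copy neighbours just outside the arm
  not_arm <- inst[!in_arm_a, , drop = FALSE]
  u_all <- arm_coord(not_arm$span_start, arm, L)
  left_u <- u_all + (not_arm$span_end - not_arm$span_start)
  left_ok <- left_u <= 0
  left_edge_u <- if (any(left_ok)) max(left_u[left_ok]) else 0L
  right_ok <- u_all >= arm[["len"]]
  right_edge_u <- if (any(right_ok)) min(u_all[right_ok]) else arm[["len"]]

  measure_runs <- function(source) {
    rec <- arm_genes$recruited & arm_genes$source_region == source
    if (!any(rec)) {
      return(list(bp = 0L, runs = NULL))
    }
    r <- rle(rec)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    run_rows <- which(r$values)
    bp <- 0L
    run_info <- vector("list", length(run_rows))
    for (ri in seq_along(run_rows)) {
      i <- run_rows[ri]
      first <- lo[i]
      last <- hi[i]
      left_anchor <- if (first == 1L) left_edge_u else arm_genes$u_end[first - 1L]
      right_anchor <- if (last == nrow(arm_genes)) {
        right_edge_u
      } else {
        arm_genes$u_start[last + 1L]
      }
      a <- floor((left_anchor + arm_genes$u_start[first]) / 2)
      b <- ceiling((arm_genes$u_end[last] + right_anchor) / 2)
      a <- max(a, 0L)
      b <- min(b, arm[["len"]])
      bp <- bp + max(0L, b - a)
      run_info[[ri]] <- tibble(
        gene = arm_genes$gene[first:last],
        source_region = source,
        run = ri
      )
    }
    runs <- dplyr::bind_rows(run_info)
    ## the run touching the junction that faces the source region is the
    ## contiguous expansion; LSC faces the arm start, SSC the arm end
    junction_run <- if (source == "LSC") 1L else max(runs$run)
    runs$non_contiguous <- runs$run != junction_run
    list(bp = as.integer(bp), runs = runs[, c("gene", "source_region", "non_contiguous")])
  }
  lsc <- measure_runs("LSC")
  ssc <- measure_runs("SSC")
  recruited <- dplyr::bind_rows(lsc$runs, ssc$runs)
  if (is.null(recruited) || nrow(recruited) == 0L) {
    recruited <- tibble(
      gene = character(), source_region = character(),
      non_contiguous = logical()
    )
  }
  expansion_report(
    species = species,
    ir_len = arm[["len"]],
    from_lsc_bp = lsc$bp,
    from_ssc_bp = ssc$bp,
    genes_from_lsc = length(unique(recruited$gene[recruited$source_region == "LSC"])),
    genes_from_ssc = length(unique(recruited$gene[recruited$source_region == "SSC"])),
    ir_len_diff = arm[["len"]] - o_str$ir_a[["len"]],
    recruited_genes = recruited
  )
}

#' Summarise quadripartite structures and expansion reports
#'
#' Produces a publication-shaped per-species table of plastome component
#' sizes and IR expansion. The plastome length is recomposed as
#' `LSC + SSC + 2*IR`; any mismatch with the measured (or printed) genome
#' length raises a warning and is flagged in `length_mismatch`, since
#' published component tables occasionally violate the identity.
#'
#' @param components A tibble with columns `species`, `plastome_length`,
#'   `lsc_len`, `ssc_len`, `ir_len`, or a named list of `quadripartite`
#'   objects.
#' @param reports Optional `expansion_report` rows (bound together) to
#'   join by species.
#' @return A tibble, one row per species, in component-table column order.
#' @export
summarize_structures <- function(components, reports = NULL) {
  if (is.list(components) && !is.data.frame(components)) {
    components <- purrr::imap_dfr(components, function(s, nm) {
      g <- glance.quadripartite(s)
      tibble(
        species = nm,
        plastome_length = g$genome_length,
        lsc_len = g$lsc_len,
        ssc_len = g$ssc_len,
        ir_len = g$ir_len
      )
    })
  }
  components <- as_tibble(components)
  out <- components |>
    dplyr::mutate(
      composed_length = .data$lsc_len + .data$ssc_len + 2L * .data$ir_len,
      length_mismatch = .data$composed_length != .data$plastome_length
    )
  if (any(out$length_mismatch)) {
    warning(
      "component lengths do not compose to the stated plastome length for: ",
      paste(out$species[out$length_mismatch], collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(reports) && nrow(reports) > 0L) {
    rep_cols <- dplyr::select(
      as_tibble(reports), "species", "expansion_total",
      "from_lsc_bp", "from_ssc_bp", "genes_from_lsc", "genes_from_ssc"
    )
    out <- dplyr::left_join(out, rep_cols, by = "species")
  }
  out
}
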