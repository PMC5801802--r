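#' Pipeline configuration
#'
#' All stage thresholds in one validated object. Unknown keys are
#' rejected; the defaults are serialized into every run's manifest.
#'
#' @param min_ir_len Minimum inverted-repeat arm length (bp).
#' @param max_mismatch_frac Maximum mismatch fraction between repeat arms.
#' @param coverage_window Rolling-median window for coverage-based repeat
#'   detection (bp).
#' @param coverage_low,coverage_high Depth-ratio band for "approximately
#'   two times" coverage.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring.
#' @param absence_threshold,partial_low,partial_high Gene-status coverage
#'   thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_ir_len = 1000L, max_mismatch_frac = 0.005,
                            coverage_window = 200L, coverage_low = 1.7,
                            coverage_high = 2.5, match = 2L, mismatch = -3L,
                            gap_open = -8L, gap_ext = -2L,
                            absence_threshold = 0.2, partial_low = 0.2,
                            partial_high = 0.8) {
  structure(
    list(
      min_ir_len = as.integer(min_ir_len),
      max_mismatch_frac = max_mismatch_frac,
      coverage_window = as.integer(coverage_window),
      coverage_low = coverage_low, coverage_high = coverage_high,
      match = as.integer(match), mismatch = as.integer(mismatch),
      gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
      absence_threshold = absence_threshold,
      partial_low = partial_low, partial_high = partial_high
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are arguments of [pipeline_config()];
#'   unknown keys are an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop(
      "unknown configuration keys: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(pipeline_config, vals)
}

load_species_bundle <- function(dir) {
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  species <- sub("\\.fasta$", "", basename(fastas))
  data <- purrr::map(seq_along(species), function(i) {
    p <- load_plastome(fastas[i])
    p$id <- species[i]
    feats <- load_features(
      file.path(dir, paste0(species[i], ".features.tsv")), p$length
    )
    covf <- file.path(dir, paste0(species[i], ".coverage.tsv"))
    cov <- if (file.exists(covf)) read_coverage(covf, p$length) else NULL
    list(plastome = p, features = feats, coverage = cov)
  })
  names(data) <- species
  tree_file <- file.path(dir, "tree.nwk")
  tree <- if (file.exists(tree_file)) ape::read.tree(tree_file) else NULL
  list(species = data, tree = tree)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Run the full comparative plastome pipeline
#'
#' Executes, for every species: repeat detection, quadripartite
#' partitioning and canonicalization, gene region assignment, (when
#' coverage is available) coverage-based repeat calls, expansion mapping
#' against the outgroup, pseudogene calling of every outgroup protein
#' gene, shared-event collection and Dollo placement on the tree. Any
#' stage error aborts with the stage name.
#'
#' @param input A `sim_result` from [simulate_plastomes()], or a
#'   directory holding `<species>.fasta`, `<species>.features.tsv`,
#'   optional `<species>.coverage.tsv` and `tree.nwk` (the layout written
#'   by [write_simulation()]).
#' @param outgroup Species label of the functional reference genome.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, publication-shaped TSV
#'   reports, a mutations table, per-gene frame/stop tracks (JSON), the
#'   decorated Newick tree and a run manifest are written.
#' @return A list of class `plastome_pipeline` with elements
#'   `structures`, `structure_table`, `coverage_calls`, `expansion`,
#'   `statuses`, `mutations`, `gene_content`, `events`, `placements`,
#'   `decorated`, `manifest`.
#' @export
run_pipeline <- function(input, outgroup, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(input, "sim_result")) {
    species_data <- purrr::imap(input$leaves, function(lf, nm) {
      list(
        plastome = lf$plastome, features = lf$features,
        coverage = input$coverage[[nm]]
      )
    })
    tree <- input$tree
  } else if (is.character(input) && dir.exists(input)) {
    bundle <- load_species_bundle(input)
    species_data <- bundle$species
    tree <- bundle$tree
  } else {
    stop("input must be a sim_result or a directory", call. = FALSE)
  }
  species <- names(species_data)
  if (!outgroup %in% species) {
    stop("outgroup '", outgroup, "' not among inputs", call. = FALSE)
  }

  ## stage 1-2: repeat detection and canonical presentation
  canon <- run_stage("detect_ir", {
    purrr::imap(species_data, function(d, nm) {
      pair <- find_inverted_repeat(
        d$plastome, config$min_ir_len, config$max_mismatch_frac
      )
      if (!pair$found) {
        stop("no IR found in ", nm)
      }
      str0 <- partition_quadripartite(d$plastome, pair)
      can <- canonicalize(d$plastome, str0)
      feats <- shift_features(d$features, can$offset, d$plastome$length)
      feats <- validate_features(feats, d$plastome$length)
      list(
        plastome = can$plastome, structure = can$structure,
        features = feats, coverage = d$coverage
      )
    })
  })

  ## stage 3: region assignment
  canon <- run_stage("assign_regions", {
    purrr::map(canon, function(d) {
      d$features <- assign_gene_regions(d$structure, d$features)
      d
    })
  })

  ## stage 4: coverage-based repeat calls
  coverage_calls <- run_stage("coverage_ir", {
    purrr::imap_dfr(species_data, function(d, nm) {
      if (is.null(d$coverage)) {
        return(tibble())
      }
      calls <- detect_ir_from_coverage(
        d$coverage, config$coverage_window,
        config$coverage_low, config$coverage_high
      )
      dplyr::mutate(calls, species = nm, .before = 1L)
    })
  })

  ## stage 5: expansion vs the outgroup
  expansion <- run_stage("expansion", {
    targets <- setdiff(species, outgroup)
    purrr::map_dfr(targets, function(nm) {
      map_ir_expansion(canon[[nm]], canon[[outgroup]], species = nm)
    })
  })

  ## stage 6: pseudogene calling against the outgroup copies
  og <- canon[[outgroup]]
  og_inst <- feature_instances(og$features)
  og_prot <- og_inst[og_inst$feature_class == "protein", , drop = FALSE]
  og_prot <- og_prot[!duplicated(og_prot$gene), , drop = FALSE]
  statuses <- run_stage("pseudogenes", {
    purrr::map_dfr(setdiff(species, outgroup), function(nm) {
      tgt <- canon[[nm]]
      tgt_inst <- feature_instances(tgt$features)
      purrr::map_dfr(seq_len(nrow(og_prot)), function(i) {
        gene <- og_prot$gene[i]
        ref_nt <- get_cds(og$plastome, og$features, og_prot$feature_id[i])
        exon_map <- reference_exon_map(og$features, og_prot$feature_id[i])
        ti <- tgt_inst[tgt_inst$gene == gene &
          tgt_inst$feature_class == "protein", , drop = FALSE]
        tgt_nt <- if (nrow(ti) == 0L) {
          NULL
        } else {
          get_cds(tgt$plastome, tgt$features, ti$feature_id[1])
        }
        aln <- align_cds(tgt_nt, ref_nt, gene = gene, species = nm,
          match = config$match, mismatch = config$mismatch,
          gap_open = config$gap_open, gap_ext = config$gap_ext
        )
        if (is.null(aln)) {
          return(call_status(gene, nm, NULL, exon_map = exon_map,
            absence_threshold = config$absence_threshold,
            partial_low = config$partial_low,
            partial_high = config$partial_high
          ))
        }
        fs <- scan_frameshifts(aln)
        sc <- scan_stops(aln, fs)
        st <- call_status(gene, nm, aln, fs, sc, exon_map = exon_map,
          absence_threshold = config$absence_threshold,
          partial_low = config$partial_low,
          partial_high = config$partial_high
        )
        st$ref_length_nt <- aln$ref_length_nt
        st
      })
    })
  })
  mutations <- dplyr::bind_rows(statuses$mutations)
  if (nrow(mutations) == 0L) mutations <- empty_mutations()

  ## stage 7: shared events and Dollo placement
  events <- run_stage("shared_events", collect_events(mutations))
  single <- singleton_mutations(mutations, events)
  placements <- run_stage("placement", {
    if (is.null(tree)) {
      tibble()
    } else {
      all_ev <- dplyr::bind_rows(
        as_tibble(events)[, c("event_id", "gene", "kind", "species_set")],
        single
      )
      all_ev$event_id <- seq_len(nrow(all_ev))
      place_events(all_ev, tree)
    }
  })
  decorated <- if (is.null(tree) || nrow(placements) == 0L) {
    NULL
  } else {
    decorate_tree(placements, tree)
  }

  structures <- purrr::map(canon, "structure")
  structure_table <- summarize_structures(structures, expansion)
  gene_content <- tabulate_gene_content(
    statuses,
    tibble(
      species = species,
      features = purrr::map(canon, "features")
    )
  )
  manifest <- list(
    package = "plastomics",
    version = as.character(utils::packageVersion("plastomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = c(
      "detect_ir", "assign_regions", "coverage_ir", "expansion",
      "pseudogenes", "shared_events", "placement"
    ),
    outgroup = outgroup,
    species = species,
    genome_lengths = purrr::map_int(species_data, ~ .x$plastome$length),
    config = unclass(config)
  )
  out <- structure(
    list(
      structures = structures, structure_table = structure_table,
      coverage_calls = coverage_calls, expansion = expansion,
      statuses = statuses, mutations = mutations,
      gene_content = gene_content, events = events,
      placements = placements, decorated = decorated, manifest = manifest
    ),
    class = "plastome_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  out
}

## reference exon boundaries in CDS coordinates for one instance
reference_exon_map <- function(features, feature_id) {
  f <- features[features$feature_id == feature_id, , drop = FALSE]
  f <- f[order(f$exon, f$segment), , drop = FALSE]
  lens <- tapply(f$end - f$start, f$exon, sum)
  ends <- cumsum(as.integer(lens))
  tibble(
    exon = as.integer(names(lens)),
    start = c(0L, ends[-length(ends)]),
    end = ends
  )
}

singleton_mutations <- function(mutations, events) {
  if (nrow(mutations) == 0L) {
    return(tibble(
      event_id = integer(), gene = character(), kind = character(),
      species_set = list()
    ))
  }
  shareable <- mutations[!(mutations$kind == "SC" &
    mutations$frameshift_induced %in% TRUE), , drop = FALSE]
  long <- write_shared_table(events)
  in_event <- paste(shareable$gene, shareable$kind, shareable$species) %in%
    paste(long$gene, long$kind, long$species)
  rest <- shareable[!in_event, , drop = FALSE]
  if (nrow(rest) == 0L) {
    return(tibble(
      event_id = integer(), gene = character(), kind = character(),
      species_set = list()
    ))
  }
  rest |>
    dplyr::distinct(.data$gene, .data$kind, .data$species) |>
    dplyr::mutate(
      event_id = NA_integer_,
      species_set = as.list(.data$species)
    ) |>
    dplyr::select("event_id", "gene", "kind", "species_set")
}

#' Write the pipeline report bundle
#'
#' @param pipeline A `plastome_pipeline` result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_reports <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(
    pipeline$structure_table, file.path(out_dir, "structures.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    pipeline$gene_content, file.path(out_dir, "gene_content.tsv"),
    progress = FALSE
  )
  mut <- pipeline$mutations
  readr::write_tsv(
    mut[, c("gene", "species", "kind", "aa_ref", "aa_target", "ref_nt_pos",
      "change", "frameshift_induced")],
    file.path(out_dir, "mutations.tsv"),
    progress = FALSE
  )
  write_shared_table(pipeline$events, file.path(out_dir, "shared_events.tsv"))
  if (nrow(pipeline$coverage_calls) > 0L) {
    readr::write_tsv(
      pipeline$coverage_calls, file.path(out_dir, "coverage_ir.tsv"),
      progress = FALSE
    )
  }
  if (!is.null(pipeline$decorated)) {
    writeLines(
      pipeline$decorated$newick, file.path(out_dir, "decorated_tree.nwk")
    )
    readr::write_tsv(
      pipeline$placements, file.path(out_dir, "placements.tsv"),
      progress = FALSE
    )
  }
  jsonlite::write_json(
    gene_tracks(pipeline$statuses),
    file.path(out_dir, "gene_tracks.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    pipeline$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Per-gene frame/stop tracks for pseudogene figures
#'
#' For every (gene, species) the track records the amino-acid segments
#' whose reading frame is shifted, premature stop positions and missing
#' exons — the machine-readable form of the classic pseudogene figure
#' (shifted frame shaded, stops as vertical lines).
#'
#' @param statuses Bound `gene_status` rows carrying a `ref_length_nt`
#'   column.
#' @return A list, one element per (gene, species).
#' @export
gene_tracks <- function(statuses) {
  purrr::map(seq_len(nrow(statuses)), function(i) {
    st <- statuses[i, ]
    mut <- st$mutations[[1]]
    aa_len <- if ("ref_length_nt" %in% names(st) && !is.na(st$ref_length_nt)) {
      st$ref_length_nt %/% 3L
    } else {
      NA_integer_
    }
    fs <- mut[mut$kind == "FS", , drop = FALSE]
    segs <- list()
    if (nrow(fs) > 0L && !is.na(aa_len)) {
      fs <- fs[order(fs$ref_nt_pos), , drop = FALSE]
      d <- 0L
      for (j in seq_len(nrow(fs))) {
        d_new <- d + fs$indel_net[j]
        if (d %% 3L == 0L && d_new %% 3L != 0L) {
          ## shift starts here; ends at next frame restoration or gene end
          k <- j
          dk <- d_new
          end_aa <- aa_len
          while (k < nrow(fs)) {
            k <- k + 1L
            dk <- dk + fs$indel_net[k]
            if (dk %% 3L == 0L) {
              end_aa <- fs$aa_ref[k]
              break
            }
          }
          segs[[length(segs) + 1L]] <- list(
            from_aa = fs$aa_ref[j], to_aa = end_aa
          )
        }
        d <- d_new
      }
    }
    list(
      gene = st$gene,
      species = st$species,
      status = st$status,
      aa_length = aa_len,
      shifted_frame = segs,
      stops = mut$aa_ref[mut$kind == "SC"],
      missing_exons = st$missing_exons[[1]]
    )
  })
}

#' @export
print.plastome_pipeline <- function(x, ...) {
  cat("<plastome_pipeline>\n")
  cat(" species:", paste(x$manifest$species, collapse = ", "), "\n")
  cat(
    " statuses:", nrow(x$statuses), "gene calls;",
    nrow(x$mutations), "mutations;", nrow(x$events), "shared events\n"
  )
  invisible(x)
}
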