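#' Collect inactivating mutations shared by two or more species
#'
#' Mutations produced against one common reference are grouped by gene,
#' kind and reference-anchored nucleotide position. Groups of two or more
#' species with byte-identical change descriptors are classed
#' `identical` — the signature of a single ancestral mutation. Mutations
#' falling in the same reference codon with differing descriptors (or
#' differing positions within the codon) in two or more species are
#' classed `convergent_same_site`: independent hits of one amino-acid
#' position. Frameshift-induced stop codons are excluded before grouping,
#' and singleton mutations are not events.
#'
#' @param mutations Bound mutation tibbles for all species (the format of
#'   [scan_frameshifts()]/[scan_stops()]).
#' @return A tibble of class `shared_events`, one row per event:
#'   `event_id`, `gene`, `kind`, `ref_nt_pos`, `change`,
#'   `identity_class`, `n_species`, plus list-columns `species_set` and
#'   `per_species_aa` (species -> target-local amino-acid position).
#' @export
collect_events <- function(mutations) {
  mutations <- as_tibble(mutations)
  if (nrow(mutations) == 0L) {
    return(empty_shared_events())
  }
  mutations <- mutations[!(mutations$kind == "SC" &
    mutations$frameshift_induced %in% TRUE), , drop = FALSE]
  ## one reference per gene: positions must be comparable
  if ("ref_length_nt" %in% names(mutations)) {
    chk <- tapply(mutations$ref_length_nt, mutations$gene, function(x) {
      length(unique(x))
    })
    if (any(chk > 1L)) {
      stop(
        "mutations for one gene reference different reference lengths: ",
        paste(names(chk)[chk > 1L], collapse = ", "),
        call. = FALSE
      )
    }
  }
  mutations <- dplyr::arrange(
    mutations, .data$gene, .data$ref_nt_pos, .data$kind, .data$species
  )
  ## identical events: same gene, kind, position and exact change
  ident_keys <- mutations |>
    dplyr::distinct(
      .data$gene, .data$kind, .data$ref_nt_pos, .data$change, .data$species
    ) |>
    dplyr::count(.data$gene, .data$kind, .data$ref_nt_pos, .data$change) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::select(!"n")
  ident <- if (nrow(ident_keys) == 0L) {
    NULL
  } else {
    mutations |>
      dplyr::semi_join(
        ident_keys,
        by = c("gene", "kind", "ref_nt_pos", "change")
      ) |>
      dplyr::group_by(.data$gene, .data$kind, .data$ref_nt_pos, .data$change) |>
      dplyr::summarise(
        species_set = list(sort(unique(.data$species))),
        per_species_aa = list(stats::setNames(.data$aa_target, .data$species)),
        .groups = "drop"
      ) |>
      dplyr::mutate(identity_class = "identical")
  }
  ## convergent events: same reference codon, not byte-identical
  rest <- dplyr::anti_join(
    mutations, ident_keys,
    by = c("gene", "kind", "ref_nt_pos", "change")
  )
  rest$aa_codon <- 1L + (rest$ref_nt_pos - 1L) %/% 3L
  conv_keys <- rest |>
    dplyr::distinct(.data$gene, .data$kind, .data$aa_codon, .data$species) |>
    dplyr::count(.data$gene, .data$kind, .data$aa_codon) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::select(!"n")
  conv <- if (nrow(conv_keys) == 0L) {
    NULL
  } else {
    rest |>
      dplyr::semi_join(conv_keys, by = c("gene", "kind", "aa_codon")) |>
      dplyr::group_by(.data$gene, .data$kind, .data$aa_codon) |>
      dplyr::summarise(
        ref_nt_pos = min(.data$ref_nt_pos),
        change = paste(sort(unique(.data$change)), collapse = " | "),
        species_set = list(sort(unique(.data$species))),
        per_species_aa = list(stats::setNames(.data$aa_target, .data$species)),
        .groups = "drop"
      ) |>
      dplyr::mutate(identity_class = "convergent_same_site") |>
      dplyr::select(!"aa_codon")
  }
  out <- dplyr::bind_rows(ident, conv)
  if (nrow(out) == 0L) {
    return(empty_shared_events())
  }
  out <- dplyr::arrange(out, .data$gene, .data$ref_nt_pos, .data$kind)
  out$event_id <- seq_len(nrow(out))
  out$n_species <- lengths(out$species_set)
  out <- out[, c(
    "event_id", "gene", "kind", "ref_nt_pos", "change",
    "identity_class", "n_species", "species_set", "per_species_aa"
  )]
  class(out) <- c("shared_events", class(out))
  out
}

empty_shared_events <- function() {
  out <- tibble(
    event_id = integer(), gene = character(), kind = character(),
    ref_nt_pos = integer(), change = character(),
    identity_class = character(), n_species = integer(),
    species_set = list(), per_species_aa = list()
  )
  class(out) <- c("shared_events", class(out))
  out
}

#' Expand shared events to one row per (event, species)
#'
#' The layout mirrors published shared-mutation tables: rows of one event
#' are adjacent and share an `event_id`; amino-acid positions are
#' species-local and may differ within one event.
#'
#' @param events A `shared_events` tibble.
#' @param path Optional path; when given the table is written as TSV.
#' @return The long-format tibble (invisibly when `path` is given).
#' @export
write_shared_table <- function(events, path = NULL) {
  long <- if (nrow(events) == 0L) {
    tibble(
      event_id = integer(), gene = character(), species = character(),
      aa_target = integer(), kind = character(), ref_nt_pos = integer(),
      identity_class = character()
    )
  } else {
    purrr::pmap_dfr(
      list(
        events$event_id, events$gene, events$kind, events$ref_nt_pos,
        events$identity_class, events$species_set, events$per_species_aa
      ),
      function(id, gene, kind, pos, cls, sset, aamap) {
        tibble(
          event_id = id,
          gene = gene,
          species = sset,
          aa_target = as.integer(aamap[sset]),
          kind = kind,
          ref_nt_pos = pos,
          identity_class = cls
        )
      }
    )
  }
  if (!is.null(path)) {
    readr::write_tsv(long, path, progress = FALSE)
    return(invisible(long))
  }
  long
}
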