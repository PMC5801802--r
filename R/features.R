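FEATURE_CLASSES <- c("protein", "tRNA", "rRNA")

feature_columns <- c(
  "feature_id", "gene", "feature_class", "strand",
  "exon", "segment", "start", "end", "wrap"
)

empty_features <- function() {
  tibble(
    feature_id = integer(), gene = character(), feature_class = character(),
    strand = character(), exon = integer(), segment = integer(),
    start = integer(), end = integer(), wrap = logical()
  )
}

#' Build a gene feature table
#'
#' The internal feature representation is a tibble with one row per exon
#' segment: `feature_id` identifies an annotation instance (inverted-repeat
#' duplicates of one gene are two instances sharing a `gene` name), `exon`
#' numbers the exons of an instance in transcription order, and
#' `start`/`end` are 0-based half-open coordinates on the forward strand.
#' Exons wrapping the origin are stored as two ordered segments
#' (`segment` 1 and 2) flagged `wrap = TRUE`.
#'
#' @param gene Gene symbols, one per exon row.
#' @param feature_class One of `"protein"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param exon 1-based exon index within the instance.
#' @param start,end 0-based half-open interval on the forward strand.
#' @param feature_id Annotation instance id; defaults to one instance per
#'   distinct `gene` value.
#' @param genome_length Genome length used to validate intervals.
#' @return A validated feature tibble.
#' @export
gene_features <- function(gene, feature_class, strand, exon, start, end,
                          feature_id = NULL, genome_length = NULL) {
  if (is.null(feature_id)) {
    feature_id <- match(gene, unique(gene))
  }
  tbl <- tibble(
    feature_id = as.integer(feature_id),
    gene = as.character(gene),
    feature_class = as.character(feature_class),
    strand = as.character(strand),
    exon = as.integer(exon),
    segment = 1L,
    start = as.integer(start),
    end = as.integer(end),
    wrap = FALSE
  )
  validate_features(tbl, genome_length)
}

validate_features <- function(features, genome_length = NULL) {
  stopifnot(is.data.frame(features))
  features <- as_tibble(features)
  if (!"segment" %in% names(features)) features$segment <- 1L
  if (!"wrap" %in% names(features)) features$wrap <- FALSE
  missing_cols <- setdiff(feature_columns, names(features))
  if (length(missing_cols) > 0L) {
    stop(
      "feature table missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_class <- setdiff(unique(features$feature_class), FEATURE_CLASSES)
  if (length(bad_class) > 0L) {
    stop(
      "unknown feature class: ", paste(bad_class, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(features$end <= features$start)) {
    stop("feature intervals must have end > start", call. = FALSE)
  }
  if (!is.null(genome_length)) {
    over <- features$end > genome_length & !features$wrap
    if (any(over)) {
      stop(
        "feature interval beyond genome length without wrap declaration: ",
        paste(unique(features$gene[over]), collapse = ", "),
        call. = FALSE
      )
    }
  }
  ## protein instances must keep a translatable length
  prot <- features[features$feature_class == "protein", , drop = FALSE]
  if (nrow(prot) > 0L) {
    len <- tapply(prot$end - prot$start, prot$feature_id, sum)
    if (any(len < 3L)) {
      short <- unique(prot$gene[prot$feature_id %in%
        as.integer(names(len)[len < 3L])])
      stop(
        "protein feature shorter than one codon: ",
        paste(short, collapse = ", "),
        call. = FALSE
      )
    }
  }
  ## exons of one instance must not overlap
  by_id <- split(features, features$feature_id)
  for (f in by_id) {
    if (nrow(f) < 2L) next
    o <- order(f$start)
    if (any(f$start[o][-1] < f$end[o][-nrow(f)])) {
      stop(
        "overlapping exons in feature ", f$gene[1],
        call. = FALSE
      )
    }
  }
  features <- features[order(
    vapply(
      features$feature_id,
      function(id) min(features$start[features$feature_id == id]), 0L
    ),
    features$feature_id, features$exon, features$segment
  ), ]
  features[, feature_columns]
}

#' Read gene features from GFF3 or the minimal TSV dialect
#'
#' The TSV dialect has columns `name`, `class`, `strand`, `exons`
#' (comma-separated 1-based inclusive ranges, e.g. `100-639,1740-2292`) and
#' an optional `wrap` column (`yes`/`no`). GFF3 files (recognised by a
#' `.gff`/`.gff3` extension or a `##gff-version` first line) are read with
#' rtracklayer; `CDS` records grouped by gene become protein features and
#' `tRNA`/`rRNA` records keep their type.
#'
#' @param table_path Path to the annotation file.
#' @param genome_length Genome length in bp, used for interval validation.
#' @return A feature tibble (see [gene_features()]), one row per exon,
#'   sorted by start, with 0-based half-open coordinates.
#' @export
load_features <- function(table_path, genome_length) {
  if (!file.exists(table_path)) {
    stop("file not found: ", table_path, call. = FALSE)
  }
  first <- readLines(table_path, n = 1L)
  is_gff <- grepl("\\.gff3?$", table_path, ignore.case = TRUE) ||
    startsWith(first, "##gff-version")
  if (is_gff) {
    return(load_features_gff3(table_path, genome_length))
  }
  raw <- readr::read_tsv(
    table_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(raw) <- tolower(names(raw))
  needed <- c("name", "class", "strand", "exons")
  if (!all(needed %in% names(raw))) {
    stop(
      "feature TSV must have columns name, class, strand, exons",
      call. = FALSE
    )
  }
  if (!"wrap" %in% names(raw)) raw$wrap <- "no"
  rows <- purrr::pmap(
    list(raw$name, raw$class, raw$strand, raw$exons, raw$wrap, seq_len(nrow(raw))),
    function(name, cls, strand, exons, wrap, id) {
      parts <- strsplit(exons, ",", fixed = TRUE)[[1]]
      m <- regmatches(parts, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", parts))
      if (any(lengths(m) != 3L)) {
        stop("malformed exon ranges for ", name, ": ", exons, call. = FALSE)
      }
      lo <- as.integer(vapply(m, `[`, "", 2L))
      hi <- as.integer(vapply(m, `[`, "", 3L))
      wrapping <- isTRUE(tolower(wrap) %in% c("yes", "true", "1"))
      segs <- purrr::map2(lo, hi, function(a, b) {
        ## 1-based inclusive input -> 0-based half-open
        s <- a - 1L
        e <- b
        if (e > genome_length) {
          if (!wrapping) {
            stop(
              "exon of ", name, " ends beyond genome length (", e, " > ",
              genome_length, ") without wrap declaration",
              call. = FALSE
            )
          }
          list(
            c(start = s, end = genome_length, segment = 1L, wrap = 1L),
            c(start = 0L, end = e - genome_length, segment = 2L, wrap = 1L)
          )
        } else {
          list(c(start = s, end = e, segment = 1L, wrap = 0L))
        }
      })
      ex_idx <- rep(seq_along(segs), lengths(segs))
      segs <- purrr::flatten(segs)
      tibble(
        feature_id = id,
        gene = name,
        feature_class = cls,
        strand = strand,
        exon = ex_idx,
        segment = vapply(segs, `[[`, 0L, "segment"),
        start = vapply(segs, `[[`, 0L, "start"),
        end = vapply(segs, `[[`, 0L, "end"),
        wrap = vapply(segs, `[[`, 0L, "wrap") == 1L
      )
    }
  )
  validate_features(dplyr::bind_rows(rows), genome_length)
}

load_features_gff3 <- function(path, genome_length) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  keep <- type %in% c("CDS", "tRNA", "rRNA")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no CDS/tRNA/rRNA records in ", path, call. = FALSE)
  }
  name <- if ("gene" %in% names(df) && !all(is.na(df$gene))) {
    df$gene
  } else if ("Name" %in% names(df)) {
    df$Name
  } else {
    df$ID
  }
  cls <- c(CDS = "protein", tRNA = "tRNA", rRNA = "rRNA")[as.character(df$type)]
  key <- paste(name, cls, df$strand, sep = "\r")
  id <- match(key, unique(key))
  tbl <- tibble(
    feature_id = id,
    gene = as.character(name),
    feature_class = unname(cls),
    strand = as.character(df$strand),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    wrap = FALSE
  )
  tbl <- tbl[order(tbl$feature_id, tbl$start), ]
  tbl$exon <- stats::ave(tbl$start, tbl$feature_id, FUN = seq_along)
  tbl$segment <- 1L
  validate_features(tbl, genome_length)
}

#' Write a feature table in the minimal TSV dialect
#'
#' @param features Feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  features <- validate_features(features)
  rows <- features |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      name = .data$gene[1],
      class = .data$feature_class[1],
      strand = .data$strand[1],
      exons = paste(
        sprintf("%d-%d", .data$start + 1L, .data$end),
        collapse = ","
      ),
      wrap = if (any(.data$wrap)) "yes" else "no",
      .groups = "drop"
    ) |>
    dplyr::select(!"feature_id")
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Extract the spliced coding sequence of a feature instance
#'
#' Exons are concatenated in exon order; minus-strand features are
#' reverse-complemented so the returned string reads 5' to 3'.
#'
#' @param x A [plastome] (or plain sequence string).
#' @param features Feature tibble.
#' @param id `feature_id` of the instance to extract.
#' @return Character string, the spliced sequence.
#' @export
get_cds <- function(x, features, id) {
  f <- features[features$feature_id == id, , drop = FALSE]
  if (nrow(f) == 0L) {
    stop("no feature with id ", id, call. = FALSE)
  }
  f <- f[order(f$exon, f$segment), , drop = FALSE]
  seq <- if (inherits(x, "plastome")) x$sequence else x
  pieces <- substring(seq, f$start + 1L, f$end)
  s <- paste(pieces, collapse = "")
  if (f$strand[1] == "-") revcomp(s) else s
}

## one row per feature instance with its genomic span and total length
feature_instances <- function(features) {
  features |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      gene = .data$gene[1],
      feature_class = .data$feature_class[1],
      strand = .data$strand[1],
      span_start = min(.data$start),
      span_end = max(.data$end),
      cds_len = sum(.data$end - .data$start),
      n_exons = max(.data$exon),
      .groups = "drop"
    )
}
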