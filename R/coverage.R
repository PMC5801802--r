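#' Read a per-base coverage track
#'
#' Accepts a two-column TSV (`pos` 1-based, `depth`) or a BedGraph file
#' (`chrom`, 0-based half-open `start`/`end`, `value`; recognised by a
#' `.bedgraph`/`.bg` extension or four columns). Positions absent from the
#' file get depth 0.
#'
#' @param path Path to the coverage file.
#' @param genome_length Expected track length; inferred from the file
#'   maximum when `NULL`.
#' @return A numeric vector of class `coverage_track`, one depth per
#'   genome position.
#' @export
read_coverage <- function(path, genome_length = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  is_bg <- grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
    stringsAsFactors = FALSE, comment.char = "#"
  )
  if (is.character(tab[[1]]) && !is_bg) is_bg <- ncol(tab) >= 4L
  if (is_bg) {
    if (ncol(tab) < 4L) {
      stop("BedGraph file needs 4 columns", call. = FALSE)
    }
    n <- if (is.null(genome_length)) max(tab[[3]]) else genome_length
    depth <- numeric(n)
    for (r in seq_len(nrow(tab))) {
      lo <- tab[r, 2] + 1L
      hi <- min(tab[r, 3], n)
      if (hi >= lo) depth[lo:hi] <- tab[r, 4]
    }
  } else {
    ## tolerate a header line
    if (is.character(tab[[1]])) {
      tab <- utils::read.table(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE
      )
    }
    n <- if (is.null(genome_length)) max(tab[[1]]) else genome_length
    depth <- numeric(n)
    depth[tab[[1]]] <- tab[[2]]
  }
  coverage_track(depth)
}

#' Construct a coverage track
#'
#' @param depth Numeric vector of non-negative per-base depths.
#' @return A `coverage_track` vector.
#' @export
coverage_track <- function(depth) {
  depth <- as.numeric(depth)
  if (any(depth < 0)) {
    stop("coverage depths must be non-negative", call. = FALSE)
  }
  structure(depth, class = "coverage_track")
}

#' Write a coverage track as a two-column TSV
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  readr::write_tsv(
    tibble(pos = seq_along(track), depth = as.numeric(track)),
    path,
    progress = FALSE
  )
  invisible(path)
}

#' Detect inverted-repeat intervals from read-coverage doubling
#'
#' The inverted repeat is present in two copies, so reads from either copy
#' pile onto each at roughly twice the single-copy depth. The track is
#' smoothed with a centred rolling median of width `window`, divided by
#' the genome-wide median depth, and maximal runs with a ratio inside
#' `[low, high]` are reported; runs shorter than `window` are discarded.
#'
#' @param track A `coverage_track`.
#' @param window Smoothing window width in bp (>= 1).
#' @param low,high Depth-ratio band treated as "approximately two times"
#'   the baseline (defaults 1.7 and 2.5).
#' @return A tibble of candidate repeat intervals with 0-based half-open
#'   `start`/`end`, `length` and `mean_ratio`.
#' @export
detect_ir_from_coverage <- function(track, window = 200L, low = 1.7, high = 2.5) {
  depth <- as.numeric(track)
  if (window < 1L) {
    stop("window must be >= 1", call. = FALSE)
  }
  if (low >= high) {
    stop("low must be < high", call. = FALSE)
  }
  if (all(depth == 0)) {
    stop("no coverage", call. = FALSE)
  }
  m <- stats::median(depth)
  k <- as.integer(window)
  if (k %% 2L == 0L) k <- k + 1L
  smooth <- if (k >= length(depth)) {
    rep(stats::median(depth), length(depth))
  } else if (k == 1L) {
    depth
  } else {
    as.numeric(stats::runmed(depth, k, endrule = "median"))
  }
  ratio <- smooth / m
  inside <- ratio >= low & ratio <= high
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= window
  tibble(
    start = starts[keep] - 1L,
    end = ends[keep],
    length = r$lengths[keep],
    mean_ratio = vapply(
      which(keep),
      function(i) mean(ratio[starts[i]:ends[i]]),
      0
    )
  )
}

#' Plot a coverage track with detected repeat intervals
#'
#' @param object A `coverage_track`.
#' @param intervals Optional tibble from [detect_ir_from_coverage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_track <- function(object, intervals = NULL, ...) {
  df <- tibble(pos = seq_along(object), depth = as.numeric(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_hline(
      yintercept = stats::median(df$depth),
      linetype = "dashed", colour = "steelblue"
    ) +
    ggplot2::labs(x = "genome position (bp)", y = "read depth")
  if (!is.null(intervals) && nrow(intervals) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = intervals,
      ggplot2::aes(
        xmin = .data$start + 1, xmax = .data$end,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p
}
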