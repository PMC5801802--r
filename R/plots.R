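#' Plot a quadripartite structure as a linear region map
#'
#' @param object A `quadripartite` object.
#' @param ... Unused.
#' @return A ggplot object showing LSC, IRa, SSC and IRb as coloured
#'   blocks along the (linearized) circle.
#' @export
autoplot.quadripartite <- function(object, ...) {
  td <- tidy.quadripartite(object)
  td$region <- factor(td$region, levels = c("LSC", "IRa", "SSC", "IRb"))
  L <- object$genome_length
  ## split wrapping regions at the origin for drawing
  rows <- purrr::pmap_dfr(
    list(td$region, td$start0, td$length),
    function(region, s, len) {
      if (s + len <= L) {
        tibble(region = region, xmin = s, xmax = s + len)
      } else {
        tibble(
          region = c(region, region),
          xmin = c(s, 0),
          xmax = c(L, s + len - L)
        )
      }
    }
  )
  ggplot2::ggplot(rows) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax, ymin = 0, ymax = 1,
        fill = .data$region
      ),
      colour = "grey20"
    ) +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "genome position (bp)", y = NULL, fill = "region")
}

#' Pseudogene frame/stop figure
#'
#' Draws, per gene and species, the protein-coding region as a bar
#' scaled to 100% of its length: segments with a shifted reading frame
#' are shaded grey, premature stop codons are black lines, and missing
#' genes or segments appear as solid black bars — the classic comparative
#' pseudogene figure.
#'
#' @param statuses Bound `gene_status` rows with `ref_length_nt`.
#' @return A ggplot object.
#' @export
plot_gene_tracks <- function(statuses) {
  tracks <- gene_tracks(statuses)
  base <- purrr::map_dfr(tracks, function(tr) {
    tibble(
      gene = tr$gene, species = tr$species, status = tr$status,
      aa_length = tr$aa_length %||% NA_integer_
    )
  })
  shifted <- purrr::map_dfr(tracks, function(tr) {
    if (length(tr$shifted_frame) == 0L || is.na(tr$aa_length)) {
      return(tibble())
    }
    purrr::map_dfr(tr$shifted_frame, function(sg) {
      tibble(
        gene = tr$gene, species = tr$species,
        xmin = sg$from_aa / tr$aa_length, xmax = sg$to_aa / tr$aa_length
      )
    })
  })
  stops <- purrr::map_dfr(tracks, function(tr) {
    if (length(tr$stops) == 0L || is.na(tr$aa_length)) {
      return(tibble())
    }
    tibble(gene = tr$gene, species = tr$species, x = tr$stops / tr$aa_length)
  })
  p <- ggplot2::ggplot(base) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = 0, xmax = 1, ymin = 0.1, ymax = 0.9),
      fill = ifelse(base$status == "absent", "black", "white"),
      colour = "grey20"
    ) +
    ggplot2::facet_grid(species ~ gene) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "protein-coding region (fraction)", y = NULL)
  if (nrow(shifted) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = shifted,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax, ymin = 0.1, ymax = 0.9
      ),
      fill = "grey60", alpha = 0.8
    )
  }
  if (nrow(stops) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = stops,
      ggplot2::aes(x = .data$x, xend = .data$x, y = 0.1, yend = 0.9),
      colour = "black", linewidth = 0.8
    )
  }
  p
}
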