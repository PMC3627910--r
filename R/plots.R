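# ggplot2 methods for the result types.

#' Plot a truncation profile
#'
#' Copy depth along the family consensus. One-ended replication shows as a
#' ramp rising toward the 3' end.
#'
#' @param object A [truncation_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.truncation_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "consensus position (bp)", y = "copy depth",
      title = sprintf("%s: coverage of %d copies", object$family_id,
                      object$n_copies),
      subtitle = sprintf("5'-intact %.0f%%, 3'-intact %.0f%%",
                         100 * object$five_prime_intact_fraction,
                         100 * object$three_prime_intact_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a family TSD summary
#'
#' TSD length histogram of a [summarize_family()] result.
#'
#' @param object A `family_insertion_summary` row.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.family_insertion_summary <- function(object, ...) {
  hist <- object$tsd_length_histogram[[1]]
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$tsd_len, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "TSD length (bp)", y = "loci",
      title = sprintf("%s: %d/%d loci with TSDs (%.0f%%)",
                      object$family_id, object$n_tsd, object$n_loci,
                      100 * object$tsd_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' Plot motif hit architecture
#'
#' Anchor positions of motif hits along their proteins: one horizontal line
#' per protein with the anchors marked.
#'
#' @param hits A tibble from [scan_protein()] or the hit rows of
#'   [scan_proteome()].
#' @param protein_lengths Optional named integer vector of protein lengths
#'   (names are protein ids), used to draw the full protein extent.
#' @return A ggplot object.
#' @export
plot_motif_hits <- function(hits, protein_lengths = NULL) {
  if (nrow(hits) == 0L) abort("plot_motif_hits: no hits to plot")
  long <- tidyr::pivot_longer(
    hits,
    cols = c("pos_d", "pos_ts1", "pos_ts2", "pos_c1", "pos_c2", "pos_c3",
             "pos_c4", "pos_r", "pos_d2"),
    names_to = "anchor", values_to = "position"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                          y = .data$protein_id)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$protein_id),
                       colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$anchor), size = 2) +
    ggplot2::labs(x = "residue position", y = NULL,
                  title = "Fanzor/TnpB motif anchors") +
    ggplot2::theme_minimal()
  if (!is.null(protein_lengths)) {
    ext <- tibble(protein_id = names(protein_lengths),
                  len = as.integer(protein_lengths))
    p <- p + ggplot2::geom_segment(
      data = ext,
      ggplot2::aes(x = 1, xend = .data$len, y = .data$protein_id,
                   yend = .data$protein_id),
      inherit.aes = FALSE, colour = "grey90", linewidth = 2
    )
  }
  p
}
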