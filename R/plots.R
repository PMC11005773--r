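subgenome_colors <- c(A = "#2166ac", B = "#b2182b", S = "#e6b800")

letter_color <- function(letters) {
  cols <- subgenome_colors[first_letter(letters)]
  cols[is.na(cols)] <- "grey40"
  unname(cols)
}

#' Plot Relative Coverage along chromosomes
#'
#' Draws the per-window Relative Coverage of both subgenomes along each
#' chromosome, one row of facets per anchor direction, with the y axis on
#' the 0--2 scale. The anchor track is drawn on top of the partner track,
#' and introgression segments (if supplied) are outlined as boxes. The
#' A subgenome is always blue, B red and S yellow.
#'
#' @param rc Relative Coverage track from [relative_coverage()].
#' @param segments Optional segment tibble from [segment_calls()].
#' @param anchor Optional single anchor to plot; default plots both
#'   directions (with a warning and single-panel fallback when only one
#'   direction is present).
#' @return A ggplot object; inputs are not modified.
#' @export
plot_relative_coverage <- function(rc, segments = NULL, anchor = NULL) {
  if (!is.null(anchor)) rc <- rc |> filter(.data$anchor == !!anchor)
  anchors <- unique(rc$anchor)
  if (is.null(anchor) && length(anchors) < 2) {
    warn("only one anchor direction present; plotting a single panel")
  }
  long <- bind_rows(
    rc |> mutate(subgenome = .data$anchor, r = .data$r_anchor, layer = "anchor"),
    rc |> mutate(subgenome = .data$partner, r = .data$r_partner, layer = "partner")
  ) |>
    mutate(mb = (.data$start + .data$end) / 2 / 1e6,
           panel = paste0("anchor: ", .data$anchor))
  pal <- setNames(letter_color(sort(unique(long$subgenome))),
                  sort(unique(long$subgenome)))
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mb, y = .data$r)) +
    ggplot2::geom_col(
      data = long |> filter(.data$layer == "partner"),
      ggplot2::aes(fill = .data$subgenome), width = 0.1, alpha = 0.55) +
    ggplot2::geom_col(
      data = long |> filter(.data$layer == "anchor"),
      ggplot2::aes(fill = .data$subgenome), width = 0.1, alpha = 0.9) +
    ggplot2::scale_fill_manual(values = pal, name = "subgenome") +
    ggplot2::coord_cartesian(ylim = c(0, 2.2)) +
    ggplot2::facet_grid(panel ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "Relative Coverage") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(1, "pt"))
  if (!is.null(segments) && nrow(segments) > 0) {
    seg <- segments |> mutate(panel = paste0("anchor: ", .data$anchor))
    gg <- gg + ggplot2::geom_rect(
      data = seg, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = 0, ymax = 2.1, colour = "black", fill = NA, linewidth = 0.3)
  }
  gg
}

#' Plot RAA per cluster and reference
#'
#' Dot plot of Relative Averaged Alignment values, one dot per sample,
#' grouped by cluster on the x axis and coloured by reference genome.
#' Per-chromosome RAA tables are faceted by chromosome.
#'
#' @param raa RAA table from [compute_raa()].
#' @param clusters Optional sample-to-cluster assignment used for grouping;
#'   without it samples are plotted individually.
#' @return A ggplot object; inputs are not modified.
#' @export
plot_raa <- function(raa, clusters = NULL) {
  df <- as_tibble(raa)
  if (!is.null(clusters)) {
    df <- df |> left_join(clusters, by = "sample_id") |>
      mutate(group = dplyr::coalesce(.data$cluster_label, "unclustered"))
  } else {
    df <- df |> mutate(group = .data$sample_id)
  }
  pal <- setNames(letter_color(sort(unique(df$reference_id))),
                  sort(unique(df$reference_id)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$raa,
                                         colour = .data$reference_id)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 1.4, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = pal, name = "reference") +
    ggplot2::labs(x = NULL, y = "Relative Averaged Alignment (%)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(setdiff(unique(df$scope), "genome")) > 0) {
    gg <- gg + ggplot2::facet_wrap(~scope)
  }
  gg
}

#' @rdname plot_relative_coverage
#' @param object,x An `rc_tbl` / `raa_tbl` object.
#' @param ... Passed on to the plotting function.
#' @export
autoplot.rc_tbl <- function(object, ...) plot_relative_coverage(object, ...)

#' @rdname plot_raa
#' @inheritParams autoplot.rc_tbl
#' @export
autoplot.raa_tbl <- function(object, ...) plot_raa(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
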