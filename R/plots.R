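#' Plot transcription-breadth distributions
#'
#' Line plot of the proportion of genes transcribed at each number of
#' timepoints, one line per gene set; the rightmost point (breadth = 10 in
#' the canonical design) is the constitutively transcribed fraction.
#'
#' @param dist Tibble from [breadth_distribution()] (may stack several gene
#'   sets).
#' @return A ggplot object.
#' @export
plot_breadth_distribution <- function(dist) {
  ggplot2::ggplot(
    dist,
    ggplot2::aes(.data$breadth, .data$proportion, colour = .data$gene_set)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq(0, max(dist$breadth))) +
    ggplot2::labs(
      x = "timepoints at which a gene is transcribed",
      y = "proportion of genes",
      colour = "gene set"
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean phylum expression over the wet-up time course
#'
#' Mean BGC z-score per phylum across the collapsed timepoints, with night
#' timepoints shaded, mirroring the phylum-resolved transcription time
#' course.
#'
#' @param profiles BGC-level profile tibble.
#' @param taxonomy Tibble with `bgc_id` and `phylum`.
#' @param meta Sample metadata.
#' @return A ggplot object.
#' @export
plot_phylum_profiles <- function(profiles, taxonomy, meta) {
  groups <- timepoint_groups(meta)
  means <- phylum_mean_profiles(profiles, taxonomy)$profiles
  long <- means %>%
    tidyr::pivot_longer(-"entity_id",
      names_to = "replicate_group", values_to = "mean_z"
    ) %>%
    left_join(groups, by = "replicate_group") %>%
    rename(phylum = "entity_id")
  night <- groups %>% filter(.data$is_night)
  idx <- match(long$replicate_group, groups$replicate_group)
  long$timepoint_index <- idx
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(.data$timepoint_index, .data$mean_z, colour = .data$phylum)
  )
  if (nrow(night) > 0) {
    shade <- tibble(
      xmin = match(night$replicate_group, groups$replicate_group) - 0.5,
      xmax = match(night$replicate_group, groups$replicate_group) + 0.5
    )
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      fill = "grey85", alpha = 0.6, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      breaks = seq_len(nrow(groups)),
      labels = paste0(groups$timepoint_hours, "h")
    ) +
    ggplot2::labs(
      x = "time since wetting", y = "mean BGC z-score", colour = "phylum"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn build_bgc_network ggplot of the network (Fruchterman-Reingold
#'   layout, nodes coloured by phylum, shaped by BGC class when few classes).
#' @param object A `bgc_network`.
#' @export
autoplot.bgc_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1) # layout only; analysis results carry no randomness
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes %>% mutate(x = xy[, 1], y = xy[, 2])
  seg <- object$edges %>%
    left_join(nodes %>% select("id", xa = "x", ya = "y"), by = c(from = "id")) %>%
    left_join(nodes %>% select("id", xb = "x", yb = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$phylum),
      size = 2
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "phylum")
}

#' @describeIn zscore_profiles heatmap of z-scores (entities by timepoint).
#' @param object A `bgc_profiles` tibble.
#' @param ... Unused.
#' @export
autoplot.bgc_profiles <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(-"entity_id", names_to = "timepoint", values_to = "z") %>%
    mutate(timepoint = factor(.data$timepoint,
      levels = setdiff(names(object), "entity_id")
    ))
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$timepoint, .data$entity_id, fill = .data$z)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white", high = "#a50026") +
    ggplot2::labs(x = "timepoint", y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
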