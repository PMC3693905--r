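#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_line
#'   geom_hline facet_wrap facet_grid labs theme_minimal geom_text
NULL

#' Plot a linkage map
#'
#' Classic map chart: one vertical bar per linkage group with loci drawn as
#' ticks at their cM positions.
#'
#' @param object A `clover_map`.
#' @param label_loci Draw locus names (sensible only for small maps).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clover_map <- function(object, label_loci = FALSE, ...) {
  loci <- object$loci
  ends <- loci %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(top = min(.data$pos_cM), bottom = max(.data$pos_cM),
                     .groups = "drop")
  p <- ggplot(loci, aes(x = .data$group)) +
    geom_segment(data = ends,
                 aes(x = .data$group, xend = .data$group,
                     y = .data$top, yend = .data$bottom),
                 linewidth = 1, colour = "grey55") +
    geom_point(aes(y = .data$pos_cM), shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = "position (cM)") +
    theme_minimal()
  if (label_loci) {
    p <- p + geom_text(aes(y = .data$pos_cM, label = .data$locus_id),
                       hjust = -0.2, size = 2.5)
  }
  p
}

#' Plot a segregation-distortion profile
#'
#' Signed distortion profile along each linkage group: `-log10 P` drawn
#' upward for female(maternal)-derived alleles and `log10 P` downward for
#' male(paternal)-derived alleles, against position as a proportion of group
#' length, with the P = 0.05 thresholds marked at +/- 1.3.
#'
#' @param scan Output of [distortion_scan()] run with a map.
#' @return A ggplot object.
#' @export
plot_distortion <- function(scan) {
  stopifnot("relative_position" %in% names(scan))
  ggplot(scan, aes(.data$relative_position, .data$signed_log10p,
                   colour = .data$parental_origin)) +
    geom_hline(yintercept = c(-log10(0.05), log10(0.05)),
               linetype = "dashed", colour = "grey50") +
    geom_hline(yintercept = 0, colour = "grey80") +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~group) +
    labs(x = "proportion of distance along group",
         y = expression(phantom() %+-% log[10] ~ italic(P)),
         colour = "parental origin") +
    theme_minimal()
}

#' Synteny dot plot
#'
#' Normalized dot-matrix plot of map groups against reference chromosomes,
#' both axes proportional distances.
#'
#' @param records Tibble from [synteny_records()] or
#'   [simulate_synteny_records()].
#' @return A ggplot object.
#' @export
plot_synteny <- function(records) {
  ggplot(records, aes(.data$tr_position, .data$ref_position)) +
    geom_point(size = 0.7, alpha = 0.8) +
    facet_grid(rows = ggplot2::vars(.data$ref_chromosome),
               cols = ggplot2::vars(.data$tr_group), switch = "both") +
    labs(x = "proportion of distance along map group",
         y = "proportion of distance along reference chromosome") +
    ggplot2::scale_x_continuous(breaks = c(0, 1)) +
    ggplot2::scale_y_continuous(breaks = c(0, 1)) +
    theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0, "pt"),
                   panel.border = ggplot2::element_rect(fill = NA,
                                                        colour = "grey85"))
}

#' Plot a map-saturation curve
#'
#' @inheritParams saturation_curve
#' @return A ggplot object.
#' @export
plot_saturation <- function(n, g, d_max = 5) {
  ggplot(saturation_curve(n, g, d_max), aes(.data$d, .data$saturation)) +
    geom_line() +
    labs(x = "distance from nearest locus (cM)",
         y = "proportion of genome covered") +
    theme_minimal()
}
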