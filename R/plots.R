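#' Daily detection plot by bay region
#'
#' The classical telemetry "barcode" plot: one row per individual, one tick
#' per detection day, colored by the bay region of the receivers involved.
#'
#' @param dataset A `bay_dataset`.
#' @return A ggplot object.
#' @export
plot_daily_detections <- function(dataset) {
  dd <- daily_detection_matrix(dataset)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$date, y = .data$transmitter_id,
                                   colour = .data$region)) +
    ggplot2::geom_point(shape = 124, size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$species), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_colour_manual(values = c(west = "#3366CC",
                                            central = "#E6B800",
                                            east = "#CC3333")) +
    ggplot2::labs(x = NULL, y = NULL, colour = "Region") +
    ggplot2::theme_minimal()
}

#' Detection-index boxplots by species (and optionally life stage)
#'
#' @param indices Tibble from [detection_indices()].
#' @param by Grouping column, `"species"` or `"life_stage"`.
#' @return A ggplot object.
#' @export
plot_detection_indices <- function(indices, by = "species") {
  long <- indices %>%
    pivot_longer(c("di_total", "di_bay"), names_to = "index",
                 values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[by]], y = .data$value,
                                     fill = .data$index)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = "Detection index", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fit_seasonal_model
#' @param object A `seasonal_fit`.
#' @param ... Unused.
#' @export
autoplot.seasonal_fit <- function(object, ...) {
  fm <- object$fitted_monthly %>%
    mutate(lo = pmax(.data$probability - 1.96 * .data$se, 0),
           hi = pmin(.data$probability + 1.96 * .data$se, 1))
  ggplot2::ggplot(fm, ggplot2::aes(x = .data$month, y = .data$probability)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species)) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = "Month", y = "Daily detection probability") +
    ggplot2::theme_minimal()
}

#' Plot a movement network over the receiver array
#'
#' Draws receivers at their coordinates, sized by detection share, with
#' edges whose width encodes the number of transitions.
#'
#' @param net A `movement_network` (individual or aggregated).
#' @param receivers Receiver tibble with `receiver_id`, `longitude`,
#'   `latitude`.
#' @return A ggplot object.
#' @export
plot_movement_network <- function(net, receivers) {
  stopifnot(inherits(net, "movement_network"))
  coords <- receivers %>% select("receiver_id", "longitude", "latitude")
  ed <- net$edges %>%
    left_join(coords, by = c(from = "receiver_id")) %>%
    rename(x = "longitude", y = "latitude") %>%
    left_join(coords, by = c(to = "receiver_id")) %>%
    rename(xend = "longitude", yend = "latitude")
  nw <- net$node_weights %>% left_join(coords, by = "receiver_id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          alpha = 0.5) +
    ggplot2::geom_point(data = nw,
                        ggplot2::aes(x = .data$longitude, y = .data$latitude,
                                     size = .data$n_detections),
                        colour = "#226688") +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::labs(title = net$owner, x = "Longitude", y = "Latitude",
                  linewidth = "Transitions", size = "Detections") +
    ggplot2::theme_minimal()
}

#' @rdname simple_ratio_index
#' @param object An `association_network`.
#' @param ... Unused.
#' @export
autoplot.association_network <- function(object, ...) {
  m <- object$sri
  df <- as_tibble(as.table(m), .name_repair = ~c("id_a", "id_b", "sri"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                   fill = .data$sri)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "SRI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
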