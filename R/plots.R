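#' @importFrom ggplot2 ggplot aes geom_rect geom_tile geom_col geom_text
#'   scale_fill_identity scale_y_continuous scale_y_discrete labs
#'   theme_minimal theme element_blank facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot scarf geometry
#'
#' One row per participant (top to bottom in registry order); main bands
#' coloured by AOI, visibility bands drawn as translucent strips below
#' each row.
#'
#' @param object A `scarf_geometry`.
#' @param ... Unused.
#' @return A `ggplot`.
#' @export
autoplot.scarf_geometry <- function(object, ...) {
  g <- object
  n_vis <- length(g$visibility_aois)
  vis_frac <- 0.3
  row_pitch <- 1 + n_vis * vis_frac + 0.15
  rects <- g$rects
  if (nrow(rects)) {
    ri <- match(rects$participant_id, g$rows$participant_id)
    top <- (ri - 1) * row_pitch
    is_main <- rects$band == "main"
    n_sub <- map_int(ri, function(i) {
      sub <- g$rects[g$rects$participant_id ==
                       g$rows$participant_id[i] &
                       g$rects$band == "main", ]
      max(c(sub$sub_band, 0L)) + 1L
    })
    y0 <- y1 <- numeric(nrow(rects))
    y0[is_main] <- top[is_main] + rects$sub_band[is_main] / n_sub[is_main]
    y1[is_main] <- top[is_main] + (rects$sub_band[is_main] + 1) /
      n_sub[is_main]
    if (any(!is_main)) {
      band_i <- match(sub("^visibility:", "", rects$band[!is_main]),
                      g$visibility_aois)
      y0[!is_main] <- top[!is_main] + 1 + (band_i - 1) * vis_frac + 0.05
      y1[!is_main] <- top[!is_main] + 1 + band_i * vis_frac
    }
    rects$.y0 <- -y1
    rects$.y1 <- -y0
    rects$.alpha <- ifelse(rects$band == "main", 1,
                           style_constants$visibility_alpha)
  }
  if (!nrow(rects)) {
    rects <- tibble(x0 = double(), x1 = double(), .y0 = double(),
                    .y1 = double(), fill = character(), .alpha = double())
  }
  breaks <- -( (seq_len(nrow(g$rows)) - 1) * row_pitch + 0.5)
  p <- ggplot(rects) +
    geom_rect(aes(xmin = x0, xmax = x1, ymin = .y0, ymax = .y1,
                  fill = fill, alpha = .alpha)) +
    scale_fill_identity(guide = "legend",
                        labels = setNames(g$legend$label, g$legend$color),
                        breaks = g$legend$color, name = NULL) +
    ggplot2::scale_alpha_identity() +
    scale_y_continuous(breaks = breaks, labels = g$rows$display_name) +
    labs(x = switch(g$axis$mode, absolute = "Time [ms]",
                    relative = "Time [% of trial]",
                    ordinal = "Segment order"),
         y = NULL, title = g$stimulus) +
    theme_minimal() +
    theme(panel.grid.minor = element_blank())
  p
}

#' Plot a transition matrix as a heatmap
#' @param object A `transition_matrix`.
#' @param ... Unused.
#' @return A `ggplot`.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy(object)
  df$from <- factor(df$from, levels = rev(object$aoi_order))
  df$to <- factor(df$to, levels = object$aoi_order)
  ggplot(df, aes(x = to, y = from, fill = n)) +
    geom_tile(color = "white") +
    geom_text(aes(label = n), size = 3.2) +
    ggplot2::scale_fill_gradient(low = "#FFFFFF", high = "#E15759",
                                 name = "transitions") +
    labs(x = "to AOI", y = "from AOI") +
    theme_minimal()
}

#' Plot aggregate AOI metrics as bars
#' @param object An `aoi_summary`.
#' @param ... Unused.
#' @return A `ggplot` faceted by metric.
#' @export
autoplot.aoi_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = aoi_id, y = value, fill = group_label)) +
    geom_col(position = "dodge") +
    facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = rep(scarf_palette(), 10),
                               name = "group") +
    labs(x = "AOI", y = NULL) +
    theme_minimal()
}

#' Plot per-participant AOI metrics
#' @param object An `aoi_metrics` tibble.
#' @param ... Unused.
#' @return A `ggplot`.
#' @export
autoplot.aoi_metrics <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(
    df, c("ttff_ms", "fixation_count", "avg_fixation_ms", "dwell_ms"),
    names_to = "metric", values_to = "value")
  ggplot(long, aes(x = aoi_id, y = value, fill = participant_id)) +
    geom_col(position = "dodge") +
    facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = rep(scarf_palette(), 20),
                               name = "participant") +
    labs(x = "AOI", y = NULL) +
    theme_minimal()
}
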