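#' Rendering style for exported figures
#'
#' @param dpi Output resolution in dots per inch (>= 72).
#' @param margins Margins in px at 96 dpi, `c(top, right, bottom, left)`.
#' @param row_height Scarf row height in px at 96 dpi.
#' @param font_size Base font size in pt.
#' @param format One of `"png"`, `"jpg"`, `"svg"`.
#' @return A `render_style` object.
#' @export
render_style <- function(dpi = 150, margins = c(10, 10, 10, 10),
                         row_height = 30, font_size = 12, format = "png") {
  if (!is.numeric(dpi) || dpi < 72) {
    validation_error("`dpi` must be a number >= 72")
  }
  if (length(margins) != 4L || any(margins < 0)) {
    validation_error("`margins` must be 4 non-negative numbers")
  }
  supported <- c("png", "jpg", "svg")
  if (!format %in% supported) {
    validation_error("unsupported format '%s'; supported: %s", format,
                     paste(supported, collapse = ", "))
  }
  structure(list(dpi = dpi, margins = margins, row_height = row_height,
                 font_size = font_size, format = format),
            class = "render_style")
}

#' Render a result object to an image file
#'
#' Accepts scarf geometry, a transition matrix, or an AOI bar summary.
#' SVG output is emitted by scarfkit's own serializer and is
#' byte-deterministic: the same object and style always produce the same
#' bytes. Raster output goes through the `ggplot2` autoplot methods; pixel
#' dimensions scale linearly with `dpi`.
#'
#' @param x A `scarf_geometry`, `transition_matrix`, or `aoi_summary`.
#' @param path Output file path.
#' @param style A [render_style()]; its `format` decides the encoder.
#' @return `path`, invisibly.
#' @export
render_plot <- function(x, path, style = render_style()) {
  stopifnot(inherits(style, "render_style"))
  if (style$format == "svg") {
    svg_txt <- if (inherits(x, "scarf_geometry")) svg_scarf(x, style)
      else if (inherits(x, "transition_matrix")) svg_matrix(x, style)
      else if (inherits(x, "aoi_summary")) svg_bars(x, style)
      else validation_error("cannot render object of class %s",
                            paste(class(x), collapse = "/"))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(svg_txt, con, sep = "\n")
    return(invisible(path))
  }
  p <- ggplot2::autoplot(x)
  base <- base_dimensions(x, style)
  # canvas snapped to whole 96-dpi cells so pixel size is exactly linear
  # in dpi (doubling dpi doubles both dimensions)
  cells_w <- ceiling(base$width / 96)
  cells_h <- ceiling(base$height / 96)
  dev <- switch(style$format,
                png = grDevices::png,
                jpg = grDevices::jpeg)
  dev(path, width = round(cells_w * style$dpi),
      height = round(cells_h * style$dpi), res = style$dpi)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

# base canvas size in px at 96 dpi
base_dimensions <- function(x, style) {
  m <- style$margins
  if (inherits(x, "scarf_geometry")) {
    n_rows <- max(nrow(x$rows), 1L)
    per_row <- style$row_height * (1 + 0.35 * length(x$visibility_aois))
    list(width = 900 + m[2] + m[4],
         height = n_rows * per_row + 80 + m[1] + m[3])
  } else if (inherits(x, "transition_matrix")) {
    n <- max(length(x$aoi_order), 1L)
    list(width = 60 + n * 50 + m[2] + m[4],
         height = 60 + n * 50 + m[1] + m[3])
  } else {
    list(width = 900 + m[2] + m[4], height = 420 + m[1] + m[3])
  }
}

# ---- deterministic SVG emitters ------------------------------------------

svg_header <- function(width, height) {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" ",
      "height=\"%s\" viewBox=\"0 0 %s %s\">"),
      fmt_svg(width), fmt_svg(height), fmt_svg(width), fmt_svg(height)))
}

fmt_svg <- function(x) {
  out <- sprintf("%.2f", x)
  sub("\\.00$", "", out)
}

svg_rect <- function(x, y, w, h, fill, opacity = NULL, title = NULL) {
  op <- if (is.null(opacity)) "" else
    sprintf(" fill-opacity=\"%s\"", fmt_svg(opacity))
  if (is.null(title)) {
    sprintf("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"%s/>",
            fmt_svg(x), fmt_svg(y), fmt_svg(w), fmt_svg(h), fill, op)
  } else {
    sprintf(paste0(
      "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"%s>",
      "<title>%s</title></rect>"),
      fmt_svg(x), fmt_svg(y), fmt_svg(w), fmt_svg(h), fill, op,
      json_escape(title))
  }
}

svg_text <- function(x, y, txt, size, anchor = "start") {
  sprintf(paste0(
    "<text x=\"%s\" y=\"%s\" font-size=\"%s\" font-family=\"sans-serif\" ",
    "text-anchor=\"%s\">%s</text>"),
    fmt_svg(x), fmt_svg(y), fmt_svg(size), anchor, xml_escape_text(txt))
}

xml_escape_text <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# scarf geometry -> SVG. Rows top to bottom; each row: main band (split
# into equal sub-bands where the geometry says so) then thin visibility
# bands; legend rendered underneath.
svg_scarf <- function(g, style) {
  m <- style$margins
  label_w <- 90
  plot_w <- 800
  rh <- style$row_height
  vis_h <- rh * 0.35
  n_vis <- length(g$visibility_aois)
  row_total <- rh + n_vis * vis_h + 6
  n_rows <- nrow(g$rows)
  legend_h <- 22 * ceiling(nrow(g$legend) / 4) + 14
  width <- m[4] + label_w + plot_w + m[2]
  height <- m[1] + n_rows * row_total + 30 + legend_h + m[3]
  xmax <- max(g$axis$xmax, 1e-12)
  xscale <- function(x) m[4] + label_w + plot_w * x / xmax

  out <- svg_header(width, height)
  out <- c(out, svg_rect(0, 0, width, height, "#FFFFFF"))
  for (ri in seq_len(n_rows)) {
    p <- g$rows$participant_id[ri]
    y0 <- m[1] + (ri - 1) * row_total
    out <- c(out, svg_text(m[4], y0 + rh * 0.65, g$rows$display_name[ri],
                           style$font_size))
    rr <- g$rects[g$rects$participant_id == p, , drop = FALSE]
    main <- rr[rr$band == "main", , drop = FALSE]
    n_sub <- max(c(main$sub_band, 0L)) + 1L
    sub_h <- rh / n_sub
    for (i in seq_len(nrow(main))) {
      out <- c(out, svg_rect(
        xscale(main$x0[i]), y0 + main$sub_band[i] * sub_h,
        plot_w * (main$x1[i] - main$x0[i]) / xmax, sub_h, main$fill[i],
        title = sprintf("%s | %s-%s ms | %s ms | %s", main$aoi_label[i],
                        fmt_svg(main$t0_ms[i]), fmt_svg(main$t1_ms[i]),
                        fmt_svg(main$duration_ms[i]), main$category[i])))
    }
    for (vi in seq_along(g$visibility_aois)) {
      va <- g$visibility_aois[vi]
      vb <- rr[rr$band == paste0("visibility:", va), , drop = FALSE]
      vy <- y0 + rh + (vi - 1) * vis_h + 2
      for (i in seq_len(nrow(vb))) {
        out <- c(out, svg_rect(
          xscale(vb$x0[i]), vy, plot_w * (vb$x1[i] - vb$x0[i]) / xmax,
          vis_h - 3, vb$fill[i], opacity = style_constants$visibility_alpha,
          title = sprintf("%s visible | %s-%s ms", vb$aoi_label[i],
                          fmt_svg(vb$t0_ms[i]), fmt_svg(vb$t1_ms[i]))))
      }
    }
  }
  # axis line + extrema labels
  ay <- m[1] + n_rows * row_total + 12
  out <- c(out,
           sprintf("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#000000\"/>",
                   fmt_svg(xscale(0)), fmt_svg(ay), fmt_svg(xscale(xmax)),
                   fmt_svg(ay)),
           svg_text(xscale(0), ay + 14, "0", style$font_size * 0.85),
           svg_text(xscale(xmax), ay + 14, axis_label(g$axis),
                    style$font_size * 0.85, anchor = "end"))
  ly <- ay + 26
  for (i in seq_len(nrow(g$legend))) {
    col <- (i - 1) %% 4
    row <- (i - 1) %/% 4
    lx <- m[4] + label_w + col * 200
    lyy <- ly + row * 22
    out <- c(out,
             svg_rect(lx, lyy, 14, 14, g$legend$color[i]),
             svg_text(lx + 20, lyy + 11, g$legend$label[i],
                      style$font_size * 0.85))
  }
  c(out, "</svg>")
}

axis_label <- function(axis) {
  switch(axis$mode,
         absolute = sprintf("%s ms", fmt_svg(axis$xmax)),
         relative = "100%",
         ordinal = fmt_svg(axis$xmax))
}

svg_matrix <- function(tm, style) {
  n <- length(tm$aoi_order)
  m <- style$margins
  cell <- 50
  width <- m[4] + 60 + n * cell + m[2]
  height <- m[1] + 60 + n * cell + m[3]
  mx <- max(tm$counts, 1L)
  out <- svg_header(width, height)
  out <- c(out, svg_rect(0, 0, width, height, "#FFFFFF"))
  for (i in seq_len(n)) {
    out <- c(out,
             svg_text(m[4] + 55, m[1] + 60 + (i - 0.4) * cell,
                      tm$aoi_order[i], style$font_size * 0.85,
                      anchor = "end"),
             svg_text(m[4] + 60 + (i - 0.5) * cell, m[1] + 50,
                      tm$aoi_order[i], style$font_size * 0.85,
                      anchor = "middle"))
    for (j in seq_len(n)) {
      v <- tm$counts[i, j]
      shade <- 255 - round(200 * v / mx)
      fill <- sprintf("#FF%02X%02X", shade, shade)
      out <- c(out,
               svg_rect(m[4] + 60 + (j - 1) * cell, m[1] + 60 + (i - 1) * cell,
                        cell - 1, cell - 1, fill,
                        title = sprintf("%s to %s: %d", tm$aoi_order[i],
                                        tm$aoi_order[j], v)),
               svg_text(m[4] + 60 + (j - 0.5) * cell,
                        m[1] + 60 + (i - 0.4) * cell,
                        as.character(v), style$font_size * 0.85,
                        anchor = "middle"))
    }
  }
  c(out, "</svg>")
}

svg_bars <- function(summary, style) {
  m <- style$margins
  df <- as_tibble(summary)
  metrics <- unique(df$metric)
  panel_w <- 280
  width <- m[4] + length(metrics) * (panel_w + 20) + m[2]
  height <- m[1] + 300 + m[3]
  out <- svg_header(width, height)
  out <- c(out, svg_rect(0, 0, width, height, "#FFFFFF"))
  groups <- unique(df$group_label)
  pal <- scarf_palette()
  for (pi in seq_along(metrics)) {
    sub <- df[df$metric == metrics[pi], , drop = FALSE]
    x0 <- m[4] + (pi - 1) * (panel_w + 20)
    out <- c(out, svg_text(x0, m[1] + 14, metrics[pi], style$font_size))
    mx <- max(c(sub$value, 1e-12), na.rm = TRUE)
    keys <- unique(paste(sub$aoi_id, sub$group_label, sep = "\r"))
    bw <- panel_w / max(length(keys), 1L)
    for (bi in seq_along(keys)) {
      row <- sub[paste(sub$aoi_id, sub$group_label, sep = "\r") ==
                   keys[bi], ][1, ]
      v <- row$value
      if (is.na(v)) v <- 0
      bh <- 220 * v / mx
      fill <- pal[(match(row$group_label, groups) - 1L) %% 12L + 1L]
      out <- c(out,
               svg_rect(x0 + (bi - 1) * bw + 2, m[1] + 250 - bh,
                        bw - 4, bh, fill,
                        title = sprintf("%s / %s: %s", row$aoi_id,
                                        row$group_label, fmt_svg(row$value))),
               svg_text(x0 + (bi - 0.5) * bw, m[1] + 264, row$aoi_id,
                        style$font_size * 0.7, anchor = "middle"))
    }
  }
  c(out, "</svg>")
}
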