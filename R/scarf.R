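#' Project a segment onto a timeline axis
#'
#' Maps a segment's half-open time interval to an x-range under one of the
#' three timeline modes: `absolute` (ms since trial onset), `relative`
#' (percent of trial duration, 0-100), or `ordinal` (one unit of width per
#' segment, x = index to index + 1).
#'
#' @param start,end Segment bounds in ms (vectors allowed).
#' @param mode `"absolute"`, `"relative"`, or `"ordinal"`.
#' @param onset,trial_end Trial bounds in ms.
#' @param index Zero-based ordinal index of the segment within its trial
#'   (required for `ordinal`).
#' @return A tibble with columns `x0`, `x1`.
#' @examples
#' project_segment(120, 300, "relative", onset = 0, trial_end = 500)
#' @export
project_segment <- function(start, end, mode = c("absolute", "relative",
                                                 "ordinal"),
                            onset = 0, trial_end = NULL, index = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    absolute = fast_tbl(x0 = start - onset, x1 = end - onset),
    relative = {
      if (is.null(trial_end)) {
        validation_error("relative mode needs `trial_end`")
      }
      span <- trial_end - onset
      if (any(span <= 0)) {
        validation_error("degenerate trial: zero-length trial in %s",
                         "relative mode")
      }
      fast_tbl(x0 = 100 * (start - onset) / span,
             x1 = 100 * (end - onset) / span)
    },
    ordinal = {
      if (is.null(index)) validation_error("ordinal mode needs `index`")
      fast_tbl(x0 = as.numeric(index), x1 = as.numeric(index) + 1)
    })
}

pick_stimulus <- function(v, stimulus) {
  stims <- unique(v$segments$stimulus_id)
  if (!is.null(stimulus)) {
    if (!stimulus %in% stims) {
      validation_error("stimulus '%s' has no segments in this view; %s",
                       stimulus,
                       sprintf("present: %s", paste(stims, collapse = ", ")))
    }
    return(stimulus)
  }
  if (length(stims) == 0L) validation_error("view contains no segments")
  if (length(stims) > 1L) {
    validation_error(
      "view spans several stimuli (%s); pick one with `stimulus=` %s",
      paste(stims, collapse = ", "), "or a stimulus filter")
  }
  stims
}

#' Build scarf-plot geometry
#'
#' Transforms one stimulus of a dataset view into resolution-independent
#' scarf geometry: one row per participant (registry order), a main band
#' of coloured rectangles — one per segment, split into stacked sub-bands
#' when a segment hits several AOIs and `split_overlaps` is on — and,
#' optionally, one visibility band per scheduled AOI underneath. Every
#' rectangle carries hover metadata: AOI display name, the original
#' absolute time range in ms, its duration, and the event category,
#' whatever the timeline mode.
#'
#' @param x A `gaze_dataset`.
#' @param mode Timeline mode: `"absolute"`, `"relative"`, or `"ordinal"`.
#' @param stimulus Stimulus to plot; may be omitted when the view holds
#'   exactly one.
#' @param show_visibility Add per-AOI visibility bands below each row
#'   (AOIs with schedule entries only; an AOI scheduled for some
#'   participants is shown as always-visible for the rest).
#' @param split_overlaps If `TRUE`, a segment hitting k AOIs becomes k
#'   stacked equal-height rectangles; otherwise a single rectangle in the
#'   reserved overlap colour.
#' @param ordinal_fixations_only In ordinal mode, count only fixations as
#'   ordinal units (default counts every rendered segment).
#' @return A `scarf_geometry` object.
#' @export
scarf_geometry <- function(x, mode = c("absolute", "relative", "ordinal"),
                           stimulus = NULL, show_visibility = FALSE,
                           split_overlaps = FALSE,
                           ordinal_fixations_only = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "gaze_dataset"))
  v <- resolve_view(x)
  stim <- pick_stimulus(v, stimulus)
  seg <- v$segments[v$segments$stimulus_id == stim, , drop = FALSE]
  aois <- v$aois[v$aois$stimulus_id == stim, , drop = FALSE]
  participants <- v$participants[
    v$participants$participant_id %in% unique(seg$participant_id), ,
    drop = FALSE]

  if (mode == "relative") {
    tb <- trial_bounds(seg)
    degen <- tb[tb$end <= tb$onset, , drop = FALSE]
    if (nrow(degen)) {
      validation_error("degenerate trial(s) in relative mode: %s",
                       paste(degen$participant_id, collapse = ", "))
    }
  }

  rect_list <- list()
  row_tbl <- tibble(participant_id = participants$participant_id,
                    display_name = participants$display_name,
                    n_segments = 0L, n_sub_bands = 1L)
  vis_aois <- character()
  if (show_visibility && !is.null(v$visibility)) {
    sched <- v$visibility[v$visibility$stimulus_id == stim, , drop = FALSE]
    vis_aois <- aois$aoi_id[aois$aoi_id %in% unique(sched$aoi_id)]
  }

  for (ri in seq_len(nrow(participants))) {
    p <- participants$participant_id[ri]
    ps <- seg[seg$participant_id == p, , drop = FALSE]
    ps <- ps[order(ps$start, ps$end), , drop = FALSE]
    if (ordinal_fixations_only && mode == "ordinal") {
      ps <- ps[ps$category == "fixation", , drop = FALSE]
    }
    if (!nrow(ps)) next
    onset <- min(ps$start); t_end <- max(ps$end)
    row_tbl$n_segments[ri] <- nrow(ps)

    xr <- project_segment(ps$start, ps$end, mode, onset = onset,
                          trial_end = t_end,
                          index = seq_len(nrow(ps)) - 1L)
    k <- lengths(ps$aoi_ids)
    is_fix <- ps$category == "fixation"
    # a fixation hitting k AOIs explodes into k stacked sub-band rects
    # when splitting; everything else is a single rect
    n_rect <- ifelse(is_fix & k > 1L & split_overlaps, k, 1L)
    idx <- rep(seq_len(nrow(ps)), n_rect)
    sub_band <- sequence(n_rect) - 1L
    fill <- character(length(idx))
    label <- character(length(idx))
    for (si in seq_len(nrow(ps))) {
      at <- which(idx == si)
      ids <- ps$aoi_ids[[si]]
      if (!is_fix[si]) {
        fill[at] <- if (ps$category[si] == "saccade")
          style_constants$saccade_color else "#999999"
        label[at] <- if (ps$category[si] == "saccade") "Saccade" else "Other"
      } else if (length(ids) == 0L) {
        fill[at] <- style_constants$no_aoi_color
        label[at] <- "No AOI"
      } else if (length(ids) == 1L || !split_overlaps) {
        reg <- match(ids, aois$aoi_id)
        if (length(ids) == 1L) {
          fill[at] <- aois$color[reg]
          label[at] <- aois$display_name[reg]
        } else {
          fill[at] <- style_constants$overlap_color
          label[at] <- paste(aois$display_name[sort(reg)], collapse = " + ")
        }
      } else {
        # stacked sub-bands in registry order (deterministic ties)
        reg <- sort(match(ids, aois$aoi_id))
        fill[at] <- aois$color[reg]
        label[at] <- aois$display_name[reg]
      }
    }
    rect_list[[length(rect_list) + 1L]] <- fast_tbl(
      participant_id = p, band = "main", sub_band = sub_band,
      x0 = xr$x0[idx], x1 = xr$x1[idx], fill = fill, aoi_label = label,
      t0_ms = ps$start[idx], t1_ms = ps$end[idx],
      duration_ms = (ps$end - ps$start)[idx], category = ps$category[idx])
    row_tbl$n_sub_bands[ri] <- max(n_rect)

    for (va in vis_aois) {
      iv <- visibility_intervals_for(v$visibility, va, stim, p)
      if (is.null(iv)) iv <- fast_tbl(start = onset, end = t_end)
      ivs <- pmax(iv$start, onset)
      ive <- pmin(iv$end, t_end)
      keep_iv <- ive > ivs
      ivs <- ivs[keep_iv]; ive <- ive[keep_iv]
      if (!length(ivs)) next
      xs <- xe <- numeric(length(ivs))
      drop_iv <- logical(length(ivs))
      for (si in seq_along(ivs)) {
        vxr <- project_visibility(ivs[si], ive[si], mode, onset, t_end, ps)
        if (is.null(vxr)) drop_iv[si] <- TRUE else {
          xs[si] <- vxr[1]; xe[si] <- vxr[2]
        }
      }
      if (all(drop_iv)) next
      reg <- match(va, aois$aoi_id)
      rect_list[[length(rect_list) + 1L]] <- fast_tbl(
        participant_id = p, band = paste0("visibility:", va),
        sub_band = 0L, x0 = xs[!drop_iv], x1 = xe[!drop_iv],
        fill = aois$color[reg], aoi_label = aois$display_name[reg],
        t0_ms = ivs[!drop_iv], t1_ms = ive[!drop_iv],
        duration_ms = (ive - ivs)[!drop_iv],
        category = "visibility")
    }
  }

  rects <- if (length(rect_list)) bind_rows(rect_list) else tibble(
    participant_id = character(), band = character(), sub_band = integer(),
    x0 = double(), x1 = double(), fill = character(),
    aoi_label = character(), t0_ms = double(), t1_ms = double(),
    duration_ms = double(), category = character())

  xmax <- switch(mode,
    absolute = if (nrow(rects)) max(rects$x1[rects$band == "main"]) else 0,
    relative = 100,
    ordinal = if (nrow(row_tbl)) max(row_tbl$n_segments) else 0)

  structure(list(
    rects = rects,
    rows = row_tbl,
    visibility_aois = vis_aois,
    axis = list(mode = mode, xmax = as.numeric(xmax)),
    stimulus = stim,
    split_overlaps = split_overlaps,
    legend = scarf_legend(v, stimulus = stim)
  ), class = "scarf_geometry")
}

# a time interval on an ordinal axis spans the ordinal extent of the
# segments it overlaps; NULL when it overlaps none
project_visibility <- function(a, b, mode, onset, t_end, ps) {
  if (mode == "absolute") return(c(a - onset, b - onset))
  if (mode == "relative") {
    span <- t_end - onset
    return(100 * c(a - onset, b - onset) / span)
  }
  hit <- which(ps$start < b & ps$end > a)
  if (!length(hit)) return(NULL)
  c(min(hit) - 1, max(hit))
}

#' Legend entries for a dataset view
#'
#' Ordered legend: AOIs in registry order (merge-aware: merged members
#' collapse into their target), then the reserved style classes that occur
#' in the data (no-AOI fixations, saccades, other events, overlaps).
#'
#' @param x A `gaze_dataset`.
#' @param stimulus Optional stimulus restriction.
#' @return Tibble with `label`, `color`, `style_class`.
#' @export
scarf_legend <- function(x, stimulus = NULL) {
  v <- resolve_view(x)
  aois <- v$aois
  seg <- v$segments
  if (!is.null(stimulus)) {
    aois <- aois[aois$stimulus_id == stimulus, , drop = FALSE]
    seg <- seg[seg$stimulus_id == stimulus, , drop = FALSE]
  }
  out <- tibble(label = aois$display_name, color = aois$color,
                style_class = "aoi")
  k <- lengths(seg$aoi_ids)
  fix <- seg$category == "fixation"
  if (any(fix & k == 0L)) {
    out <- bind_rows(out, tibble(label = "No AOI",
                                 color = style_constants$no_aoi_color,
                                 style_class = "no_aoi"))
  }
  if (any(seg$category == "saccade")) {
    out <- bind_rows(out, tibble(label = "Saccade",
                                 color = style_constants$saccade_color,
                                 style_class = "saccade"))
  }
  if (any(seg$category == "other")) {
    out <- bind_rows(out, tibble(label = "Other", color = "#999999",
                                 style_class = "other"))
  }
  if (any(fix & k > 1L)) {
    out <- bind_rows(out, tibble(label = "Overlap",
                                 color = style_constants$overlap_color,
                                 style_class = "overlap"))
  }
  out
}

#' @export
print.scarf_geometry <- function(x, ...) {
  cat(sprintf(
    "<scarf_geometry> stimulus '%s', %s timeline | %d rows | %d rectangles\n",
    x$stimulus, x$axis$mode, nrow(x$rows), nrow(x$rects)))
  if (length(x$visibility_aois)) {
    cat(sprintf("  visibility bands: %s\n",
                paste(x$visibility_aois, collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.scarf_geometry <- function(x, ...) x$rects

#' @export
glance.scarf_geometry <- function(x, ...) {
  main <- x$rects[x$rects$band == "main", ]
  tibble(mode = x$axis$mode, stimulus = x$stimulus,
         n_rows = nrow(x$rows), n_rectangles = nrow(x$rects),
         n_visibility_bands = length(x$visibility_aois),
         xmax = x$axis$xmax,
         total_duration_ms = sum(main$duration_ms[
           !duplicated(paste(main$participant_id, main$t0_ms, main$t1_ms,
                             main$category))]))
}

#' Serialize scarf geometry to canonical JSON
#' @param x A `scarf_geometry`.
#' @return A JSON string (canonical key order, exact number formatting).
#' @export
scarf_to_json <- function(x) {
  stopifnot(inherits(x, "scarf_geometry"))
  canonical_json(list(
    axis = x$axis,
    legend = df_to_records(x$legend),
    rects = df_to_records(x$rects),
    rows = df_to_records(x$rows),
    split_overlaps = x$split_overlaps,
    stimulus = x$stimulus,
    visibility_aois = as.list(x$visibility_aois)
  ))
}
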