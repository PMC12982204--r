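#' Write a dataset in one of the supported dialects
#'
#' Emits byte-stable files: fixed column order, LF line endings, no
#' trailing delimiter, fixed 3-decimal millisecond formatting (integer
#' milliseconds for `tobii_like`). Used both as a normal export path and to
#' close the parse/write round trip the test suite relies on.
#'
#' Dialect-specific notes:
#' * `generic_interval` cannot represent saccades or "other" events; they
#'   are dropped with a warning (lenient) or an error (`strict = TRUE`).
#' * `tobii_like` rounds every timestamp to integer milliseconds, as
#'   mobile eye-tracking exports do. When `cut_points` are supplied, each
#'   trial is split at those times into numbered recording intervals,
#'   emulating a stimulus that disappears and reappears; a segment lying
#'   after k cut points is written into interval k+1. Cut points should
#'   fall on event boundaries — a real interval boundary ends the ongoing
#'   event, and a cut inside a fixation would split it into two.
#'
#' @param x A `gaze_dataset` (pending filters/merges are resolved first).
#' @param dialect Dialect id, see [list_dialects()].
#' @param path Output file path.
#' @param cut_points Optional tibble `participant_id`, `stimulus_id`,
#'   `cut_ms` (absolute ms) used by `tobii_like` to split trials into
#'   intervals.
#' @param strict If `TRUE`, lossy writes (events the dialect cannot
#'   represent) are errors instead of warnings.
#' @return `path`, invisibly.
#' @export
write_dialect <- function(x, dialect, path, cut_points = NULL,
                          strict = FALSE) {
  stopifnot(inherits(x, "gaze_dataset"))
  d <- dialect_descriptor(dialect)
  v <- resolve_view(x)
  seg <- v$segments
  lines <- switch(
    d$dialect_id,
    generic_long = emit_generic_long(seg),
    generic_interval = emit_generic_interval(seg, strict),
    begaze_like = emit_begaze(seg),
    tobii_like = emit_tobii(seg, cut_points)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(d$header, collapse = d$delimiter), lines), con,
             sep = "\n")
  invisible(path)
}

# one row per (segment, AOI hit); empty AOI field for unassigned events
explode_aoi_rows <- function(seg) {
  k <- pmax(lengths(seg$aoi_ids), 1L)
  idx <- rep(seq_len(nrow(seg)), k)
  aoi <- unlist(lapply(seg$aoi_ids, function(v) if (length(v)) v else ""),
                use.names = FALSE) %||% character()
  list(idx = idx, aoi = aoi)
}

emit_generic_long <- function(seg) {
  if (!nrow(seg)) return(character())
  e <- explode_aoi_rows(seg)
  paste(seg$participant_id[e$idx], seg$stimulus_id[e$idx],
        fmt_ms(seg$start[e$idx]), fmt_ms(seg$end[e$idx] - seg$start[e$idx]),
        seg$category[e$idx], e$aoi, sep = ",")
}

emit_generic_interval <- function(seg, strict) {
  drop <- seg$category != "fixation"
  if (any(drop)) {
    if (strict) {
      validation_error(
        "generic_interval cannot represent %d non-fixation event(s)",
        sum(drop))
    }
    warn(sprintf(
      "generic_interval is lossy: dropping %d non-fixation event(s)",
      sum(drop)))
    seg <- seg[!drop, , drop = FALSE]
  }
  if (!nrow(seg)) return(character())
  e <- explode_aoi_rows(seg)
  paste(seg$participant_id[e$idx], seg$stimulus_id[e$idx], e$aoi,
        fmt_ms(seg$start[e$idx]), fmt_ms(seg$end[e$idx]),
        seg$category[e$idx], sep = ";")
}

emit_begaze <- function(seg) {
  if (!nrow(seg)) return(character())
  e <- explode_aoi_rows(seg)
  paste(seg$participant_id[e$idx], seg$stimulus_id[e$idx],
        fmt_ms(seg$start[e$idx]), fmt_ms(seg$end[e$idx]),
        seg$category[e$idx], e$aoi, sep = "\t")
}

emit_tobii <- function(seg, cut_points) {
  if (!nrow(seg)) return(character())
  interval <- rep(1L, nrow(seg))
  if (!is.null(cut_points) && nrow(cut_points)) {
    cp <- as_tibble(cut_points)
    for (i in seq_len(nrow(seg))) {
      cuts <- cp$cut_ms[cp$participant_id == seg$participant_id[i] &
                          cp$stimulus_id == seg$stimulus_id[i]]
      interval[i] <- 1L + sum(cuts <= seg$start[i])
    }
  }
  r_start <- round(seg$start)
  r_end <- round(seg$end)
  dur <- r_end - r_start
  keep <- dur > 0
  if (any(!keep)) {
    warn(sprintf("tobii_like: dropping %d segment(s) with sub-millisecond %s",
                 sum(!keep), "duration after rounding"))
  }
  ev <- tobii_event_types[seg$category]
  paste(seg$participant_id[keep], seg$stimulus_id[keep], interval[keep],
        unname(ev)[keep], sprintf("%d", as.integer(r_start[keep])),
        sprintf("%d", as.integer(dur[keep])), sep = "\t") |>
    rep_tobii_aoi(seg[keep, , drop = FALSE])
}

# tobii_like also uses one row per (event, AOI hit)
rep_tobii_aoi <- function(prefix_lines, seg) {
  if (!nrow(seg)) return(character())
  e <- explode_aoi_rows(seg)
  paste(prefix_lines[e$idx], e$aoi, sep = "\t")
}

#' Write a visibility schedule as a CSV file
#'
#' Emits the `aoi,stimulus,start_ms,end_ms` layout read by
#' [read_visibility()]. Scope is a property of the file as a whole, so one
#' scope is selected per file.
#'
#' @param schedule A `visibility_schedule` or interval tibble.
#' @param path Output path.
#' @param scope `"global"` or a participant id: which intervals to write.
#' @return `path`, invisibly.
#' @export
write_visibility <- function(schedule, path, scope = "global") {
  iv <- if (inherits(schedule, "visibility_schedule")) schedule$intervals
        else as_tibble(schedule)
  label <- if (identical(scope, "global")) "global" else
    paste0("participant:", scope)
  iv <- iv[iv$scope == label, , drop = FALSE]
  lines <- if (nrow(iv)) {
    paste(iv$aoi_id, iv$stimulus_id, fmt_ms(iv$start), fmt_ms(iv$end),
          sep = ",")
  } else character()
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("aoi,stimulus,start_ms,end_ms", lines), con, sep = "\n")
  invisible(path)
}
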