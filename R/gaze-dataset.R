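#' Canonical gaze dataset
#'
#' A `gaze_dataset` is the in-memory container every other function in
#' scarfkit consumes: an ordered table of timestamped eye-movement segments
#' (fixations, saccades, other events) with pre-assigned AOI hits, plus
#' registries describing AOIs, participants and stimuli, an optional
#' dynamic-AOI visibility schedule, and parsing metadata.
#'
#' Segments live on a per-trial timeline, where a trial is one participant
#' viewing one stimulus. Intervals are half-open `[start, end)` in
#' milliseconds, so an event ending at t and the next starting at t do not
#' overlap and durations sum exactly. Trial onset is the minimum `start`
#' over the trial and trial end the maximum `end`; all derived quantities
#' (time to first fixation, relative timelines) are referenced to that
#' onset, which makes them independent of the recording clock used by any
#' particular export format.
#'
#' A segment may hit several AOIs at once; hits are stored as a set (a
#' list-column of AOI ids), never as duplicated rows, so dwell-time sums
#' count each millisecond once per AOI.
#'
#' @param segments Data frame with columns `participant_id`, `stimulus_id`,
#'   `start`, `end` (milliseconds), `category` (one of `"fixation"`,
#'   `"saccade"`, `"other"`), and `aoi_ids` — either a list-column of
#'   character vectors or a character column with `;`-separated ids
#'   (empty string or `NA` meaning no AOI hit).
#' @param aois Optional AOI registry: data frame with `stimulus_id`,
#'   `aoi_id` and optionally `display_name`, `color` (6-digit hex),
#'   `merged_into`. Missing AOIs referenced by segments are auto-registered
#'   unless `strict = TRUE`.
#' @param participants Optional participant registry with `participant_id`
#'   and optionally `display_name`, `group_label`.
#' @param stimuli Optional ordered stimulus registry: character vector of
#'   ids or data frame with `stimulus_id` and optional `display_name`.
#' @param visibility Optional visibility schedule, see [read_visibility()].
#' @param meta Optional named list of parse metadata.
#' @param strict If `TRUE`, AOI ids appearing in segments but not in the
#'   registry are an error instead of being auto-registered.
#' @return An object of class `gaze_dataset`.
#' @examples
#' d <- gaze_dataset(tibble::tibble(
#'   participant_id = "P1", stimulus_id = "S",
#'   start = c(0, 100, 120), end = c(100, 120, 300),
#'   category = c("fixation", "saccade", "fixation"),
#'   aoi_ids = c("A", "", "B")
#' ))
#' d
#' @export
gaze_dataset <- function(segments = NULL, aois = NULL, participants = NULL,
                         stimuli = NULL, visibility = NULL, meta = NULL,
                         strict = FALSE) {
  segments <- normalize_segments(segments)
  validate_segments(segments)

  # collapse rows identical up to AOI hits into one segment with the union set
  key <- paste(segments$participant_id, segments$stimulus_id,
               segments$start, segments$end, segments$category, sep = "\r")
  if (anyDuplicated(key)) {
    ukey <- unique(key)
    grp <- match(key, ukey)
    aoi_union <- vector("list", length(ukey))
    for (g in seq_along(ukey)) {
      aoi_union[[g]] <- sort_c(unique(unlist(segments$aoi_ids[grp == g])))
    }
    segments <- segments[!duplicated(key), , drop = FALSE]
    segments$aoi_ids <- aoi_union
  }

  segments <- segments[order_c(segments$participant_id, segments$stimulus_id,
                               segments$start, segments$end), , drop = FALSE]
  check_trial_overlaps(segments)

  participants <- normalize_participants(participants, segments$participant_id)
  stimuli <- normalize_stimuli(stimuli, segments$stimulus_id)
  aois <- normalize_aois(aois, segments, stimuli$stimulus_id, strict = strict)

  structure(
    list(
      segments = segments,
      aois = aois,
      participants = participants,
      stimuli = stimuli,
      visibility = normalize_visibility(visibility),
      meta = normalize_meta(meta),
      filters = list()
    ),
    class = "gaze_dataset"
  )
}

#' Canonicalize raw segment data into a gaze dataset
#'
#' Idempotent constructor: sorts segments, validates the half-open interval
#' model, merges duplicate rows, and completes the registries. Applying it
#' to an existing `gaze_dataset` re-validates and returns an equal dataset.
#'
#' @inheritParams gaze_dataset
#' @param x A data frame of raw segments or an existing `gaze_dataset`.
#' @return A `gaze_dataset`.
#' @export
canonicalize <- function(x, aois = NULL, participants = NULL, stimuli = NULL,
                         visibility = NULL, meta = NULL, strict = FALSE) {
  if (inherits(x, "gaze_dataset")) {
    return(gaze_dataset(x$segments, aois %||% x$aois,
                        participants %||% x$participants,
                        stimuli %||% x$stimuli,
                        visibility %||% x$visibility,
                        meta %||% x$meta, strict = strict))
  }
  gaze_dataset(x, aois, participants, stimuli, visibility, meta,
               strict = strict)
}

segment_categories <- c("fixation", "saccade", "other")

empty_segments <- function() {
  tibble(participant_id = character(), stimulus_id = character(),
         start = double(), end = double(), category = character(),
         aoi_ids = list())
}

normalize_segments <- function(segments) {
  if (is.null(segments) || (is.data.frame(segments) && nrow(segments) == 0L)) {
    return(empty_segments())
  }
  if (!is.data.frame(segments)) {
    validation_error("`segments` must be a data frame")
  }
  needed <- c("participant_id", "stimulus_id", "start", "end", "category",
              "aoi_ids")
  missing <- setdiff(needed, names(segments))
  if (length(missing)) {
    validation_error("`segments` is missing column(s): %s",
                     paste(missing, collapse = ", "))
  }
  segments <- as_tibble(segments)[needed]
  segments$participant_id <- as.character(segments$participant_id)
  segments$stimulus_id <- as.character(segments$stimulus_id)
  segments$start <- as.numeric(segments$start)
  segments$end <- as.numeric(segments$end)
  segments$category <- as.character(segments$category)
  if (!is.list(segments$aoi_ids)) {
    raw <- as.character(segments$aoi_ids)
    raw[is.na(raw)] <- ""
    segments$aoi_ids <- lapply(strsplit(raw, ";", fixed = TRUE),
                               function(v) sort_c(unique(v[nzchar(v)])))
  } else {
    segments$aoi_ids <- lapply(segments$aoi_ids, function(v) {
      v <- as.character(v)
      sort_c(unique(v[!is.na(v) & nzchar(v)]))
    })
    # ";" is the textual set separator in every export, so ids cannot use it
    if (any(grepl(";", unlist(segments$aoi_ids), fixed = TRUE))) {
      validation_error("AOI ids must not contain ';'")
    }
  }
  segments
}

validate_segments <- function(segments) {
  bad_cat <- which(!segments$category %in% segment_categories)
  if (length(bad_cat)) {
    validation_error(
      "row %d: category '%s' is not one of %s", bad_cat[1],
      segments$category[bad_cat[1]],
      paste(segment_categories, collapse = ", "))
  }
  if (anyNA(segments$start) || anyNA(segments$end)) {
    validation_error("segment start/end must not be missing")
  }
  neg <- which(segments$start < 0)
  if (length(neg)) {
    validation_error("row %d: negative start time (%g ms)", neg[1],
                     segments$start[neg[1]])
  }
  zero <- which(segments$end <= segments$start)
  if (length(zero)) {
    validation_error(
      "row %d: zero or negative duration segment [%g, %g) is not allowed",
      zero[1], segments$start[zero[1]], segments$end[zero[1]])
  }
  invisible(segments)
}

# same-category events within one trial must not overlap (beyond fp noise)
check_trial_overlaps <- function(segments) {
  if (nrow(segments) < 2L) return(invisible(NULL))
  df <- segments[order_c(segments$participant_id, segments$stimulus_id,
                         segments$category, segments$start), ]
  same <- df$participant_id == lag_chr(df$participant_id) &
    df$stimulus_id == lag_chr(df$stimulus_id) &
    df$category == lag_chr(df$category)
  ov <- which(same & df$start < c(-Inf, df$end[-nrow(df)]) - 1e-9)
  if (length(ov)) {
    i <- ov[1]
    validation_error(
      "overlapping %s segments for participant '%s' on stimulus '%s' near %g ms",
      df$category[i], df$participant_id[i], df$stimulus_id[i], df$start[i])
  }
  invisible(NULL)
}

lag_chr <- function(x) c(NA_character_, x[-length(x)])

normalize_participants <- function(participants, seen_ids) {
  if (is.null(participants)) {
    participants <- tibble(participant_id = character())
  } else if (is.character(participants)) {
    participants <- tibble(participant_id = participants)
  }
  participants <- as_tibble(participants)
  if (!"participant_id" %in% names(participants)) {
    validation_error("participant registry needs a `participant_id` column")
  }
  participants$participant_id <- as.character(participants$participant_id)
  if (!"display_name" %in% names(participants)) {
    participants$display_name <- participants$participant_id
  }
  if (!"group_label" %in% names(participants)) {
    participants$group_label <- NA_character_
  }
  participants <- participants[c("participant_id", "display_name",
                                 "group_label")]
  if (anyDuplicated(participants$participant_id)) {
    validation_error("duplicate participant_id in registry")
  }
  new_ids <- setdiff(unique(seen_ids), participants$participant_id)
  if (length(new_ids)) {
    participants <- bind_rows(participants, tibble(
      participant_id = new_ids, display_name = new_ids,
      group_label = NA_character_))
  }
  participants
}

normalize_stimuli <- function(stimuli, seen_ids) {
  if (is.null(stimuli)) {
    stimuli <- tibble(stimulus_id = character())
  } else if (is.character(stimuli)) {
    stimuli <- tibble(stimulus_id = stimuli)
  }
  stimuli <- as_tibble(stimuli)
  if (!"stimulus_id" %in% names(stimuli)) {
    validation_error("stimulus registry needs a `stimulus_id` column")
  }
  stimuli$stimulus_id <- as.character(stimuli$stimulus_id)
  if (!"display_name" %in% names(stimuli)) {
    stimuli$display_name <- stimuli$stimulus_id
  }
  stimuli <- stimuli[c("stimulus_id", "display_name")]
  new_ids <- setdiff(unique(seen_ids), stimuli$stimulus_id)
  if (length(new_ids)) {
    stimuli <- bind_rows(stimuli,
                         tibble(stimulus_id = new_ids, display_name = new_ids))
  }
  stimuli
}

#' Default categorical palette for AOIs
#'
#' A fixed 12-colour categorical cycle assigned to AOIs in registration
#' order; individual AOIs can be recoloured with [set_aoi_style()].
#' @return Character vector of 12 hex colours.
#' @export
scarf_palette <- function() {
  c("#4E79A7", "#F28E2B", "#E15759", "#76B7B2", "#59A14F", "#EDC948",
    "#B07AA1", "#FF9DA7", "#9C755F", "#BAB0AC", "#1170AA", "#A3CCE9")
}

# reserved styles for non-AOI content in scarf plots
style_constants <- list(
  saccade_color = "#555555",
  no_aoi_color = "#CFCFCF",
  overlap_color = "#2B2B2B",
  visibility_alpha = 0.45
)

normalize_aois <- function(aois, segments, stimulus_ids, strict = FALSE) {
  if (is.null(aois)) {
    aois <- tibble(stimulus_id = character(), aoi_id = character())
  }
  aois <- as_tibble(aois)
  if (!all(c("stimulus_id", "aoi_id") %in% names(aois))) {
    validation_error("AOI registry needs `stimulus_id` and `aoi_id` columns")
  }
  aois$stimulus_id <- as.character(aois$stimulus_id)
  aois$aoi_id <- as.character(aois$aoi_id)
  if (!"display_name" %in% names(aois)) aois$display_name <- aois$aoi_id
  if (!"color" %in% names(aois)) aois$color <- NA_character_
  if (!"merged_into" %in% names(aois)) aois$merged_into <- NA_character_
  if (!"auto_created" %in% names(aois)) aois$auto_created <- FALSE
  aois <- aois[c("stimulus_id", "aoi_id", "display_name", "color",
                 "merged_into", "auto_created")]
  if (anyDuplicated(paste(aois$stimulus_id, aois$aoi_id, sep = "\r"))) {
    validation_error("duplicate (stimulus_id, aoi_id) in AOI registry")
  }

  # AOIs referenced by segments but absent from the registry
  if (nrow(segments)) {
    ref <- tibble(
      stimulus_id = rep(segments$stimulus_id,
                        lengths(segments$aoi_ids)),
      aoi_id = unlist(segments$aoi_ids) %||% character()
    )
    ref <- distinct(ref)
    ref <- ref[order_c(ref$stimulus_id, ref$aoi_id), ]
    unknown <- anti_join(ref, aois, by = c("stimulus_id", "aoi_id"))
    if (nrow(unknown)) {
      if (strict) {
        validation_error(
          "unknown AOI id(s) not in registry: %s",
          paste(sprintf("%s/%s", unknown$stimulus_id, unknown$aoi_id),
                collapse = ", "))
      }
      aois <- bind_rows(aois, tibble(
        stimulus_id = unknown$stimulus_id, aoi_id = unknown$aoi_id,
        display_name = unknown$aoi_id, color = NA_character_,
        merged_into = NA_character_, auto_created = FALSE))
    }
  }
  bad_color <- !is.na(aois$color) &
    !grepl("^#[0-9A-Fa-f]{6}$", aois$color)
  if (any(bad_color)) {
    validation_error("invalid AOI colour '%s' (expect 6-digit hex)",
                     aois$color[which(bad_color)[1]])
  }
  check_merge_forest(aois)

  # assign palette colours per stimulus in registration order
  for (s in unique(aois$stimulus_id)) {
    idx <- which(aois$stimulus_id == s)
    fill <- is.na(aois$color[idx])
    aois$color[idx][fill] <-
      scarf_palette()[(which(fill) - 1L) %% 12L + 1L]
  }
  aois
}

check_merge_forest <- function(aois) {
  for (s in unique(aois$stimulus_id)) {
    sub <- aois[aois$stimulus_id == s, ]
    ptr <- setNames(sub$merged_into, sub$aoi_id)
    for (a in sub$aoi_id) {
      seen <- character()
      cur <- a
      while (!is.na(ptr[cur] %||% NA_character_)) {
        if (cur %in% seen) {
          validation_error("AOI merge pointers form a cycle at '%s'", a)
        }
        seen <- c(seen, cur)
        nxt <- unname(ptr[cur])
        if (!nxt %in% sub$aoi_id) {
          validation_error("AOI '%s' merged into unregistered '%s'", cur, nxt)
        }
        cur <- nxt
      }
    }
  }
  invisible(NULL)
}

normalize_visibility <- function(visibility) {
  if (is.null(visibility)) return(NULL)
  if (inherits(visibility, "visibility_schedule")) {
    visibility <- visibility$intervals
  }
  visibility <- as_tibble(visibility)
  needed <- c("aoi_id", "stimulus_id", "scope", "start", "end")
  if (!all(needed %in% names(visibility))) {
    validation_error("visibility schedule needs columns %s",
                     paste(needed, collapse = ", "))
  }
  visibility <- visibility[needed]
  if (any(visibility$end <= visibility$start)) {
    validation_error("visibility interval with end <= start")
  }
  merge_visibility_intervals(visibility)
}

# union of overlapping same-(aoi, stimulus, scope) intervals
merge_visibility_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order_c(iv$aoi_id, iv$stimulus_id, iv$scope, iv$start, iv$end), ]
  key <- paste(iv$aoi_id, iv$stimulus_id, iv$scope, sep = "\r")
  out <- lapply(split(seq_len(nrow(iv)), key), function(idx) {
    s <- iv$start[idx]; e <- iv$end[idx]
    ms <- s[1]; me <- e[1]; keep_s <- c(); keep_e <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me) me <- max(me, e[i]) else {
        keep_s <- c(keep_s, ms); keep_e <- c(keep_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    keep_s <- c(keep_s, ms); keep_e <- c(keep_e, me)
    tibble(aoi_id = iv$aoi_id[idx[1]], stimulus_id = iv$stimulus_id[idx[1]],
           scope = iv$scope[idx[1]], start = keep_s, end = keep_e)
  })
  out <- bind_rows(out[sort_c(names(out))])
  out[order_c(out$aoi_id, out$stimulus_id, out$scope, out$start), ]
}

normalize_meta <- function(meta) {
  base <- list(
    source_filename = NA_character_,
    detected_dialect = NA_character_,
    file_size_bytes = NA_real_,
    parse_duration_ms = NA_real_,
    tool_version = as.character(utils::packageVersion("scarfkit"))
  )
  if (is.null(meta)) return(base)
  modifyList(base, meta[intersect(names(meta), names(base))])
}

#' @export
print.gaze_dataset <- function(x, ...) {
  cat(sprintf(
    "<gaze_dataset> %d segments | %d participants | %d stimuli | %d AOIs\n",
    nrow(x$segments), nrow(x$participants), nrow(x$stimuli), nrow(x$aois)))
  if (length(x$filters)) {
    cat(sprintf("  %d filter(s) pending (non-destructive)\n",
                length(x$filters)))
  }
  if (!is.null(x$visibility)) {
    cat(sprintf("  visibility schedule: %d interval(s)\n",
                nrow(x$visibility)))
  }
  if (!is.na(x$meta$detected_dialect)) {
    cat(sprintf("  parsed from '%s' (%s)\n",
                x$meta$source_filename, x$meta$detected_dialect))
  }
  invisible(x)
}

#' Tidy a gaze dataset into a flat segment table
#'
#' @param x A `gaze_dataset`.
#' @param resolved If `TRUE` (default) AOI merges and pending filters are
#'   applied first.
#' @param ... Unused.
#' @return Tibble with one row per segment; `aoi_ids` collapsed to a
#'   `;`-separated string.
#' @export
tidy.gaze_dataset <- function(x, resolved = TRUE, ...) {
  if (resolved) x <- resolve_view(x)
  seg <- x$segments
  seg$aoi_ids <- map_chr(seg$aoi_ids, paste, collapse = ";")
  seg$duration <- seg$end - seg$start
  seg
}

#' One-row summary of a gaze dataset
#' @param x A `gaze_dataset`.
#' @param ... Unused.
#' @export
glance.gaze_dataset <- function(x, ...) {
  v <- resolve_view(x)
  fix <- v$segments[v$segments$category == "fixation", ]
  tibble(
    n_segments = nrow(v$segments),
    n_fixations = nrow(fix),
    n_participants = nrow(v$participants),
    n_stimuli = nrow(v$stimuli),
    n_aois = nrow(v$aois),
    n_trials = nrow(trial_bounds(v)),
    total_fixation_ms = sum(fix$end - fix$start)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Trial onset and end per (participant, stimulus)
#'
#' Trial onset is the minimum segment start and trial end the maximum
#' segment end within each participant-stimulus pair.
#' @param x A `gaze_dataset` (resolved or not; segments are used as-is).
#' @return Tibble with `participant_id`, `stimulus_id`, `onset`, `end`.
#' @export
trial_bounds <- function(x) {
  seg <- if (inherits(x, "gaze_dataset")) x$segments else x
  if (!nrow(seg)) {
    return(tibble(participant_id = character(), stimulus_id = character(),
                  onset = double(), end = double()))
  }
  seg |>
    group_by(participant_id, stimulus_id) |>
    summarise(onset = min(start), end = max(end), .groups = "drop") |>
    (\(df) df[order_c(df$participant_id, df$stimulus_id), ])()
}
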