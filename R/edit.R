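#' Merge AOIs non-destructively
#'
#' Adds a merge pointer from each member AOI to `target`. The underlying
#' segments are untouched: whenever a view is resolved (metrics, scarf
#' geometry, exports), every hit on a member resolves to the target, with
#' set semantics — a segment hitting two members of the same merge reports
#' the target once, so dwell sums never double count. [unmerge_aois()]
#' restores the previous state exactly.
#'
#' @param x A `gaze_dataset`.
#' @param target AOI id the members merge into. Created if absent.
#' @param members Character vector of existing AOI ids.
#' @param stimulus Stimulus the merge applies to; defaults to every
#'   stimulus on which all members are registered.
#' @param display_name,color Optional style for a newly created target.
#' @return The dataset with updated merge pointers.
#' @export
merge_aois <- function(x, target, members, stimulus = NULL,
                       display_name = NULL, color = NULL) {
  stopifnot(inherits(x, "gaze_dataset"))
  if (!is_string(target)) validation_error("`target` must be a single AOI id")
  members <- as.character(members)
  if (!length(members)) validation_error("`members` must not be empty")
  stims <- stimulus %||% unique(
    x$aois$stimulus_id[x$aois$aoi_id %in% members])
  for (s in stims) {
    sub <- x$aois$stimulus_id == s
    known <- x$aois$aoi_id[sub]
    miss <- setdiff(members, known)
    if (length(miss)) {
      validation_error("AOI(s) not registered for stimulus '%s': %s",
                       s, paste(miss, collapse = ", "))
    }
    if (!target %in% known) {
      n_before <- sum(x$aois$stimulus_id == s)
      x$aois <- bind_rows(x$aois, tibble(
        stimulus_id = s, aoi_id = target,
        display_name = display_name %||% target,
        color = color %||% scarf_palette()[n_before %% 12L + 1L],
        merged_into = NA_character_, auto_created = TRUE))
      sub <- x$aois$stimulus_id == s
    }
    idx <- which(sub & x$aois$aoi_id %in% setdiff(members, target))
    x$aois$merged_into[idx] <- target
  }
  check_merge_forest(x$aois)
  x
}

#' Undo an AOI merge
#'
#' Clears the merge pointers to `target`; if the target AOI was created by
#' [merge_aois()] and no segment hits it directly, its registry row is
#' removed, so merge followed by unmerge is the identity on every
#' queryable value.
#'
#' @param x A `gaze_dataset`.
#' @param target AOI id previously used as a merge target.
#' @return The restored dataset.
#' @export
unmerge_aois <- function(x, target) {
  stopifnot(inherits(x, "gaze_dataset"))
  hit <- !is.na(x$aois$merged_into) & x$aois$merged_into == target
  if (!any(hit)) validation_error("no AOI is merged into '%s'", target)
  x$aois$merged_into[hit] <- NA_character_
  direct <- any(map_lgl(x$segments$aoi_ids, function(v) target %in% v))
  drop <- x$aois$aoi_id == target & x$aois$auto_created & !direct
  x$aois <- x$aois[!drop, , drop = FALSE]
  x
}

#' Restyle an AOI
#'
#' Non-destructive display edits: rename and/or recolour one AOI.
#' @param x A `gaze_dataset`.
#' @param aoi AOI id.
#' @param display_name,color New values (either may be omitted).
#' @param stimulus Restrict to one stimulus (default: all).
#' @export
set_aoi_style <- function(x, aoi, display_name = NULL, color = NULL,
                          stimulus = NULL) {
  stopifnot(inherits(x, "gaze_dataset"))
  idx <- x$aois$aoi_id == aoi
  if (!is.null(stimulus)) idx <- idx & x$aois$stimulus_id == stimulus
  if (!any(idx)) validation_error("AOI '%s' is not registered", aoi)
  if (!is.null(display_name)) x$aois$display_name[idx] <- display_name
  if (!is.null(color)) {
    if (!grepl("^#[0-9A-Fa-f]{6}$", color)) {
      validation_error("invalid colour '%s' (expect 6-digit hex)", color)
    }
    x$aois$color[idx] <- color
  }
  x
}

#' Assign participants to a named group
#' @param x A `gaze_dataset`.
#' @param participants Character vector of participant ids.
#' @param group Group label (a string, or `NA` to clear).
#' @export
set_participant_group <- function(x, participants, group) {
  stopifnot(inherits(x, "gaze_dataset"))
  miss <- setdiff(participants, x$participants$participant_id)
  if (length(miss)) {
    validation_error("unknown participant(s): %s; known: %s",
                     paste(miss, collapse = ", "),
                     paste(x$participants$participant_id, collapse = ", "))
  }
  idx <- x$participants$participant_id %in% participants
  x$participants$group_label[idx] <- group
  x
}

#' Rename a stimulus for display
#' @param x A `gaze_dataset`.
#' @param stimulus Stimulus id.
#' @param display_name New display name.
#' @export
rename_stimulus <- function(x, stimulus, display_name) {
  stopifnot(inherits(x, "gaze_dataset"))
  idx <- x$stimuli$stimulus_id == stimulus
  if (!any(idx)) validation_error("unknown stimulus '%s'", stimulus)
  x$stimuli$display_name[idx] <- display_name
  x
}

#' Construct a view filter
#'
#' Filters are non-destructive and compose by intersection: applying two
#' filters keeps the segments satisfying both. `time_range` is a half-open
#' interval `[t0, t1)` on the segments' own millisecond clock; segments
#' partially inside are clipped at the bounds (which can shift a trial's
#' onset for later onset-referenced computations).
#'
#' @param stimulus Optional stimulus id.
#' @param group Optional participant group label.
#' @param aoi Optional character vector of AOI ids; keeps segments whose
#'   (merge-resolved) AOI set intersects it, plus all saccades.
#' @param time_range Optional numeric `c(t0, t1)` in ms on the segment
#'   clock.
#' @return A `view_filter` object.
#' @export
view_filter <- function(stimulus = NULL, group = NULL, aoi = NULL,
                        time_range = NULL) {
  if (!is.null(time_range)) {
    if (length(time_range) != 2L || !is.numeric(time_range) ||
        time_range[2] <= time_range[1]) {
      validation_error("`time_range` must be numeric c(t0, t1) with t1 > t0")
    }
  }
  structure(list(stimulus = stimulus, group = group,
                 aoi = if (is.null(aoi)) NULL else as.character(aoi),
                 time_range = time_range),
            class = "view_filter")
}

#' @export
print.view_filter <- function(x, ...) {
  parts <- c(
    if (!is.null(x$stimulus)) sprintf("stimulus=%s", x$stimulus),
    if (!is.null(x$group)) sprintf("group=%s", x$group),
    if (!is.null(x$aoi)) sprintf("aoi={%s}", paste(x$aoi, collapse = ",")),
    if (!is.null(x$time_range)) sprintf("time=[%g,%g)", x$time_range[1],
                                        x$time_range[2]))
  cat("<view_filter>", if (length(parts)) paste(parts, collapse = " ")
      else "(empty)", "\n")
  invisible(x)
}

#' Apply a filter to a dataset, non-destructively
#'
#' The filter is validated against the registries and queued; the
#' underlying data are untouched and [clear_filters()] reverses the
#' operation. Consumers resolve pending filters lazily.
#'
#' @param x A `gaze_dataset`.
#' @param filter A [view_filter()].
#' @return The dataset with the filter queued.
#' @export
apply_filter <- function(x, filter) {
  stopifnot(inherits(x, "gaze_dataset"))
  if (!inherits(filter, "view_filter")) {
    validation_error("`filter` must be created with view_filter()")
  }
  if (!is.null(filter$stimulus) &&
      !filter$stimulus %in% x$stimuli$stimulus_id) {
    validation_error("unknown stimulus '%s'; valid: %s", filter$stimulus,
                     paste(x$stimuli$stimulus_id, collapse = ", "))
  }
  if (!is.null(filter$group)) {
    groups <- unique(x$participants$group_label)
    groups <- groups[!is.na(groups)]
    if (!filter$group %in% groups) {
      validation_error("unknown group '%s'; valid: %s", filter$group,
                       if (length(groups)) paste(groups, collapse = ", ")
                       else "(no groups assigned)")
    }
  }
  if (!is.null(filter$aoi)) {
    known <- unique(c(x$aois$aoi_id,
                      resolved_aoi_targets(x$aois)))
    miss <- setdiff(filter$aoi, known)
    if (length(miss)) {
      validation_error("unknown AOI(s) in filter: %s; valid: %s",
                       paste(miss, collapse = ", "),
                       paste(sort_c(unique(x$aois$aoi_id)), collapse = ", "))
    }
  }
  x$filters <- c(x$filters, list(filter))
  x
}

#' Drop all pending filters
#' @param x A `gaze_dataset`.
#' @export
clear_filters <- function(x) {
  stopifnot(inherits(x, "gaze_dataset"))
  x$filters <- list()
  x
}

resolved_aoi_targets <- function(aois) {
  unique(aois$merged_into[!is.na(aois$merged_into)])
}

# follow merge pointers to the root, per stimulus; returns a named map
aoi_resolution_map <- function(aois, stimulus) {
  sub <- aois[aois$stimulus_id == stimulus, ]
  ptr <- setNames(sub$merged_into, sub$aoi_id)
  vapply(sub$aoi_id, function(a) {
    cur <- a
    while (!is.na(ptr[[cur]] %||% NA_character_)) cur <- ptr[[cur]]
    cur
  }, character(1))
}

#' Materialize a dataset view
#'
#' Applies AOI merge pointers and all pending filters, producing a plain
#' `gaze_dataset` whose segments, registries and visibility schedule
#' reflect the view. All analysis functions call this internally; it is
#' exported for inspection and tests.
#'
#' @param x A `gaze_dataset`.
#' @return A resolved `gaze_dataset` (no pending filters, no merge
#'   pointers).
#' @export
resolve_view <- function(x) {
  stopifnot(inherits(x, "gaze_dataset"))
  seg <- x$segments
  aois <- x$aois

  has_merge <- any(!is.na(aois$merged_into))
  if (has_merge && nrow(seg)) {
    maps <- lapply(setNames(nm = unique(aois$stimulus_id)),
                   function(s) aoi_resolution_map(aois, s))
    seg$aoi_ids <- map2(seg$aoi_ids, seg$stimulus_id, function(v, s) {
      if (!length(v)) return(v)
      m <- maps[[s]]
      sort_c(unique(unname(m[v])))
    })
  }
  if (has_merge) {
    # collapse registry to merge roots; a root inherits its own style
    root <- aois[is.na(aois$merged_into), , drop = FALSE]
    aois <- root
  }
  vis <- x$visibility
  if (!is.null(vis) && has_merge && nrow(vis)) {
    for (s in unique(vis$stimulus_id)) {
      m <- aoi_resolution_map(x$aois, s)
      idx <- vis$stimulus_id == s & vis$aoi_id %in% names(m)
      vis$aoi_id[idx] <- unname(m[vis$aoi_id[idx]])
    }
    vis <- merge_visibility_intervals(vis)
  }

  participants <- x$participants
  stimuli <- x$stimuli
  for (f in x$filters) {
    if (!is.null(f$stimulus)) {
      seg <- seg[seg$stimulus_id == f$stimulus, , drop = FALSE]
      stimuli <- stimuli[stimuli$stimulus_id == f$stimulus, , drop = FALSE]
    }
    if (!is.null(f$group)) {
      keep <- participants$participant_id[
        !is.na(participants$group_label) &
          participants$group_label == f$group]
      seg <- seg[seg$participant_id %in% keep, , drop = FALSE]
      participants <- participants[
        participants$participant_id %in% keep, , drop = FALSE]
    }
    if (!is.null(f$aoi)) {
      keep <- map_lgl(seg$aoi_ids, function(v) length(intersect(v, f$aoi)) > 0)
      seg <- seg[keep | seg$category == "saccade", , drop = FALSE]
    }
    if (!is.null(f$time_range)) {
      seg$start <- pmax(seg$start, f$time_range[1])
      seg$end <- pmin(seg$end, f$time_range[2])
      seg <- seg[seg$end > seg$start, , drop = FALSE]
    }
  }
  aois <- aois[aois$stimulus_id %in% stimuli$stimulus_id, , drop = FALSE]
  out <- x
  out$segments <- seg
  out$aois <- aois
  out$participants <- participants
  out$stimuli <- stimuli
  out$visibility <- vis
  out$filters <- list()
  out
}
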