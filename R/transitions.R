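#' AOI-to-AOI transition matrix
#'
#' Counts transitions between consecutive fixations within each trial
#' (saccades and "other" events are skipped; transitions never cross trial
#' or participant boundaries). For a consecutive pair of fixations, one
#' count is added for every ordered pair (a, b) with a in the first
#' fixation's AOI set and b in the second's. An empty AOI set maps to the
#' pseudo-label `(no AOI)` when `include_no_aoi` is on, otherwise the pair
#' is skipped. Self-transitions (a == b) are counted only when
#' `include_self` is on. Counts are summed over all trials in the view.
#'
#' @param x A `gaze_dataset`.
#' @param include_self Count self-transitions (default `FALSE`, the usual
#'   convention in transition analysis).
#' @param include_no_aoi Add a `(no AOI)` row/column (default `FALSE`).
#' @return A `transition_matrix` object: integer count matrix with AOI ids
#'   in registry order (pseudo-label last), plus the view's filters as
#'   scope.
#' @examples
#' d <- gaze_dataset(tibble::tibble(
#'   participant_id = "P1", stimulus_id = "S",
#'   start = c(0, 100, 200), end = c(100, 200, 300),
#'   category = "fixation", aoi_ids = c("A", "B", "A")
#' ))
#' transition_matrix(d)
#' @export
transition_matrix <- function(x, include_self = FALSE,
                              include_no_aoi = FALSE) {
  stopifnot(inherits(x, "gaze_dataset"))
  scope <- x$filters
  v <- resolve_view(x)
  aoi_order <- unique(v$aois$aoi_id)
  no_aoi_label <- "(no AOI)"
  if (include_no_aoi) aoi_order <- c(aoi_order, no_aoi_label)
  counts <- matrix(0L, nrow = length(aoi_order), ncol = length(aoi_order),
                   dimnames = list(from = aoi_order, to = aoi_order))

  fix <- v$segments[v$segments$category == "fixation", , drop = FALSE]
  if (nrow(fix) >= 2L) {
    fix <- fix[order_c(fix$participant_id, fix$stimulus_id, fix$start), ]
    trial <- paste(fix$participant_id, fix$stimulus_id, sep = "\r")
    for (i in seq_len(nrow(fix) - 1L)) {
      if (trial[i] != trial[i + 1L]) next
      from <- fix$aoi_ids[[i]]
      to <- fix$aoi_ids[[i + 1L]]
      if (!length(from)) {
        if (!include_no_aoi) next
        from <- no_aoi_label
      }
      if (!length(to)) {
        if (!include_no_aoi) next
        to <- no_aoi_label
      }
      for (a in from) for (b in to) {
        if (!include_self && a == b) next
        counts[a, b] <- counts[a, b] + 1L
      }
    }
  }
  structure(list(counts = counts, aoi_order = aoi_order,
                 include_self = include_self,
                 include_no_aoi = include_no_aoi,
                 scope = scope),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d AOI(s), %d transition(s)\n",
              length(x$aoi_order), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.transition_matrix <- function(x, ...) {
  df <- as.data.frame.table(x$counts, stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "n")
  as_tibble(df)
}

#' @export
glance.transition_matrix <- function(x, ...) {
  tibble(n_aois = length(x$aoi_order), total_transitions = sum(x$counts),
         include_self = x$include_self, include_no_aoi = x$include_no_aoi)
}

#' Write a transition matrix as CSV
#'
#' First row: empty cell then the destination AOI labels; one row per
#' source AOI with integer counts.
#' @param x A `transition_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(x, path) {
  stopifnot(inherits(x, "transition_matrix"))
  header <- paste(c("", x$aoi_order), collapse = ",")
  rows <- vapply(seq_along(x$aoi_order), function(i) {
    paste(c(x$aoi_order[i], x$counts[i, ]), collapse = ",")
  }, character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}
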