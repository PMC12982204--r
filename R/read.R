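#' Read a gaze-event export into a canonical dataset
#'
#' Streams the file chunk by chunk: only the carry-over of the last partial
#' line is retained between chunks, so peak retained input is bounded by
#' one record regardless of file size, and the parsed dataset is identical
#' for every chunk decomposition of the same bytes. The dialect is
#' auto-detected from the header with [detect_dialect()] unless given.
#'
#' @param path Path to a delimited text file (UTF-8, LF or CRLF).
#' @param dialect Optional dialect id (see [list_dialects()]); default
#'   auto-detect.
#' @param strict If `TRUE`, malformed rows abort with their 1-based line
#'   number and unknown AOI references are errors; if `FALSE` (default,
#'   mirroring permissive interactive ingestion) malformed rows are
#'   skipped and counted.
#' @param chunk_size Chunk size in bytes for the streaming reader.
#' @return A `gaze_dataset` with populated parse metadata. The attribute
#'   `max_carry_bytes` records the largest carry-over buffer the reader
#'   held between chunks (used to verify the bounded-memory contract).
#' @export
read_gaze <- function(path, dialect = NULL, strict = FALSE,
                      chunk_size = 65536L) {
  if (!file.exists(path)) validation_error("no such file: %s", path)
  t0 <- proc.time()[["elapsed"]]
  scan <- stream_lines(path, chunk_size)
  if (length(scan$lines) == 0L) {
    validation_error("empty file: %s", path)
  }
  d <- if (is.null(dialect)) detect_dialect(scan$lines[1]) else
    dialect_descriptor(dialect)

  toks <- strsplit(scan$lines[1], d$delimiter, fixed = TRUE)[[1]]
  if (!identical(toks, d$header)) {
    validation_error(
      "unrecognized format: header does not match dialect '%s'",
      d$dialect_id)
  }

  body <- scan$lines[-1]
  body <- body[nzchar(body)]
  n_fields <- length(d$header)
  fields <- strsplit(body, d$delimiter, fixed = TRUE)
  # a trailing empty field is dropped by strsplit; restore it
  fields <- lapply(fields, function(f) {
    if (length(f) == n_fields - 1L) c(f, "") else f
  })
  bad <- which(lengths(fields) != n_fields)
  skipped <- 0L
  if (length(bad)) {
    if (strict) {
      validation_error("malformed row at line %d of %s (expected %d fields)",
                       bad[1] + 1L, path, n_fields)
    }
    skipped <- length(bad)
    fields <- fields[-bad]
  }
  mat <- if (length(fields)) {
    matrix(unlist(fields), ncol = n_fields, byrow = TRUE)
  } else {
    matrix(character(), ncol = n_fields)
  }
  colnames(mat) <- d$header

  seg <- switch(
    d$dialect_id,
    generic_long = rows_generic_long(mat, strict, path),
    generic_interval = rows_generic_interval(mat, strict, path),
    begaze_like = rows_begaze(mat, strict, path),
    tobii_like = rows_tobii(mat, strict, path)
  )
  if (skipped > 0L) {
    inform(sprintf("read_gaze: skipped %d malformed row(s) in %s",
                   skipped, path))
  }
  meta <- list(
    source_filename = basename(path),
    detected_dialect = d$dialect_id,
    file_size_bytes = as.numeric(file.size(path)),
    parse_duration_ms = (proc.time()[["elapsed"]] - t0) * 1000
  )
  out <- gaze_dataset(seg, meta = meta, strict = strict)
  attr(out, "max_carry_bytes") <- scan$max_carry_bytes
  out
}

# chunked line reader: returns all complete lines; only the trailing
# partial line is ever carried between chunks
stream_lines <- function(path, chunk_size) {
  con <- file(path, "rb")
  on.exit(close(con))
  carry <- ""
  max_carry <- 0L
  lines <- vector("list", 64L)
  n <- 0L
  push <- function(batch) {
    if (!length(batch)) return(invisible(NULL))
    if (n + 1L > length(lines)) {
      length(lines) <<- 2L * length(lines)
    }
    n <<- n + 1L
    lines[[n]] <<- batch
    invisible(NULL)
  }
  repeat {
    raw <- readBin(con, "raw", n = chunk_size)
    if (!length(raw)) break
    txt <- paste0(carry, rawToChar(raw))
    parts <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    ends_nl <- endsWith(txt, "\n")
    if (ends_nl) {
      carry <- ""
      push(parts)
    } else {
      carry <- parts[length(parts)]
      push(parts[-length(parts)])
    }
    max_carry <- max(max_carry, nchar(carry, type = "bytes"))
  }
  if (nzchar(carry)) push(carry)
  out <- unlist(lines[seq_len(n)]) %||% character()
  out <- sub("\r$", "", out)
  list(lines = out, max_carry_bytes = max_carry)
}

parse_ms <- function(x, what, strict, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & nzchar(x))
  bad <- union(bad, which(!nzchar(x)))
  if (length(bad)) {
    validation_error("non-numeric %s value '%s' in %s",
                     what, x[bad[1]], path)
  }
  out
}

rows_generic_long <- function(mat, strict, path) {
  ts <- parse_ms(mat[, "timestamp_ms"], "timestamp_ms", strict, path)
  dur <- parse_ms(mat[, "duration_ms"], "duration_ms", strict, path)
  tibble(
    participant_id = mat[, "participant"],
    stimulus_id = mat[, "stimulus"],
    start = ts, end = ts + dur,
    category = mat[, "category"],
    aoi_ids = as.list(mat[, "aoi"])
  )
}

rows_generic_interval <- function(mat, strict, path) {
  tibble(
    participant_id = mat[, "participant"],
    stimulus_id = mat[, "stimulus"],
    start = parse_ms(mat[, "interval_start"], "interval_start", strict, path),
    end = parse_ms(mat[, "interval_end"], "interval_end", strict, path),
    category = mat[, "event"],
    aoi_ids = as.list(mat[, "aoi"])
  )
}

rows_begaze <- function(mat, strict, path) {
  tibble(
    participant_id = mat[, "Participant"],
    stimulus_id = mat[, "Stimulus"],
    start = parse_ms(mat[, "Event Start Trial Time [ms]"], "start",
                     strict, path),
    end = parse_ms(mat[, "Event End Trial Time [ms]"], "end", strict, path),
    category = mat[, "Category"],
    aoi_ids = as.list(mat[, "AOI Name"])
  )
}

rows_tobii <- function(mat, strict, path) {
  start <- parse_ms(mat[, "Start"], "Start", strict, path)
  dur <- parse_ms(mat[, "Duration"], "Duration", strict, path)
  interval <- suppressWarnings(as.integer(mat[, "Interval"]))
  if (anyNA(interval) && nrow(mat)) {
    validation_error("non-integer Interval value in %s", path)
  }
  stim <- mat[, "Presented Stimulus"]
  # a stimulus that appears in more than one interval is split into
  # per-interval trials "S#k"; single-interval stimuli keep their id
  multi <- tapply(interval, stim, function(v) length(unique(v)) > 1L)
  is_multi <- unname(multi[stim])
  stim_out <- ifelse(is_multi & length(stim) > 0,
                     interval_stimulus_id(stim, interval), stim)
  tibble(
    participant_id = mat[, "Recording"],
    stimulus_id = as.character(stim_out),
    start = start, end = start + dur,
    category = tobii_category(mat[, "Eye movement type"]),
    aoi_ids = as.list(mat[, "AOI hit"])
  )
}

#' Read an AOI visibility file
#'
#' Visibility files describe when each dynamic AOI is visible: CSV with
#' header `aoi,stimulus,start_ms,end_ms`. Overlapping intervals of the same
#' AOI within one scope are merged. A schedule may be global or scoped to
#' one participant; participant-scoped intervals override global ones for
#' that participant, and an AOI with no schedule at all is treated as
#' always visible.
#'
#' @param path Path to a visibility CSV.
#' @param scope `"global"` or a participant id.
#' @return A `visibility_schedule` object.
#' @export
read_visibility <- function(path, scope = "global") {
  if (!file.exists(path)) validation_error("no such file: %s", path)
  lines <- stream_lines(path, 65536L)$lines
  header <- c("aoi", "stimulus", "start_ms", "end_ms")
  if (!length(lines) ||
      !identical(strsplit(lines[1], ",", fixed = TRUE)[[1]], header)) {
    validation_error(
      "unrecognized visibility file: expected header '%s'",
      paste(header, collapse = ","))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  scope_label <- if (identical(scope, "global")) "global" else
    paste0("participant:", scope)
  if (!length(body)) {
    return(visibility_schedule(tibble(
      aoi_id = character(), stimulus_id = character(),
      scope = character(), start = double(), end = double())))
  }
  f <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(f) != 4L)) {
    validation_error("malformed visibility row at line %d of %s",
                     which(lengths(f) != 4L)[1] + 1L, path)
  }
  mat <- matrix(unlist(f), ncol = 4L, byrow = TRUE)
  iv <- tibble(
    aoi_id = mat[, 1], stimulus_id = mat[, 2],
    scope = scope_label,
    start = parse_ms(mat[, 3], "start_ms", TRUE, path),
    end = parse_ms(mat[, 4], "end_ms", TRUE, path)
  )
  if (any(iv$end <= iv$start)) {
    validation_error("visibility interval with end <= start in %s", path)
  }
  visibility_schedule(merge_visibility_intervals(iv))
}

#' Construct a visibility schedule from an interval table
#' @param intervals Tibble with columns `aoi_id`, `stimulus_id`, `scope`
#'   (`"global"` or `"participant:<id>"`), `start`, `end` (ms).
#' @return A `visibility_schedule`.
#' @export
visibility_schedule <- function(intervals) {
  intervals <- as_tibble(intervals)
  if (any(intervals$end <= intervals$start)) {
    validation_error("visibility interval with end <= start")
  }
  structure(list(intervals = merge_visibility_intervals(intervals)),
            class = "visibility_schedule")
}

#' @export
print.visibility_schedule <- function(x, ...) {
  cat(sprintf("<visibility_schedule> %d interval(s), %d AOI(s)\n",
              nrow(x$intervals), length(unique(x$intervals$aoi_id))))
  invisible(x)
}

#' Attach a visibility schedule to a dataset
#' @param x A `gaze_dataset`.
#' @param schedule A `visibility_schedule` (or its interval tibble).
#' @param append If `TRUE` (default) the intervals are added to any
#'   existing schedule; if `FALSE` they replace it.
#' @param strict If `TRUE`, intervals naming unregistered AOIs are errors.
#' @export
attach_visibility <- function(x, schedule, append = TRUE, strict = FALSE) {
  stopifnot(inherits(x, "gaze_dataset"))
  iv <- if (inherits(schedule, "visibility_schedule")) schedule$intervals
        else as_tibble(schedule)
  if (strict && nrow(iv)) {
    known <- paste(x$aois$stimulus_id, x$aois$aoi_id, sep = "\r")
    ref <- paste(iv$stimulus_id, iv$aoi_id, sep = "\r")
    if (any(!ref %in% known)) {
      i <- which(!ref %in% known)[1]
      validation_error("visibility interval for unregistered AOI '%s' on '%s'",
                       iv$aoi_id[i], iv$stimulus_id[i])
    }
  }
  if (append && !is.null(x$visibility)) iv <- bind_rows(x$visibility, iv)
  x$visibility <- merge_visibility_intervals(iv)
  x
}

# effective intervals for (aoi, stimulus, participant):
# participant scope wins over global; NULL means "always visible"
visibility_intervals_for <- function(vis, aoi, stimulus, participant) {
  if (is.null(vis) || !nrow(vis)) return(NULL)
  sub <- vis[vis$aoi_id == aoi & vis$stimulus_id == stimulus, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  p <- sub[sub$scope == paste0("participant:", participant), , drop = FALSE]
  if (nrow(p)) return(p[c("start", "end")])
  g <- sub[sub$scope == "global", , drop = FALSE]
  if (nrow(g)) return(g[c("start", "end")])
  # schedule exists for the AOI but not for this participant: the AOI is
  # treated as always visible for them
  NULL
}

#' Query dynamic-AOI visibility at a time point
#'
#' @param x A `gaze_dataset` or `visibility_schedule`.
#' @param aoi,stimulus,participant Identify the AOI, stimulus, and
#'   participant.
#' @param t Time in ms (same clock as the segment times).
#' @return Logical: is the AOI visible to that participant at `t`? AOIs
#'   without any schedule are always visible.
#' @export
visibility_at <- function(x, aoi, stimulus, participant, t) {
  vis <- if (inherits(x, "gaze_dataset")) x$visibility
         else if (inherits(x, "visibility_schedule")) x$intervals
         else as_tibble(x)
  iv <- visibility_intervals_for(vis, aoi, stimulus, participant)
  if (is.null(iv)) return(rep(TRUE, length(t)))
  vapply(t, function(tt) any(iv$start <= tt & tt < iv$end), logical(1))
}
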