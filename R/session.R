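# ---- canonical JSON -------------------------------------------------------
# Sessions and geometry snapshots are serialized with a canonical writer:
# UTF-8, object keys sorted, LF-free single line, numbers in the shortest
# decimal form that round-trips the double exactly. Canonical form makes
# save -> load -> save byte-identical, so sessions can be diffed and
# content-addressed.

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s
}

canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (inherits(x, "view_filter")) x <- unclass(x)
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm) || all(!nzchar(nm))) {
      return(paste0("[", paste(vapply(x, canonical_json, character(1)),
                               collapse = ","), "]"))
    }
    if (any(!nzchar(nm))) stopf("cannot serialize partially named list")
    ord <- order_c(nm)
    # canonical form drops null-valued members: absent and null are the
    # same reading, and omission keeps save -> load -> save byte-stable
    parts <- vapply(ord, function(i) {
      v <- canonical_json(x[[i]])
      if (identical(v, "null")) return(NA_character_)
      paste0("\"", json_escape(nm[i]), "\":", v)
    }, character(1))
    parts <- parts[!is.na(parts)]
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (length(x) != 1L) {
    return(paste0("[", paste(vapply(seq_along(x),
                                    function(i) canonical_json(x[i]),
                                    character(1)), collapse = ","), "]"))
  }
  if (is.na(x)) return("null")
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(fmt_num_exact(as.numeric(x)))
  paste0("\"", json_escape(as.character(x)), "\"")
}

# data frame -> list of row-objects (aoi_ids list-columns joined with ";")
df_to_records <- function(df) {
  df <- as_tibble(df)
  lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(names(df), function(nm) {
      v <- df[[nm]][[i]]
      if (is.list(df[[nm]])) paste(v, collapse = ";") else v
    })
    setNames(row, names(df))
  })
}

records_to_chr <- function(records, field) {
  vapply(records, function(r) {
    v <- r[[field]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
}

records_to_num <- function(records, field) {
  vapply(records, function(r) {
    v <- r[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, double(1))
}

records_to_lgl <- function(records, field) {
  vapply(records, function(r) {
    v <- r[[field]]
    if (is.null(v)) NA else as.logical(v)
  }, logical(1))
}

# ---- workspace sessions ---------------------------------------------------

session_format_id <- "scarfkit-session"
session_format_version <- 1

#' Create a workspace session
#'
#' A session bundles full canonical datasets, a panel list (what is shown,
#' with which filter, timeline mode and options), and version metadata.
#' Loading a saved session never re-parses source files: the data travel
#' inside the JSON document.
#'
#' @param datasets Named list of `gaze_dataset` objects.
#' @param panels List of panel descriptions, e.g.
#'   `list(list(kind = "scarf", dataset = "main", mode = "absolute",
#'   filter = NULL, options = list(), slot = 1))`.
#' @return A `workspace_session`.
#' @export
workspace_session <- function(datasets, panels = list()) {
  if (inherits(datasets, "gaze_dataset")) datasets <- list(data = datasets)
  if (!length(names(datasets)) || any(!nzchar(names(datasets)))) {
    validation_error("`datasets` must be a fully named list")
  }
  for (d in datasets) stopifnot(inherits(d, "gaze_dataset"))
  structure(list(
    datasets = datasets,
    panels = panels,
    tool_version = as.character(utils::packageVersion("scarfkit")),
    extra = list()
  ), class = "workspace_session")
}

#' @export
print.workspace_session <- function(x, ...) {
  cat(sprintf("<workspace_session> %d dataset(s), %d panel(s), v%s\n",
              length(x$datasets), length(x$panels), x$tool_version))
  invisible(x)
}

dataset_to_json_obj <- function(d) {
  list(
    segments = df_to_records(d$segments),
    aois = df_to_records(d$aois),
    participants = df_to_records(d$participants),
    stimuli = df_to_records(d$stimuli),
    visibility = if (is.null(d$visibility)) NULL
                 else df_to_records(d$visibility),
    meta = d$meta
  )
}

dataset_from_json_obj <- function(obj, where) {
  seg_rec <- obj$segments %||% list()
  seg <- tibble(
    participant_id = records_to_chr(seg_rec, "participant_id"),
    stimulus_id = records_to_chr(seg_rec, "stimulus_id"),
    start = records_to_num(seg_rec, "start"),
    end = records_to_num(seg_rec, "end"),
    category = records_to_chr(seg_rec, "category"),
    aoi_ids = records_to_chr(seg_rec, "aoi_ids")
  )
  aoi_rec <- obj$aois %||% list()
  aois <- if (length(aoi_rec)) tibble(
    stimulus_id = records_to_chr(aoi_rec, "stimulus_id"),
    aoi_id = records_to_chr(aoi_rec, "aoi_id"),
    display_name = records_to_chr(aoi_rec, "display_name"),
    color = records_to_chr(aoi_rec, "color"),
    merged_into = records_to_chr(aoi_rec, "merged_into"),
    auto_created = records_to_lgl(aoi_rec, "auto_created")
  ) else NULL
  par_rec <- obj$participants %||% list()
  participants <- if (length(par_rec)) tibble(
    participant_id = records_to_chr(par_rec, "participant_id"),
    display_name = records_to_chr(par_rec, "display_name"),
    group_label = records_to_chr(par_rec, "group_label")
  ) else NULL
  sti_rec <- obj$stimuli %||% list()
  stimuli <- if (length(sti_rec)) tibble(
    stimulus_id = records_to_chr(sti_rec, "stimulus_id"),
    display_name = records_to_chr(sti_rec, "display_name")
  ) else NULL
  vis <- NULL
  if (!is.null(obj$visibility)) {
    vr <- obj$visibility
    vis <- tibble(
      aoi_id = records_to_chr(vr, "aoi_id"),
      stimulus_id = records_to_chr(vr, "stimulus_id"),
      scope = records_to_chr(vr, "scope"),
      start = records_to_num(vr, "start"),
      end = records_to_num(vr, "end")
    )
  }
  gaze_dataset(seg, aois = aois, participants = participants,
               stimuli = stimuli, visibility = vis, meta = obj$meta)
}

#' Save a workspace session as canonical JSON
#'
#' @param ws A `workspace_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_session <- function(ws, path) {
  stopifnot(inherits(ws, "workspace_session"))
  known <- list(
    format = session_format_id,
    version = session_format_version,
    tool_version = ws$tool_version,
    datasets = lapply(ws$datasets[sort_c(names(ws$datasets))],
                      dataset_to_json_obj),
    panels = ws$panels
  )
  obj <- modifyList(ws$extra, known)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(canonical_json(obj), con, sep = "\n")
  invisible(path)
}

#' Load a workspace session
#'
#' Validates the document structure (reporting a JSON-pointer path on
#' failure), rebuilds the canonical datasets, warns on a format-version
#' mismatch and continues best-effort, and preserves unknown top-level
#' fields so they survive a re-save.
#'
#' @param path Path to a session JSON file.
#' @return A `workspace_session`.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) validation_error("no such file: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
    validation_error("not a valid JSON document: %s", conditionMessage(e))
  })
  if (!is.list(obj)) validation_error("schema error at '': expected object")
  for (field in c("format", "version", "datasets")) {
    if (is.null(obj[[field]])) {
      validation_error("schema error at '/%s': required field missing",
                       field)
    }
  }
  if (!identical(obj$format, session_format_id)) {
    validation_error("schema error at '/format': expected \"%s\"",
                     session_format_id)
  }
  if (!identical(as.numeric(obj$version), session_format_version)) {
    warn(sprintf(
      "session version %s differs from supported %s; loading best-effort",
      obj$version, session_format_version))
  }
  ds_names <- names(obj$datasets)
  datasets <- lapply(seq_along(obj$datasets), function(i) {
    dataset_from_json_obj(obj$datasets[[i]],
                          sprintf("/datasets/%s", ds_names[i]))
  })
  names(datasets) <- ds_names
  ws <- workspace_session(datasets, panels = obj$panels %||% list())
  if (!is.null(obj$tool_version)) ws$tool_version <- obj$tool_version
  ws$extra <- obj[setdiff(names(obj),
                          c("format", "version", "tool_version",
                            "datasets", "panels"))]
  ws
}
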