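#' Supported input dialects
#'
#' scarfkit reads four delimited-text layouts, recognised purely by the
#' structure of the header line (token sequence plus delimiter), never by
#' filename:
#'
#' * `generic_long` — comma-separated, one row per gaze event:
#'   `participant,stimulus,timestamp_ms,duration_ms,category,aoi`. An empty
#'   `aoi` cell means no AOI hit; a multi-AOI event is written as repeated
#'   rows sharing the same timestamps, merged back into one segment's AOI
#'   set on parse.
#' * `generic_interval` — semicolon-separated, one row per AOI visit with
#'   explicit bounds: `participant;stimulus;aoi;interval_start;
#'   interval_end;event`. Represents fixation-level visits only, so
#'   saccades are not representable (writers warn or fail).
#' * `begaze_like` — tab-separated event-per-row layout in the style of
#'   desktop analysis suites, with trial-time columns and one row per
#'   (event, AOI hit); AOI visibility ships in separate files.
#' * `tobii_like` — tab-separated layout in the style of mobile
#'   eye-tracking exports: timestamps rounded to integer milliseconds, and
#'   a recording split into numbered intervals when a stimulus reappears,
#'   so one logical trial may arrive as several interval blocks. On parse,
#'   interval k of stimulus S becomes stimulus id `S#k` (when the file
#'   holds more than one interval for S); [reconstruct_aoi_metrics()]
#'   unifies metrics across the interval trials.
#'
#' @format A named list of dialect descriptors (id, delimiter, header).
#' @name dialects
NULL

scarfkit_dialects <- list(
  generic_long = list(
    dialect_id = "generic_long", delimiter = ",",
    header = c("participant", "stimulus", "timestamp_ms", "duration_ms",
               "category", "aoi")),
  generic_interval = list(
    dialect_id = "generic_interval", delimiter = ";",
    header = c("participant", "stimulus", "aoi", "interval_start",
               "interval_end", "event")),
  begaze_like = list(
    dialect_id = "begaze_like", delimiter = "\t",
    header = c("Participant", "Stimulus", "Event Start Trial Time [ms]",
               "Event End Trial Time [ms]", "Category", "AOI Name")),
  tobii_like = list(
    dialect_id = "tobii_like", delimiter = "\t",
    header = c("Recording", "Presented Stimulus", "Interval",
               "Eye movement type", "Start", "Duration", "AOI hit"))
)

#' List the supported dialect ids
#' @return Character vector of dialect ids.
#' @export
list_dialects <- function() names(scarfkit_dialects)

dialect_descriptor <- function(id) {
  d <- scarfkit_dialects[[id]]
  if (is.null(d)) {
    validation_error("unknown dialect '%s'; known: %s", id,
                     paste(names(scarfkit_dialects), collapse = ", "))
  }
  d
}

#' Detect the input dialect from the header line
#'
#' Detection is structural: the first line of the chunk is split with each
#' candidate delimiter and compared token-by-token against each dialect's
#' header signature. Signatures are pairwise distinct, so at most one
#' dialect can match; the filename plays no role.
#'
#' @param first_chunk Character scalar holding at least the complete first
#'   line of the file.
#' @return The matching dialect descriptor (a list with `dialect_id`,
#'   `delimiter`, `header`).
#' @export
detect_dialect <- function(first_chunk) {
  if (!is_string(first_chunk)) {
    validation_error("`first_chunk` must be a single string")
  }
  header_line <- sub("\r?\n.*$", "", first_chunk)
  header_line <- sub("\r$", "", header_line)
  matches <- keep(scarfkit_dialects, function(d) {
    toks <- strsplit(header_line, d$delimiter, fixed = TRUE)[[1]]
    identical(toks, d$header)
  })
  if (length(matches) == 1L) return(matches[[1]])
  if (length(matches) > 1L) {
    stopf("internal error: header matches multiple dialects (%s)",
          paste(names(matches), collapse = ", "))
  }
  validation_error(
    "unrecognized format: header '%s' matches none of the known dialects (%s)",
    header_line, paste(names(scarfkit_dialects), collapse = ", "))
}

# convention for tobii_like interval trials: "<stimulus>#<k>"
interval_stimulus_id <- function(stimulus, interval) {
  paste0(stimulus, "#", interval)
}

#' Strip the interval suffix from tobii_like stimulus ids
#' @param stimulus_id Character vector of stimulus ids, possibly of the
#'   form `S#k`.
#' @return The base stimulus ids.
#' @export
base_stimulus <- function(stimulus_id) {
  sub("#[0-9]+$", "", stimulus_id)
}

#' Extract the interval index from tobii_like stimulus ids
#' @param stimulus_id Character vector of stimulus ids.
#' @return Integer interval indices (1 when the id carries no suffix).
#' @export
stimulus_interval <- function(stimulus_id) {
  m <- regmatches(stimulus_id, regexpr("#[0-9]+$", stimulus_id))
  out <- rep(1L, length(stimulus_id))
  has <- grepl("#[0-9]+$", stimulus_id)
  out[has] <- as.integer(sub("^#", "", m))
  out
}

tobii_event_types <- c(fixation = "Fixation", saccade = "Saccade",
                       other = "Unclassified")

tobii_category <- function(event_type) {
  idx <- match(event_type, tobii_event_types)
  out <- names(tobii_event_types)[idx]
  out[is.na(idx)] <- "other"
  out
}
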