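#' Export AOI metrics as CSV
#'
#' Fixed column order `participant,stimulus,aoi,ttff_ms,fixation_count,
#' avg_fixation_ms,dwell_ms`, milliseconds with three decimal places,
#' absent values (AOI never fixated) as empty cells — empty rather than 0,
#' because 0 is a legal time to first fixation.
#'
#' @param records An `aoi_metrics` tibble (see [aoi_metrics()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_metrics_csv <- function(records, path) {
  records <- as_tibble(records)
  lines <- paste(
    records$participant_id, records$stimulus_id, records$aoi_id,
    fmt_ms(records$ttff_ms), records$fixation_count,
    fmt_ms(records$avg_fixation_ms), fmt_ms(records$dwell_ms), sep = ",")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("participant,stimulus,aoi,ttff_ms,fixation_count,avg_fixation_ms,dwell_ms",
               lines), con, sep = "\n")
  invisible(path)
}

#' Export raw event data as CSV
#'
#' Writes the resolved view in the `generic_long` layout, which re-imports
#' through [read_gaze()] loss-free (to the documented 3-decimal
#' millisecond precision).
#'
#' @param x A `gaze_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_events_csv <- function(x, path) {
  write_dialect(x, "generic_long", path)
}

scangraph_alphabet <- c(letters, LETTERS, as.character(0:9))

#' Export ScanGraph-compatible fixation sequences
#'
#' Writes one character-coded AOI sequence per participant for graph-based
#' scanpath comparison: header lines `#<char>=<AOI display name>` mapping
#' each AOI to a single character, then `<participant>\t<sequence>` lines
#' with the participant's fixated AOIs in time order. Fixations without an
#' AOI hit are skipped; a fixation hitting several AOIs is transcribed as
#' the AOI with the lowest registry index, with a warning. The dialect is
#' plain text and versioned via a `#scarfkit-scangraph v1` first line;
#' consecutive duplicate collapsing is off by default.
#'
#' @param x A `gaze_dataset`.
#' @param path Output path.
#' @param stimulus Stimulus to export; may be omitted when the view holds
#'   exactly one.
#' @param collapse_repeats Collapse consecutive identical characters.
#' @return `path`, invisibly.
#' @export
export_scangraph <- function(x, path, stimulus = NULL,
                             collapse_repeats = FALSE) {
  stopifnot(inherits(x, "gaze_dataset"))
  v <- resolve_view(x)
  stim <- pick_stimulus(v, stimulus)
  aois <- v$aois[v$aois$stimulus_id == stim, , drop = FALSE]
  if (nrow(aois) > length(scangraph_alphabet)) {
    validation_error(
      "%d AOIs exceed the %d-character alphabet; merge AOIs first",
      nrow(aois), length(scangraph_alphabet))
  }
  char_map <- setNames(scangraph_alphabet[seq_len(nrow(aois))], aois$aoi_id)
  seg <- v$segments[v$segments$stimulus_id == stim &
                      v$segments$category == "fixation", , drop = FALSE]
  participants <- v$participants$participant_id[
    v$participants$participant_id %in% unique(
      v$segments$participant_id[v$segments$stimulus_id == stim])]

  n_overlap <- 0L
  seq_lines <- vapply(participants, function(p) {
    ps <- seg[seg$participant_id == p, , drop = FALSE]
    ps <- ps[order(ps$start), , drop = FALSE]
    chars <- character()
    for (ids in ps$aoi_ids) {
      if (!length(ids)) next
      if (length(ids) > 1L) {
        n_overlap <<- n_overlap + 1L
        ids <- ids[which.min(match(ids, aois$aoi_id))]
      }
      chars <- c(chars, unname(char_map[ids]))
    }
    if (collapse_repeats && length(chars)) {
      chars <- chars[c(TRUE, chars[-1] != chars[-length(chars)])]
    }
    paste0(p, "\t", paste(chars, collapse = ""))
  }, character(1))
  if (n_overlap > 0L) {
    warn(sprintf(
      "ScanGraph export: %d overlap fixation(s) resolved to the %s",
      n_overlap, "lowest-registry-index AOI"))
  }
  header <- c("#scarfkit-scangraph v1",
              sprintf("#%s=%s", unname(char_map), aois$display_name))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, seq_lines), con, sep = "\n")
  invisible(path)
}
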