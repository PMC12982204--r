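#' AOI-level fixation metrics
#'
#' Computes, per (participant, stimulus, AOI), the four standard AOI
#' metrics from fixation-category segments:
#'
#' * time to first fixation (TTFF): start of the first fixation hitting
#'   the AOI minus the trial onset (minimum segment start of the trial);
#' * fixation count: number of fixations hitting the AOI;
#' * average fixation duration: dwell time divided by fixation count;
#' * dwell time: summed duration of fixations hitting the AOI.
#'
#' A fixation hitting k AOIs contributes its full duration to each of the
#' k dwell sums (set semantics, no fractional split). Saccades and "other"
#' events never enter these metrics. An AOI never fixated has count 0,
#' dwell 0, and absent (`NA`) TTFF and average — `NA`, not 0, because 0 is
#' a legal TTFF.
#'
#' @param x A `gaze_dataset`; pending filters and AOI merges are resolved
#'   first.
#' @param include_zero If `TRUE`, emit a record for every registered
#'   (participant-trial, AOI) pair even when the AOI was never fixated.
#' @return A tibble of class `aoi_metrics` with columns `participant_id`,
#'   `stimulus_id`, `aoi_id`, `ttff_ms`, `fixation_count`,
#'   `avg_fixation_ms`, `dwell_ms`.
#' @examples
#' d <- gaze_dataset(tibble::tibble(
#'   participant_id = "P1", stimulus_id = "S",
#'   start = c(0, 100, 120, 300), end = c(100, 120, 300, 350),
#'   category = c("fixation", "saccade", "fixation", "fixation"),
#'   aoi_ids = c("A", "", "B", "A")
#' ))
#' aoi_metrics(d)
#' @export
aoi_metrics <- function(x, include_zero = FALSE) {
  stopifnot(inherits(x, "gaze_dataset"))
  v <- resolve_view(x)
  seg <- v$segments
  tb <- trial_bounds(v)
  fix <- seg[seg$category == "fixation", , drop = FALSE]

  if (nrow(fix)) {
    k <- lengths(fix$aoi_ids)
    idx <- rep(seq_len(nrow(fix)), k)
    hits <- tibble(
      participant_id = fix$participant_id[idx],
      stimulus_id = fix$stimulus_id[idx],
      aoi_id = unlist(fix$aoi_ids, use.names = FALSE) %||% character(),
      start = fix$start[idx],
      dur = (fix$end - fix$start)[idx]
    )
    res <- hits |>
      group_by(participant_id, stimulus_id, aoi_id) |>
      summarise(first_start = min(start), fixation_count = n(),
                dwell_ms = sum(dur), .groups = "drop") |>
      left_join(tb, by = c("participant_id", "stimulus_id")) |>
      mutate(ttff_ms = first_start - onset,
             avg_fixation_ms = dwell_ms / fixation_count) |>
      select(participant_id, stimulus_id, aoi_id, ttff_ms, fixation_count,
             avg_fixation_ms, dwell_ms)
  } else {
    res <- tibble(participant_id = character(), stimulus_id = character(),
                  aoi_id = character(), ttff_ms = double(),
                  fixation_count = integer(), avg_fixation_ms = double(),
                  dwell_ms = double())
  }

  if (include_zero && nrow(tb)) {
    full <- inner_join(tb[c("participant_id", "stimulus_id")],
                       v$aois[c("stimulus_id", "aoi_id")],
                       by = "stimulus_id", relationship = "many-to-many")
    zero <- anti_join(full, res,
                      by = c("participant_id", "stimulus_id", "aoi_id"))
    if (nrow(zero)) {
      zero$ttff_ms <- NA_real_
      zero$fixation_count <- 0L
      zero$avg_fixation_ms <- NA_real_
      zero$dwell_ms <- 0
      res <- bind_rows(res, zero)
    }
  }
  res <- res[order_c(res$participant_id, res$stimulus_id, res$aoi_id), ]
  class(res) <- c("aoi_metrics", class(tibble()))
  res
}

#' Brute-force rasterization oracle for AOI metrics
#'
#' Independent re-computation of [aoi_metrics()] by a completely different
#' route: each trial's timeline is rasterized into cells of `resolution`
#' milliseconds; a cell belongs to a fixation if the cell's left edge lies
#' inside the fixation's half-open interval. Dwell is the cell count times
#' the resolution, TTFF the earliest owned cell, the fixation count the
#' number of distinct fixations owning at least one cell. With integer
#' boundaries and 1 ms resolution the oracle is exact; otherwise it
#' converges to [aoi_metrics()] as the resolution shrinks.
#'
#' Intended for verification on modest views (the rasterization
#' materializes every cell).
#'
#' @param x A `gaze_dataset`.
#' @param resolution Cell size in ms (> 0).
#' @param include_zero As in [aoi_metrics()].
#' @return A tibble with the same columns as [aoi_metrics()].
#' @export
aoi_metrics_oracle <- function(x, resolution = 1, include_zero = FALSE) {
  stopifnot(inherits(x, "gaze_dataset"))
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution <= 0) {
    validation_error("`resolution` must be a single positive number")
  }
  v <- resolve_view(x)
  seg <- v$segments
  fix <- seg[seg$category == "fixation", , drop = FALSE]
  tb <- trial_bounds(v)
  if (!nrow(fix)) {
    out <- aoi_metrics(v, include_zero = include_zero)
    return(out)
  }
  tb$trial <- seq_len(nrow(tb))
  fix <- left_join(fix, tb[c("participant_id", "stimulus_id", "onset",
                             "trial")],
                   by = c("participant_id", "stimulus_id"))

  k <- lengths(fix$aoi_ids)
  idx <- rep(seq_len(nrow(fix)), k)
  aoi <- unlist(fix$aoi_ids, use.names = FALSE) %||% character()
  # cell k of a trial spans [onset + k*res, onset + (k+1)*res)
  kmin <- as.integer(ceiling((fix$start - fix$onset) / resolution - 1e-9))
  kmax <- as.integer(ceiling((fix$end - fix$onset) / resolution - 1e-9)) - 1L
  kmin_h <- kmin[idx]; kmax_h <- kmax[idx]
  n_cells <- pmax(kmax_h - kmin_h + 1L, 0L)
  cells <- sequence(n_cells, from = kmin_h, by = 1L)
  cell_owner <- rep(seq_along(idx), n_cells)

  lab <- paste(fix$trial[idx], aoi, sep = "\r")
  cell_lab <- lab[cell_owner]
  # dwell: cells per (trial, aoi); ttff: earliest cell; count: distinct
  # fixations owning >= 1 cell
  groups <- sort_c(unique(cell_lab))
  gi <- match(cell_lab, groups)
  dwell <- as.numeric(tabulate(gi, length(groups))) * resolution
  ttff_cell <- rep(Inf, length(groups))
  mn <- tapply(cells, gi, min)
  ttff_cell[as.integer(names(mn))] <- as.numeric(mn)
  has_cell <- n_cells > 0
  cnt_tab <- table(factor(lab[has_cell], levels = groups))
  cnt <- as.integer(cnt_tab)

  parts <- strsplit(groups, "\r", fixed = TRUE)
  trial_i <- as.integer(vapply(parts, `[[`, "", 1))
  res <- tibble(
    participant_id = tb$participant_id[trial_i],
    stimulus_id = tb$stimulus_id[trial_i],
    aoi_id = vapply(parts, `[[`, "", 2),
    ttff_ms = ttff_cell * resolution,
    fixation_count = cnt,
    dwell_ms = dwell
  )
  res$avg_fixation_ms <- res$dwell_ms / res$fixation_count
  res <- res[c("participant_id", "stimulus_id", "aoi_id", "ttff_ms",
               "fixation_count", "avg_fixation_ms", "dwell_ms")]

  if (include_zero) {
    full <- inner_join(tb[c("participant_id", "stimulus_id")],
                       v$aois[c("stimulus_id", "aoi_id")],
                       by = "stimulus_id", relationship = "many-to-many")
    zero <- anti_join(full, res,
                      by = c("participant_id", "stimulus_id", "aoi_id"))
    if (nrow(zero)) {
      zero$ttff_ms <- NA_real_
      zero$fixation_count <- 0L
      zero$avg_fixation_ms <- NA_real_
      zero$dwell_ms <- 0
      res <- bind_rows(res, zero)
    }
  }
  res <- res[order_c(res$participant_id, res$stimulus_id, res$aoi_id), ]
  class(res) <- c("aoi_metrics", class(tibble()))
  res
}

#' Per-trial interval offsets for split recordings
#'
#' For datasets parsed from interval-split exports (tobii_like), each
#' interval of a stimulus is a separate trial `S#k`. This helper returns,
#' per interval trial, the offset of its onset from the onset of the
#' earliest interval of the same base stimulus — the quantity
#' [reconstruct_aoi_metrics()] needs to re-reference TTFF values.
#'
#' @param x A `gaze_dataset`.
#' @return Tibble `participant_id`, `stimulus_id`, `base_stimulus`,
#'   `interval_offset_ms`.
#' @export
interval_offsets <- function(x) {
  v <- resolve_view(x)
  tb <- trial_bounds(v)
  tb$base_stimulus <- base_stimulus(tb$stimulus_id)
  tb |>
    group_by(participant_id, base_stimulus) |>
    mutate(interval_offset_ms = onset - min(onset)) |>
    ungroup() |>
    select(participant_id, stimulus_id, base_stimulus, interval_offset_ms)
}

#' Reconstruct unified AOI metrics across recording intervals
#'
#' Mobile eye-tracking exports split one logical trial into several
#' recording intervals when the stimulus reappears. Given per-interval
#' metric records plus each interval's onset offset, this reconstructs the
#' unified per-(participant, stimulus, AOI) values: counts and dwell sum;
#' the average fixation duration is the count-weighted mean; TTFF is the
#' minimum of (interval offset + interval TTFF) over intervals in which
#' the AOI was fixated.
#'
#' With full-precision inputs the reconstruction equals direct computation
#' on the unsplit data exactly; with integer-millisecond-rounded inputs
#' the temporal metrics agree within 1 ms and the counts exactly.
#'
#' @param records An `aoi_metrics` tibble whose `stimulus_id` carries the
#'   interval convention `S#k` (plain ids count as single intervals).
#' @param offsets Optional tibble from [interval_offsets()]; if omitted,
#'   every interval offset is taken as 0 — fine when the interval trials
#'   share the recording clock is not needed, wrong otherwise.
#' @return An `aoi_metrics` tibble keyed by (participant, base stimulus,
#'   AOI).
#' @export
reconstruct_aoi_metrics <- function(records, offsets = NULL) {
  records <- as_tibble(records)
  if (!nrow(records)) {
    validation_error("`records` must contain at least one metric record")
  }
  needed <- c("participant_id", "stimulus_id", "aoi_id", "ttff_ms",
              "fixation_count", "avg_fixation_ms", "dwell_ms")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    validation_error("`records` is missing column(s): %s",
                     paste(miss, collapse = ", "))
  }
  if (is.null(offsets)) {
    records$interval_offset_ms <- 0
  } else {
    records <- left_join(
      records,
      offsets[c("participant_id", "stimulus_id", "interval_offset_ms")],
      by = c("participant_id", "stimulus_id"))
    if (anyNA(records$interval_offset_ms)) {
      validation_error("`offsets` does not cover every (participant, %s)",
                       "stimulus) pair in `records`")
    }
  }
  records$stimulus_id <- base_stimulus(records$stimulus_id)
  out <- records |>
    group_by(participant_id, stimulus_id, aoi_id) |>
    summarise(
      ttff_ms = if (sum(fixation_count) == 0L) NA_real_ else
        min(interval_offset_ms[fixation_count > 0] +
              ttff_ms[fixation_count > 0]),
      dwell_ms = sum(dwell_ms),
      fixation_count = sum(fixation_count),
      .groups = "drop") |>
    mutate(avg_fixation_ms = ifelse(fixation_count > 0,
                                    dwell_ms / fixation_count, NA_real_)) |>
    select(participant_id, stimulus_id, aoi_id, ttff_ms, fixation_count,
           avg_fixation_ms, dwell_ms)
  out <- out[order_c(out$participant_id, out$stimulus_id, out$aoi_id), ]
  class(out) <- c("aoi_metrics", class(tibble()))
  out
}

#' Aggregate AOI metrics for bar summaries
#'
#' Collapses per-participant AOI metrics into per-(group, AOI) bar-plot
#' data for the three headline metrics (dwell time, fixation count, time
#' to first fixation).
#'
#' @param x A `gaze_dataset`.
#' @param stat `"mean"` (default) or `"sum"` across participants; TTFF is
#'   always averaged over participants who fixated the AOI.
#' @return A tibble of class `aoi_summary`: `group_label`, `stimulus_id`,
#'   `aoi_id`, `metric`, `value`, `n_participants`.
#' @export
aoi_summary <- function(x, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  v <- resolve_view(x)
  m <- aoi_metrics(v, include_zero = TRUE)
  m <- left_join(m, v$participants[c("participant_id", "group_label")],
                 by = "participant_id")
  m$group_label[is.na(m$group_label)] <- "(all)"
  agg <- function(vals, how) {
    if (how == "sum") sum(vals, na.rm = TRUE) else {
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
  }
  out <- m |>
    group_by(group_label, stimulus_id, aoi_id) |>
    summarise(
      dwell_time_ms = agg(dwell_ms, stat),
      fixation_count = agg(as.numeric(fixation_count), stat),
      time_to_first_fixation_ms = agg(ttff_ms, "mean"),
      n_participants = dplyr::n_distinct(participant_id),
      .groups = "drop")
  out <- tidyr::pivot_longer(
    out, c("dwell_time_ms", "fixation_count", "time_to_first_fixation_ms"),
    names_to = "metric", values_to = "value")
  out <- out[c("group_label", "stimulus_id", "aoi_id", "metric", "value",
               "n_participants")]
  out <- out[order_c(out$group_label, out$stimulus_id, out$aoi_id,
                     out$metric), ]
  class(out) <- c("aoi_summary", class(tibble()))
  out
}
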