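#' Specification for a synthetic gaze recording
#'
#' Describes the study conditions the generator emulates: alternating
#' fixation/saccade event trains per trial, AOI hits with configurable
#' overlap and miss probabilities, occasional untracked gaps, random
#' per-trial recording offsets (so trial onsets differ from zero, as in
#' real exports), and per-participant dynamic-AOI visibility windows.
#'
#' Defaults emulate a moderate screen-based study: 10 participants, 5
#' stimuli, 4 AOIs per stimulus, 3-second trials, fixations of 80-350 ms
#' and saccades of 20-80 ms, 10% multi-AOI (overlap) fixations, 10%
#' fixations off every AOI, and visibility windows for half the AOIs. All
#' times are drawn on a 1 ms grid by default (`time_grid_ms = NULL` draws
#' continuous times to exercise sub-millisecond arithmetic).
#'
#' @param n_participants,n_stimuli,n_aois Counts.
#' @param trial_duration_ms Length of each trial in ms.
#' @param fixation_ms,saccade_ms Duration ranges `c(min, max)` in ms.
#' @param p_overlap Probability a fixation hits a second AOI.
#' @param p_no_aoi Probability a fixation hits no AOI.
#' @param p_other Probability an inter-fixation event is "other" instead
#'   of a saccade.
#' @param p_gap Probability of an untracked gap after an event.
#' @param visibility_density Probability a (participant, stimulus, AOI)
#'   triple gets a visibility window.
#' @param time_grid_ms Rounding grid for all times (`NULL` = continuous).
#' @param seed Integer seed; fully determines the output.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_participants = 10, n_stimuli = 5, n_aois = 4,
                         trial_duration_ms = 3000,
                         fixation_ms = c(80, 350), saccade_ms = c(20, 80),
                         p_overlap = 0.1, p_no_aoi = 0.1, p_other = 0.05,
                         p_gap = 0.1, visibility_density = 0.5,
                         time_grid_ms = 1, seed = 1) {
  probs <- c(p_overlap, p_no_aoi, p_other, p_gap, visibility_density)
  if (any(probs < 0 | probs > 1)) {
    validation_error("probabilities must be in [0, 1]")
  }
  for (r in list(fixation_ms, saccade_ms)) {
    if (length(r) != 2L || r[1] <= 0 || r[2] < r[1]) {
      validation_error("duration ranges must be c(min, max) with 0 < min <= max")
    }
  }
  if (fixation_ms[1] > trial_duration_ms) {
    validation_error(
      "impossible spec: minimum fixation (%g ms) exceeds trial duration",
      fixation_ms[1])
  }
  structure(list(
    n_participants = n_participants, n_stimuli = n_stimuli,
    n_aois = n_aois, trial_duration_ms = trial_duration_ms,
    fixation_ms = fixation_ms, saccade_ms = saccade_ms,
    p_overlap = p_overlap, p_no_aoi = p_no_aoi, p_other = p_other,
    p_gap = p_gap, visibility_density = visibility_density,
    time_grid_ms = time_grid_ms, seed = as.integer(seed)
  ), class = "fixture_spec")
}

with_fixture_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

snap <- function(x, grid) {
  if (is.null(grid)) x else round(x / grid) * grid
}

#' Generate a synthetic gaze recording with ground-truth metrics
#'
#' Produces a canonical dataset and, alongside it, ground-truth AOI
#' metrics accumulated incrementally *during* generation — an independent
#' bookkeeping path, not a call into [aoi_metrics()] — so metric tests
#' against the ground truth are non-circular.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `dataset` (a `gaze_dataset`), `truth` (a tibble of
#'   per-(participant, stimulus, AOI) metrics including zero-count rows),
#'   and `spec`.
#' @export
generate_gaze_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    participants <- sprintf("P%02d", seq_len(spec$n_participants))
    stimuli <- sprintf("S%d", seq_len(spec$n_stimuli))
    aoi_ids <- sprintf("AOI_%s", LETTERS[seq_len(spec$n_aois)])
    grid <- spec$time_grid_ms

    trial_tables <- list()

    truth_env <- new.env(parent = emptyenv())
    truth_key <- function(p, s, a) paste(p, s, a, sep = "\r")
    add_truth <- function(p, s, a, start_rel, dur) {
      k <- truth_key(p, s, a)
      cur <- truth_env[[k]] %||% list(count = 0L, dwell = 0, first = Inf)
      truth_env[[k]] <- list(count = cur$count + 1L,
                             dwell = cur$dwell + dur,
                             first = min(cur$first, start_rel))
    }

    vis_rows <- list()
    for (p in participants) {
      for (s in stimuli) {
        t0 <- snap(runif(1, 0, 10000), grid)
        t_end <- t0 + spec$trial_duration_ms
        t <- t0
        cap <- 4L * ceiling(spec$trial_duration_ms /
                              (spec$fixation_ms[1] + spec$saccade_ms[1])) + 8L
        e_start <- numeric(cap); e_end <- numeric(cap)
        e_cat <- character(cap); e_ids <- vector("list", cap)
        ne <- 0L
        repeat {
          dur <- snap(runif(1, spec$fixation_ms[1], spec$fixation_ms[2]),
                      grid)
          if (t + dur > t_end) {
            dur <- t_end - t
            if (dur < max(spec$fixation_ms[1] / 4,
                          if (is.null(grid)) 1e-6 else grid)) break
          }
          ids <- character()
          if (runif(1) >= spec$p_no_aoi) {
            ids <- sample(aoi_ids, 1)
            if (spec$n_aois > 1 && runif(1) < spec$p_overlap) {
              ids <- c(ids, sample(setdiff(aoi_ids, ids), 1))
            }
          }
          ne <- ne + 1L
          e_start[ne] <- t; e_end[ne] <- t + dur
          e_cat[ne] <- "fixation"; e_ids[[ne]] <- sort_c(ids)
          for (a in ids) add_truth(p, s, a, t - t0, dur)
          t <- t + dur
          if (t >= t_end) break
          gdur <- snap(runif(1, spec$saccade_ms[1], spec$saccade_ms[2]),
                       grid)
          if (t + gdur > t_end) break
          ne <- ne + 1L
          e_start[ne] <- t; e_end[ne] <- t + gdur
          e_cat[ne] <- if (runif(1) < spec$p_other) "other" else "saccade"
          e_ids[[ne]] <- character()
          t <- t + gdur
          if (runif(1) < spec$p_gap) {
            skip <- snap(runif(1, 0, 100), grid)
            if (t + skip + spec$fixation_ms[1] > t_end) break
            t <- t + skip
          }
        }
        if (ne > 0L) {
          trial_tables[[length(trial_tables) + 1L]] <- fast_tbl(
            participant_id = p, stimulus_id = s,
            start = e_start[seq_len(ne)], end = e_end[seq_len(ne)],
            category = e_cat[seq_len(ne)], aoi_ids = e_ids[seq_len(ne)])
        }
        # per-participant visibility windows on the trial's own clock
        for (a in aoi_ids) {
          if (runif(1) < spec$visibility_density) {
            u <- sort(runif(2, 0, spec$trial_duration_ms))
            if (diff(u) < 1) next
            vis_rows[[length(vis_rows) + 1L]] <- tibble(
              aoi_id = a, stimulus_id = s,
              scope = paste0("participant:", p),
              start = snap(t0 + u[1], grid), end = snap(t0 + u[2], grid))
          }
        }
      }
    }

    seg <- bind_rows(trial_tables)
    vis <- if (length(vis_rows)) bind_rows(vis_rows) else NULL
    vis <- if (!is.null(vis)) vis[vis$end > vis$start, , drop = FALSE]
    aoi_registry <- tidyr::expand_grid(stimulus_id = stimuli,
                                       aoi_id = aoi_ids)
    groups <- rep(c("expert", "novice"), length.out = spec$n_participants)
    dataset <- gaze_dataset(
      seg, aois = aoi_registry,
      participants = tibble(participant_id = participants,
                            display_name = participants,
                            group_label = groups),
      stimuli = stimuli, visibility = vis)

    truth <- tidyr::expand_grid(participant_id = participants,
                                stimulus_id = stimuli, aoi_id = aoi_ids)
    vals <- lapply(seq_len(nrow(truth)), function(i) {
      truth_env[[truth_key(truth$participant_id[i], truth$stimulus_id[i],
                           truth$aoi_id[i])]] %||%
        list(count = 0L, dwell = 0, first = Inf)
    })
    truth$ttff_ms <- map_dbl(vals, function(v)
      if (is.finite(v$first)) v$first else NA_real_)
    truth$fixation_count <- map_int(vals, "count")
    truth$avg_fixation_ms <- ifelse(truth$fixation_count > 0,
                                    map_dbl(vals, "dwell") /
                                      truth$fixation_count, NA_real_)
    truth$dwell_ms <- map_dbl(vals, "dwell")
    truth <- truth[order_c(truth$participant_id, truth$stimulus_id,
                           truth$aoi_id), ]
    list(dataset = dataset, truth = truth, spec = spec)
  })
}

#' Draw random trial cut points at event boundaries
#'
#' Picks, per trial, `n_per_trial` interior event boundaries to act as
#' recording-interval cuts for the `tobii_like` writer. Boundaries (not
#' arbitrary times) are used because a real interval boundary terminates
#' the ongoing event.
#'
#' @param x A `gaze_dataset`.
#' @param n_per_trial Cuts per trial (trials with too few events get
#'   fewer).
#' @param seed Integer seed.
#' @return Tibble `participant_id`, `stimulus_id`, `cut_ms`.
#' @export
random_cut_points <- function(x, n_per_trial = 1, seed = 1) {
  v <- resolve_view(x)
  seg <- v$segments
  with_fixture_rng(seed, {
    out <- list()
    tb <- trial_bounds(v)
    for (i in seq_len(nrow(tb))) {
      ps <- seg[seg$participant_id == tb$participant_id[i] &
                  seg$stimulus_id == tb$stimulus_id[i], , drop = FALSE]
      bounds <- sort(unique(ps$start))
      bounds <- bounds[bounds > tb$onset[i]]
      if (!length(bounds)) next
      k <- min(n_per_trial, length(bounds))
      cuts <- sort(sample(bounds, k))
      out[[length(out) + 1L]] <- tibble(
        participant_id = tb$participant_id[i],
        stimulus_id = tb$stimulus_id[i], cut_ms = cuts)
    }
    if (length(out)) bind_rows(out) else
      tibble(participant_id = character(), stimulus_id = character(),
             cut_ms = double())
  })
}

#' Write a complete fixture corpus
#'
#' Emits one file per supported dialect plus per-participant visibility
#' files into a directory, so every reader and the round-trip property can
#' be exercised from disk.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture_corpus <- function(spec = fixture_spec(), dir) {
  fx <- generate_gaze_fixture(spec)
  d <- fx$dataset
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  for (dialect in list_dialects()) {
    ext <- if (dialect %in% c("begaze_like", "tobii_like")) "tsv" else "csv"
    path <- file.path(dir, sprintf("fixture_%s.%s", dialect, ext))
    suppressWarnings(write_dialect(d, dialect, path))
    files <- c(files, path)
  }
  if (!is.null(d$visibility)) {
    scopes <- unique(d$visibility$scope)
    for (sc in scopes) {
      pid <- sub("^participant:", "", sc)
      label <- if (sc == "global") "global" else pid
      path <- file.path(dir, sprintf("visibility_%s.csv", label))
      write_visibility(d$visibility, path,
                       scope = if (sc == "global") "global" else pid)
      files <- c(files, path)
    }
  }
  truth_path <- file.path(dir, "ground_truth_metrics.csv")
  truth <- fx$truth
  class(truth) <- class(tibble())
  export_metrics_csv(truth, truth_path)
  files <- c(files, truth_path)
  invisible(files)
}
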