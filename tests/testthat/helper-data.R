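# shared fixtures and comparison helpers

# the worked micro-example used throughout the docs: one trial with two
# fixations on A, one on B, and a saccade between
worked_example <- function() {
  gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 100, 120, 300), end = c(100, 120, 300, 350),
    category = c("fixation", "saccade", "fixation", "fixation"),
    aoi_ids = c("A", "", "B", "A")
  ))
}

small_fixture <- function(seed = 1, ...) {
  generate_gaze_fixture(fixture_spec(n_participants = 4, n_stimuli = 2,
                                     seed = seed, ...))
}

# flat, comparable representation of everything queryable in a dataset
dataset_signature <- function(d, digits = NULL) {
  v <- resolve_view(d)
  seg <- tidy(v, resolved = FALSE)
  if (!is.null(digits)) {
    seg$start <- round(seg$start, digits)
    seg$end <- round(seg$end, digits)
    seg$duration <- round(seg$duration, digits)
  }
  list(
    segments = as.data.frame(seg),
    participants = as.data.frame(v$participants),
    stimuli = as.data.frame(v$stimuli),
    aois = as.data.frame(v$aois[c("stimulus_id", "aoi_id")])
  )
}

expect_datasets_equal <- function(a, b, tolerance = 1e-9) {
  sa <- dataset_signature(a)
  sb <- dataset_signature(b)
  expect_equal(sa$segments, sb$segments, tolerance = tolerance,
               ignore_attr = TRUE)
  expect_equal(sa$aois, sb$aois, ignore_attr = TRUE)
  expect_setequal(sa$participants$participant_id,
                  sb$participants$participant_id)
}

# round a dataset's times to integer ms (the tobii_like write precision)
round_dataset_times <- function(d) {
  seg <- d$segments
  seg$start <- round(seg$start)
  seg$end <- round(seg$end)
  gaze_dataset(seg, aois = d$aois, participants = d$participants,
               stimuli = d$stimuli, visibility = d$visibility,
               meta = d$meta)
}

# independent pair-enumeration oracle for transition counting
brute_force_transitions <- function(d, include_self = FALSE,
                                    include_no_aoi = FALSE) {
  v <- resolve_view(d)
  aoi_order <- unique(v$aois$aoi_id)
  if (include_no_aoi) aoi_order <- c(aoi_order, "(no AOI)")
  m <- matrix(0L, length(aoi_order), length(aoi_order),
              dimnames = list(aoi_order, aoi_order))
  seg <- v$segments[v$segments$category == "fixation", ]
  for (p in unique(seg$participant_id)) {
    for (s in unique(seg$stimulus_id[seg$participant_id == p])) {
      tr <- seg[seg$participant_id == p & seg$stimulus_id == s, ]
      tr <- tr[order(tr$start), ]
      if (nrow(tr) < 2) next
      for (i in seq_len(nrow(tr) - 1)) {
        from <- tr$aoi_ids[[i]]
        to <- tr$aoi_ids[[i + 1]]
        if (!length(from)) from <- if (include_no_aoi) "(no AOI)" else next
        if (!length(to)) to <- if (include_no_aoi) "(no AOI)" else next
        for (a in from) for (b in to) {
          if (!include_self && a == b) next
          m[a, b] <- m[a, b] + 1L
        }
      }
    }
  }
  m
}
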