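test_that("canonicalization sorts, validates, and is idempotent", {
  # empty input -> empty dataset
  d0 <- gaze_dataset(NULL)
  expect_s3_class(d0, "gaze_dataset")
  expect_equal(nrow(d0$segments), 0L)
  expect_equal(nrow(d0$participants), 0L)

  # reverse start order is sorted ascending
  d <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(200, 0), end = c(300, 100),
    category = "fixation", aoi_ids = c("B", "A")))
  expect_equal(d$segments$start, c(0, 200))

  # zero-length segment forced out by the half-open convention
  expect_error(gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S", start = 100, end = 100,
    category = "fixation", aoi_ids = "A")), "zero or negative")

  # unknown category
  expect_error(gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S", start = 0, end = 10,
    category = "blink", aoi_ids = "")), "category")

  # overlapping same-category events in one trial are rejected
  expect_error(gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 50), end = c(100, 150),
    category = "fixation", aoi_ids = c("A", "B"))), "overlapping")

  # adjacent events (end == next start) are fine under half-open intervals
  expect_silent(gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 100), end = c(100, 200),
    category = "fixation", aoi_ids = c("A", "B"))))

  # idempotence
  d2 <- canonicalize(d)
  expect_datasets_equal(d, d2)

  # registries auto-completed from segments
  expect_equal(d$participants$participant_id, "P1")
  expect_equal(d$stimuli$stimulus_id, "S")
  expect_setequal(d$aois$aoi_id, c("A", "B"))
})

test_that("duplicate rows collapse into AOI hit sets", {
  d <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 0), end = c(100, 100),
    category = "fixation", aoi_ids = c("A", "B")))
  expect_equal(nrow(d$segments), 1L)
  expect_equal(d$segments$aoi_ids[[1]], c("A", "B"))
})

test_that("strict mode rejects unregistered AOI references", {
  seg <- tibble::tibble(participant_id = "P1", stimulus_id = "S",
                        start = 0, end = 100, category = "fixation",
                        aoi_ids = "Z")
  expect_error(
    gaze_dataset(seg, aois = tibble::tibble(stimulus_id = "S",
                                            aoi_id = "A"),
                 strict = TRUE),
    "unknown AOI")
  d <- gaze_dataset(seg, aois = tibble::tibble(stimulus_id = "S",
                                               aoi_id = "A"))
  expect_setequal(d$aois$aoi_id, c("A", "Z"))
})

test_that("merge then unmerge is the identity on queryable values", {
  fx <- small_fixture(3)
  d <- fx$dataset
  m0 <- aoi_metrics(d, include_zero = TRUE)
  l0 <- scarf_legend(apply_filter(d, view_filter(stimulus = "S1")),
                     stimulus = "S1")
  dm <- merge_aois(d, "AB", c("AOI_A", "AOI_B"))
  du <- unmerge_aois(dm, "AB")
  expect_equal(aoi_metrics(du, include_zero = TRUE), m0)
  expect_equal(scarf_legend(apply_filter(du, view_filter(stimulus = "S1")),
                            stimulus = "S1"), l0)
  expect_datasets_equal(du, d)
})

test_that("merged AOI dwell is additive when members never co-occur", {
  d <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 100, 200), end = c(100, 200, 260),
    category = "fixation", aoi_ids = c("A", "B", "A")))
  m <- aoi_metrics(d)
  dm <- merge_aois(d, "AB", c("A", "B"))
  mm <- aoi_metrics(dm)
  expect_equal(mm$aoi_id, "AB")
  expect_equal(mm$dwell_ms,
               m$dwell_ms[m$aoi_id == "A"] + m$dwell_ms[m$aoi_id == "B"])
  # cross-check by the independent rasterization oracle
  om <- aoi_metrics_oracle(dm, 1)
  expect_equal(mm$dwell_ms, om$dwell_ms)
  expect_equal(mm$fixation_count, om$fixation_count)
})

test_that("merging a segment's overlapping hits uses set semantics", {
  d <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S", start = 0, end = 100,
    category = "fixation", aoi_ids = list(c("A", "B"))))
  dm <- merge_aois(d, "AB", c("A", "B"))
  v <- resolve_view(dm)
  expect_equal(v$segments$aoi_ids[[1]], "AB")
  # no double count: one fixation, dwell 100
  m <- aoi_metrics(dm)
  expect_equal(m$fixation_count, 1L)
  expect_equal(m$dwell_ms, 100)
})

test_that("merge pointer cycles are rejected", {
  d <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 100), end = c(100, 200),
    category = "fixation", aoi_ids = c("A", "B")))
  dm <- merge_aois(d, "B", "A")
  expect_error(merge_aois(dm, "A", "B"), "cycle")
})

test_that("filters are non-destructive, composable, and validated", {
  fx <- small_fixture(4)
  d <- fx$dataset

  # empty filter is the identity
  expect_datasets_equal(apply_filter(d, view_filter()), d)

  # time-range filter [0, 150) clips segment [100, 300) to [100, 150)
  ds <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S", start = 100, end = 300,
    category = "fixation", aoi_ids = "A"))
  clipped <- resolve_view(apply_filter(ds, view_filter(
    time_range = c(0, 150))))
  expect_equal(clipped$segments$start, 100)
  expect_equal(clipped$segments$end, 150)
  # a segment entirely outside the window is dropped
  gone <- resolve_view(apply_filter(ds, view_filter(time_range = c(0, 100))))
  expect_equal(nrow(gone$segments), 0L)

  # group filter keeps only matching participants
  dg <- set_participant_group(ds, "P1", "expert")
  dg$segments <- rbind(dg$segments, tibble::tibble(
    participant_id = "P2", stimulus_id = "S", start = 0, end = 50,
    category = "fixation", aoi_ids = list("A")))
  dg <- canonicalize(dg$segments, participants = dg$participants)
  dg <- set_participant_group(dg, "P1", "expert")
  dg <- set_participant_group(dg, "P2", "novice")
  v <- resolve_view(apply_filter(dg, view_filter(group = "expert")))
  expect_equal(unique(v$segments$participant_id), "P1")

  # unknown values are rejected with the valid values listed
  expect_error(apply_filter(d, view_filter(stimulus = "nope")), "S1")
  expect_error(apply_filter(d, view_filter(group = "wizard")), "expert")
  expect_error(apply_filter(d, view_filter(aoi = "XX")), "AOI")

  # underlying dataset untouched; clear_filters reverses
  df <- apply_filter(d, view_filter(stimulus = "S1"))
  expect_equal(df$segments, d$segments)
  expect_datasets_equal(clear_filters(df), d)

  # clipped total duration never exceeds the original
  f <- view_filter(time_range = c(100, 800))
  v2 <- resolve_view(apply_filter(d, f))
  expect_lte(sum(v2$segments$end - v2$segments$start),
             sum(d$segments$end - d$segments$start))
})

test_that("display edits are cosmetic and validated", {
  d <- worked_example()
  d2 <- set_aoi_style(d, "A", display_name = "Face", color = "#112233")
  expect_equal(d2$aois$display_name[d2$aois$aoi_id == "A"], "Face")
  expect_error(set_aoi_style(d, "A", color = "red"), "hex")
  expect_error(set_aoi_style(d, "missing"), "not registered")
  d3 <- rename_stimulus(d, "S", "Map task")
  expect_equal(d3$stimuli$display_name, "Map task")
  expect_equal(aoi_metrics(d3), aoi_metrics(d))
  expect_error(set_participant_group(d, "P9", "g"), "unknown participant")
})
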