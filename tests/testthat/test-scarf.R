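test_that("timeline projection follows the three mode definitions", {
  # linear map onto percent of trial duration
  xr <- project_segment(120, 300, "relative", onset = 0, trial_end = 500)
  expect_equal(c(xr$x0, xr$x1), c(24, 60))
  # a segment spanning the whole trial normalizes to the endpoints
  xr2 <- project_segment(0, 500, "relative", onset = 0, trial_end = 500)
  expect_equal(c(xr2$x0, xr2$x1), c(0, 100))
  # third segment of a trial occupies unit cell [2, 3)
  xr3 <- project_segment(900, 950, "ordinal", index = 2)
  expect_equal(c(xr3$x0, xr3$x1), c(2, 3))
  # absolute mode is onset-referenced
  xr4 <- project_segment(1120, 1300, "absolute", onset = 1000)
  expect_equal(c(xr4$x0, xr4$x1), c(120, 300))
  expect_error(project_segment(0, 10, "relative", onset = 5, trial_end = 5),
               "degenerate")
})

test_that("scarf geometry satisfies its axis invariants", {
  fx <- small_fixture(61)
  d <- apply_filter(fx$dataset, view_filter(stimulus = "S1"))
  seg <- resolve_view(d)$segments

  ga <- scarf_geometry(d, "absolute")
  for (p in ga$rows$participant_id) {
    main <- ga$rects[ga$rects$participant_id == p & ga$rects$band == "main", ]
    ps <- seg[seg$participant_id == p, ]
    # total bar length equals summed durations
    expect_equal(sum(main$x1 - main$x0), sum(ps$end - ps$start))
    # metadata always carries the original absolute range
    expect_equal(main$duration_ms, main$t1_ms - main$t0_ms)
  }

  gr <- scarf_geometry(d, "relative")
  for (p in gr$rows$participant_id) {
    main <- gr$rects[gr$rects$participant_id == p & gr$rects$band == "main", ]
    expect_equal(min(main$x0), 0)
    expect_equal(max(main$x1), 100)
    expect_true(all(main$x0 >= 0 & main$x1 <= 100 + 1e-9))
  }

  go <- scarf_geometry(d, "ordinal")
  for (i in seq_len(nrow(go$rows))) {
    p <- go$rows$participant_id[i]
    main <- go$rects[go$rects$participant_id == p & go$rects$band == "main", ]
    expect_equal(max(main$x1), go$rows$n_segments[i])
  }

  # within a sub-band rectangles are x-sorted and non-overlapping
  main0 <- ga$rects[ga$rects$band == "main" & ga$rects$sub_band == 0, ]
  for (p in unique(main0$participant_id)) {
    mp <- main0[main0$participant_id == p, ]
    expect_true(all(diff(mp$x0) >= 0))
    expect_true(all(mp$x0[-1] >= mp$x1[-nrow(mp)] - 1e-9))
  }
})

test_that("overlap splitting changes sub-band structure only", {
  d <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 100, 150), end = c(100, 150, 300),
    category = c("fixation", "saccade", "fixation"),
    aoi_ids = list("A", character(), c("A", "B"))))
  g1 <- scarf_geometry(d, "absolute", split_overlaps = FALSE)
  g2 <- scarf_geometry(d, "absolute", split_overlaps = TRUE)
  # split: the {A,B} fixation becomes two stacked rects on one x-range
  ov <- g2$rects[g2$rects$t0_ms == 150 & g2$rects$band == "main", ]
  expect_equal(nrow(ov), 2L)
  expect_equal(ov$sub_band, c(0L, 1L))
  expect_equal(unique(ov$x0), 150)
  expect_equal(unique(ov$x1), 300)
  # unsplit: one rect in the reserved overlap colour
  ov1 <- g1$rects[g1$rects$t0_ms == 150 & g1$rects$band == "main", ]
  expect_equal(nrow(ov1), 1L)
  expect_equal(ov1$aoi_label, "A + B")
  # x-extents and metadata identical between the two geometries
  key <- function(g) {
    r <- g$rects[g$rects$band == "main", ]
    unique(r[order(r$t0_ms), c("x0", "x1", "t0_ms", "t1_ms",
                               "duration_ms", "category")])
  }
  expect_equal(key(g1), key(g2))
})

test_that("visibility bands follow the override rule per participant", {
  d <- gaze_dataset(tibble::tibble(
    participant_id = rep(c("P1", "P2"), each = 2),
    stimulus_id = "S",
    start = c(0, 200, 0, 200), end = c(200, 400, 200, 400),
    category = "fixation",
    aoi_ids = c("A", "B", "B", "A")))
  d <- attach_visibility(d, tibble::tibble(
    aoi_id = "A", stimulus_id = "S", scope = "participant:P1",
    start = 0, end = 100))
  g <- scarf_geometry(d, "absolute", show_visibility = TRUE)
  expect_equal(g$visibility_aois, "A")
  v1 <- g$rects[g$rects$participant_id == "P1" &
                  g$rects$band == "visibility:A", ]
  v2 <- g$rects[g$rects$participant_id == "P2" &
                  g$rects$band == "visibility:A", ]
  expect_equal(c(v1$x0, v1$x1), c(0, 100))
  # P2 has no schedule of their own: band spans the whole trial
  expect_equal(c(v2$x0, v2$x1), c(0, 400))
  # every row carries one band per scheduled AOI
  for (p in c("P1", "P2")) {
    bands <- unique(g$rects$band[g$rects$participant_id == p])
    expect_true("visibility:A" %in% bands)
  }
  # layer off: no visibility bands
  g0 <- scarf_geometry(d, "absolute", show_visibility = FALSE)
  expect_equal(length(g0$visibility_aois), 0L)
  expect_true(all(g0$rects$band == "main"))
})

test_that("geometry is stable under merge/unmerge and filter/clear", {
  fx <- small_fixture(62)
  d <- fx$dataset
  sig <- function(g) {
    r <- g$rects
    r[order(r$participant_id, r$band, r$t0_ms, r$sub_band), ]
  }
  g0 <- scarf_geometry(d, "absolute", stimulus = "S2")
  g1 <- scarf_geometry(
    unmerge_aois(merge_aois(d, "M", c("AOI_A", "AOI_B")), "M"),
    "absolute", stimulus = "S2")
  expect_equal(sig(g1), sig(g0))
  g2 <- scarf_geometry(clear_filters(apply_filter(
    d, view_filter(group = "expert"))), "absolute", stimulus = "S2")
  expect_equal(sig(g2), sig(g0))
})

test_that("filtering then building equals building then clipping", {
  fx <- small_fixture(63)
  d <- apply_filter(fx$dataset, view_filter(stimulus = "S1"))
  seg <- resolve_view(d)$segments
  t0 <- as.numeric(quantile(seg$start, 0.25))
  t1 <- as.numeric(quantile(seg$start, 0.9))
  gf <- scarf_geometry(apply_filter(d, view_filter(time_range = c(t0, t1))),
                       "absolute")
  g <- scarf_geometry(d, "absolute")
  # geometric clip of the unfiltered geometry, on the raw time metadata
  clip <- g$rects[g$rects$band == "main", ]
  clip$c0 <- pmax(clip$t0_ms, t0)
  clip$c1 <- pmin(clip$t1_ms, t1)
  clip <- clip[clip$c1 > clip$c0, ]
  got <- gf$rects[gf$rects$band == "main", ]
  expect_setequal(unique(got$participant_id), unique(clip$participant_id))
  for (p in unique(got$participant_id)) {
    a <- got[got$participant_id == p, ]
    b <- clip[clip$participant_id == p, ]
    expect_equal(sort(a$x1 - a$x0), sort(b$c1 - b$c0), tolerance = 1e-9)
  }
})

test_that("legend is registry-ordered, merge-aware, and style-complete", {
  d <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 100, 120), end = c(100, 120, 300),
    category = c("fixation", "saccade", "fixation"),
    aoi_ids = c("A", "", "B")))
  l <- scarf_legend(d)
  expect_equal(l$label, c("A", "B", "Saccade"))
  lm <- scarf_legend(merge_aois(d, "AB", c("A", "B")))
  expect_equal(lm$label, c("AB", "Saccade"))
  expect_equal(nrow(scarf_legend(gaze_dataset(NULL))), 0L)
})

test_that("ordinal mode can restrict ordinal units to fixations", {
  d <- gaze_dataset(tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 100, 120), end = c(100, 120, 300),
    category = c("fixation", "saccade", "fixation"),
    aoi_ids = c("A", "", "B")))
  g_all <- scarf_geometry(d, "ordinal")
  g_fix <- scarf_geometry(d, "ordinal", ordinal_fixations_only = TRUE)
  expect_equal(max(g_all$rects$x1), 3)
  expect_equal(max(g_fix$rects$x1), 2)
})

test_that("geometry serializes to stable JSON", {
  d <- worked_example()
  g <- scarf_geometry(d, "absolute")
  j1 <- scarf_to_json(g)
  j2 <- scarf_to_json(scarf_geometry(d, "absolute"))
  expect_identical(j1, j2)
  parsed <- jsonlite::fromJSON(j1)
  expect_equal(parsed$axis$mode, "absolute")
  expect_equal(nrow(parsed$rects), nrow(g$rects))
})
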