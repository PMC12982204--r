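test_that("dialect detection is structural and unambiguous", {
  expect_equal(detect_dialect(
    "participant,stimulus,timestamp_ms,duration_ms,category,aoi\n...")$dialect_id,
    "generic_long")
  expect_equal(detect_dialect(
    "participant;stimulus;aoi;interval_start;interval_end;event")$dialect_id,
    "generic_interval")
  expect_equal(detect_dialect(paste(
    "Participant", "Stimulus", "Event Start Trial Time [ms]",
    "Event End Trial Time [ms]", "Category", "AOI Name",
    sep = "\t"))$dialect_id, "begaze_like")
  expect_equal(detect_dialect(paste(
    "Recording", "Presented Stimulus", "Interval", "Eye movement type",
    "Start", "Duration", "AOI hit", sep = "\t"))$dialect_id, "tobii_like")
  expect_error(detect_dialect("foo,bar"), "unrecognized format")
  # detection tolerates CRLF headers
  expect_equal(detect_dialect(
    "participant,stimulus,timestamp_ms,duration_ms,category,aoi\r\nx")$dialect_id,
    "generic_long")
})

test_that("parsing is invariant to how the byte stream is chunked", {
  fx <- small_fixture(5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dialect(fx$dataset, "generic_long", f)
  ref <- read_gaze(f)
  for (cs in c(1L, 7L, 4096L, file.size(f) + 10L)) {
    d <- read_gaze(f, chunk_size = cs)
    expect_identical(tidy(d), tidy(ref))
    # bounded memory: carry-over never exceeds the longest record
    max_line <- max(nchar(readLines(f), type = "bytes"))
    expect_lte(attr(d, "max_carry_bytes"), max_line + 1L)
  }
})

test_that("every dialect round-trips fixture datasets", {
  for (seed in c(1, 2)) {
    fx <- small_fixture(seed)
    d <- fx$dataset
    for (dialect in list_dialects()) {
      f <- withr::local_tempfile()
      suppressWarnings(write_dialect(d, dialect, f))
      back <- read_gaze(f)
      expect_equal(back$meta$detected_dialect, dialect)
      if (dialect == "generic_interval") {
        # fixation-only dialect: compare the fixation stream
        keep <- d$segments$category == "fixation"
        ref <- canonicalize(d$segments[keep, ])
        expect_datasets_equal(back, ref)
      } else if (dialect == "tobii_like") {
        # documented precision: integer-ms rounding
        expect_datasets_equal(back, round_dataset_times(d))
      } else {
        expect_datasets_equal(back, d)
      }
    }
  }
})

test_that("parse metadata is fully populated", {
  fx <- small_fixture(6)
  f <- withr::local_tempfile()
  write_dialect(fx$dataset, "begaze_like", f)
  d <- read_gaze(f)
  expect_equal(d$meta$source_filename, basename(f))
  expect_equal(d$meta$detected_dialect, "begaze_like")
  expect_equal(d$meta$file_size_bytes, file.size(f))
  expect_false(is.na(d$meta$parse_duration_ms))
  expect_equal(d$meta$tool_version,
               as.character(packageVersion("scarfkit")))
})

test_that("malformed rows error in strict mode and are skipped leniently", {
  f <- withr::local_tempfile()
  writeLines(c("participant,stimulus,timestamp_ms,duration_ms,category,aoi",
               "P1,S,0,100,fixation,A",
               "this row is broken",
               "P1,S,200,50,fixation,B"), f)
  expect_error(read_gaze(f, strict = TRUE), "line 3")
  expect_message(d <- read_gaze(f), "skipped 1")
  expect_equal(nrow(d$segments), 2L)
})

test_that("a tobii-style interval split arrives as separate trials", {
  f <- withr::local_tempfile()
  writeLines(c(
    paste("Recording", "Presented Stimulus", "Interval",
          "Eye movement type", "Start", "Duration", "AOI hit", sep = "\t"),
    "P1\tS\t1\tFixation\t0\t100\tA",
    "P1\tS\t2\tFixation\t500\t60\tA"), f)
  d <- read_gaze(f)
  # one logical AOI visit split across two intervals -> two segments in
  # two interval trials
  expect_setequal(unique(d$segments$stimulus_id), c("S#1", "S#2"))
  expect_equal(nrow(d$segments), 2L)
  expect_equal(base_stimulus(unique(d$segments$stimulus_id)),
               c("S", "S"))
  expect_equal(stimulus_interval(c("S#1", "S#2", "S")), c(1L, 2L, 1L))
})

test_that("visibility files parse, merge overlaps, and default to visible", {
  f <- withr::local_tempfile()
  writeLines(c("aoi,stimulus,start_ms,end_ms",
               "A,S,0.000,100.000",
               "A,S,50.000,150.000"), f)
  sched <- read_visibility(f)
  expect_equal(nrow(sched$intervals), 1L)
  expect_equal(sched$intervals$start, 0)
  expect_equal(sched$intervals$end, 150)

  # empty file: every AOI defaults to always visible
  f2 <- withr::local_tempfile()
  writeLines("aoi,stimulus,start_ms,end_ms", f2)
  empty <- read_visibility(f2)
  expect_true(visibility_at(empty, "A", "S", "P1", 9999))

  expect_error({
    f3 <- withr::local_tempfile()
    writeLines(c("aoi,stimulus,start_ms,end_ms", "A,S,100,50"), f3)
    read_visibility(f3)
  }, "end <= start")
})

test_that("participant-scoped visibility overrides global", {
  d <- worked_example()
  d <- attach_visibility(d, tibble::tibble(
    aoi_id = "A", stimulus_id = "S", scope = "global",
    start = 0, end = 100))
  d <- attach_visibility(d, tibble::tibble(
    aoi_id = "A", stimulus_id = "S", scope = "participant:P1",
    start = 200, end = 300))
  expect_false(visibility_at(d, "A", "S", "P1", 50))
  expect_true(visibility_at(d, "A", "S", "P1", 250))
  expect_true(visibility_at(d, "A", "S", "P2", 50))
  expect_false(visibility_at(d, "A", "S", "P2", 250))
  # an AOI with no schedule at all is always visible
  expect_true(visibility_at(d, "B", "S", "P1", 1e6))
})

test_that("visibility round-trips through its file format", {
  sched <- visibility_schedule(tibble::tibble(
    aoi_id = c("A", "B"), stimulus_id = "S", scope = "global",
    start = c(0, 10), end = c(100, 60)))
  f <- withr::local_tempfile()
  write_visibility(sched, f, scope = "global")
  back <- read_visibility(f)
  expect_equal(back$intervals, sched$intervals)
})
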