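test_that("the worked example yields the documented metrics", {
  d <- worked_example()
  for (m in list(aoi_metrics(d), aoi_metrics_oracle(d, 1))) {
    a <- m[m$aoi_id == "A", ]
    b <- m[m$aoi_id == "B", ]
    expect_equal(a$ttff_ms, 0)
    expect_equal(a$fixation_count, 2L)
    expect_equal(a$avg_fixation_ms, 75)
    expect_equal(a$dwell_ms, 150)
    expect_equal(b$ttff_ms, 120)
    expect_equal(b$fixation_count, 1L)
    expect_equal(b$avg_fixation_ms, 180)
    expect_equal(b$dwell_ms, 180)
  }
})

test_that("zero-count AOIs report absent temporal metrics, not zeros", {
  d <- gaze_dataset(
    tibble::tibble(participant_id = "P1", stimulus_id = "S",
                   start = 0, end = 100, category = "fixation",
                   aoi_ids = "A"),
    aois = tibble::tibble(stimulus_id = "S", aoi_id = c("A", "B")))
  m <- aoi_metrics(d, include_zero = TRUE)
  b <- m[m$aoi_id == "B", ]
  expect_equal(b$fixation_count, 0L)
  expect_true(is.na(b$ttff_ms))
  expect_true(is.na(b$avg_fixation_ms))
  expect_equal(b$dwell_ms, 0)
  # a fixation starting at onset has TTFF exactly 0
  expect_equal(m$ttff_ms[m$aoi_id == "A"], 0)
})

test_that("metric identities hold on generated data", {
  fx <- small_fixture(11)
  m <- aoi_metrics(fx$dataset)
  # avg * count == dwell
  expect_equal(m$avg_fixation_ms * m$fixation_count, m$dwell_ms,
               tolerance = 1e-9)
  # dwell bounded by trial duration
  tb <- trial_bounds(resolve_view(fx$dataset))
  md <- dplyr::left_join(m, tb, by = c("participant_id", "stimulus_id"))
  expect_true(all(md$dwell_ms <= md$end - md$onset + 1e-9))

  # conservation: with no overlapping hits, dwell sums + unassigned
  # fixation time equal total fixation time
  fx0 <- small_fixture(12, p_overlap = 0)
  v <- resolve_view(fx0$dataset)
  fixseg <- v$segments[v$segments$category == "fixation", ]
  total_fix <- sum(fixseg$end - fixseg$start)
  unassigned <- sum((fixseg$end - fixseg$start)[lengths(fixseg$aoi_ids) == 0])
  m0 <- aoi_metrics(fx0$dataset)
  expect_equal(sum(m0$dwell_ms) + unassigned, total_fix)
})

test_that("metrics equal the rasterization oracle", {
  # integer boundaries: exact agreement
  for (seed in c(21, 22)) {
    fx <- small_fixture(seed)
    m <- aoi_metrics(fx$dataset, include_zero = TRUE)
    o <- aoi_metrics_oracle(fx$dataset, 1, include_zero = TRUE)
    expect_identical(m$fixation_count, o$fixation_count)
    expect_equal(m$ttff_ms, o$ttff_ms, tolerance = 1e-12)
    expect_equal(m$dwell_ms, o$dwell_ms, tolerance = 1e-12)
  }
  # fractional boundaries: within one cell of the rasterization
  fx <- small_fixture(23, time_grid_ms = NULL)
  m <- aoi_metrics(fx$dataset)
  o <- aoi_metrics_oracle(fx$dataset, 1)
  expect_identical(m$fixation_count, o$fixation_count)
  expect_true(all(abs(m$ttff_ms - o$ttff_ms) <= 1 + 1e-9))
  per_fix_slack <- m$fixation_count * 2  # each fixation edge off by < 1 cell
  expect_true(all(abs(m$dwell_ms - o$dwell_ms) <= per_fix_slack + 1e-9))
  expect_error(aoi_metrics_oracle(fx$dataset, 0), "positive")
})

test_that("metrics equal the generator's incremental ground truth", {
  for (seed in c(31, 32)) {
    fx <- small_fixture(seed)
    m <- aoi_metrics(fx$dataset, include_zero = TRUE)
    tr <- fx$truth
    expect_equal(m$participant_id, tr$participant_id)
    expect_equal(m$aoi_id, tr$aoi_id)
    expect_identical(m$fixation_count, as.integer(tr$fixation_count))
    expect_equal(m$ttff_ms, tr$ttff_ms)
    expect_equal(m$dwell_ms, tr$dwell_ms)
    expect_equal(m$avg_fixation_ms, tr$avg_fixation_ms)
  }
})

test_that("interval reconstruction combines partial records correctly", {
  # documented two-interval example
  recs <- tibble::tibble(
    participant_id = "P1",
    stimulus_id = c("S#1", "S#2"),
    aoi_id = "A",
    ttff_ms = c(0, 10), fixation_count = c(2L, 1L),
    avg_fixation_ms = c(75, 60), dwell_ms = c(150, 60))
  offs <- tibble::tibble(participant_id = "P1",
                         stimulus_id = c("S#1", "S#2"),
                         interval_offset_ms = c(0, 500))
  u <- reconstruct_aoi_metrics(recs, offs)
  expect_equal(u$stimulus_id, "S")
  expect_equal(u$fixation_count, 3L)
  expect_equal(u$dwell_ms, 210)
  expect_equal(u$avg_fixation_ms, 70)
  expect_equal(u$ttff_ms, 0)

  # single interval: identity
  one <- reconstruct_aoi_metrics(recs[1, ], offs[1, ])
  expect_equal(one$fixation_count, 2L)
  expect_equal(one$ttff_ms, 0)
  expect_equal(one$dwell_ms, 150)

  expect_error(reconstruct_aoi_metrics(recs[0, ]), "at least one")
})

test_that("splitting a trial and reconstructing reproduces direct metrics", {
  fx <- small_fixture(41)
  d <- fx$dataset
  direct <- aoi_metrics(d, include_zero = TRUE)

  # full precision split via tobii-style interval trials renamed in memory
  cuts <- random_cut_points(d, n_per_trial = 2, seed = 99)
  seg <- resolve_view(d)$segments
  interval <- rep(1L, nrow(seg))
  for (i in seq_len(nrow(seg))) {
    cc <- cuts$cut_ms[cuts$participant_id == seg$participant_id[i] &
                        cuts$stimulus_id == seg$stimulus_id[i]]
    interval[i] <- 1L + sum(cc <= seg$start[i])
  }
  seg$stimulus_id <- paste0(seg$stimulus_id, "#", interval)
  dsplit <- gaze_dataset(seg)
  m <- aoi_metrics(dsplit, include_zero = TRUE)
  rec <- reconstruct_aoi_metrics(m, interval_offsets(dsplit))
  rec <- rec[rec$fixation_count > 0 | direct$fixation_count == 0, ]
  keyed <- dplyr::inner_join(
    direct, rec, by = c("participant_id", "stimulus_id", "aoi_id"))
  expect_equal(nrow(keyed), nrow(direct))
  expect_identical(keyed$fixation_count.x, keyed$fixation_count.y)
  expect_equal(keyed$ttff_ms.x, keyed$ttff_ms.y, tolerance = 1e-12)
  expect_equal(keyed$avg_fixation_ms.x, keyed$avg_fixation_ms.y,
               tolerance = 1e-12)
  expect_equal(keyed$dwell_ms.x, keyed$dwell_ms.y, tolerance = 1e-12)
})

test_that("adding a fixation moves the metrics monotonically", {
  base <- tibble::tibble(
    participant_id = "P1", stimulus_id = "S",
    start = c(0, 200), end = c(100, 350),
    category = "fixation", aoi_ids = c("A", "A"))
  m0 <- aoi_metrics(gaze_dataset(base))
  extra <- rbind(base, tibble::tibble(
    participant_id = "P1", stimulus_id = "S", start = 400, end = 480,
    category = "fixation", aoi_ids = list("A")))
  m1 <- aoi_metrics(gaze_dataset(extra))
  expect_gte(m1$fixation_count, m0$fixation_count)
  expect_gte(m1$dwell_ms, m0$dwell_ms)
  expect_lte(m1$ttff_ms, m0$ttff_ms)
})

test_that("aoi_summary aggregates the three headline metrics per group", {
  fx <- small_fixture(51)
  s <- aoi_summary(fx$dataset)
  expect_s3_class(s, "aoi_summary")
  expect_setequal(unique(s$metric),
                  c("dwell_time_ms", "fixation_count",
                    "time_to_first_fixation_ms"))
  expect_setequal(unique(s$group_label), c("expert", "novice"))
  # mean dwell for one cell equals hand aggregation
  m <- aoi_metrics(fx$dataset, include_zero = TRUE)
  v <- resolve_view(fx$dataset)
  experts <- v$participants$participant_id[
    v$participants$group_label == "expert"]
  cell <- m[m$participant_id %in% experts & m$stimulus_id == "S1" &
              m$aoi_id == "AOI_A", ]
  got <- s$value[s$group_label == "expert" & s$stimulus_id == "S1" &
                   s$aoi_id == "AOI_A" & s$metric == "dwell_time_ms"]
  expect_equal(got, mean(cell$dwell_ms))
})
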