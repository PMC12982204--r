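# scarfkit

Headless R toolkit for **AOI sequence analysis** of eye-tracking data:
parsing event-level exports, computing the standard per-AOI fixation
metrics, building scarf-plot geometry, counting AOI transitions, and
exporting figures, tables, scanpath sequences, and reproducible analysis
sessions.

## Who it is for

Researchers who already have *event-level* exports — fixations and
saccades with timestamps and pre-assigned area-of-interest (AOI) labels —
and want scripted, testable versions of the analyses usually done by
hand or in GUI tools: scarf plots (one row per participant, coloured AOI
segments over time), dwell/TTFF/count summaries, transition matrices,
and ScanGraph-ready scanpath strings. Everything runs offline on plain
delimited text; no raw gaze coordinates, fixation detection, or AOI
geometry is involved.

## The model in brief

A **gaze segment** is one event on a trial timeline: participant *p*,
stimulus *s*, half-open interval [start, end) in ms, a category
(fixation / saccade / other), and a *set* of AOI hits. With trial onset
`t₀ = min(start)` over the trial, the per-AOI metrics over the trial's
fixations F(a) hitting AOI *a* are

- time to first fixation: `TTFF(a) = min{ start(f) : f ∈ F(a) } − t₀`
- fixation count: `n(a) = |F(a)|`
- dwell time: `D(a) = Σ_{f ∈ F(a)} (end(f) − start(f))`
- average fixation duration: `D(a) / n(a)`

A fixation hitting *k* AOIs counts fully toward each. Every metric is
verified against an independent 1-ms rasterization oracle, and
interval-split recordings (stimulus reappearances in mobile exports)
are reconstructed with exact counts and ±1 ms temporal agreement.

Scarf geometry supports **absolute** (ms), **relative** (% of trial),
and **ordinal** (segment order) timelines, optional stacked rendering of
overlapping AOI hits, and per-participant dynamic-AOI visibility bands.

## Worked example

```r
library(scarfkit)

d <- gaze_dataset(tibble::tibble(
  participant_id = "P1", stimulus_id = "S",
  start    = c(0, 100, 120, 300),
  end      = c(100, 120, 300, 350),
  category = c("fixation", "saccade", "fixation", "fixation"),
  aoi_ids  = c("A", "", "B", "A")))

aoi_metrics(d)
#> # A tibble: 2 × 7
#>   participant_id stimulus_id aoi_id ttff_ms fixation_count avg_fixation_ms dwell_ms
#>   <chr>          <chr>       <chr>    <dbl>          <int>           <dbl>    <dbl>
#> 1 P1             S           A            0              2              75      150
#> 2 P1             S           B          120              1             180      180
```

Reading: AOI `A` is fixated from trial onset (TTFF 0 ms) twice, for
100 ms + 50 ms = 150 ms of dwell (average 75 ms); `B` is first fixated
120 ms after onset, once, for 180 ms. The 20 ms saccade contributes to
no metric but still renders in the scarf plot:

```r
g <- scarf_geometry(d, mode = "absolute")
render_plot(g, "scarf.svg", render_style(format = "svg"))   # deterministic SVG
autoplot(g)                                                 # ggplot version

transition_matrix(d)
#> <transition_matrix> 2 AOI(s), 2 transition(s)
#>     to
#> from A B
#>    A 0 1
#>    B 1 0
```

No real export at hand? The built-in generator produces complete
synthetic recordings (with ground-truth metrics) and writes them in
every supported dialect:

```r
fx <- generate_gaze_fixture(fixture_spec(seed = 1))
write_fixture_corpus(fixture_spec(seed = 1), "fixtures/")
d  <- read_gaze("fixtures/fixture_generic_long.csv")   # format auto-detected
```

A thin command-line front end covers the same ground
(`inst/cli/scarfkit metrics data.csv -o metrics.csv`; see
`?run_scarfkit`).

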