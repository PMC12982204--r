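---
title: "AOI sequence analysis with scarfkit: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AOI sequence analysis with scarfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarfkit)
```

## The analysis model

Eye trackers classify gaze into *events* — fixations (stable gaze),
saccades (rapid movements between fixations), and residual "other"
samples — and, when areas of interest (AOIs) are defined on the stimulus,
label each event with the AOIs it lands on. scarfkit works entirely at
this event level: it never sees raw gaze coordinates, never detects
fixations, and never computes AOI geometry. The atom of every analysis is
a **gaze segment**: one timestamped event belonging to one participant's
viewing of one stimulus (a *trial*), carrying a possibly empty *set* of
AOI hits.

Three conventions anchor all downstream arithmetic:

* **Half-open intervals.** A segment spans `[start, end)` milliseconds.
  A fixation ending at *t* and a saccade starting at *t* therefore do not
  overlap, and durations add exactly with no boundary double counting.
  Zero-length segments are rejected outright.
* **Onset-referenced trials.** Export formats disagree about what time 0
  means (recording start, stimulus onset, device boot). scarfkit defines
  the trial onset as the minimum segment start within the trial, and the
  trial end as the maximum segment end. Every onset-referenced quantity
  (time to first fixation, relative timelines) is thereby independent of
  the source format's clock.
* **AOI hits are sets.** An event landing on two overlapping AOIs is one
  segment with a two-element hit set, never two duplicated rows. Dwell
  sums count each millisecond once per AOI; merging two AOIs that
  co-occur on one segment yields a single hit (set union), not a double
  count.

## AOI metrics

For each (participant, stimulus, AOI), `aoi_metrics()` computes the four
standard quantities from fixation-category segments only:

* **time to first fixation** — start of the first fixation hitting the
  AOI, minus trial onset;
* **fixation count** — number of fixations hitting the AOI;
* **dwell time** — summed duration of those fixations;
* **average fixation duration** — dwell / count.

Saccades and "other" events are excluded from all four metrics (they
still render in scarf plots). Whether a tool's dwell should include
saccades spent inside an AOI visit is genuinely ambiguous across vendors;
the fixation-only definition is the one the metric names imply, and it is
the one this package tests against. A fixation hitting *k* AOIs counts
fully toward each — consistent with set semantics and with exact integer
fixation counts. An AOI never fixated has count 0 and dwell 0, and its
temporal metrics are *absent* (`NA`, exported as empty cells) rather than
0, because 0 is a legitimate time to first fixation.

### The independent oracle

`aoi_metrics_oracle()` recomputes the same records by a deliberately
different route: it rasterizes each trial into cells of a chosen
resolution (1 ms by default) and assigns each cell to the fixation whose
half-open interval contains the cell's left edge. Dwell is then a cell
count, TTFF the earliest owned cell, and the fixation count the number of
distinct fixations owning at least one cell. With integer event
boundaries and 1 ms cells the two routes must agree exactly; with
fractional boundaries each temporal metric can differ by at most one
cell. The test suite holds this equivalence over hundreds of randomized
synthetic recordings, which is how the metric implementation earns trust
without any proprietary reference export.

### Interval-split recordings

Mobile eye-tracking exports often split one logical trial into several
numbered recording intervals when a stimulus disappears and reappears.
The `tobii_like` dialect models this: timestamps are rounded to integer
milliseconds and each interval arrives as its own block, parsed into
per-interval trials (`S#1`, `S#2`, ...). `reconstruct_aoi_metrics()`
unifies the per-interval metrics: counts and dwell add, average fixation
duration is the count-weighted mean, and TTFF is the minimum of interval
offset plus interval TTFF, with offsets recovered from the recording
clock by `interval_offsets()`. At full precision the reconstruction
equals direct computation on the unsplit data exactly; under integer-ms
rounding the temporal metrics stay within ±1 ms and the counts remain
exact — the same contract the test suite enforces.

Interval cut points used in testing are drawn at event boundaries, not
arbitrary times: in a real export, a stimulus disappearing terminates the
ongoing event, whereas a cut through the middle of a fixation would split
it into two and change the count.

## Scarf geometry

`scarf_geometry()` turns one stimulus of a view into
resolution-independent rectangles: one row per participant, one rectangle
per segment (or per AOI hit, stacked into equal-height sub-bands, when
`split_overlaps` is on). Three timeline modes are supported:

* **absolute** — x is milliseconds since trial onset;
* **relative** — x is percent of the trial's duration, so every row spans
  exactly [0, 100] (a zero-length trial is an error here);
* **ordinal** — each segment occupies one unit of width, encoding order
  and discarding duration. Every rendered segment counts as one unit by
  default; `ordinal_fixations_only` restricts the units to fixations.

Normalizing the relative mode by the trial's own duration (not by any
global recording duration) was an open choice; trial duration is the
interpretation under which "every participant's row spans the full axis"
holds, which is the property users read scarf plots by. Rectangles always
carry their original absolute time range, duration, and category as
metadata, whatever the mode, so hover/tooltip layers and tests can
recover the ground truth from the geometry alone. Untracked gaps between
segments render as empty space rather than a filled style — absence of
data is shown as absence of ink.

Dynamic AOIs contribute *visibility bands* below each row: per scheduled
AOI, the intervals during which it was visible to that participant.
Participant-scoped schedules override global ones; an AOI with no
schedule for a given participant is treated as always visible. In ordinal
mode a visibility interval is mapped to the ordinal extent of the
segments it overlaps, since clock time has no direct position on an
ordinal axis.

Colours come from a fixed 12-colour categorical cycle assigned at AOI
registration order and overridable per AOI; saccades, no-AOI fixations,
unsplit overlaps, and "other" events each have a reserved style. Overlap
sub-bands stack in registry order, which makes ties deterministic.

## Transitions and summaries

`transition_matrix()` counts moves between consecutive fixations within a
trial (never across trials or participants; saccades are skipped as they
are not AOI-bearing events). A pair of fixations contributes the full
Cartesian product of their hit sets. Self-transitions and a "(no AOI)"
pseudo-label are both off by default — the common convention in
transition analysis — and both are plain flags, since reasonable analyses
want either reading. `aoi_summary()` aggregates dwell time, fixation
count, and TTFF per AOI and participant group for bar charts; the
default aggregation is the participant mean (comparable across groups of
different sizes), with participant sums available via `stat = "sum"`.

## Formats and streaming

Four delimited-text dialects are supported, detected purely from the
header line's token structure — never the filename: two generic layouts
(`generic_long`, one row per event; `generic_interval`, one row per AOI
visit with explicit bounds) and two simplified vendor-style dialects
capturing the behaviours that make real exports hard (`begaze_like`,
event-per-row with separate visibility files; `tobii_like`, integer-ms
interval-split). The six proprietary vendor formats themselves are
byte-level moving targets and are out of scope; the two vendor-style
dialects are fully specified here, and the package's own writers close
the loop so that `parse(write(d)) == d` is a testable property for every
dialect (up to the documented integer-ms precision for `tobii_like`, and
minus non-fixation events for `generic_interval`, which cannot represent
them and warns on lossy writes).

The reader streams: it consumes the file in chunks and retains only the
trailing partial line between chunks, so peak retained input is bounded
by one record regardless of file size, and the parsed result is provably
independent of how the byte stream is chunked (the suite parses the same
file at 1-byte, 7-byte, 4-KiB, and whole-file chunk sizes). Delimiters
are fixed per dialect; decimal separators are dots only — locale sniffing
is error-prone enough that it is better treated as a documented
constraint than a heuristic. Times are kept at full floating precision
internally and rounded only at export (3-decimal milliseconds in CSV,
integer milliseconds in `tobii_like`).

Filters (`view_filter()`) compose by intersection and never mutate the
dataset; `time_range` clips segments against a half-open window on the
segments' own millisecond clock. AOI merges are non-destructive pointer
edits (`merged_into`) forming a forest; unmerging restores the previous
state exactly, and both operations are exercised as identities on
metrics and geometry.

## Sessions and exports

`save_session()` writes the full canonical data, panel configuration and
version metadata as *canonical JSON*: sorted keys, shortest exact decimal
representation for numbers, null-valued members omitted. Canonical form
makes save → load → save byte-identical, so sessions diff cleanly and can
be shared without reprocessing source files. Unknown fields found in a
session survive a re-save, and a format-version mismatch warns and loads
best-effort rather than refusing.

SVG figures are emitted by the package's own serializer, which writes
geometry rectangles directly; identical inputs produce identical bytes.
Raster output (PNG/JPG) goes through the `ggplot2` `autoplot()` methods
with the canvas snapped to whole 96-dpi cells so pixel dimensions scale
exactly linearly with the requested DPI. The ScanGraph export maps each
AOI to a single character and writes one fixation sequence per
participant; the exact grammar of that external tool is not formally
published, so the dialect written here is versioned in-file
(`#scarfkit-scangraph v1`) with consecutive-duplicate collapsing off by
default. Overlap fixations are transcribed as the lowest-registry-index
AOI, with a warning.

## The synthetic-recording generator

`generate_gaze_fixture()` stands in for real exports throughout the test
suite. It emulates: alternating fixation/saccade trains (fixations 80–350
ms, saccades 20–80 ms, uniform) over 3-second trials, 10 participants × 5
stimuli × 4 AOIs by default; a 10% chance that a fixation misses every
AOI and a 10% chance it lands on two; occasional untracked gaps; random
per-trial recording offsets so trial onsets are far from zero; and
per-participant visibility windows for about half the AOIs. Ground-truth
metrics are accumulated incrementally *during* generation — an
independent bookkeeping path, so tests of `aoi_metrics()` against the
ground truth are not circular. All times sit on a 1 ms grid by default
(real trackers report at millisecond or finer granularity);
`time_grid_ms = NULL` draws continuous times to exercise sub-millisecond
arithmetic.

What the generator does *not* emulate: oculomotor dynamics
(main-sequence relationships, realistic saccade amplitudes), gaze
coordinates, drift or loss patterns specific to individual devices, and
vendor-specific byte layouts beyond the two simplified dialects. Passing
tests therefore demonstrate the correctness of the arithmetic, the
format round trips, and the invariants — not compatibility with any
specific proprietary export.

Problem sizes in the routine test runs are chosen to keep the whole suite
fast while still giving the properties room to fail: 200 recordings of
~50 trials for the oracle equivalence, 100 recordings for the geometry
invariants, 1000 random sequences for transition counting.

## Numerical choices and edge cases

* Same-category events in one trial must not overlap (beyond 1e-9 ms
  floating noise); violations are validation errors naming the location.
* Sorting uses radix (C-locale) order everywhere, so registry and output
  order are platform-independent.
* `tobii_like` rounding uses R's `round()`; segments whose duration
  rounds to zero are dropped with a warning.
* Empty AOI-hit sets, empty datasets, header-only files, and
  zero-fixation participants are all legal and covered by tests.
* AOI ids may not contain `;`, which is the textual set separator in
  every export format.

## Known limitations

* Strictly event-level: no fixation detection, no AOI polygon handling.
* Two simplified vendor-style dialects, not bit-exact vendor parsers.
* WebP raster output is not offered; PNG, JPG, and SVG are.
* The ScanGraph dialect is compatible-by-intent and versioned, not an
  official grammar.
* Interactive behaviour (hover, drag-and-drop dashboards) is out of
  scope; the geometry carries the metadata an interactive layer would
  need.
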