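---
title: "Models and methods behind luxmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind luxmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxmetrics)
```

## The data model

Wearable light loggers record one row per sampling interval ("epoch"),
typically between 10 s and 5 min, over days to weeks of free-living wear.
`luxmetrics` represents one deployment as a `light_series`: a tibble with
a timezone-aware `Datetime` column and one numeric column per light
channel (illuminance or melanopic equivalent daylight illuminance, both
in lux), carrying the participant id and the epoch as attributes.

Three conventions fix the semantics of everything downstream:

* **A timestamp marks the start of its epoch.** Every duration-type
  metric is therefore a count of qualifying epochs times the epoch
  length — an exact integer multiple of the sampling interval, which
  makes results discrete, comparable across devices with the same epoch,
  and directly testable.
* **The epoch is the modal successive timestamp difference**, with ties
  broken toward the smaller interval. Wear gaps produce a minority of
  large differences; the mode is robust to them, and the tie rule
  guarantees a gap can never masquerade as the sampling interval.
* **Intervals are closed at the start and open at the end**, matching
  epoch-start attribution: an instant exactly at a diary interval's end
  belongs to the following state.

Each series carries a single IANA timezone and all time-of-day
computations use local wall time. Around daylight-saving transitions the
wall clock duplicates or skips an hour; the series is left untouched
(no resampling), which matches how field data are exported, and the
consequences are confined to the one or two affected days.

### Regularisation and missingness

Loggers encode non-wear implicitly by omitting rows. `regularize()` lays
a series onto the complete grid between its first and last timestamp;
`find_gaps()` reports the maximal runs of absent instants. Input
timestamps must sit on the grid within **1% of the epoch**: that band
absorbs device clock jitter (which is snapped to the grid) while
anything larger stops with an error naming the offending timestamp,
rather than silently resampling data recorded at a different rate.

Missing epochs stay explicit. Every metric takes an `ignore_missing`
flag (default `TRUE`: missing epochs are excluded from sums and counts)
and reports the fraction of missing epochs alongside its value. With
`ignore_missing = FALSE` any missingness makes the result undefined.
Undefined outcomes — all-missing input, no qualifying epochs, zero
variance, zero total exposure — are always returned as a typed result
with an `NA` value and a reason string, never as a silent zero, because
a zero dose and an unknowable dose are very different findings.

`fill_gaps()` offers three policies: explicit missing (default — gaps
become visible but no data is invented), zero fill, and last observation
carried forward bounded by `max_span`. The default is deliberately the
least presumptuous one; the paper-trail `filled` column keeps fills
distinguishable from observations for any downstream audit.

## Preprocessing

`aggregate_epochs()` averages numeric channels (modal value for
categorical state channels) into windows anchored at **local midnight**
rather than at the first sample, so hourly bins line up with clock time
and day-based metrics are well defined. An all-missing window stays
missing. Aggregation conserves dose on complete windows to within
floating-point error — a property the test-suite checks at a relative
tolerance of 1e-9.

`interval_to_state()` joins a sleep diary (or any interval table) onto a
series by labelling each epoch with the interval covering its start
instant. Overlapping intervals within one id are rejected with an error
naming the first overlap: a diary that claims a participant was both
asleep and awake is a data error the user must resolve, not something to
resolve silently by precedence.

`join_series()` outer-joins several series (e.g. personal exposure and
an environmental daylight-availability reference) after aggregating all
of them to the coarsest common epoch; colliding channel names are
suffixed with the source id.

## The metric engine

The registry enumerates **61 metrics in 17 families**, each implemented
over one `light_series` and returning a typed result row (value, units,
parameters, missing fraction). A driver maps day-scope metrics over
local days (incomplete first/last days are included but flagged) and
id-scope metrics over whole recordings.

### Threshold families

All threshold comparators are inclusive — *above* means x ≥ T, *below*
means x ≤ T, *within* is the closed interval — one convention applied
uniformly so that the three modes of every family partition cleanly.

* *Duration above threshold*: qualifying-epoch count × epoch.
* *Timing above threshold* (MLiT-style): mean local epoch-start time of
  qualifying epochs, with a circular-mean option for bands that straddle
  midnight.
* *Period above threshold*: longest qualifying run, where interruptions
  no longer than `max_interrupt` neither break the run nor are excluded
  from its duration.
* *Frequency crossing threshold*: comparator sign changes between
  successive non-missing epochs (comparisons bridge missing epochs).
* *Threshold for duration*: the k-th largest (or smallest) value with
  k = round(d / Δt) — the highest threshold sustained for at least d.
* *Pulses above threshold*: qualifying runs merged across interruptions
  ≤ `max_interrupt`, filtered to a minimum duration, summarised by
  count, mean level, mean and total duration, and mean onset, midpoint
  and offset clock times. Onset is the first epoch's start; offset the
  last epoch's start; midpoint is onset + duration/2. Defaults (250 lx,
  minimum 8 min, interruptions up to 2 min) describe the conventional
  "bright-light bout" and are plain parameters, not constants.

### Rhythm and distribution families

* *Brightest/darkest period* (M10/L5-style): the rolling window (10 h /
  5 h by default) maximising or minimising the mean level; ties go to
  the earliest onset, and `loop = TRUE` evaluates windows wrapping
  across midnight by treating the day circularly.
* *Centroid of exposure*: exposure-weighted mean clock time.
* *Midpoint of cumulative exposure*: earliest epoch at which the
  running dose reaches half the daily total (the earliest-≥ rule makes
  the result unique on plateaus).
* *Interdaily stability*:
  IS = (n·Σ_h (x̄_h − x̄)²) / (p·Σ_i (x_i − x̄)²)
  on the series binned to p bins per 24 h (1 h default), with x̄_h the
  across-days mean of clock bin h. Two identical days give exactly 1.
* *Intradaily variability*:
  IV = (n·Σ (x_i − x_{i−1})²) / ((n−1)·Σ (x_i − x̄)²)
  on the binned series; strict alternation of even length gives exactly
  4, which the suite asserts to 1e-12.
* *Exponential moving average*: s_i = λx_i + (1−λ)s_{i−1} with
  λ = 1 − 2^(−Δt/t½), so the response to a step reaches one half
  exactly one half-life after the step; missing inputs leave the state
  unchanged and emit a missing output.
* *Disparity index*: mean |Δ log(x+1)| between successive epochs.
* *Barroso lighting metrics*: per-day 90th/10th percentile bright/dark
  thresholds, the mean levels and longest runs beyond them, and the
  coefficient of variation of daily means across days. Only the family
  name circulates in the metrics literature without a universally fixed
  formula, so the percentile-based definitions here are this package's
  concrete, parameterised choice (`bright_quantile`, `dark_quantile`).
* *Dose*: time-integrated exposure Σ x·Δt in lux·hours. The sixteen
  families above plus this cumulative-dose family bring the registry to
  17 families and 61 metrics; dose is also the conservation quantity
  used to validate aggregation.

### Non-visual response models

The direct (nvRD) and circadian (nvRC) response families model the
melanopsin-mediated drive of light. The field's named models are not
published as closed formulas alongside their names, so `luxmetrics`
ships a transparent, fully parameter-exposed formalisation and makes no
claim of numerical equality with any specific prior implementation:

1. **History filter**: effective light E(t) is the exponential smoothing
   of melanopic EDI with half-life τ_h (default 60 min) — light
   adaptation integrates over recent history rather than reacting to
   instantaneous level.
2. **Hill dose–response**: R_D = Eⁿ / (Eⁿ + C50ⁿ), default n = 2 and
   C50 = 100 melanopic-EDI lx, bounded in [0, 1]; cumulative response
   integrates R_D over time (response-hours).
3. **Circadian gate** (nvRC only): C = R_D·(1 + a·cos(2π(tod − φ)/24 h))
   / (1 + a), clipped to [0, 1]; default amplitude a = 0.5 and peak
   phase φ = 03:00, when non-visual sensitivity is conventionally
   highest.

Against a reference response on the identical grid (e.g. the response
to available daylight), three comparison scalars are defined: circadian
disturbance CD (time-averaged |C − C_ref|), circadian bias CB
(time-averaged signed difference) and relative amplitude error RAE
(|amp(C) − amp(C_ref)| / amp(C_ref), amp = max − min over the day).
CD ≥ |CB| always; identical curves give CD = CB = RAE = 0.

## Device import

Seventeen wearables are importable through declarative dialects — one
YAML file per device describing delimiter, preamble lines, header,
timestamp columns and format, decimal mark, timezone policy (embedded
offset, supplied zone, or unix epoch) and light channels. The parsing
machinery is generic; the dialect files are data. Because vendors do
not publish their export layouts, the shipped layouts are invented but
structurally varied (two-column timestamps, 12-hour clocks, decimal
commas, tab separation, headerless files, unix seconds and
milliseconds, embedded UTC offsets), and each one is exercised by a
write–import round-trip that must reproduce the generated series
exactly. Replacing a layout with a vendor's real one is a one-file
edit. The GENEActiv dialect is registered but refuses raw import —
those exports require external preprocessing (GGIR) first — unless the
caller asserts `preprocessed = TRUE`.

Rows with unparseable timestamps are dropped and counted (an error only
if more than half of a run drops); duplicate timestamps within an id
keep the first occurrence, counted. The import report reconciles
exactly: rows parsed = rows emitted + rows dropped.

## The synthetic generator

`generate_scenario()` emulates a small field study: per-participant
multi-day series at a fixed epoch, a diurnal template (rectangular or
half-sine photoperiod, default 08:00–18:00 at 1000 lx over a 1 lx
night), multiplicative log-normal noise on (value + 1) — light spans
decades and must stay nonnegative — wear gaps implemented as removed
rows, and a jittered nightly sleep diary. Defaults describe a plausible
week of wear (3 participants × 7 days at 60 s epochs, noise sd 0.25,
3 gaps of 5–30 epochs). Everything is deterministic under the scenario
seed.

The generator records its own ground truth at construction time: exact
gap positions, the noise-free template dose per day over the epochs
actually emitted, and the daylight pulse blocks remaining after gap
removal. Truth-recovery tests therefore compare the pipeline against
construction, not against a second implementation of the same
computation. Two truths are only exact under restricted scenarios and
are used as such: template dose requires zero noise, and one-block-per-
day pulse truth requires gaps confined to the night (`gap_window`).

What the generator deliberately does not emulate: realistic spectral
composition, behavioural variation between days, sensor saturation and
nonlinearity, or timezone changes mid-recording. Passing tests
demonstrate correctness of the computations on well-defined input, not
that any device's field data are this clean.

## Numerical and design choices

* Grid alignment tolerance: 1% of the epoch (jitter snapped, more is an
  error).
* Tie-breaks: modal epoch → smaller duration; brightest/darkest window
  → earliest onset; midpoint of cumulative exposure → earliest epoch
  reaching half.
* Aggregation windows anchor at local midnight; days split at local
  midnight, with incomplete edge days flagged rather than dropped.
* Negative values in device files are treated as sensor garbage and
  imported as missing; the series container rejects negative values
  outright.
* Undefined results are typed (`Value = NA` + reason), never zero.
* Problem sizes in the test-suite and acceptance script are chosen to
  exercise every code path at small scale: single synthetic days for
  closed-form identities, 200–500 random series of length ≤ 200 for the
  brute-force oracles, and 2–3 participants × a few days for pipeline
  runs.

## Known limitations

* Dialect layouts are structural stand-ins until real vendor exports
  are available; the registry and parser are the tested surface.
* The Barroso and non-visual response definitions are this package's
  parameterised formalisations of families that circulate in the
  literature under a name rather than a fixed formula.
* No imputation beyond zero/LOCF, no actigraphy modelling, no circadian
  phase estimation (e.g. DLMO prediction), and no spectral
  reconstruction from colour-channel counts.
* One timezone per series; recordings spanning travel across zones must
  be split beforehand.
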