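---
title: "Single-electrode burst metrics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-electrode burst metrics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## The problem

Multi-electrode arrays (MEAs) record extracellular action potentials
("spikes") from excitable cell cultures through a grid of microelectrodes
embedded in each well of a culture plate. Runs of closely spaced spikes on
one electrode ("bursts") are a standard functional readout: their number,
duration, spike content and internal timing characterise a network's
excitability. Acquisition software usually reports these quantities at the
whole-well level; this package computes and visualises them **per
electrode** over user-defined time windows, so spatial heterogeneity within
a well (uneven cell distribution, proximity to grounding electrodes,
locally divergent drug responses) is visible instead of averaged away.

The native input is the electrode burst list CSV exported by AxIS Navigator
(Axion BioSystems): one row per detected burst with the electrode token,
burst start time in seconds, burst size in spikes, and burst duration in
seconds. A built-in detector reproduces the same burst definition from raw
spike timestamps, and a seeded simulator produces fully ground-truthed
fixtures, so every stage of the pipeline is testable without recordings.

## Burst definition and detector

A single-electrode burst is a maximal run of consecutive spikes in which
every inter-spike interval (ISI) is at most `max_isi_s`, kept only if the
run has at least `min_spikes` spikes. The defaults, 5 spikes and 100 ms,
are the standard AxIS single-electrode criterion. Three conventions are
deliberately pinned down because the verbal definition leaves them open:

* **Boundary inclusivity.** An ISI exactly equal to 100 ms joins the burst
  ("maximum ISI of 100 ms" is read as inclusive). Numerically the
  comparison is `isi <= max_isi_s + 1e-12`: real timestamps are multiples
  of the 80 µs sampling period, and without the epsilon a nominal 0.1 s
  gap can fall out of a burst purely through the binary representation of
  0.1. The margin is ten orders of magnitude below one sample period, so
  it can never admit a genuinely longer interval.
* **Duration convention.** Burst duration is last minus first spike time.
  Acquisition software has been observed to report durations one sample
  period longer on otherwise identical bursts; the convention here is the
  one that makes `duration = sum of within-burst ISIs` an identity.
* **Maximality.** A spike belongs to at most one burst and bursts are
  never merged across a gap wider than the threshold, so detection is
  local: splitting a recording at any silent gap and detecting the halves
  separately gives the same result.

The implementation is a run-length scan over the ISI sequence; the test
suite holds it to exact agreement with a brute-force oracle that
enumerates every contiguous spike range and keeps the maximal valid ones
(1000 random trains per run).

## Time windows

Analysis windows are labelled half-open intervals `[t0, t1)`, and a burst
belongs to the window containing its **start** time. A burst straddling a
boundary is therefore counted exactly once, and per-window burst counts
over any partition of the recording sum to the unwindowed counts — a
conservation property the tests assert exactly. The alternative (clipping
or prorating straddling bursts) would make counts depend on the window
grid; nothing downstream would gain from that.

## The four burst parameters

Per electrode and window the package reports:

1. **Number of bursts** — a count; 0 is a real value.
2. **Mean burst duration** (s) — arithmetic mean over in-window bursts.
3. **Mean spikes per burst** — likewise.
4. **Mean within-burst ISI** (s) — for one burst this is
   `duration / (size - 1)`, the duration divided by the number of
   intervals; the electrode-level parameter is the **mean over bursts of
   that per-burst value**, *not* the ratio of the mean duration to the
   mean size minus one. The two differ on any electrode whose bursts are
   heterogeneous, and only the per-burst mean reproduces published
   per-electrode validation values. A regression test keeps the two
   conventions from being silently swapped.

Where an electrode has no in-window bursts the three means are undefined
and are represented as `NA`, never as 0: a zero would be a fabricated
measurement and would bias any well-level average taken over it.

## Well-level aggregation

Well summaries average electrode-level values and attach the standard
error of the mean, `SEM = sd / sqrt(n)` with the sample (n−1) standard
deviation. Two populations are deliberately different:

* **Burst counts** average over **all** electrodes of the well, inactive
  ones contributing 0 — an electrode that detected nothing is evidence of
  low activity, and a count of zero is a valid count.
* **Duration, spikes/burst and mean ISI** average over **active**
  electrodes only, because those parameters are undefined (`NA`) where no
  burst exists.

Whether inactive electrodes should enter the count average is genuinely
arguable, so it is a named switch (`count_inactive`), with the inclusive
behaviour as default.

## Electrode consistency: ICC(2,k)

To quantify whether the electrodes of a well tell the same story, the
package computes the Shrout–Fleiss intraclass correlation ICC(2,k):
two-way random effects, absolute agreement, average of k raters. From the
two-way ANOVA decomposition of a complete n × k ratings matrix into
subject, rater and residual mean squares (MSR, MSC, MSE):

$$\mathrm{ICC}(2,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}$$

The mean squares are computed from explicit sums of squares; the tests
verify the decomposition conserves the total sum of squares to 1e−9 and
cross-check the coefficient against R's own `aov()` fit on random
matrices.

Design choices worth knowing:

* **Orientation.** "Subjects" and "raters" are a modelling choice. The
  default treats wells as subjects and the 16 electrode positions as
  raters (one matrix per parameter per window). The alternative,
  `windows-by-electrodes`, treats time windows as subjects and the
  electrodes of one well as raters — appropriate for asking whether
  electrodes agree on a temporal (e.g. drug-response) profile. Both are
  exposed; neither is asserted as canonical.
* **Missing cells.** The matrix must be complete. Electrodes with
  undefined values make construction fail with the offending cells
  listed; `drop_incomplete_raters = TRUE` removes such electrodes
  entirely. No imputation, ever.
* **Degenerate input.** An all-equal matrix has no variance to apportion;
  the result is an error, not 0 or 1.
* **Known bias.** ICC(2,k) is a ratio statistic. For pure i.i.d. noise its
  expectation is not 0 but slightly negative (about −0.115 at n = 20,
  k = 8, because E[MSE/MSR] = (n−1)/(n−3) > 1). The property tests assert
  this actual behaviour rather than an idealised zero. Interpreting small
  negative coefficients as "slightly worse than chance" is therefore
  over-reading; they are what chance looks like.

## The synthetic generator

`synth_params()` / `simulate_spike_trains()` draw per-electrode spike
trains as a sequence of bursts:

| quantity | distribution | default |
|---|---|---|
| burst size | shifted Poisson, minimum `min_spikes` | mean 20 spikes |
| within-burst ISI | log-normal, truncated | median 8 ms, σ = 0.6 |
| inter-burst gap | exponential above a floor | floor 0.2 s |
| burst rate | set via gap mean | 10 bursts/min |
| recording | 24 wells × 16 electrodes | 600 s, 120 s windows |

The defaults were chosen once to land the four parameters in the ranges
seen in mature hippocampal cultures (durations 0.08–0.2 s, sizes 7–42
spikes, mean ISIs 4–29 ms). Two truncations are invariants, not tuning:
within-burst ISIs are capped two sample periods **below** `max_isi_s`, and
the gap floor sits more than two sample periods **above** it. Timestamps
are then quantized to the 12.5 kHz acquisition grid (rounding moves each
timestamp by at most half a sample period, so a capped ISI can grow by at
most one period and still cannot reach the threshold). Together these
guarantee the detector recovers every generated burst exactly — never
split, never merged — which the tests assert on every seed rather than
assume. Parameter combinations violating the truncations are rejected at
construction.

Per-window rate modulation (a named multiplier vector) emulates
stimulus-like transients. One global seed expands into per-electrode
substreams by stable hashing of the electrode token, so enlarging a
simulation never perturbs the trains already generated.

**What the generator does not emulate:** network-level synchrony between
electrodes (trains are independent), firing outside bursts (no tonic
spikes), non-stationarity within a window, amplitude information, or
electrode cross-talk. Passing the recovery tests therefore shows the
*bookkeeping* — detection, windowing, summarisation, I/O — is exact under
the stated burst model; it is not evidence about spike *detection* from
voltage traces, which is upstream of this package's scope.

## Numerical and degenerate-input choices

* CSV numeric fields are written with shortest round-trip formatting, so
  write→read is the identity on doubles; this backs the fixture files.
* The burst-list reader skips a metadata preamble by scanning (up to 200
  lines) for the first line containing an electrode-column alias; header
  aliases match case-insensitively after stripping a parenthesised unit.
  Rows with unparseable numerics are dropped with a warning naming the
  rows; missing required columns are a hard error.
* Undefined means are `NA` end to end; plots annotate them instead of
  drawing zero-height bars, and sidecar CSVs keep the `NA` rows.
* Every figure writes a sidecar CSV of exactly the values drawn; plots
  are views of tables, never recomputations.
* The electrode grid is drawn with row 1 at the top; the orientation is a
  documented convention with a `flip_rows` switch, since the physical
  plate orientation is a matter of viewpoint.

## Problem sizes in the shipped tests

The test suite simulates single wells over 120–600 s recordings (about
300–1300 bursts per fixture), runs 1000-train detector/oracle
comparisons, and 500-draw ICC noise ensembles; these sizes give exact or
Monte-Carlo-tight checks in well under a minute each and were chosen as
the smallest configurations that still exercise every code path with
non-trivial data.

## Known limitations

* Only the AxIS burst-list CSV dialect (and simple spike-time CSVs) are
  parsed; hierarchical "advanced metrics" reports and binary acquisition
  files are out of scope by design.
* Network (multi-electrode) bursts, synchrony metrics and weighted mean
  firing rate are not computed.
* ICC confidence intervals and other ICC forms — (1,1), (3,k) — are not
  provided; the single reported form is the average-raters
  absolute-agreement coefficient described above.
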