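---
title: "Query-driven system suitability testing for LC-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Query-driven system suitability testing for LC-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzSST)
```

## Why query-driven SST

System suitability testing (SST) asks whether an LC-MS platform is
performing acceptably *before* samples are committed to it: are the
standards eluting at their usual retention times, in the right order, with
stable peak areas and accurate masses, and are the MS/MS spectra
consistent with history? mzSST implements this as a batch evaluation of
named queries — written in a small mass-spectrometry query dialect — over
a directory of open-format (mzML) runs. The worked example throughout is a
panel of six deuterated acylcarnitines (acetyl- through
oleoyl-L-carnitine-d3), chosen because they are commercially available,
absent from biological samples, and span a reversed-phase gradient from
roughly 1 to 10 minutes.

A precursor trace for one analyte looks like

```
QUERY scansum(MS1DATA) WHERE MS1MZ=249.1888 AND TOLERANCEPPM=10
  AND RTMIN=4.13 AND RTMAX=4.46
```

which reads: over MS1 scans between 4.13 and 4.46 minutes, sum the
intensity of every centroid peak within 10 ppm of m/z 249.1888
(valeryl-carnitine-d3, [M+H]+).

## Exact-mass arithmetic

All m/z anchors are computed, never transcribed. Formulas are parsed with
deuterium as a first-class element symbol `D` (monoisotopic mass
2.014102 Da), and the protonated adduct adds the *proton* mass
(1.007276466 Da) rather than the hydrogen atom mass — the electron
bookkeeping is what makes the panel's [M+H]+ values come out right at
four decimal places:

```{r masses}
adductMz("C12H20D3NO4")                       # valeryl-carnitine-d3 [M+H]+
neutralLossProductMz(adductMz("C9H14D3NO4"),  # acetyl: trimethylamine loss
                     "C3H9N")
cationMz("C4H5O2")                            # diagnostic acylium fragment
```

Two choices deserve a note. First, tolerance boundaries are **inclusive**
(a scan at exactly 10 ppm is kept): dropping scans exactly on the stated
tolerance would make results depend on floating-point rounding direction.
Second, ppm error is always anchored on the *query* m/z, the fixed
reference, not on the observed value.

Not every printed product ion of the panel derives from simple
neutral-loss arithmetic: the acetyl product ion (148.0684) is exactly
[M+H]+ minus trimethylamine, but the octanoyl, lauroyl and oleoyl values
differ from any trimethylamine(-d3) loss in the fourth decimal or more.
The package therefore treats tabulated product ions as *query inputs*;
which analytes carry their three deuteriums on the trimethylamine versus
the acyl chain is configured per analyte in the panel table rather than
inferred.

## Query evaluation and chromatographic integration

A scan matches a query when its MS level matches the source
(`MS1DATA`/`MS2DATA`), its retention time lies in the closed window
`[RTMIN, RTMAX]`, and the m/z condition holds: a centroid peak within
tolerance (`MS1MZ`, `MS2PROD`), the recorded precursor within tolerance
(`MS2PREC`), or a peak whose distance below the recorded precursor
matches the stated loss (`MS2NL`). Matched peak intensities are summed
per scan; the reported `observed_mz` is their intensity-weighted mean.
Because non-matching scans are simply omitted, every emitted row has
passed the mass-accuracy gate implicitly — a batch whose calibration has
drifted beyond tolerance produces empty traces, not wrong ones. The
engine is checked in the test suite against an independently written
brute-force scan-by-scan filter on randomized runs.

The extracted ion chromatogram (EIC) lives on the run's MS1 scan grid
restricted to the query window, zero-filled where nothing matched, so
acquisition cadence — not interpolation — determines resolution. (For
`MS2DATA` queries the grid is the matching fragmentation-scan grid
instead.) Peak detection is deliberately minimal: the apex is the global
intensity maximum (earliest time wins ties), the peak is the contiguous
nonzero segment containing it extended by one zero-valued anchor point on
each side, and the area is the trapezoidal integral over that segment in
intensity·minutes. A peak must span at least `min_scans` points (default
3, i.e. one nonzero point between its anchors) and exceed `apex_floor`
(default 0). There is no smoothing, baseline correction, deconvolution or
shape fitting, and peaks are integrated over the detected segment rather
than the full query window — with one analyte per window and zero-filled
gaps the two coincide for clean signals, and the segment choice keeps
noise outside the peak from leaking into the area.

## Batch statistics and deficiency flags

`runBatch()` applies every named query to every run (ordered by
acquisition timestamp when present, else by filename), yielding exactly
one record per run × query; a corrupt file is logged and skipped, never
fatal. `summarizeBatch()` reports per query the found count and the mean,
sample (n−1) standard deviation and relative standard deviation
(RSD = sd/mean × 100) of apex retention time and area. The sample
denominator suits small longitudinal QC series; RSD is only defined for
at least two found records and a positive mean, and statistics run over
found records only with `n_found` surfaced so that a missing analyte
depresses the count instead of silently distorting a mean.

`flagDeviations()` compares records against a reference of expected apex
times (nominal window midpoints, or a historical summary):

* `MISSING_ANALYTE` — no peak found for a run × query;
* `RT_SHIFT` — apex outside the analyte's nominal window widened by
  `rt_margin` (default 0.1 min, about a third of a panel window: wide
  enough to ignore scan-grid jitter, narrow enough to catch a 0.3 min
  lot-to-lot column drift);
* `ELUTION_ORDER` — within a run, any Kendall-discordant pair between
  observed and expected apex ranks; a fully inverted order is reported as
  a reversal. Rank comparison rather than absolute time is used because
  the characteristic failure (wrong column or method left on the system)
  scrambles *order* even where individual times remain plausible.

## MS/MS consistency

For each analyte, fragmentation scans are selected by precursor m/z and
window, and the intensity of a target product ion (or of peaks matching a
neutral loss) is divided by the scan's total ion current. TIC
normalization was chosen over base-peak normalization because it bounds
every value in [0, 1] and accounts for the varying total signal of MS2
scans triggered across a chromatographic peak; base-peak mode remains
available through the same per-scan function. Scans are aggregated by
activation type × collision energy (NCE grouped by stated value, matched
to 1e-3 for floating encodings; scans lacking metadata aggregate under
"unknown" rather than vanishing), giving a mean ± sd profile per group
across days.

## The synthetic panel generator

Every pipeline stage is testable without instrument data.
`defaultSstFixture()` builds a six-analyte panel whose precursor m/z are
computed from the molecular formulas and whose Gaussian elution peaks sit
at the nominal window midpoints (windows 1.11–1.44 … 9.27–9.59 min,
σ = 0.05 min, amplitude 10⁶, MS1 scans every 0.01 min over an 11-min run
— matching a ~20-second-wide peak sampled ~100× on a modern orbitrap
gradient). DDA synthesis follows inclusion-list scheduling: each
in-window MS1 survey scan is followed by HCD scans at NCE 10–60 ascending
and then CID scans ascending, and each MS2 scan realizes a configured
fraction table of a constant nominal TIC, with the unassigned remainder
on the surviving precursor so that TIC-normalization recovers the
fractions exactly. The default fraction trends emulate acylcarnitine
behaviour: the m/z 85.0284 product grows with NCE and is stronger under
HCD; the trimethylamine(-d3) loss is prominent only under CID above
NCE 30.

Noise is two-dimensional and deliberately simple: a per-run, per-analyte
log-normal amplitude multiplier (sd *s* produces an area RSD of
100·√(exp(s²)−1) percent across runs, which the tests verify), and
per-peak ppm jitter on m/z. Both default to 0 so the study conditions are
noiseless parameter-recovery fixtures. What the generator does **not**
emulate — peak tailing, chemical noise, co-eluting isobars, calibration
drift, isotope envelopes, stochastic DDA triggering — bounds what passing
tests show: they validate the *computation* (extraction, integration,
statistics, flagging), not robustness to messy chromatography.

Failure-mode variants mirror the two deficiency scenarios: `"reversed"`
permutes apex times into reverse elution order (wrong column/method);
`"shifted"` moves late eluters (nominal apex ≥ 5 min) by +0.3 min
(column lot drift). These variants issue *windowless* screening queries —
with the nominal windows in force a displaced peak is clipped or lost at
the window edge, which is precisely why deficiency screening must look
beyond the windows it is validating.

## Numerical choices and edge cases

Retention time is minutes everywhere internally; second-annotated files
are converted at the I/O boundary. Input is assumed centroided; profile
spectra load with a warning and are matched as centroid points. Scans
with zero peaks are retained (they matter for zero-filling), zero-TIC
MS2 scans normalize to `NA` with a warning and are excluded from
aggregation, and an empty RT grid ("no scans in window") is an error
distinct from an all-zero EIC ("no signal"). Written mzML stores 64-bit
uncompressed arrays with the shortest decimal attribute rendering that
round-trips each double, so write→read is lossless and a fixed seed
yields byte-identical files. Problem sizes in the shipped tests — 3-run
MS1 batches at 0.01-min cadence, 5-day DDA sets at 0.05–0.1-min cadence
— were chosen as the smallest grids on which apex recovery to half a
scan interval and area recovery to 2% are meaningful.

## Limitations

The query dialect is the SST subset only (no variables, isotope-pattern,
intensity or ion-mobility conditions); multi-analyte windows are not
deconvolved (one peak per query window by design); xlsx export is a
minimal single-sheet writer; and the longitudinal acceptance bound of
2.3% maximum retention-time RSD can only be checked meaningfully against
a real multi-month archive — on synthetic replicates it is a smoke test,
not evidence about any instrument.
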