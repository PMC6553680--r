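---
title: "Noise-responsive detection of fasciculation potentials in HDSEMG"
author: "fpquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-responsive detection of fasciculation potentials in HDSEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpquant)
```

## The problem and the model

Surface EMG noise varies strongly between patients, muscles and visits, so
any fixed amplitude criterion for fasciculation potentials (FPs) trades
sensitivity in quiet recordings against specificity in noisy ones.
`fpquant` ties the inclusion criterion to a *local* noise estimate: every
detected spike carries a noise band `X` (mean positive minus mean negative
amplitude over one second either side of the spike, its own samples
excluded), and is accepted as an FP only when its peak-trough amplitude
strictly exceeds

- `Y = A2 * X` — the noise-responsive linear model (default `A2 = 8`), or
- `Y = A1` — a constant threshold in microvolts, kept as the comparison
  baseline.

The linear model has no intercept: at zero noise any deviation from zero is
genuine signal, and empirically the noise-vs-threshold relation passes
through the origin. A direct consequence, which the test suite asserts, is
that FP labels under the linear model are invariant to a global rescaling
of the recording, while constant-threshold labels are not.

## Pipeline stages and their parameters

1. **Ingestion** (`read_recording`): delimited channels-by-samples matrix
   with a JSON sidecar (`fs_hz`, `grid_rows`, `grid_cols`, …) or a minimal
   16-bit EDF. Amplitudes are microvolts throughout; the input is assumed
   already referenced.
2. **Bandpass** (`bandpass`): 4th-order Butterworth, 20–500 Hz, applied
   forward–backward. Zero-phase filtering is essential because downstream
   validation matches events against annotated peak *times*; a causal
   filter would shift spike peaks by a frequency-dependent lag. No notch
   filter is applied.
3. **Perimeter removal** (`select_inner_grid`): the outer ring of the
   electrode grid has the poorest skin contact; an 8 × 8 grid keeps its 36
   interior channels.
4. **Bad-channel exclusion** (`detect_bad_channels`): null channels
   (amplitude range under 0.5 μV — a floor we chose, as no standard value
   exists) are dropped first; then channels falling outside mean ± 1.96 SD
   across channels on any of three metrics — passband FFT-magnitude area,
   amplitude range, fraction of spectral power below 20 Hz (computed
   pre-filter, since the bandpass removes the drift being measured) — are
   excluded in a single pass. The interval is computed per recording, not
   pooled across recordings.
5. **Spike detection** (`probability_threshold`, `segment_spikes`): the
   threshold is the empirical 98th percentile (inverse ECDF, quantile type
   1) of the channel's absolute amplitude, computed per channel over the
   whole recording; polarity is not distinguished. Suprathreshold
   excursions are tracked to their nearest zero crossings. A zero crossing
   is a sign change between consecutive samples; exact zeros count as
   crossings and belong to no spike. Immediately adjacent opposite-polarity
   phases merge transitively, so biphasic and triphasic excursions are one
   spike each. No minimum spike duration is imposed.
6. **Super-channel** (`build_superchannel`): spikes whose sample intervals
   overlap across channels (≥ 1 shared sample — the weakest coincidence
   assumption) group by transitive closure; the event adopts the interval
   and amplitude of the member with maximal peak-trough amplitude. Ties
   break to the lower channel index, then the earlier onset, making the
   stream independent of channel order. A quality-assurance pass splits
   events longer than 100 ms that contain two absolute-amplitude maxima
   above the noise band separated by a return to within it; **this split
   rule and its parameters are a heuristic of this package** — the
   procedure it stands in for is not publicly specified, so it is
   deliberately conservative (duration alone never splits an event).
7. **Classification and filters** (`classify_events`,
   `exclude_noisy_blocks`, `flag_voluntary`): classification is per spike,
   against the spike's own noise band, with strict inequality. Blocks of
   5 s tile the recording from t = 0 (a trailing partial block is tested
   with the same rules and its actual duration subtracted); membership is
   decided by the event's peak time. A block is excluded when per-spike
   thresholds exceed `AT_exc` (100 μV) for strictly more than half of its
   spikes, or any single spike exceeds `2 * AT_exc` (the latter reason is
   reported when both hold). Runs of ≥ 4 consecutive FPs with every
   inter-peak interval < 250 ms are relabelled voluntary. Only excluded
   blocks adjust the time denominator; voluntary-train time does not.
8. **Summary** (`summarise_recording`): FP count, analysed minutes and
   FPs/min at full precision, with a round-half-up integer for display.

## Validation machinery

Event matching is one-to-one and greedy in time order: a manual peak
matches the (unique, since events are disjoint) event containing it. True
positives are included events with a matched peak; false positives,
included events without one; false negatives, manual peaks not matched to
an *included* event — so a peak landing in a subthreshold event counts as a
miss, and that event no longer counts as a true negative. Block and
voluntary filters are disabled during matching so the comparison isolates
the amplitude criterion.

Median ROC curves use the standard coefficient grids (`A2`: 14, 12, 10, 9,
8, 7, 6, 5, 4, 2; `A1`: 100, 60, 40, 35, 30, 25, 20, 15, 10, 5).
Recordings with no annotated FPs contribute specificity only. The AUC is
trapezoidal in (1 − specificity, sensitivity) space with the curve anchored
at (0,0) and (1,1) — the published curves do not span the full range and no
anchoring convention is stated, so we chose the usual one. The optimal
coefficient minimises the Euclidean distance to (0, 1), ties to the smaller
value. Cross-validation shuffles recordings into folds with a seeded RNG,
selects the coefficient on the training median ROC and pools test-fold
confusion counts; accuracy is `(tp + tn) / total` (no formula is standard,
so the obvious one is used). The noise-vs-threshold regression uses
weights ∝ `1/x²` (residual SD proportional to the noise band); a two-stage
variant that estimates the SD–noise relation from an OLS pre-fit is exposed
as an option. `optimal_atinc_search` follows the count-matching rule
literally: the lowest threshold on the scan grid whose FP count is within
one of the manual count, with an explicit `absent` flag when no threshold
qualifies.

## The synthetic generator

`generate_recording` emulates the statistical structure the pipeline
assumes: per-channel Gaussian noise bandpassed to 20–500 Hz and scaled so
each channel's realised noise band hits a target drawn from 2–8 μV; focal
FPs as smooth biphasic (optionally triphasic) wavelets of 5–20 ms whose
lobes are deliberately unequal so the ground-truth peak is unambiguous;
peak-trough amplitudes log-normal around ~10× the focal channel's noise
band (`sdlog = 0.3`, so roughly a fifth of events fall below the 8× default
threshold — matching the regime in which the method's sensitivity operates,
rather than a trivially separable corpus); exponential spatial decay across
the grid (space constant 1.5 electrodes, giving the multi-channel
footprints the manual definition of an FP relies on); Poisson event times
with a 120 ms refractory gap; optional broad-band noise bursts and regular
voluntary trains. `generate_corpus` spreads noise scales log-normally
across recordings to emulate between-muscle and between-visit differences,
and derives annotations from ground truth, optionally with miss/false
rates.

What it does **not** emulate: volume-conductor physics, motor-unit
morphology and propagation, electrode artefacts with structured spectra,
or annotator idiosyncrasies. Passing tests therefore demonstrate the
pipeline's internal correctness and its behaviour under the assumed noise
model, not clinical performance.

## Numerical choices and degenerate inputs

- Quantile type 1 keeps the threshold an observed amplitude, so the
  suprathreshold fraction is exactly `1 - p` up to ties.
- An all-zero channel yields threshold 0 with a warning and no spikes; a
  spike spanning the whole signal gets noise band 0 with a warning; fewer
  than 4 non-null channels skip CI-based exclusion with a warning; zero
  analysable time is an error rather than an infinite frequency.
- Two-point regressions return exact fits with CIs flagged undefined.
- The EDF writer requires whole-second durations (records are 1 s) and
  stores the physical range rounded upward to 4 significant digits so the
  int16 round trip never clips.
- The empirical probability threshold assumes contaminated segments are a
  small fraction of the recording. In 30-minute clinical recordings a
  several-second burst is negligible; in short simulations a burst
  occupying more than ~2% of samples inflates the threshold itself and
  suppresses detection — keep simulated bursts brief relative to the
  recording, as the examples do.

## Simulation scales used by the tests

Corpus-level checks run on 80 recordings of 15 s on 4 × 4 grids at 2048 Hz
(the full validation loop: both ROC families, 100 × 5-fold CV), a choice
that keeps the complete suite executable on a laptop core in a few minutes
while preserving the quantities being tested — heterogeneous noise scales,
hundreds of events per recording, and fold counts identical to the
reference analysis. Rate-recovery checks use 4 × 4 × 20 s corpora with a
tight amplitude distribution (`sdlog = 0.05`), since rate recovery is only
well-defined when the configured amplitudes sit clearly above threshold.
The acceptance script additionally runs one full-size 8 × 8 × 60 s
recording through the complete default pipeline, including perimeter
removal and bad-channel exclusion.

## Known limitations

- The QA split heuristic is invented (flagged above); its parameters have
  not been validated against real compound events.
- Whether neighbouring spikes should be excluded from a spike's noise
  window is unresolved; they are not excluded here, which measurably
  inflates noise bands in dense trains.
- The per-channel 98% threshold saturates sensitivity: events missed at
  that stage cannot be recovered by lowering `A2`. The ROC tests assert
  this plateau explicitly.
- Real EDF edge cases (discontinuous records, annotations channels) are
  out of scope; the reader targets the continuous subset the writer emits.
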