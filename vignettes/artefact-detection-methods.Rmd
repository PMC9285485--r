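---
title: "Detecting flat lines and large amplitude fluctuations in neonatal EEG"
author: "eegartefacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting flat lines and large amplitude fluctuations in neonatal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegartefacts)
```

## The problem

Neonatal EEG recorded in the intensive care unit is long (hours to days)
and heavily contaminated by two distinct, predominant non-physiological
artefacts: **flat line segments**, where contact between an electrode and
the head box is temporarily lost and the recorded signal is exactly
constant, and **large amplitude fluctuations**, transients produced by
infant movement, usually affecting all channels and often accompanied by
muscle (EMG) activity.  Both must be removed before any automated
analysis (sleep staging, seizure detection, functional brain-age
estimation), and removing them by visual inspection is slow and
operator-dependent.  `eegartefacts` implements a threshold-based detector
tailored to infants at *term-equivalent age* (postmenstrual age about
37–42 weeks), whose background EEG stays in the tens of microvolts: above
100 µV no cortical activity is expected at this age, and above 150 µV a
segment can be discarded unconditionally.

The detector deliberately **removes** artefactual intervals rather than
correcting them: during a flat line no cortical signal was recorded at
all, and movement artefacts are too variable in waveform and topography
for interpolation to be trustworthy.

## Signal views

Three aligned views of the recording feed the two detectors
(`prepare_views()`):

* **raw** — unfiltered; used for flat-line detection, because a
  lost-contact segment is *exactly* constant only before any filtering;
* **notched** — 50 Hz power-line notch only (2nd-order IIR, quality
  factor 30, applied forward–backward); used for the high-frequency power
  ratio, which needs the spectrum *above* 50 Hz;
* **band** — notch followed by a 0.5–40 Hz Butterworth band-pass (three
  poles per edge, forward–backward); used for the amplitude features.

Computing the high-frequency ratio on the notch-only view is the only
self-consistent routing: a 40 Hz low-pass would annihilate the very
content that ratio measures.  All filters are zero-phase so that artefact
onsets are not displaced.  The band-pass order was chosen so that the
documented stop-band contract (a 60 Hz sinusoid attenuated by more than
20 dB) holds with margin in the measured steady-state response; filters
are applied to the full record without edge trimming, since the
detectors' own padding absorbs edge transients.

## Flat-line detection

For each channel the second difference
\(z(n) = x(n+2) - 2x(n+1) + x(n)\) is computed over the whole
acquisition.  Both constant and linearly drifting segments give
\(z = 0\), and continuous physiological EEG essentially never sits below
the flatness threshold of \(10^{-4}\) µV.  The chain is:

1. **Flagging** (`flag_flat_samples`): time is split into fixed
   consecutive 1-s bins; within a bin, samples with \(|z|\) strictly
   below threshold are counted (they need not be consecutive) and all are
   flagged if at least 2 occur.  Fixed bins are the simplest reading of
   "multiple samples within one second"; a sliding window would count the
   same samples repeatedly.  Both the bin rule and the minimum count are
   configurable.
2. **Grouping** (`group_flags`): flagged samples at most 2.5 s apart
   (inclusive) merge into one candidate interval, so isolated samples
   marginally above threshold do not split one physical flat line.
   The gap is measured between flagged sample times.
3. **Consensus** (`flat_consensus`): a candidate survives only where at
   least \(K = \mathrm{round}(0.75\,C)\) of the \(C\) channels agree —
   14 of 19 and 7 of 9 channels at the default fraction.
4. **Padding** (`pad_intervals`): flat lines are typically flanked by
   sharp deflections, so each detected interval grows by 1 s on both
   sides if it lasts at most 5 s, else by 3 s.  A tie at exactly 5 s
   takes the short padding (the duration rule leaves the tie open; the
   choice is configurable).  Padding is applied after consensus, on the
   unpadded durations.

## Large-amplitude detection

The recording is tiled with non-overlapping windows of `window_s`
seconds (1–7 s admissible).  Trailing remainders of at least 1 s become a
shorter final window; shorter remainders are absorbed into the last full
window to keep the spectral estimate stable.  Per window and channel,
three features are computed:

* **MAFD** \(= \max |x(n+1) - x(n)|\) — abrupt amplitude changes
  (band view);
* **MAA** \(= \max |x|\) — peak amplitude (band view);
* **RFC** \(= P(f > 50\,\mathrm{Hz}) / P(f)\) — fraction of spectral
  power above 50 Hz (notched view), estimated by Welch's method with
  Hamming sub-windows of `min(256, window)` samples and 50 % overlap.
  The sub-window length is not dictated by the procedure itself; 256
  samples gives about 1 Hz resolution at 250–256 Hz.  No detrending is
  applied (the notch leaves the mean near zero and only the power ratio
  matters).

A window is removed iff one of four criteria holds in **at least one
channel** (all inequalities strict, so boundary equality never selects):

1. MAFD \(> 4.5\,[\mathrm{median} + \mathrm{MAD}]\) of that channel's
   MAFD over all windows of the recording;
2. MAA \(> 150\) µV (PT150) — certainly not cortical;
3. \(100 < \mathrm{MAA} < 150\) µV (the *doubtful* range) **and**
   RFC \(> 1.5\,[\mathrm{median} + \mathrm{MAD}]\) of that channel's RFC
   — muscle contamination decides the doubtful case;
4. \(100 < \mathrm{MAA} < 150\) µV **and** an adjacent window was already
   selected by criteria 1–3.

The MAD here is the **unscaled** median absolute deviation (no 1.4826
factor).  Thresholds are computed per channel over the whole recording,
so the criteria are invariant to permuting windows.  Criterion 4 is a
single backward+forward sweep over the selections of criteria 1–3: it
does not iterate, so a chain of doubtful windows is not progressively
swallowed.  Its amplitude condition and the neighbour's selection may
come from different channels.  Consecutive selected windows fuse, and
intervals separated by at most 6 s (inclusive — the rule's phrasing does
not settle the boundary, and inclusive is the conservative reading for
artefact removal) fuse again.

The pipeline (`run_pipeline`) unions both detectors' intervals; where
they overlap, the sample is reported as `flatline`, since lost contact
explains the signal there.  Everything is deterministic: output depends
only on the input samples and the configuration.

## Synthetic data and what it shows

`simulation_spec()` / `generate_dataset()` produce seeded synthetic
recordings with ground truth: per-channel Gaussian noise shaped to a
\(1/f\) power spectrum (flattened below 0.5 Hz), scaled to 20 µV RMS —
the term-age background regime, with peaks below 100 µV in ≥ 99 % of 1-s
bins; flat events that hold the last pre-onset value exactly, optionally
flanked by one-sample deflections; and Tukey-tapered bursts, either
*movement* (2 Hz, peaks above PT150 unless the doubtful range is being
probed) or *muscle* (60 Hz — above the 50 Hz split but within the notch's
pass-band, and outside the 0.5–40 Hz band, so it is visible to RFC only).
The default study conditions are 9 channels at 250 Hz for 20 minutes,
two all-channel flats (3 s and 10 s) and six bursts, mirroring a
9-electrode clinical montage and the 20-min annotated segments used for
detector evaluation; 19 channels at 256 Hz are used where the
full-montage consensus count matters.

The generator emulates only the *threshold-relevant* structure of
neonatal EEG.  It has no sleep-state alternation (e.g., tracé alternant
discontinuity), no ECG or eye-movement artefacts, no electrode physics,
and its background is stationary.  Recovery results on it therefore show
that the decision logic is implemented correctly — every injected
all-channel flat ≥ 2 s is recovered in full, bursts above 200 µV reach a
sample-wise hit rate over 0.9 while a burst-free background loses under
5 % — but they do not predict clinical false-discovery rates, which on
real recordings are dominated by physiology the generator does not model.

## Evaluation tools

Detector output is scored sample-wise (duration-weighted) against
annotations: accuracy \((TP+TN)/N\), hit rate \(TP/(TP+FN)\) and false
discovery rate \(FP/(TP+FP)\), with undefined ratios reported as `NA`
rather than 0.  `sweep_windows()` tabulates these per window duration
(1–7 s), together with accuracy × hit-rate, the figure of merit used to
recommend the 2–3 s operating range; the package default is 3 s.  For
application-based validation, `multiclass_metrics()` scores a K-class
extended confusion matrix (overall accuracy, one-vs-all precision and
sensitivity and their unweighted means) and `classifier_confidence()`
computes the mean gap between the two highest class probabilities.
`epsilon_squared()` (\(E^2 = H(n+1)/(n^2-1)\) for a Kruskal–Wallis
\(H\)) and `eta_squared_z()` (\(\eta^2 = Z^2/n\) for a rank-sum \(Z\))
follow the usual rank-test conventions; the \(\eta^2\) form is a
convention choice, as the rank-sum effect size is often left unstated in
applied work.

## Numerical choices and degenerate inputs

* Time is 0-based, in seconds; sample \(i\) covers
  \([i/f_s, (i+1)/f_s)\); all interval sets are half-open, sorted, and
  disjoint per label, so mask/interval conversions are exact inverses on
  the sample grid.
* The consensus count uses `round()` (half-to-even); both published
  channel counts (14/19, 7/9) are reproduced.
* An all-zero window has RFC 0 by definition; single-window recordings
  cannot form the median+MAD thresholds and are rejected.
* EDF I/O quantizes to 16 bits over ±1000 µV (LSB ≈ 0.03 µV), wide
  enough for > 150 µV artefacts without clipping.
* Problem sizes in the test-suite recovery experiments: twenty 20-min
  9-channel recordings for the flat-line experiment and five 10-min
  recordings for the burst experiment — large enough for stable rates,
  small enough to run on a laptop in a couple of minutes.

## Known limitations

Thresholds are tuned to term-equivalent age; younger preterm EEG has
larger physiological amplitudes and would need a different PT100/PT150.
Pathological records (e.g., with seizures) may violate the criteria's
assumptions.  Only the two artefact families above are handled — ECG,
eye movement and isolated-channel failures need dedicated methods — and
bad channels present throughout a recording should be excluded before
detection, since a permanently flat channel distorts neither detector
but contributes nothing to consensus.
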