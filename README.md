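# eegartefacts

Automated detection and removal of the two predominant non-physiological
artefacts in multichannel neonatal EEG at term-equivalent age:

* **flat line segments** — lost contact between an electrode and the head
  box leaves the recorded signal exactly constant;
* **large amplitude fluctuations** — movement transients, often with
  accompanying muscle (EMG) activity.

Long neonatal EEG recordings must be cleaned of these before automated
analysis (sleep staging, seizure detection, brain-age estimation), and
doing so by visual inspection is slow and operator-dependent.  This
package implements a deterministic threshold-based detector for
researchers and engineers building neonatal EEG pipelines, together with
EDF input/output, interval/mask algebra, evaluation metrics, and a seeded
synthetic-EEG generator with ground-truth annotations.

## Method

Flat lines are found per channel from the second difference
z(n) = x(n+2) − 2x(n+1) + x(n): samples with |z| < 10⁻⁴ µV are flagged
when at least two occur within a 1-s bin, flagged samples ≤ 2.5 s apart
are grouped into candidate intervals, candidates are accepted only where
≥ round(0.75·C) of the C channels agree (14/19, 7/9), and accepted
intervals are padded by 1 s or 3 s per side depending on whether they
are at most or longer than 5 s.

Large amplitude fluctuations are found on non-overlapping windows
(default 3 s).  Per window and channel the detector computes
MAFD = max |x(n+1) − x(n)|, MAA = max |x|, and
RFC = P(f > 50 Hz)/P(f) (Welch PSD, Hamming sub-windows, 50 % overlap).
A window is removed iff, in at least one channel,

1. MAFD > 4.5·[median(MAFD) + MAD(MAFD)]  (channel-specific), or
2. MAA > 150 µV (PT150), or
3. 100 µV < MAA < 150 µV and RFC > 1.5·[median(RFC) + MAD(RFC)], or
4. 100 µV < MAA < 150 µV and an adjacent window was selected by 1–3,

with MAD the unscaled median absolute deviation.  Consecutive selected
windows fuse, as do intervals within 6 s of each other.  Amplitude
features use the notch (50 Hz) + band-pass (0.5–40 Hz) view; RFC uses
the notch-only view; flat-line detection uses the raw signal.  See the
methods vignette (`vignettes/artefact-detection-methods.Rmd`) for the
full rationale.

## Worked example

```r
library(eegartefacts)

# 20-min synthetic 9-channel recording with ground truth:
# two all-channel flats (3 s and 10 s) and six bursts
ds  <- generate_dataset(default_simulation_spec(seed = 7))
res <- run_pipeline(ds$recording)
res
#> <pipeline_result> 1200.0 s, 9 channels @ 250 Hz
#>   removed: 4.00% total (flatline 1.75%, large amplitude 2.25%)
#>   windows selected by criterion 1/2/3/4: 0/9/2/0
#>   clean segments kept: 8

res$artifacts
#>   start_s    end_s           label
#> 1      99  105.000 large_amplitude
#> 2     198  204.000 large_amplitude
#> 3     299  303.992        flatline
#> 4     450  456.000 large_amplitude
#> 5     600  603.000 large_amplitude
#> 6     697  712.992        flatline
#> 7    1050 1056.000 large_amplitude
```

Both injected flats (at 300 s and 700 s) are recovered with their
duration-dependent padding (1 s and 3 s per side), and every movement
burst above 150 µV is removed with its window context.  Scoring against
the ground truth, sample by sample:

```r
tm <- intervals_to_mask(ds$truth, 250, n_samples(ds$recording))
pm <- intervals_to_mask(res$artifacts, 250, n_samples(ds$recording))
cc <- confusion_from_masks(pm, tm)
c(accuracy(cc), hit_rate(cc), false_discovery_rate(cc))
#> 0.985 0.875 0.271
```

The hit rate below 1 here is by design: one of the six injected bursts
is a 60 µV muscle-only burst, which the amplitude criteria correctly
leave alone (it matters only when it coincides with doubtful 100–150 µV
amplitudes).  `sweep_windows()` tabulates accuracy / hit rate / FDR over
window durations 1–7 s; a command-line front end with `detect`,
`evaluate`, `simulate` and `sweep` verbs is installed at
`inst/cli/eegartefacts.R`.

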