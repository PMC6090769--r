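# eegbatch

Batch EEG preprocessing, segmentation, and spectral analysis in R.

## The problem

EEG studies increasingly pool recordings collected on different hardware:
the same longitudinal or multi-site dataset can mix sampling rates (250
and 500 Hz), electrode layouts (64- and 128-channel geodesic nets), mains
frequencies (50/60 Hz), and per-file event-tag transmission delays. Hand
scripting each file's quirks is error-prone and hard to reproduce.
**eegbatch** is a scriptable batch platform for exactly this situation: a
declarative run configuration selects an ordered menu of processing
stages, every file flows through them with per-file harmonization
(offsets, line noise, layout, recording-period selection), failures are
contained per file, and the run emits summary CSVs plus a complete
provenance ledger so any analysis can be re-run or audited later.

It is aimed at researchers who want automated, reproducible batch
processing without writing their own pipeline code — resting ("baseline")
EEG, event-related (stimulus-tagged) EEG, and "conditioned baseline" data
(baseline spans delimited by onset/offset tags, e.g. eyes open/closed)
are all supported.

## What it computes

**Preprocessing (continuous data).** Zero-phase windowed-sinc FIR
filtering (high-pass, low-pass, band-stop notch) with two safety rules: a
run whose resampling target `R` and low-pass cutoff `L` violate `R >= 2L`
is rejected up front (aliasing), and a file sampled below the low-pass
band has its filter stage skipped with a notice while the batch
continues. Resampling by linear interpolation with event-sample
remapping; re-referencing to the average, a single channel, or a channel
subset (bad channels stored as `NA` and excluded from every mean); and
mean, linear, or Kalman (local-level model + RTS smoother) detrending.

**Segmentation.** Baseline data is tiled into non-overlapping fixed-length
segments (remainders dropped; recording periods never concatenated).
Event data is epoched at `[t + start, t + end)` around each
offset-corrected stimulus tag. Artifact handling follows hand-editing
practice: either reject whole segments whose amplitude crosses a
threshold, or first mask the continuous data — every sample with
`|x| > threshold` in any channel is extended to the nearest zero-crossings
before and after it, and segments are tiled in the clean gaps. A
joint-probability criterion (z-scored per-segment log-likelihood under
each channel's empirical amplitude distribution, per channel and across
channels) flags improbable segments. Within-segment linear detrending,
sub-segment extraction and baseline correction are available after
segmentation.

**Spectral analysis.** Per-segment single-sided power spectra with
rectangular or Hanning windows, zero-padded to the next power of 2,
normalized per bin as

    P_k = 2 |X_k|^2 / (l * sr)        (factor 1 at DC and Nyquist)

with `l` the transform length and `sr` the sampling rate, so a
bin-centred cosine of amplitude 2 uV yields power 2.0 uV^2 at its bin and
the summed spectrum preserves total energy. A multitaper estimator
averages eigen-spectra over the first *k* Slepian (DPSS) tapers at
`NW = (k+1)/2`. Inter-trial phase coherence (ITPC) slides a
Hanning-tapered subwindow across the epochs and averages unit phasors
across trials,

    ITPC(f, t) = (1/n) * sum_k F_k(f, t) / |F_k(f, t)|

giving magnitude 0 for random phase and 1 for perfect phase locking.
Band-binned power (absolute, normalized, ln, log10) and per-channel ITPC
max/mean summaries are written as CSVs.

**Fixtures.** A seeded synthetic-EEG generator produces 1/f background,
oscillatory components, line noise, high-amplitude artifacts, and
oddball-style event streams with known ground truth, including a 20-file
mixed-rate/mixed-layout batch with per-file tag offsets of 0/8/18 samples
and a matching offset CSV — the whole pipeline is testable without any
data download. EDF/EDF+ files (with annotations) are read and written
directly.

## A worked example

```r
library(eegbatch)

spec <- synthSpec(nChannels = 16, samplingRate = 250, durationS = 60,
                  artifacts = data.frame(period = 1, start_s = c(12, 40),
                                         duration_s = 0.3, peak_uv = 180),
                  seed = 11)
rec <- generateRecording(spec)$recording
rec
#> EEGRecording: 16 channels (HydroCel GSN 128 1.0), 1 period(s), 60.0 s total @ 250 Hz
#>   data type: baseline; 0 event tag(s); 0 bad channel(s); line noise 60 Hz
#>   history: format

rec  <- filterRecording(rec, highpass = 1, lowpass = 80, notch = TRUE)
mask <- buildArtifactMask(rec, 100)
mask
#> ArtifactMask: 2 interval(s) over 1 period(s), threshold 100 uV

segs <- segmentMasked(rec, mask, 1)
segs
#> SegmentSet: 58 segment(s) of 250 sample(s) x 16 channel(s) @ 250 Hz (58 kept)

psd <- computePsd(segs, window = "hanning")
tab <- bandPower(psd, data.frame(name = c("theta", "alpha", "beta"),
                                 lo = c(4, 6, 13), hi = c(6, 13, 30)))
head(tab[order(tab$channel, tab$band), ], 6)
#>    channel  band power_abs power_norm power_ln power_log10
#> 17      E1 alpha     0.802     0.4078  -0.2210    -0.09599
#> 33      E1  beta     0.145     0.0739  -1.9295    -0.83799
#> 1       E1 theta     1.019     0.5183   0.0186     0.00809
#> 26     E10 alpha     0.689     0.3541  -0.3729    -0.16197
#> 42     E10  beta     0.138     0.0711  -1.9783    -0.85914
#> 10     E10 theta     1.118     0.5748   0.1114     0.04837
```

The two injected 180 uV artifacts were masked out to their surrounding
zero-crossings, so 58 (not 60) one-second segments survive; band power is
the across-segment mean per channel, normalized within the three defined
bands.

Batch runs are driven by a YAML configuration (inputs, ordered `stages`,
per-stage parameter blocks, per-module save flags, offset CSV, out
directory, overwrite flag, seed); `runBatch()` / `validateConfig()` are
the programmatic entry points, and `exec/eegbatch` is a thin CLI with
`run`, `validate` and `synth` subcommands (exit codes 0 ok / 1 config
error / 2 partial failure). Each run writes `out/power_summary.csv`,
`out/itpc_summary.csv`, `out/run_ledger.json` and `out/command_log.txt`.

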