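---
title: "Methods and design notes for eegbatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for eegbatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The data model

An `EEGRecording` holds one amplitude matrix (channels x samples, real
microvolts) per *recording period* — a contiguous span of continuously
recorded data. Gaps between periods represent times when no EEG was
recorded, so no operation in the package ever bridges them: filtering,
detrending and segmentation act strictly within periods, and outputs are
reported per period. Event tags live in a table (label, period, 0-based
sample, applied offset) and an append-only history records every module
run with its parameter set, so a file's full processing provenance
travels with the data.

Two indexing conventions coexist deliberately. *Sample* indices are
0-based and intervals are half-open `[start, end)`, because timing
arithmetic is then exact (`sample = time * rate`; an annotation at 10.0 s
in a 250 Hz file is sample 2500). *Channel* and *recording-period*
indices are 1-based, matching R's matrix and list semantics. Bad channels
are stored as `NA` rows and excluded from every average; they are never
silently dropped, so channel indexing stays stable across the pipeline.

The on-disk native container is a directory with a versioned JSON
metadata sidecar plus one raw little-endian float64 array per period.
This is a deliberate re-design rather than a clone of any existing
binary format: it is transparent, diff-able, language-neutral and
round-trips every field bit-exactly (including `NA` sentinels). EDF/EDF+
is the supported exchange format for continuous data; the reader and
writer are implemented directly (16-bit samples, one annotations channel
carrying timestamped annotation lists), and one unit test cross-checks a
written file against an independent Python EDF reader. EDF export
quantizes each channel to its own full 16-bit range, so re-import agrees
with the source to within one quantization step of the channel's
amplitude range.

# Harmonizing heterogeneous acquisitions

Multi-setup datasets differ in event-tag transmission delay, mains
frequency, layout, and usable recording periods. One CSV
(`file_id, offset_samples, line_noise_hz, layout_name, periods,
data_type`) carries all per-file overrides. Offsets are expressed in
samples at the file's original sampling rate and added to every tag
exactly once (a second application is an error); events shifted past a
period boundary are *dropped*, never clamped, because clamping would
fabricate timing. If resampling happens later, already-applied offsets
travel with the remapped event samples.

Two pure predicates guard common mistakes. The aliasing rule fails a run
configuration whenever the minimum post-resampling rate is below twice
the low-pass cutoff; the comparison is exact (no float tolerance), and a
boundary hit (exactly 2x) passes but is flagged, since a real filter's
transition band extends beyond its cutoff. The ICA sample-size rule
`s >= x * c^2` (default `x = 20`, the minimum of the commonly cited
20–30 range) is exposed for users planning decompositions downstream.

# Preprocessing

**Filtering.** All filters are odd-length symmetric (linear-phase)
windowed-sinc FIRs designed with a Hamming window, applied in a single
centred pass after reflection padding — for a symmetric FIR this is
exactly zero-phase, so no forward–backward pass is needed. Tap count
follows the Hamming rule `ntaps ~ 3.3 * sr / transition`, with transition
bandwidth `max(2, 0.25 * cutoff)` Hz for high/low pass and a quarter of
the stop-band width for the notch (a 2 Hz-wide notch needs a ~0.5 Hz
transition to reach a deep null at the line frequency). The filtering
contract is specified by attenuation, not by coefficient equality with
any other implementation: a tone two transition-widths into the stop band
is attenuated below 5% in steady state. Finite data means edge
transients within one group delay of each period boundary; the
reflection padding keeps them small but they are measurable, which is
why attenuation tests read the central portion of a long probe signal.
If any requested cutoff reaches the file's Nyquist frequency the whole
filter stage is skipped for that file with a logged notice and the
pipeline continues — heterogeneous batches should not die because one
file was sampled slowly.

**Resampling** is linear interpolation onto a uniform grid sharing the
first sample's timestamp (`floor((n-1) * target/source) + 1` samples).
Event samples are remapped by `sample * target / source` and rounded
half-up; round-half-up is used everywhere a time is converted to a
sample index, because the convention has to be fixed somewhere and
half-up keeps `x.5` mappings monotone. Upsampling is allowed but logged.

**Re-referencing** subtracts the per-timepoint mean of the reference set
(all good channels, one channel, or a subset). Bad channels never enter
a mean and referencing *to* a bad channel is an error, since it would
propagate its noise into every other channel.

**Detrending** offers mean and least-squares-line removal plus a Kalman
option for structured drift: a local-level state-space model (random-walk
level observed in white noise) estimated by a forward Kalman filter and
Rauch–Tung–Striebel smoother, with the trend taken as the smoothed level.
Only the ratio Q/R matters; it sets the smoother's cutoff at roughly
`sr * sqrt(Q/R) / (2*pi)` Hz. The default `1e-6` targets very slow drift
(~0.04 Hz at 250 Hz); the drift-recovery test uses `1e-4` (~0.4 Hz)
because its injected random walk (0.05 uV per step over 40 s) has most
of its energy around 0.1–0.4 Hz, while the 10 Hz probe oscillation sits
far above the cutoff and passes through with its amplitude intact. Users
should choose the ratio the same way: cutoff below the slowest activity
of interest, above the drift to be removed.

# Segmentation and artifact handling

Baseline data is tiled with non-overlapping windows of
`round(len_s * sr)` samples from each period's start; a trailing
remainder too short for a full segment is excluded. Event segments are
`[t + round(start_ms * sr/1000), t + round(end_ms * sr/1000))` around
each matching tag; windows that would leave the period are skipped and
counted. Conditioned-baseline spans pair each onset tag with the nearest
following offset in the same period; malformed sequences (an offset with
no onset, consecutive onsets, a trailing onset) are resolved by dropping
with a warning, never by inferring a span.

Amplitude-based artifact handling comes in two orders. *After*
segmentation, a segment is rejected if any good channel exceeds the
threshold anywhere in it — rejection only flips keep-flags, the data
stay. *Before* segmentation, the continuous data are masked: every
suprathreshold sample is extended, in its channel, to the nearest
zero-crossing at or before and at or after it, capturing the excursion's
full rise and fall the way a human editor would mark it. A
zero-crossing is the first sample that is exactly zero or of opposite
sign; with no crossing the mask runs to the period edge. The mask is the
union over channels, merged when intervals touch, and segments are then
tiled from the start of each clean gap (tiling restarts per gap; there
is no global phase). The threshold is two-sided (`|x| > threshold`) and
applied to the signal as passed in — no implicit detrending. The
implementation is O(n) over sign-runs and is verified, in the tests and
the acceptance script, against a literal brute-force outward scan on
hundreds of random signals.

Joint-probability rejection estimates, per channel, each segment's
log-likelihood under the channel's empirical amplitude distribution — a
100-bin histogram over all kept segments, probabilities floored at
`1/(10 N)` so empty bins do not produce `-Inf`. A segment is rejected
when the z-score of its log-likelihood across segments exceeds the
threshold (default 3) for any single channel, or when the z-score of its
channel-summed log-likelihood does. The estimator (bin count, floor) is
a declared design choice; the construct itself — unlikely segments are
probably artifact — is standard. Zero-variance channels are skipped, and
with fewer than 8 kept segments the statistic is too unstable, so the
operation warns and does nothing.

# Spectral analysis

Power uses the single-sided FFT convention `2 |X_k|^2 / (l * sr)` per
bin, with the doubling dropped at the DC and Nyquist bins. Applying the
factor 2 uniformly would double-count those two self-conjugate bins;
dropping it there makes the summed spectrum equal `sum(x^2)/sr` exactly
(Parseval), which the tests assert to well under 1%. Segments are
zero-padded with trailing zeros to the next power of 2; `l` is the
padded transform length by default, with the pre-padding segment length
available as an option (the choice scales absolute power, not spectral
shape). No window-gain compensation is applied for the Hanning window —
its peak power for a sinusoid is the rectangular window's times the
squared coherent gain (~1/4) — but an option restores it.

The multitaper estimator averages eigen-spectra over the first *k*
Slepian tapers with time–bandwidth `NW = (k+1)/2`, so one knob (the
taper count) fully determines the estimator: more tapers, lower variance,
wider main lobe. The tapers come from the standard symmetric tridiagonal
eigenproblem and are scaled to the rectangular window's energy so the
normalization contract matches the FFT path.

ITPC slides a Hanning-tapered subwindow (default 256 ms, hop half the
subwindow, i.e. overlapping windows) across the epochs; per channel,
frequency bin and window position it averages the trials' unit phasors
`F_k / |F_k|` (a zero-energy bin contributes a zero phasor). Identical
trials give magnitude exactly 1; a trial pair in antiphase gives 0; for
n independent uniform phases `E|ITPC|^2 = 1/n` exactly, which the
acceptance script checks at n = 8 over 10,000 replicates. Summaries
report per-channel max and mean magnitude over a user-selected
window-centre x frequency rectangle, the argmax location, and optionally
which channel of a named group (e.g. a frontocentral set) attains the
maximum.

# The batch layer

A run configuration is one declarative YAML file: inputs, ordered stage
list (format -> filter -> resample -> rereference -> detrend -> segment
-> psd/itpc; the order is enforced), per-stage parameter blocks,
per-module save flags, the offset CSV, the out directory, an overwrite
flag and a seed. Unknown keys are rejected rather than ignored.
`validateConfig()` returns findings without executing; requesting ITPC
on baseline data is a warning (the numbers would be computable but
stimulus-free), while an aliasing violation is an error that aborts
before any file is touched. Per-file failures are caught, logged in the
ledger with their error text, and do not halt the batch. Intermediates
of modules whose save flag is false are pruned at the end of the run;
pointing a later analysis-only run at a saved segment directory
reproduces the original summary CSVs. Named no-op hook points after each
stage let external cleaners (robust-referencing or ICA-class pipelines,
which this package deliberately does not re-implement) be registered
without changing the architecture. Summary CSVs are UTF-8, comma
separated, "." decimal, header mandatory; list-valued cells are
semicolon-joined; undefined power is an empty cell, not 0 or "NaN".
"Normalized power" divides by the channel's total over the *defined*
bands (not the whole spectrum), so it sums to 1 exactly when the bands
partition the axis.

# The synthetic fixtures: what they do and do not show

The generator emulates the structure of a heterogeneous longitudinal
infant-EEG dataset: 10 baseline + 10 auditory-oddball files, sampling
rates 250/500 Hz, 64/128-channel geodesic layouts, 60 Hz line noise,
per-file tag offsets of 0/8/18 samples, and oddball label proportions of
80/10/10% (standard/native/non-native). Signals are 1/f background
(spectrally shaped white noise, slope −1, ~8 uV SD), white sensor noise,
low-amplitude mains, optional narrowband components, triangular
high-amplitude excursions with exact ground-truth intervals, and — for
event files — a Hann-enveloped 6 Hz burst added 150–300 ms after every
*true* stimulus time with identical phase across trials, so phase
locking is present by construction. Stimulus trains are jittered
(±0.2 s around a 1.8 s base interval): with a strictly periodic train,
any background oscillation whose frequency divides the repetition rate
is itself phase-locked to the stimuli and would contaminate ITPC — the
jitter is what makes the background "random phase" in the stimulus
frame, as in real paradigm designs.

What passing tests on these fixtures show: the arithmetic, masking,
normalization, offsets and orchestration behave exactly as specified,
end to end, under realistic data sizes. What they do not show: anything
about real scalp topography (channels are statistically exchangeable;
there is no head-model forward simulation), real artifact morphology
(blinks and muscle are not triangular), or the behaviour of the external
cleaning pipelines this package exposes hook points for. Default
durations (30 s per file in the batch generator, 30–60 s in single-file
examples) are the package's chosen test scale; all counts and laws are
length-invariant.

# Numerical choices and degenerate inputs

* Round-half-up (`floor(x + 0.5)`) everywhere a time maps to a sample.
* Exact zero counts as a zero-crossing; sign changes without a zero mask
  one opposite-sign boundary sample on each side, symmetrically.
* Mask intervals are merged when overlapping *or* adjacent.
* Empty results are warnings, not errors, wherever the empty case is a
  legitimate data outcome (no matching events, everything masked, zero
  kept segments); they are errors where the operation is undefined
  (ITPC with fewer than 2 trials, an empty summary selection).
* Degenerate channels (zero variance) are skipped in the
  joint-probability statistic; all-NA (bad) channels propagate NA
  through spectra rather than being dropped.
* Filter tap counts are capped below the shortest period length so short
  recordings degrade gracefully rather than erroring.
* The bit-exactness contract of the native container and the end-to-end
  byte-determinism of batch CSVs are tested, not assumed.

# Known limitations

EDF import assumes one contiguous data span per file (discontinuous
EDF+D files are read as one period) and a single sampling rate across
ordinary signals. The Kalman detrender models a single random-walk level
per channel; polynomial or oscillatory trends belong to the other
detrend modes or to filtering. The joint-probability density estimator
is a fixed-bin histogram, adequate for gross outliers but not a
calibrated likelihood. ITPC subwindow taper and hop are fixed design
choices (Hanning, 0.5) exposed as parameters, not inferred from data.
Processing is single-threaded; the per-file loop is embarrassingly
parallel and a natural future extension.
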