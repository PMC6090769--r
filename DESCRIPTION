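Package: eegbatch
Title: Batch EEG Preprocessing, Segmentation, and Spectral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable batch-processing platform for heterogeneous EEG
    datasets. Harmonizes acquisitions that differ in sampling rate, electrode
    layout, line-noise frequency and event-tag offsets; conditions continuous
    recordings (zero-phase FIR filtering with Nyquist safety checks,
    interpolation resampling, average/single-channel/subset re-referencing,
    mean/linear/Kalman detrending); segments baseline, event-tagged and
    conditioned-baseline data with amplitude-threshold artifact handling
    before or after segmentation (zero-crossing extension masking) and
    joint-probability segment rejection; and computes per-segment power
    spectra (FFT windowed or multitaper) and inter-trial phase coherence,
    with band-binned CSV summaries and full run provenance. Includes a
    seeded synthetic-EEG fixture generator and an EDF/EDF+ reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'recording.R'
    'io-native.R'
    'io-edf.R'
    'formatting.R'
    'preprocess.R'
    'segmentation.R'
    'spectral.R'
    'reporting.R'
    'synthetic.R'
    'batch.R'
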