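Package: speechtrack
Title: Neural Tracking of Perceived Speech in Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("speechtrack", "developers", email = "speechtrack@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how cortical
    high-frequency-band (65-125 Hz) activity tracks the acoustic structure
    of perceived speech. Provides a synthetic-data generator that couples
    multichannel electrocorticography-like signals to an annotated
    soundtrack with known ground truth, signal preprocessing (notch
    filtering, common average referencing, Gabor-wavelet high-frequency-band
    extraction), auditory feature extraction (cochlear-style spectral
    envelope, autocorrelation pitch, sound on/off), labeled 4-second
    fragment construction, lag-resolved Spearman cross-correlation
    contrasts between speech and nonspeech conditions, and an ON/OFF
    regression suite with fragment-permutation null distributions,
    partial rank correlations, rank-based group comparisons and
    contingency-table controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
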