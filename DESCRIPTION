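Package: phaselock
Title: Spiking Auditory-Periphery Simulation with a Configurable Phase-Locking Limit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of the auditory periphery in which the
    upper frequency limit of auditory nerve phase locking is an explicit,
    adjustable parameter (the inner-hair-cell low-pass cutoff). Provides
    calibrated stimulus synthesis (tones, harmonic complexes, noises) on a
    sound-pressure scale, binaural cue imposition and estimation (ITD/ILD),
    psychoacoustic stimulus manipulations (tone vocoding, inharmonic jitter,
    speech-shaped and sinusoidally dB-modulated noise), a gammatone-filterbank
    cochlear model with fiber-type rate-level functions and binomial spike
    sampling, psychometric fitting and threshold estimation, human-model
    behavioral-similarity statistics, and executable experiment protocols
    with simple reference observers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
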