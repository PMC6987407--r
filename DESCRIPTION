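Package: spikecodec
Title: Perceptually Masked Spike Encoding and Decoding of Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An auditory neural codec that converts mono audio into sparse,
    precisely timed spike patterns and back. Audio is decomposed by a
    time-domain constant-Q cochlear filter bank, framed into a log-energy
    spectrogram, pruned by a psychoacoustic masking model (absolute hearing
    threshold, cross-channel simultaneous masking, and exponentially decaying
    temporal masking), and encoded with population threshold (level-crossing)
    coding. A matched synthesis filter bank reconstructs audio from spike
    events, and quality (RMSE, signal-to-distortion ratio) and spike-efficiency
    metrics quantify the cost of masking. Includes a seeded synthetic-audio
    fixture generator and a corpus-to-spike-dataset converter for building
    neuromorphic speech datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
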