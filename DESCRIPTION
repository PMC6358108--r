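Package: gstreams
Title: Hierarchical Stochastic-Network Model of Auditory Stream Segregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Trains and interrogates a hierarchical model of auditory scene
    analysis: a biomimetic cochlear filterbank maps sound to an auditory
    spectrogram, a sparse Gaussian-Bernoulli restricted Boltzmann machine
    learns local (simultaneous) spectro-temporal grouping cues, a bank of
    conditional RBMs over multiple temporal contexts learns sequential cues,
    and a Hebbian temporal-coherence layer binds coherent channels into
    auditory streams. Includes bit-reproducible generators for classic
    psychoacoustic streaming stimuli (two-tone sequences, ABA triplets,
    amplitude-modulated noise, harmonic tone complexes, moving ripples),
    modulation-transfer-function characterization with ripple probes,
    agglomerative clustering and lesioning of model units, and
    signal-detection readouts (d-prime, percent correct, buildup curves,
    Gaussian-mixture token identification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
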