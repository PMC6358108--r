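# gstreams

A trainable, hierarchical model of auditory stream segregation — how a
listener parses a sound mixture into separate perceptual streams — together
with the psychoacoustic experiment battery used to test it.

The model follows the classic *analysis-then-fusion* account of auditory
scene analysis:

1. **Peripheral stage** — audio at 8 kHz is mapped to an auditory
   spectrogram `S(t, f)`: 128 constant-Q (Q ≈ 4) log-spaced cochlear
   channels, spectral sharpening, half-wave rectification, 10 ms leaky
   integration.
2. **L1, simultaneous cues** — a sparse Gaussian–Bernoulli restricted
   Boltzmann machine with energy
   `E(x,h) = ½Σ(x_k−A_k)² − ΣB_l h_l − Σx_k h_l W_kl`, trained by
   contrastive divergence on 3-frame (384-dimensional) spectrogram patches,
   learns local spectro-temporal grouping cues (harmonicity, onsets, AM
   structure). Its weight columns become 3×128 filters `F(t,f)` applied
   convolutionally, followed by Tsodyks-style synaptic adaptation
   `da/dt = (1−a)/τ_a − α a r(t)`.
3. **L2, sequential cues** — a bank of conditional RBMs whose visible and
   hidden biases are linear functions of the last τ frames
   (τ ∈ 30–600 ms), trained by CD on L1 responses, applied linearly.
4. **L3, temporal coherence** — a Hebbian matrix `V` accumulated from
   centered channel co-activations, `V ← leak·V + r rᵀ`, applied
   multiplicatively `R̂_t = R_t V_t`: coherent channels bind into streams,
   anti-correlated channels are suppressed.

Streaming decisions use a signal-detection readout: Euclidean distances
between responses to a sequence and to the same sequence with a perturbed
final target, a calibrated noisy threshold, and `d′ = z(H) − z(F)`.

The package also ships bit-reproducible generators for every stimulus the
battery needs (two-tone sequences, ABA triplets, AM-noise triplets,
harmonic tone complexes in MBS/MBD designs, moving ripples, spectrally
matched noise, a synthetic vowel-token corpus and a synthetic
natural-sound training ensemble), modulation-transfer-function
characterization with ripple probes, agglomerative clustering of unit
tuning, and lesion controls (removing tagged unit clusters, switching off
adaptation or coherence).

## Worked example

Train the desk-scale model (64 L1 units, two cRBM contexts, a 10-minute
synthetic ensemble; a few minutes on one CPU) and run the two-tone
streaming experiment:

```r
library(gstreams)

model <- train_stream_model(scaled_config(seed = 1))
model
#> <stream_model>
#>   L1: sparse RBM, 64/64 units active (384-dim patches)
#>   L2: 2 cRBM contexts (60, 240 ms), 48 hidden units each
#>   L3: temporal coherence on (leak 0.990)

tt <- run_two_tone(model, seed = 1)
tt$summary[tt$summary$mode == "alternating",
           c("mode", "dF", "distance", "dprime")]
#>          mode dF distance dprime
#>   alternating  1     3.44   0.36
#>   alternating  3     3.65   0.25
#>   alternating  6    10.80   1.63
#>   alternating  9    12.53   1.87
#>   alternating 15    36.66   4.50
```

`distance` is the coherence-weighted relative distance (how strongly the
temporal-coherence layer amplifies the response difference produced by a
4% change of the final A tone), and `dprime` the detection sensitivity
after the calibrated noisy decision. Read: with alternating tones the
model's ability to track the A stream grows with the A–B separation —
1 semitone is heard as one fused stream (d′ ≈ 0.4), 15 semitones as two
segregated streams (d′ ≈ 4.5). The synchronous rows of the same table stay
fused at wide separations (d′ well below the alternating value at 15
semitones), the signature of temporal coherence.

Other paradigms: `run_buildup()`, `run_am_noise()`, `run_mbx()`,
`run_speech_synthetic()`, `characterize_model()` (MTFs + clustering +
tags), `run_lesion_suite()`. `run_pipeline()` trains from a config (or a
directory of WAVs) and writes a model plus manifest; thin CLIs are in
`inst/cli/` (`stimgen`, `gstreams`).

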