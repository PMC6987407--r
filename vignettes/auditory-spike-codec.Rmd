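---
title: "An auditory spike codec: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An auditory spike codec: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecodec)
```

# Overview

`spikecodec` encodes mono audio into sparse spike patterns through a chain
modelled on the auditory periphery — cochlear filtering, hair-cell energy
framing, psychoacoustic masking, threshold spike coding — and decodes
waveform-path patterns back to audio so that each sparsification step can
be priced in signal-to-distortion terms. This vignette records the model,
its assumptions, and the choices made where the design was genuinely open.

# Cochlear filter bank

The analysis front end is a bank of constant-Q FIR filters applied in the
time domain: channel `k` computes the sliding inner product of the signal
with its taps, window starting at the output sample, tail zero-padded so
every sub-band has the signal's length. The canonical preset (`"cq20"`,
`inst/extdata/cq20_filters.tsv`) has 19 constant-Q bands (Q ≈ 2.87, four
bands per octave from 200.2 Hz) plus one wide top band (centre 8000.5 Hz,
bandwidth 6949.2 Hz) treated as a deliberate catch-all for everything above
the last constant-Q band.

Each impulse response is a Hann-windowed cosine at the centre frequency.
The window support is tied to bandwidth, `M_k = round(α · fs / BW_k)` with
α = 1.5 by default, so narrow low-frequency bands get long taps (433
samples at 69.3 Hz bandwidth) and wide bands short ones. A windowed
sinusoid with bandwidth-matched support is the standard realization when
only centre frequencies and bandwidths are specified; the exact wavelet
family is not critical, and α is exposed for users who want narrower
(larger α) or shorter (smaller α) filters. Each filter is normalised to
unit magnitude response at its centre frequency.

Synthesis uses matched filtering: the analysis stage slides the taps
forward (transfer `conj(H)`), the synthesis stage convolves with the same
taps (transfer `H`), so each channel chain is zero-phase — `|H|²` — with no
net group delay, which makes sample-aligned fidelity metrics possible
without cross-correlation alignment. Because adjacent bands overlap
substantially (roughly −5 dB power at the neighbouring centre), per-channel
gains cannot be calibrated independently: the package solves the K×K system
`Σ_j g_j |H_j(f_i)|² = 1` over the centre frequencies once per bank. The
residual ripple of the summed chain between centre frequencies is about
±3 % over 250–4500 Hz, rising to −1 dB in the sparsely covered region
between the last constant-Q band and the catch-all band; this bounds the
round-trip SDR of off-centre tones at roughly 30 dB.

# Spectrogram

Sub-bands are framed with 30 ms windows advanced by 15 ms, and each frame
reports `10·log10(Σ x_q²)` (a decibel reading of the frame's energy; base
10). Silent frames are floored at `e_floor = −100 dB` rather than −∞.
Frame time stamps are window centres, in seconds, with 0-based sample
indexing internally. Note the energy is the *sum* over the window, not the
mean, so absolute dB values depend on the window length; the masking
defaults below are calibrated against this scale with full-scale signals in
mind.

# Masking model

Three components form the audibility decision per time-frequency bin.

**Absolute threshold.** The standard three-term approximation of the
hearing threshold in dB SPL. Internal energies are dB-FS-like, so a
calibration offset maps them onto SPL: `spl_offset = 90 dB` by default
(a full-scale sine is taken to be 90 dB SPL). This is a free calibration —
nothing in the digital signal fixes its physical playback level.

**Simultaneous masking.** Each bin spreads a two-slope triangular threshold
across channels: `O = 10 dB` below its own level at distance zero, falling
by 27 dB/band toward lower channels and 15 dB/band toward higher ones
(steeper downward spread, as in perceptual audio coders). The per-bin
surface is the maximum over all maskers and the absolute threshold. The
slopes are per critical band, not per Hz, and are configurable; tonality
estimation (tonal vs noise maskers) is deliberately out of scope.

**Temporal masking.** Per channel, a left-to-right scan: the first frame is
a peak; a frame `n` frames after the current peak is masked below
`cⁿ · p₁`, and becomes the new peak when it exceeds that threshold. The
decay is applied to the dB value itself by default (`scale = "db"`), which
reproduces the textbook hand-stepped example (energies 60, 40, 50, 20 with
c = 0.9 give thresholds 60, 54, 50, 45); a `"linear"` power-domain variant
is available. Two consequences of the literal multiplicative-dB rule are
worth knowing:

* it is not scale-invariant — thresholds depend on the absolute dB level of
  the content, so the `spl_offset`/frame-energy conventions above matter;
* for *negative* peak levels the threshold rises toward 0 dB as the decay
  shortens, so the "longer decay masks more" monotonicity holds only where
  the active bins are positive-energy (true of speech-scale material; the
  white-noise fixture sits below 0 dB and inverts it).

**Decay constant.** `c` is the calibration knob of the whole codec and is
tuned for hearing quality rather than fixed by theory. The package default
is `c = 0.3` per 15 ms frame, chosen once by the following procedure: over
the speech-like fixtures, pick the largest decay for which reconstructions
from perceptually masked spike trains still beat random deletion of the
same number of spikes. At `c = 0.3` the codec removes ≈ 39–48 % of spikes
on speech-like material while keeping the masked reconstruction within
≈ 5 dB of the unmasked one; by `c = 0.9` the decaying flank of every
syllable is masked (the threshold stays within 2 dB of the peak for several
frames at speech-scale energies) and masked reconstructions fall *below*
the random baseline, defeating the method's purpose. Users reproducing
corpus-level reduction rates should expect to retune `c` (and the spreading
offsets) per corpus.

Masking is all-or-nothing: bins below threshold are discarded entirely
(spike patterns carry no amplitude to re-quantize), ties `s = m` stay
audible, and a bin can never mask itself (the spread is ≥ `O` dB below the
masker's own level).

# Spike coding

**Pattern path** (`threshold_encode()`): the frame-energy trajectory of
each channel, min–max normalised per utterance to [0, 1], is scanned
against L = 15 uniform thresholds `θ_n = n/(L+1)`. Upward crossings fire
the level's onset neuron, downward crossings its offset neuron, and strict
interior local maxima fire a per-channel peak neuron. Crossing times are
linearly interpolated between frame centres; a trajectory touching a level
exactly counts as a crossing on the arrival side only, so onsets and
offsets strictly alternate per (channel, level). The default population is
20 × (15 + 15 + 1) = 620 neurons. The 31-neurons-per-channel accounting
(15 onset + 15 offset + 1 peak) is a documented choice — an onset-only
31-threshold reading of the same population is possible and the map is
fully configurable. Per-utterance normalisation makes patterns
amplitude-invariant, which suits classification; `"fixed-range"` mode is
available when absolute level matters.

**Waveform path** (`level_crossing_encode()`): each sub-band waveform is
scanned against L = 31 amplitude levels placed uniformly strictly inside
the channel's min–max range (interior placement avoids degenerate
single-touch crossings at the extremes); events carry sub-sample
interpolated times and the crossed level's amplitude. Channels with
numerically zero range emit nothing. This path is what reconstruction
uses — frame energies alone cannot recover carrier phase, which is why
`decode_subbands()` rejects pattern-path input outright instead of
synthesising noise-excited audio.

**Masking application** (`apply_mask()`): the Hadamard product of pattern
and audibility map. Frames overlap 50 %, so an event generally lies in two
frame windows; it is deleted only when *every* covering frame is masked.
(Deleting on the nearest frame alone clips the flanks of every masked
region and measurably hurts masked reconstructions.) Events outside the
framed range are assigned to the nearest frame with a warning.

**Baselines.** `latency_encode()` implements the classical
one-neuron-per-channel latency code (spike delay `(n − e)·T` within the
encoding window). `random_mask_baseline()` deletes a seeded uniform sample
of events, keeping exactly `floor(n·(1 − target))` of them (round-down, so
realized reduction never undershoots the target; bit-reproducible given the
seed, and the global RNG state is restored). `doubled_threshold_encode()`
keeps every second level of the base set — the energy-only masking control.

# Reconstruction

Per channel, the decoder interpolates linearly (or zero-order hold) through
the surviving (time, amplitude) events, zero outside the event support.
Event-free stretches longer than `gap_s = 30 ms` are decoded as silence —
the estimate ramps to zero within half a gap after the last event — because
dense level crossings accompany any signal-bearing stretch, so a long
silence between events means the channel was quiet or masked there;
bridging such gaps with a single chord injects spurious energy exactly
where the mask declared the signal inaudible. Estimates then pass through
the matched synthesis filters and the calibrated gains and are summed.

Design constants worth restating: interpolation default linear (zero-order
hold kept for comparison), silence decodes to silence, an empty pattern
decodes to digital silence, and the chain's zero net delay means metrics
need no alignment search.

# Fidelity and efficiency metrics

`rmse()` and `sdr()` implement the usual definitions on time-aligned
samples; an exact reconstruction reports the documented 300 dB cap instead
of +∞. `spike_stats()` reports spikes/second and the reduction percentage
`100·(1 − n_processed/n_raw)`. PESQ is a hook only: supply an external
implementation via `options(spikecodec.pesq = <function>)`; otherwise a
typed "unavailable" marker is returned and nothing else depends on it.

# Synthetic fixtures

`fixture_suite()` generates the 12-signal suite all cross-module properties
run on: four tones at interior centre frequencies, a two-tone
simultaneous-masking probe, a decaying-burst temporal-masking probe (30 ms
bursts, the trailing burst 20 dB down and 30 ms behind the masker), a
chirp, two seeded noise tokens, and three "vowel-like" tokens — three
damped harmonics near formant frequencies on a fundamental, under a
raised-cosine syllabic envelope at ≈ 5 syllables/s so that frame-energy
trajectories re-peak the way running speech does. All fixtures are mono
20 kHz, peak ≤ 1, bit-reproducible given the spec.

What they do *not* emulate: consonant transients, coarticulation, noise
robustness, room reverberation, or natural level variation. Passing the
suite therefore shows the codec's machinery is correct and its masking is
perceptually ordered on clean, stationary-ish material; it does not certify
corpus-level reduction rates or recognition accuracy, which depend on real
speech statistics and on per-corpus tuning of the masking constants.

# Problem sizes and numerical choices

The test-suite and acceptance runs use 0.3–1.0 s fixtures at 20 kHz,
level counts L ∈ {8, 16, 32, 64} for the fidelity sweep, L = 31 for
round trips, and a 2464-utterance synthetic manifest (11 labels × 224
repetitions of 0.15 s tokens) for dataset bookkeeping — sizes chosen so the
whole battery runs in a few minutes on one CPU while every property is
exercised end to end. Numerical tie-breaks worth knowing: crossings count
on the arrival side only; map ties (`s = m`) are audible; the temporal scan
treats the first frame as a peak; a new peak requires strictly exceeding
the running threshold; random deletion rounds down; FFT-based convolution
is padded to a power of two and matches the brute-force double loop to
≈ 1e−10.

# Known limitations

* The summed analysis–synthesis chain has a gain dip between the last
  constant-Q band and the catch-all band (≈ 4500–7000 Hz); tones there
  reconstruct ≈ 1 dB low.
* Temporal masking's multiplicative-dB rule is level-dependent (see above);
  content below 0 dB frame energy is masked on a different effective
  schedule than loud content.
* Reconstruction quality is bounded by FIR edge transients on short
  signals (≈ 43 ms of ringing per end from the lowest band), so SDR
  improves with signal length; steady-state fidelity is essentially exact.
* The random-deletion baseline is far gentler on this decoder (which keeps
  absolute level tags on every event) than on delta-style decoders that
  track level increments; SDR gaps between masked and random conditions are
  therefore a few dB here rather than tens of dB.
* The masking constants are calibrated at full-scale fixture levels;
  heavily attenuated recordings shift the dB scale and need a matching
  `spl_offset`/decay retune.
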