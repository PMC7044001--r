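---
title: "From adaptive-gain pixel words to compressed photon images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From adaptive-gain pixel words to compressed photon images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jfproc)
```

## The problem

JUNGFRAU is an adaptive-gain charge-integrating pixel detector used for
macromolecular crystallography (MX). Each of the 524 288 pixels of a module
(512 rows × 1024 columns) integrates charge during an exposure and reads
out a 16-bit word: two bits select one of three amplification modes — G0
(single-photon sensitive), G1, G2 (progressively coarser, extending the
dynamic range to roughly 10⁴ photons of 12.4 keV) — and fourteen bits carry
the digitized charge in arbitrary detector units (ADU). Unlike
photon-counting detectors, the raw readout is meaningless to
crystallography software: every pixel must be converted to energy or photon
counts using per-pixel, per-gain calibration constants, at rates of roughly
5 × 10⁹ pixels per second for an 8-module detector at 1.1 kHz. `jfproc`
implements that pipeline at desk scale: every stage is real and tested, but
problem sizes are chosen so the whole suite runs on one CPU in minutes.

## Conversion model

For a pixel reading `(g, adu)` the deposited energy is

```
E = (adu − pedestal[g]) · gain_factor[g]      [keV]
photons = E / beam_energy
```

The *pedestal* is the mean dark reading of that pixel at that gain; the
*gain factor* converts pedestal-subtracted ADU to keV. Gain factors are
measured once, before operation, and enter the pipeline as inputs
(`read_calibration()`); pedestals depend on the thermal state of the system
and must be measured in situ. The gain code `10` never occurs in the
encoding (only `00`, `01`, `11` are defined); the package treats it as an
invalid pixel: masked downstream, counted, never fatal.

The default synthetic constants anchor the two published endpoints of the
dynamic range at 12.4 keV: 1 ADU at G0 is about 0.005 photons
(`gain_g0 = 0.062` keV/ADU, i.e. ≈200 ADU per photon), and G2 saturation is
about 10⁴ photons. The G1 factor is their geometric mean, as only the
endpoints are pinned down. The ratio of largest value to smallest increment
is 2 × 10⁶, hence `dynamic_range_bits(10000, 0.005) = 21`: a 21-bit
integer covers the linear photon scale, and the package stores rounded
images as 32-bit integers with two sentinels (masked = −2³¹, which is R's
`NA_integer_` bit pattern; saturated = 2³¹ − 1).

## Pedestals and drift tracking

Pedestals for the low gains come from dedicated dark runs with the detector
forced to G1/G2 (`simulate_dark(..., gain = "G1")`,
`estimate_pedestal()`). The G0 pedestal comes from the frames recorded
before the shutter opens; `detect_beam_start()` finds the first illuminated
frame as the first whose total converted signal exceeds `factor` (default
5) times the rolling baseline of preceding totals. Because slow pedestal
drift inflates dark totals gradually, the multiplicative baseline absorbs
it; two cold-start guards (a minimum mean signal of 0.01 photons/pixel and
the dark-total noise predicted from the pedestal RMS map) keep the first
frames from false-triggering while still letting a genuinely bright first
frame trigger immediately.

During long exposures the G0 pedestal drifts with temperature, up to
~100 ADU (2.5 keV — a fraction of a photon, but half a photon of bias if
ignored). The published pipelines monitor and update pedestals during the
measurement without stating the update rule, so the tracker here is the
package's own design, chosen for fixed-point friendliness: an exponential
moving average with weight α = 1/128 (= 2⁻⁷, exactly representable in the
8 fractional bits of the 22-bit fixed-point pedestal), gated to pixels
reading G0 within k = 3 RMS of the current pedestal so photon hits
(≈200 ADU ≈ 42 RMS units) never contaminate the update. A single frame can
therefore never move a pedestal by more than α·k·RMS ≈ 0.11 ADU. For a
ramp of slope *s* ADU/frame the EMA steady-state lag is s(1−α)/α; at the
published worst case (100 ADU over 10⁴ frames, s = 0.01) that is 1.27 ADU
≈ 0.006 photons. The tests verify the measured lag stays below 2 ADU and
that converting tracked dark frames leaves a mean bias below 0.02 photons,
against ≈0.45 photons with tracking disabled — which is why tracking
exists. Whether G1/G2 pedestals drift too is not addressed in the source
material; the tracker follows G0 only.

## Fixed-point arithmetic emulation

The streaming-hardware conversion path is emulated in software with
integer-only arithmetic: the G0 pedestal as a 22-bit fixed-point value (14
integer + 8 fractional bits), all other constants as 16-bit values with a
per-map power-of-two scale chosen so the largest magnitude fills 15 bits
plus sign. Conversion is a subtract, a multiply and a rounding right-shift
straight to whole photons; intermediates stay below 2⁴⁰ and are held
exactly in doubles. Tests require the RMS difference against the
floating-point path (rounded to photons) to stay ≤ 0.5 photon on synthetic
diffraction — a pure quantization-error budget; the figure published for
real data (0.22 photon) depends on that data and is not asserted.

## Geometry

A module is built from 4 × 2 readout chips of 256 × 256 pixels (the
standard construction; the chip grid is configurable). Pixels adjacent to
internal chip boundaries are physically double-sized, so a module expands
to 514 × 1030 equal-sized output pixels: boundary pixels split into two,
chip-corner pixels into four. With two large rows and six large columns,
12 source pixels per module split four ways. The default convention
divides intensity equally (weights ½ and ¼), conserving integrated Bragg
intensities exactly; replication (weight 1) is available behind a flag
because integration programs differ in convention. Multi-module assembly
places expanded modules on a configurable grid with masked mechanical gaps
(default 36 rows / 8 columns — masks, not metrology).

## Transport

Frames travel as UDP-like datagrams that can be dropped (a flooded
receiver buffer loses packets irrecoverably) or reordered. The packet
schema is self-defined and versioned (the real detector layout is not
public): default payload 4096 pixels = 8192 bytes, 128 packets per module
frame. `assemble_frames()` tolerates arbitrary reordering within a bounded
window of 16 in-flight frames — the real-time constraint modeled as
memory, not time — emits incomplete frames with missing regions masked,
and accounts every packet: received + lost = emitted, exactly, in the
seeded tests.

## Rounding and compression

Converted images are rounded to a multiple *m* of the photon count
(`quantize()`, ties away from zero so ±x stay symmetric under the `keep`
negative policy). Rounding coarser than one photon costs data quality;
finer mostly costs bits. Negative counts — dark pixels under pedestal
noise — are kept, clipped to zero, or offset, because rotation-method
processing programs reject negative intensities while serial
crystallography software accepts them.

Lossless compression is the two-step scheme standard for diffraction
images: Bitshuffle (block-wise bit-plane transposition, 8 kB blocks for
LZ4, 64 kB for Zstd where longer blocks measurably help) followed by a
dictionary codec. The in-repo transform supports the canonical layout
(most significant plane first) and the byte-lane-grouped order used by the
HDF5 filter stream; framed `bslz4`/`bszstd` chunks follow the de-facto
filter framing (8-byte big-endian element count, 4-byte big-endian block
size, length-prefixed blocks) so they are decodable by standard filter
implementations — the test suite cross-checks byte-for-byte against an
independent NumPy reconstruction of the documented transform plus
numcodecs' LZ4/Zstd. LZ4, Zstd and zlib themselves are consumed from their
established C libraries, never re-implemented.

The error-bounded lossy codec (for the use case where a 336× compressed
dataset travels home on a laptop while full-precision data stays at the
facility) is the package's own design in the spirit of compressors for
scientific arrays: a per-row previous-value predictor, residual
quantization with step 2e (so |x̂ − x| ≤ e by construction), verbatim
escapes for row starts and irregular pixels (making constant rows exact
and masked pixels survive), and a Bitshuffle/Zstd entropy stage. The bound
is re-verified after decoding in tests for e ∈ {0.5, 1, 2, 4, 8}.

### What the compression fixture does and does not show

The "standard fixture" for compression trends is a full simulator pass —
Poisson photons from a radially falling diffuse background with a water
ring plus Bragg spots, 200 e⁻ long-integration read noise, raw words,
conversion — so pixel values carry realistic fractional content. On it,
bits/pixel falls strictly as *m* goes 1/8 → 8, and each extra bit of
precision costs 0.8–1.7 bits/pixel *except* the ½ → 1 step: the simulator
deliberately omits charge sharing (conversion is strictly per-pixel), so
converted counts sit within ~0.06 photons of integers and half-photon
precision carries almost no entropy. Real beamline data, with continuous
charge-shared energies, pays roughly 0.9 bits/pixel for every extra bit.
This is the main feature of real data the simulator does not emulate, and
absolute bits/pixel values here should not be compared against published
ones, which also depend on the 150 GB reference dataset.

## File format

Output mimics the Eiger writer dialect so existing MX tooling can read it:
`/entry/data/data_000001 …` with 1000 images per dataset, one frame per
chunk (1 × H × W), `image_nr_low`/`image_nr_high` attributes, int32 (or
float64) little-endian. Chunks are compressed *before* the HDF5 library
sees them and written with the direct chunk writer — the HDF5 library is
not thread safe, so hiding codecs inside its filter pipeline is avoided;
the filter entry (bitshuffle 32008, LZ4 32004, Zstd 32015, deflate 1) is
still recorded so plugin-equipped readers decode the files, and reads via
the regular filtered path are cross-checked in tests (for gzip against the
HDF5 library's own deflate — an implementation we do not control). Object
timestamp tracking is disabled so a seeded run is byte-reproducible.
Provenance that NXmx cannot express — rounding multiple, negative policy,
seed, calibration checksum — lives in attributes under `/entry/jfproc`;
full NXmx compliance is out of scope. Raw gain+ADU data is not kept by
default (`keep_raw = FALSE`): it is poorly compressible and rarely useful
downstream.

## Simulator defaults and desk-scale sizes

The simulator is the package's ground truth and follows the published
detector characteristics: 3500 e⁻ per 12.4 keV photon; 83 e⁻ RMS noise at
short integration (the default, giving the σ ≈ 4.7 ADU used throughout
the calibration tests) and 200 e⁻ at the long integration used for
rotation crystallography (used by the compression fixture); ~200 ADU per
photon at G0; pedestal drift up to 100 ADU as a spatially uniform ramp;
880 µs frame time and 100°/s rotation, hence 0.088° per image and 2045
images per 180°. Where the sources are silent the defaults are package
choices: gain switching at 90% of the 14-bit full scale (the real
breakpoints guarantee accuracy below Poisson uncertainty but are not
printed), per-pixel pedestal variation uniform ±50 ADU, and Gaussian spot
profiles parameterized by expected photons. Identical seeds give
bit-identical frames; all randomness derives from one seed per
configuration.

Tests and the acceptance script run the same algorithms on reduced frames
(typically 16×32 to 128×256 pixels, 10⁴ frames for drift scenarios, 10⁵
packets for transport) — per-pixel arithmetic is size-independent, and
full-module checks (the scalar-loop conversion oracle at 512 × 1024, the
constant-frame compression bounds at 524 288 pixels) are retained where
size matters.

## Numerical choices and degenerate inputs

Rounding is half-away-from-zero everywhere (quantization, fixed point) to
keep ±x symmetric. Pedestal estimation uses the sample standard deviation
(n − 1) and flags pixels that ever report a foreign gain, computing their
statistics from matching readings only; pixels never at the requested gain
get `NA` plus the flag. Empty dark runs error; a single frame is not
enough for an RMS. Gain factors may legitimately be negative (real G1/G2
slopes invert); validation only rejects zero. The tracker clamps pedestals
to the physical 14-bit range. `quantize()` rejects m ≤ 0, saturates values
beyond the int32 range to the sentinel and flags them. Chunk framing
handles block sizes that do not divide the element count (trailing partial
block, then raw tail elements that cannot fill a bit-plane octet).

## Known limitations

No charge sharing, pile-up, or sensor physics beyond Gaussian electronics
noise; no common-mode correction (unnecessary for MX); no spot finding or
veto beyond `frame_stats()`'s empty/strong flags; no real network I/O —
the transport stage models packet loss and reordering, not sockets; NXmx
master files are not written; crystallographic quality metrics (R factors,
anomalous signal) require external processing suites and real data, and no
claim about them is made or tested here.
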