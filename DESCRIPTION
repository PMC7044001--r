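Package: jfproc
Title: Adaptive-Gain Pixel Detector Data Pipeline for Macromolecular
    Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of the data-acquisition pipeline for
    JUNGFRAU adaptive-gain charge-integrating pixel detectors at
    macromolecular crystallography beamlines: decoding of the 16-bit
    gain+ADU pixel word, per-pixel pedestal estimation with drift tracking,
    conversion of raw frames to energy or photon counts (including a
    fixed-point arithmetic emulation), expansion of the oversized
    inter-chip pixels and multi-module assembly, frame summation,
    photon-count rounding, Bitshuffle-based lossless and error-bounded
    lossy compression, Eiger-dialect HDF5 output with pre-compressed
    direct chunk writing, a synthetic detector simulator so every stage is
    testable without beamline data, and analytic calculators for detector
    data rates and conversion memory traffic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: HDF5 (libhdf5), liblz4, libzstd, zlib
NeedsCompilation: yes
Config/testthat/edition: 3
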