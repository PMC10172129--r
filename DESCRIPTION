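Package: lsbrillouin
Title: Line-Scan Brillouin Microscopy Spectral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral-analysis pipeline for line-scan Brillouin microscopy
    (LSBM) with a virtually imaged phased array (VIPA) spectrometer.
    Provides VIPA calibration against rubidium D2 hyperfine reference
    lines, pixel-to-frequency remapping by spline interpolation,
    multi-order spectrum summation, separate Stokes and anti-Stokes
    Lorentzian peak fitting, and downstream Brillouin shift-map
    quantification (bilinear rescaling to fluorescence dimensions,
    overlay registration, median re-slice projections, masked region
    statistics and relative time series). A physics-based forward
    simulator generates synthetic spectrometer frames, calibration
    frames and embryo-like phantoms with known ground truth, so that
    every stage of the pipeline can be validated without instrument
    hardware: multi-order VIPA dispersion, rubidium-cell notch
    suppression of the Rayleigh line, instrument spectral broadening,
    and Poisson photon statistics with camera gain and read noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
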