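Package: cbfmap
Title: Pixelwise Cerebral Blood Flow Mapping from Dynamic-Contrast
    Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bolus-tracking analysis of time-series fluorescence image
    stacks acquired after an intravascular indocyanine-green injection.
    Per-pixel time-intensity curves are smoothed (Savitzky-Golay),
    interpolated (natural cubic spline) and reduced to four perfusion
    parameters: bolus arrival time, rising time of the first pass, mean
    transit time over a fixed post-arrival window, and a blood flow index
    (slope of the first peak). The package assembles 2D parametric maps
    with quality-control masking, extracts bregma-referenced regions of
    interest with contralateral mirroring, and runs the associated
    two-group comparisons. A synthetic phantom generator with analytic
    ground truth (gamma-variate first pass, recirculation peaks, camera
    noise, 12-bit quantization) makes every stage testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    png,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
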