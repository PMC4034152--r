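Package: ectospec
Title: Infrared Spectral Fingerprinting of Ectomycorrhizal Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of ectomycorrhizal fungal species on tree root
    tips from attenuated total reflectance Fourier-transform infrared
    (ATR-FTIR) absorbance spectra. Implements the chemotaxonomic workflow of
    Savitzky-Golay second-derivative preprocessing with vector normalization
    over diagnostic spectral windows, hierarchical cluster analysis with
    Euclidean distances and Ward's minimum-variance linkage, Fourier
    self-deconvolution for band narrowing, second-derivative peak picking
    with supplementary/missing-band comparison between sample groups, and a
    cellulose contamination screen. Ships a synthetic spectrum generator
    parameterized by published per-species band assignments so the full
    pipeline is testable without instrument data, plus readers and writers
    for wide-CSV spectra and a minimal JCAMP-DX subset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
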