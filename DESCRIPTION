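Package: WMIdetect
Title: Stochastic Transition-Model Detection of White Matter Injury in
    Neonatal MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects punctate white matter injury (WMI) in 2D T1-weighted
    MRI slices of very preterm neonates. White-matter intensities are
    histogram-stretched and quantized into a small state space; adjacent-pixel
    intensity transitions are modelled by a one-parameter geometric law whose
    decay rate is the unique root in (0,1) of a low-degree polynomial.
    Transitions with very low model probability mark candidate injury
    boundaries; boundaries at the white-matter margin are discarded and injury
    regions are grown from the brighter seed pixels by a similarity criterion.
    Includes evaluation machinery (accuracy-distance histograms, Bland-Altman
    agreement, binned area-difference tables), a synthetic phantom generator
    with known ground truth, readers and writers for NIfTI/PNG/TIFF slices and
    masks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    png,
    tiff,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
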