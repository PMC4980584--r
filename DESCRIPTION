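Package: dscaif
Title: Automated Arterial Input Function Selection and CBF Quantification
    for DSC-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative perfusion analysis of dynamic
    susceptibility contrast MRI (DSC-MRI). Implements a physics-based
    simulator of the contrast-agent bolus passage (static dephasing and
    diffusional narrowing relaxation regimes) for a three-compartment
    digital phantom with controlled partial-volume mixing and
    contrast-to-noise ratio; spatial independent component analysis for
    semi-automatic segmentation of the artery and the artery-surrounding
    tissue; z-score-map weighted extraction of the arterial input function;
    gamma-variate characterisation of candidate input functions
    (time-to-peak, arrival time, FWHM, peak height); and truncated
    singular-value-decomposition deconvolution with an adaptive,
    oscillation-index-driven truncation threshold, yielding cerebral blood
    flow maps in mL/100 g/min. Includes segmentation scoring against the
    phantom ground truth, regional CBF statistics, NIfTI input/output, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ica,
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
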