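Package: perfkit
Title: Deconvolution-Based CT and MR Brain Perfusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes cerebral perfusion parameter maps (CBF, CBV, MTT, TTP,
    TMAX, BAT, first moment, peak concentration) from dynamic CT or MR bolus
    series using indicator-dilution theory. Provides regularized algebraic
    deconvolution (truncated SVD and Tikhonov filtering on Toeplitz or
    block-circulant system matrices, with an equivalent Fourier-domain path
    and a model-based exponential-residue fit), regularization-parameter
    selection by fixed value, oscillation index, or L-curve corner detection,
    preprocessing of raw time-attenuation and time-signal series (baseline
    conversion, hematocrit correction, smoothing, masking, automated AIF
    selection, partial-volume rescaling), nondeconvolution estimators
    (maximum slope, AUC- and peak-ratio blood volume), and a digital
    perfusion phantom with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
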