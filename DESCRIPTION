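Package: ftirguide
Title: FTIR-Guided MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A multimodal imaging pipeline that uses Fourier transform infrared
    (FTIR) hyperspectral microscopy to guide MALDI mass spectrometry imaging
    (MSI). FTIR cubes are preprocessed (asymmetric least squares baseline,
    Savitzky-Golay first derivative, standard normal variate scaling, spectral
    window selection, edge-preserving denoising) and jointly segmented across
    sections by k-means++ clustering. Binary tissue shapes are registered onto
    the optical/MSI coordinate frame by similarity-transform mean-squared-error
    minimization, evaluated with the Dice coefficient, and segment masks are
    transferred across pixel grids. MALDI spectra are TIC-normalized, top-hat
    baseline corrected and peak picked against a supersmoother noise reference;
    segment-discriminating m/z features are ranked by an ROC-area or pooled
    t-statistic criterion. Transferred segments become acquisition regions of
    interest with data-load and acquisition-time reduction reports. A phantom
    generator produces paired FTIR/MSI datasets with known morphology, spectra
    and inter-modality transform for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    EBImage,
    xml2,
    jsonlite,
    yaml,
    png,
    tibble,
    dplyr,
    purrr,
    generics,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
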