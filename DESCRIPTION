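Package: lineprofiler
Title: Strand Distances and Protein Distribution Widths from Super-Resolution
    Images of Synaptonemal Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, unbiased measurement of strand-to-strand distances and
    protein-distribution widths in 2D super-resolution fluorescence images of
    synaptonemal complexes and similar twisted two-strand filaments. The
    pipeline blurs and Otsu-binarizes a guide channel, skeletonizes it to
    one-pixel centerlines, fits smoothing splines, selects in-plane (frontal
    view) regions by border flood fill, extracts cross-sectional intensity
    profiles perpendicular to the spline, measures per-profile peak-to-peak
    distances with sub-pixel parabolic refinement, and recovers the true
    strand separation by fitting a half-normal cutoff model to the distance
    histogram. Monomodal profiles are summarized by single-Gaussian widths
    (SD and FWHM). A synthetic renderer produces ground-truth helices,
    parallel ridges and binary shape fixtures so every stage is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
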