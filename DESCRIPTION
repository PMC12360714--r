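Package: phantomQA
Title: Fluorescence Phantom Analysis for Imaging-System Quality Assurance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterization of fluorescence imaging systems from images of
    solid reference phantoms: detection of fluorescent wells in dot-grid
    (uniformity/distortion) targets, fitting and normalization of fluorescence
    uniformity surfaces (tensor-product b-spline or thin-plate radial basis
    function), iso-maps and line profiles, local geometric distortion against a
    reference grid built from central wells, inverse-profile flat-field
    correction with flatness evaluation, and concentration-linearity analysis
    of nine-well dilution-series targets via a log-log power-law fit. Includes
    a synthetic phantom-image renderer with parametric illumination, radial and
    keystone distortion, PSF blur and noise, providing ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, graphics, mgcv, EBImage, tiff,
    png, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
biocViews: Software, QualityControl, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
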