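Package: cervimorph
Title: Morphometric Grading of Cervical Intraepithelial Neoplasia from
    Epithelium Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic morphometric analysis of cervical epithelium
    micrographs for objective grading of cervical intraepithelial neoplasia
    (CIN). Nuclei are segmented from 8-bit grayscale images, their Voronoi
    zones of influence approximate cytoplasm, a Delaunay triangulation of the
    geodesic zone centers yields the mean inter-nuclear edge, and a
    dilation/erosion coefficient derived from edge length and nuclear radius
    drives a morphological measurement of the differentiated epithelium
    compartment. Six parameters (epithelium area, mean nucleus area, mean
    zone of influence, differentiated area, total and upper nuclei
    chromaticism) are combined into three discriminant ratios and a
    calibrated 0-100 cervical score. A seeded synthetic epithelium generator
    with known ground truth replaces clinical biopsy images for testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
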