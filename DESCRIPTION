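Package: hepfract
Title: Fractal Morphometry and Neural-Network Classification of Liver
    Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computer-aided classification of liver histology micrographs
    from fractal morphometry. Segments hematoxylin-stained nuclei and
    CD31/CD34-immunolabeled vessels by hue-saturation thresholding in HSV
    colour space, computes per-element box-counting (Minkowski-Bouligand)
    fractal dimensions, aggregates them into per-image and per-case
    feature vectors, and classifies images as malignant or benign and
    malignant cases as hepatocellular carcinoma or liver metastasis with
    a two-stage feed-forward neural-network cascade trained by
    back-propagation. Includes confusion-matrix statistics and Cohen's
    kappa agreement diagnostics, plus a seeded synthetic-cohort generator
    with ground-truth masks so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
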