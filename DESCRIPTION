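Package: vinecloud
Title: Yield Parameter Estimation from 3D Point Clouds of Grapevine Rows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A phenotyping pipeline that derives grapevine yield parameters
    (number of grape bunches, number of berries, berry diameter) from colored
    3D point clouds of vineyard rows, such as those produced by multi-view
    stereo reconstruction. Provides PLY point-cloud input/output, preprocessing
    (HSV background removal, statistical outlier removal, moving-least-squares
    smoothing, minimum-distance subsampling), 125-bin surface feature
    histograms plus HSV color features, an import vector machine classifier
    with posterior probabilities, exact graph-cut label smoothing, two-stage
    connected-component bunch segmentation, randomized sphere-fitting berry
    detection (findBerries), evaluation metrics, and a synthetic grapevine
    scene generator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
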