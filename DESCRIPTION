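Package: phenonode
Title: Node Detection and Internode Length Estimation from Seedling Image
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures internode elongation of young seedlings from
    time-series RGB images. Pixels are classified into stem, leaf and
    background with a decision tree over 15 colour features from five
    colour spaces; the stem silhouette is thinned and skeleton branch
    points become candidate nodes; candidates are filtered by distance
    from a fitted main-stem line and by a bag-of-visual-words patch
    classifier (Harris corners, SIFT-style descriptors, k-means
    vocabulary, random forest); detections are clustered into node
    orders by affinity propagation on their y-coordinates and per-order
    node lines are fitted against capture time, from which internode
    lengths in millimetres are derived. Includes a synthetic seedling
    renderer with exact ground truth, evaluation metrics (recall,
    precision, relative error) and a leave-one-seedling-out protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tree,
    withr,
    yaml
Config/testthat/edition: 3
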