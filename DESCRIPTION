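Package: incaclust
Title: Distance-Based Cluster-Number Estimation and Typicality Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based tools for deciding how many clusters a data set
    contains, for detecting the absence of any cluster structure, and for
    testing whether a new unit is typical of a fixed partition or belongs to
    a previously unseen group. The core statistic is the squared orthogonal
    height of a unit above the hyperplane spanned by the cluster centres,
    computed directly from any dissimilarity matrix via geometric
    variabilities and proximity functions, so mixed continuous, binary and
    qualitative variables (with missing values) are supported through the
    Gower coefficient alongside Bhattacharyya, pairwise Mahalanobis and
    correlation distances. Includes a bootstrap typicality test with an
    allocation rule, a cluster-count index with noise-unit screening over
    partitions from medoid or agglomerative clustering, synthetic-data
    generators for module-structured expression and time-course profiles,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    MASS,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
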