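Package: tracktags
Title: Tracklet-Graph Tracking of Color-Tagged Insects in Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation-based multi-object tracking for groups of
    color-tagged insects filmed in a fixed arena. Frames are background
    subtracted and segmented into blobs that may contain one or several
    animals; blobs are linked across frames with a mask-overlap fast path
    and dense optical flow, organized into tracklets of constant animal
    composition, and arranged in a directed acyclic tracklet graph.
    Identifiable single-animal tracklets are labeled by a pluggable image
    classifier, and the identity composition of all remaining tracklets is
    inferred by greedy iterative propagation of ID constraints over the
    graph. Includes a synthetic-arena simulator with full ground truth, an
    exhaustive enumeration oracle for the propagation solver, per-ID
    trajectory export, and validation measures (assignment rate, assignment
    error with exact Clopper-Pearson confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
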