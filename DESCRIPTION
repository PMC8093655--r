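Package: trapcurate
Title: Camera-Trap Dataset Curation, Infusion Planning and Detector Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for curating wildlife camera-trap image datasets ahead of
    object-detector training and for scoring detector output afterwards.
    Removes near-duplicate frames with a structural similarity (SSIM)
    clustering algorithm, groups capture-event bursts by connected components
    over pairwise SSIM, plans deterministic 90/10 train/validation splits with
    incremental camera-trap "infusion" of a web-image pool and explicit
    negative-sample supplementation, reads and writes PASCAL VOC bounding-box
    annotations, and computes PASCAL VOC average precision and mAP over
    configurable confidence thresholds. Includes a synthetic fixture generator
    (textured scenes, near-duplicate bursts, simulated detection sets with
    known ground truth) so the whole pipeline is testable without image
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
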